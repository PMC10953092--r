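#' Run the full characterization pipeline from a configuration
#'
#' Orchestrates the single-stage tools over a directory of inputs and writes a
#' combined per-sample report. The configuration is a named list (or a path to
#' a JSON file with the same structure) with per-stage blocks; unknown
#' top-level keys are rejected, stages whose block is absent are skipped, and
#' any stage error aborts with a stage-named message.
#'
#' Blocks:
#' * `cohort`: `table` (cohort TSV)
#' * `msi`: `traces` (TSV), optional `tol_bp`, `rel_threshold`
#' * `methylation`: `plate` (TSV), optional `threshold`, `mode`
#' * `mutations`: `vcf`, `fasta`, `signatures` (TSV), `callable_mbp`
#' * `shape`: `table` (TSV), `sites` (FASTA), `promoter` (FASTA),
#'   `cpg_positions` (integer vector), optional `motif_start`
#' * `out_dir`: where `report.tsv`, `report.json` and `metadata.json` go
#'
#' @param config Named list or JSON file path.
#' @return The per-sample report `data.frame`, invisibly; also written to
#'   `out_dir` when given.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  known <- c("cohort", "msi", "methylation", "mutations", "shape", "out_dir")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop_bad("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_bad("stage '", name, "' failed: ", conditionMessage(e))
    })
  }
  need_file <- function(path, what) {
    if (is.null(path) || !file.exists(path)) {
      stop_bad("missing ", what, " file: ", path %||% "<unset>")
    }
    path
  }
  results <- list()
  metadata <- list(parameters = list())

  if (!is.null(config$cohort)) {
    results$cohort_summary <- stage("cohort", {
      summarize_cohort(read_cohort_table(
        need_file(config$cohort$table, "cohort table")))
    })
  }
  if (!is.null(config$msi)) {
    results$msi <- stage("msi", {
      tol <- config$msi$tol_bp %||% 1L
      thr <- config$msi$rel_threshold %||% 0.10
      metadata$parameters$msi <- list(tol_bp = tol, rel_threshold = thr)
      call_msi_samples(read_msi_traces(need_file(config$msi$traces, "trace")),
                       tol_bp = tol, rel_threshold = thr)
    })
  }
  if (!is.null(config$methylation)) {
    results$methylation <- stage("methylation", {
      thr <- config$methylation$threshold %||% 20
      mode <- config$methylation$mode %||% "pmr"
      metadata$parameters$methylation <- list(threshold = thr, mode = mode)
      methylight(read_qpcr_plate(need_file(config$methylation$plate, "plate")),
                 threshold = thr, mode = mode)
    })
  }
  if (!is.null(config$mutations)) {
    results$mutations <- stage("mutations", {
      genome <- Biostrings::readDNAStringSet(
        need_file(config$mutations$fasta, "reference FASTA"))
      names(genome) <- sub("\\s.*$", "", names(genome))
      variants <- read_vcf_minimal(
        need_file(config$mutations$vcf, "VCF"), genome)
      callable <- config$mutations$callable_mbp %||%
        (sum(Biostrings::width(genome)) / 1e6)
      metadata$parameters$mutations <- list(callable_mbp = callable)
      spectrum <- compute_spectrum(variants, genome)
      sig <- read_signature_matrix(
        need_file(config$mutations$signatures, "signature matrix"))
      list(spectrum = spectrum,
           signature = best_signature(spectrum, sig),
           tmb = compute_tmb(variants, callable))
    })
  }
  if (!is.null(config$shape)) {
    results$shape <- stage("shape", {
      table <- read_shape_table(need_file(config$shape$table, "shape table"))
      sites <- read_site_set(need_file(config$shape$sites, "site set"))
      env <- build_envelope(sites, table)
      prom <- Biostrings::readDNAStringSet(
        need_file(config$shape$promoter, "promoter FASTA"))
      seq <- as.character(prom[[1]])
      start <- config$shape$motif_start %||% 1L
      motif_seq <- substr(seq, start, start + env$site_length - 1L)
      cpg_global <- as.integer(config$shape$cpg_positions %||% integer(0))
      cpg_local <- cpg_global - start + 1L
      cpg_local <- cpg_local[cpg_local >= 1L & cpg_local < env$site_length]
      unmeth <- departure_score(predict_shape(motif_seq, table), env)
      meth <- departure_score(
        predict_shape(encode_methylation(motif_seq, cpg_local), table), env)
      list(unmethylated = unmeth, methylated = meth)
    })
  }

  report <- assemble_report(results)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_strict(report, file.path(config$out_dir, "report.tsv"))
    jsonlite::write_json(
      list(samples = report, metadata = metadata$parameters),
      file.path(config$out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  }
  attr(report, "results") <- results
  invisible(report)
}

# Join per-stage per-sample results into one report table.
assemble_report <- function(results) {
  samples <- character(0)
  if (!is.null(results$msi)) samples <- union(samples, results$msi$sample)
  if (!is.null(results$methylation)) {
    samples <- union(samples, results$methylation$samples$sample)
  }
  if (!length(samples)) samples <- "cohort"
  report <- data.frame(sample = samples, stringsAsFactors = FALSE)
  if (!is.null(results$msi)) {
    m <- results$msi
    report$msi_category <- m$category[match(report$sample, m$sample)]
    report$msi_n_unstable <- m$n_unstable[match(report$sample, m$sample)]
  }
  if (!is.null(results$methylation)) {
    ms <- results$methylation$samples
    i <- match(report$sample, ms$sample)
    report$cimp <- ms$cimp[i]
    report$cimp_n_methylated <- ms$n_methylated[i]
    report$mlh1_methylated <- ms$mlh1_methylated[i]
    report$mlh1_concordance <- ms$mlh1_concordance[i]
  }
  if (!is.null(results$mutations)) {
    report$tmb <- results$mutations$tmb$tmb
    report$tmb_high <- results$mutations$tmb$high
    report$top_signature <- results$mutations$signature$best
    report$top_signature_similarity <- results$mutations$signature$similarity
  }
  if (!is.null(results$shape)) {
    sh <- results$shape
    get <- function(tab, f, col) tab[tab$feature == f, col]
    report$shape_prot_departure_meth <-
      get(sh$methylated, "ProT", "mean_rank_deviation")
    report$shape_prot_departure_unmeth <-
      get(sh$unmethylated, "ProT", "mean_rank_deviation")
    report$shape_roll_departure_meth <-
      get(sh$methylated, "Roll", "mean_rank_deviation")
    report$shape_roll_departure_unmeth <-
      get(sh$unmethylated, "Roll", "mean_rank_deviation")
  }
  report
}
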