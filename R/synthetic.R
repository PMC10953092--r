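#' Synthetic SBS6-like and decoy signatures
#'
#' Deterministic construction (no RNG) of a small signature matrix for testing
#' and demonstration: `SBS6like` concentrates mass on C>T at NCG
#' trinucleotides (the mismatch-repair-deficiency pattern), plus clearly
#' distinct decoys (`Flat`, `CtoAheavy`, `TtoCheavy`, `TtoAheavy`). These are
#' synthetic stand-ins, not COSMIC signatures.
#'
#' @return 96 x 5 column-normalized matrix with canonical rownames.
#' @export
synthetic_signature_matrix <- function() {
  ctx <- sbs96_contexts()
  parts <- sbs96_parts(ctx)
  sub <- paste0(parts$ref, ">", parts$alt)
  sbs6 <- numeric(96)
  ncg_ct <- sub == "C>T" & parts$f3 == "G"
  sbs6[ncg_ct] <- 0.17
  sbs6[sub == "C>T" & !ncg_ct] <- 0.015
  sbs6[sbs6 == 0] <- (1 - sum(sbs6)) / sum(sbs6 == 0)
  flat <- rep(1 / 96, 96)
  c2a <- ifelse(sub == "C>A", 0.9 / 16, 0.1 / 80)
  t2c <- ifelse(sub == "T>C", 0.9 / 16, 0.1 / 80)
  t2a <- ifelse(sub == "T>A", 0.9 / 16, 0.1 / 80)
  mat <- cbind(SBS6like = sbs6, Flat = flat, CtoAheavy = c2a,
               TtoCheavy = t2c, TtoAheavy = t2a)
  rownames(mat) <- ctx
  sweep(mat, 2, colSums(mat), "/")
}

#' Generate a random reference sequence
#'
#' Bases are drawn i.i.d. at the stated GC fraction; deterministic per seed.
#'
#' @param length Sequence length (>= 1000).
#' @param gc GC fraction in `[0, 1]`.
#' @param seed Integer seed (mandatory).
#' @param name Contig name.
#' @param path Optional FASTA output path.
#' @return `Biostrings::DNAStringSet` with one contig.
#' @export
gen_reference_fasta <- function(length = 100000L, gc = 0.41, seed,
                                name = "chrS", path = NULL) {
  if (length < 1000L) stop_bad("length must be >= 1000")
  if (!is.numeric(gc) || gc < 0 || gc > 1) stop_bad("gc must be in [0, 1]")
  set.seed(seed)
  bases <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  genome <- Biostrings::DNAStringSet(setNames(paste(bases, collapse = ""), name))
  if (!is.null(path)) Biostrings::writeXStringSet(genome, path)
  genome
}

# index of genomic positions by pyrimidine-centered trinucleotide
pyrimidine_context_index <- function(genome) {
  tris <- c(outer(c(outer(c("A","C","G","T"), c("C","T"), paste0)),
                  c("A","C","G","T"), paste0))
  idx <- list()
  for (chrom in names(genome)) {
    s <- as.character(genome[[chrom]])
    L <- nchar(s)
    tri <- substring(s, seq_len(L - 2L), seq_len(L - 2L) + 2L)
    center <- substr(tri, 2, 2)
    key <- ifelse(center %in% c("C", "T"), tri, revcomp_chr(tri))
    pos <- seq_len(L - 2L) + 1L
    sp <- split(pos, key)
    for (k in names(sp)) {
      idx[[k]] <- rbind(idx[[k]],
                        data.frame(chrom = chrom, pos = sp[[k]],
                                   stringsAsFactors = FALSE))
    }
  }
  idx
}

#' Simulate SNVs from SBS96 category weights
#'
#' Each variant is drawn by sampling a category from `weights` and then a
#' uniformly chosen genomic position whose pyrimidine-centered trinucleotide
#' matches that category's context (positions on the purine strand are used
#' via the reverse complement). REF is always consistent with the genome.
#'
#' @param genome Named character vector or `DNAStringSet`.
#' @param n Number of SNVs.
#' @param weights Numeric vector of 96 nonnegative weights named by
#'   [sbs96_contexts()] (normalized internally).
#' @param seed Integer seed (mandatory).
#' @param path Optional VCF output path (written with [write_vcf_minimal()]).
#' @return Variant `data.frame` (`chrom`, `pos`, `ref`, `alt`, `class`).
#' @export
gen_variants <- function(genome, n, weights, seed, path = NULL) {
  genome <- as_genome(genome)
  ctx <- sbs96_contexts()
  if (is.null(names(weights))) names(weights) <- ctx
  if (!setequal(names(weights), ctx)) stop_bad("weights must be named by the 96 contexts")
  weights <- weights[ctx]
  if (any(weights < 0)) stop_bad("weights must be nonnegative")
  weights <- weights / sum(weights)
  set.seed(seed)
  out <- data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                    alt = character(0), class = character(0),
                    stringsAsFactors = FALSE)
  if (n == 0L) {
    if (!is.null(path)) write_vcf_minimal(out, path, genome)
    return(out)
  }
  idx <- pyrimidine_context_index(genome)
  parts <- sbs96_parts(ctx)
  tri_of <- paste0(parts$f5, parts$ref, parts$f3)
  draws <- sample(96L, n, replace = TRUE, prob = weights)
  counts <- tabulate(draws, 96L)
  seq_chars <- lapply(setNames(nm = names(genome)),
                      function(ch) as.character(genome[[ch]]))
  rows <- list()
  for (j in which(counts > 0L)) {
    pool <- idx[[tri_of[j]]]
    if (is.null(pool) || !nrow(pool)) {
      stop_bad("no genomic context available for category ", ctx[j])
    }
    pick <- pool[sample.int(nrow(pool), counts[j], replace = TRUE), , drop = FALSE]
    ref <- character(nrow(pick))
    for (ch in unique(pick$chrom)) {
      sel <- pick$chrom == ch
      ref[sel] <- substring(seq_chars[[ch]], pick$pos[sel], pick$pos[sel])
    }
    alt <- ifelse(ref == parts$ref[j], parts$alt[j],
                  chartr("ACGT", "TGCA", parts$alt[j]))
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = pick$chrom, pos = pick$pos, ref = ref, alt = alt,
      class = "SNV", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  if (!is.null(path)) write_vcf_minimal(out, path, genome)
  out
}

#' Simulate paired microsatellite electropherogram traces
#'
#' Each (sample, locus) gets a normal trace with the germline allele peak and
#' a geometric polymerase stutter ladder. With per-locus probability
#' `p_instable` the tumor acquires a novel allele shifted by 2-4 bp (either
#' direction) carrying its own stutter ladder on top of the residual germline
#' allele (tumor impurity); otherwise the tumor trace repeats the normal one.
#' A ground-truth sidecar records the instability labels.
#'
#' @param n_samples Number of samples.
#' @param p_instable Per-locus probability of instability in `[0, 1]`.
#' @param seed Integer seed (mandatory).
#' @param loci Locus panel (default [msi_panel()]).
#' @param stutter_ratio Geometric decay of the stutter ladder (default 0.35).
#' @param path,truth_path Optional TSV output paths.
#' @param sample_ids Sample identifiers (default \code{S001, S002, ...}).
#' @return A list: `traces` (long `data.frame`) and `truth`
#'   (`sample`, `locus`, `unstable`).
#' @export
gen_msi_traces <- function(n_samples, p_instable, seed, loci = msi_panel(),
                           stutter_ratio = 0.35, path = NULL, truth_path = NULL,
                           sample_ids = sprintf("S%03d", seq_len(n_samples))) {
  if (p_instable < 0 || p_instable > 1) stop_bad("p_instable must be in [0, 1]")
  if (length(sample_ids) != n_samples) stop_bad("need one sample id per sample")
  set.seed(seed)
  base_len <- setNames(c(121L, 118L, 140L, 158L, 172L, 149L)[seq_along(loci)], loci)
  ladder <- function(allele, height) {
    k <- 0:3
    data.frame(length_bp = allele - k, intensity = height * stutter_ratio^k)
  }
  merge_ladders <- function(...) {
    d <- do.call(rbind, list(...))
    agg <- stats::aggregate(intensity ~ length_bp, d, sum)
    agg[order(agg$length_bp), ]
  }
  trace_rows <- list()
  truth_rows <- list()
  for (i in seq_len(n_samples)) {
    s <- sample_ids[i]
    for (loc in loci) {
      L0 <- base_len[[loc]]
      normal <- merge_ladders(ladder(L0, 100))
      unstable <- runif(1) < p_instable
      tumor <- if (unstable) {
        shift <- sample(c(-4L, -3L, -2L, 2L, 3L, 4L), 1L)
        merge_ladders(ladder(L0, 60), ladder(L0 + shift, 80))
      } else {
        merge_ladders(ladder(L0, 100))
      }
      trace_rows[[length(trace_rows) + 1L]] <- data.frame(
        sample = s, tissue = "normal", locus = loc, normal,
        stringsAsFactors = FALSE)
      trace_rows[[length(trace_rows) + 1L]] <- data.frame(
        sample = s, tissue = "tumor", locus = loc, tumor,
        stringsAsFactors = FALSE)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        sample = s, locus = loc, unstable = unstable, stringsAsFactors = FALSE)
    }
  }
  traces <- do.call(rbind, trace_rows)
  truth <- do.call(rbind, truth_rows)
  rownames(traces) <- rownames(truth) <- NULL
  if (!is.null(path)) write_tsv_strict(traces, path)
  if (!is.null(truth_path)) write_tsv_strict(truth, truth_path)
  list(traces = traces, truth = truth)
}

#' Simulate a MethyLight qPCR plate from known methylation fractions
#'
#' Ct model with perfect doubling efficiency:
#' `Ct(methylation assay) = intercept - log2(fraction) + N(0, sigma)` and
#' `Ct(control assay) = intercept + N(0, sigma)`, so the noiseless recovered
#' percent methylation equals `100 * fraction`. Fraction 0 yields an
#' undetermined Ct. Fully methylated calibrator wells (fraction 1) are
#' included for every assay.
#'
#' @param fractions `data.frame` with `sample`, `tissue`
#'   (`tumor`/`normal`), `marker`, `fraction` in `[0, 1]`.
#' @param sigma Gaussian Ct noise in cycles (>= 0, default 0.2).
#' @param seed Integer seed (mandatory).
#' @param intercept Ct at full input (default 25 cycles).
#' @param replicates Wells per (sample, assay) (default 2).
#' @param path,truth_path Optional TSV output paths.
#' @return A list: `plate` (well table as from [read_qpcr_plate()]) and
#'   `truth` (the input fractions).
#' @export
gen_qpcr_plate <- function(fractions, sigma = 0.2, seed, intercept = 25,
                           replicates = 2L, path = NULL, truth_path = NULL) {
  if (sigma < 0) stop_bad("sigma must be >= 0")
  if (any(fractions$fraction < 0 | fractions$fraction > 1)) {
    stop_bad("fractions must be in [0, 1]")
  }
  set.seed(seed)
  rows <- list()
  add_wells <- function(sample, tissue, assay, role, true_ct) {
    for (r in seq_len(replicates)) {
      ct <- if (is.na(true_ct)) NA_real_ else true_ct + rnorm(1, 0, sigma)
      rows[[length(rows) + 1L]] <<- data.frame(
        sample = sample, tissue = tissue, assay = assay, role = role,
        ct = ct, replicate = r, stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(nrow(fractions))) {
    s <- fractions$sample[i]; tis <- fractions$tissue[i]
    mk <- fractions$marker[i]; f <- fractions$fraction[i]
    true_ct <- if (f == 0) NA_real_ else intercept - log2(f)
    add_wells(s, tis, mk, "methylation", true_ct)
  }
  for (combo in unique(paste(fractions$sample, fractions$tissue, sep = "\r"))) {
    st <- strsplit(combo, "\r", fixed = TRUE)[[1]]
    add_wells(st[1], st[2], "ACTB", "control", intercept)
  }
  for (mk in unique(fractions$marker)) {
    add_wells("M.SssI", "calibrator", mk, "methylation", intercept)
  }
  add_wells("M.SssI", "calibrator", "ACTB", "control", intercept)
  plate <- do.call(rbind, rows)
  rownames(plate) <- NULL
  plate$undetermined <- is.na(plate$ct)
  if (!is.null(path)) write_qpcr_plate(plate, path)
  if (!is.null(truth_path)) write_tsv_strict(fractions, truth_path)
  list(plate = plate, truth = fractions)
}

#' Methylation fractions for a paper-structured synthetic cohort
#'
#' Builds the marker-by-tissue methylation fraction map for `n_tumors`
#' tumor/normal pairs in which the MLH1 promoter (both probes) is
#' hypermethylated in every tumor while the other four CIMP markers vary, so
#' CIMP categories span negative/low/high — the dissociation of MLH1 status
#' from CIMP status. Default mix: 5 CIMP-high, 4 CIMP-low, 7 CIMP-negative
#' out of 16.
#'
#' @param n_tumors Number of tumors (default 16).
#' @param seed Integer seed (mandatory).
#' @param n_high,n_low Target numbers of CIMP-high and CIMP-low tumors.
#' @return A list: `fractions` (`data.frame` for [gen_qpcr_plate()]) and
#'   `truth` (`sample`, `cimp_expected`, `n_other_methylated`).
#' @export
gen_cohort_fractions <- function(n_tumors = 16L, seed,
                                 n_high = round(n_tumors * 5 / 16),
                                 n_low = round(n_tumors * 4 / 16)) {
  if (n_high + n_low > n_tumors) stop_bad("n_high + n_low exceeds n_tumors")
  set.seed(seed)
  others <- setdiff(cimp_panel(), "MLH1_p1")
  categories <- c(rep("high", n_high), rep("low", n_low),
                  rep("negative", n_tumors - n_high - n_low))
  rows <- list()
  truth <- list()
  for (i in seq_len(n_tumors)) {
    s <- sprintf("T%02d", i)
    n_other <- switch(categories[i],
                      high = sample(3:4, 1L),
                      low = 2L,
                      negative = sample(0:1, 1L))
    meth_others <- sample(others, n_other)
    markers <- c("MLH1_p1", "MLH1_p2", others)
    for (mk in markers) {
      meth <- mk %in% c("MLH1_p1", "MLH1_p2") || mk %in% meth_others
      tumor_f <- if (meth) runif(1, 0.55, 0.9) else runif(1, 0.0, 0.05)
      normal_f <- runif(1, 0.0, 0.03)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s, tissue = "tumor", marker = mk, fraction = tumor_f,
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s, tissue = "normal", marker = mk, fraction = normal_f,
        stringsAsFactors = FALSE)
    }
    truth[[i]] <- data.frame(sample = s, cimp_expected = categories[i],
                             n_other_methylated = n_other,
                             stringsAsFactors = FALSE)
  }
  list(fractions = do.call(rbind, rows), truth = do.call(rbind, truth))
}

#' Sample aligned binding sites around a consensus
#'
#' Per position, each site keeps the consensus base with probability
#' `1 - mut_rate`, else substitutes a uniformly chosen different base;
#' positions listed in `fixed` never mutate (e.g. an obligate CpG).
#'
#' @param consensus Consensus sequence (A/C/G/T).
#' @param n Number of sites.
#' @param seed Integer seed (mandatory).
#' @param mut_rate Per-position substitution probability (default 0.15).
#' @param fixed 1-based positions exempt from substitution.
#' @param motif Motif name.
#' @param path Optional FASTA output path.
#' @return Site-set list (`motif`, `sites`).
#' @export
gen_motif_sites <- function(consensus, n, seed, mut_rate = 0.15,
                            fixed = integer(0), motif = "synthetic_motif",
                            path = NULL) {
  consensus <- toupper(consensus)
  if (grepl("[^ACGT]", consensus)) stop_bad("consensus must be A/C/G/T")
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  cons <- strsplit(consensus, "", fixed = TRUE)[[1]]
  sites <- vapply(seq_len(n), function(i) {
    chars <- cons
    for (p in seq_along(chars)) {
      if (p %in% fixed) next
      if (runif(1) < mut_rate) {
        chars[p] <- sample(setdiff(bases, chars[p]), 1L)
      }
    }
    paste(chars, collapse = "")
  }, "")
  out <- list(motif = motif, sites = sites)
  if (!is.null(path)) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(setNames(sites, sprintf("site_%04d", seq_len(n)))),
      path)
  }
  out
}

#' Generate a complete synthetic pentamer shape table
#'
#' Covers all pentamers over the extended alphabet A/C/G/T/M/W. Values for a
#' methylated pentamer equal the values of its demethylated counterpart
#' (M read as C, W as G) plus declared effect shifts whenever the pentamer
#' contains an M or W: propeller twist shifted by `prot_shift` (negative by
#' default), roll by `roll_shift` (positive by default), minor groove width
#' and helix twist by their (default zero, i.e. marginal) shifts. Base values
#' are drawn once per plain pentamer from realistic ranges, deterministically
#' per seed.
#'
#' @param seed Integer seed (mandatory).
#' @param prot_shift,roll_shift,mgw_shift,helt_shift Methylation effect sizes
#'   (degrees / Angstrom); defaults -3, +3, 0, 0.
#' @param path Optional TSV output path.
#' @return A `shape_table` matrix (7776 pentamers).
#' @export
gen_shape_table <- function(seed, prot_shift = -3, roll_shift = 3,
                            mgw_shift = 0, helt_shift = 0, path = NULL) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  plain <- do.call(paste0, expand.grid(bases, bases, bases, bases, bases,
                                       stringsAsFactors = FALSE))
  np <- length(plain)
  base_vals <- cbind(
    MGW = rnorm(np, 5.0, 0.4),
    ProT = rnorm(np, -7.0, 2.5),
    HelT1 = rnorm(np, 34.5, 1.2),
    HelT2 = rnorm(np, 34.5, 1.2),
    Roll1 = rnorm(np, -0.5, 2.0),
    Roll2 = rnorm(np, -0.5, 2.0))
  rownames(base_vals) <- plain
  ext <- c(bases, "M", "W")
  all_pent <- do.call(paste0, expand.grid(ext, ext, ext, ext, ext,
                                          stringsAsFactors = FALSE))
  demeth <- chartr("MW", "CG", all_pent)
  vals <- base_vals[demeth, , drop = FALSE]
  rownames(vals) <- all_pent
  has_mark <- grepl("[MW]", all_pent)
  vals[has_mark, "ProT"] <- vals[has_mark, "ProT"] + prot_shift
  vals[has_mark, "Roll1"] <- vals[has_mark, "Roll1"] + roll_shift
  vals[has_mark, "Roll2"] <- vals[has_mark, "Roll2"] + roll_shift
  vals[has_mark, "MGW"] <- vals[has_mark, "MGW"] + mgw_shift
  vals[has_mark, "HelT1"] <- vals[has_mark, "HelT1"] + helt_shift
  vals[has_mark, "HelT2"] <- vals[has_mark, "HelT2"] + helt_shift
  out <- structure(vals, class = c("shape_table", "matrix"))
  if (!is.null(path)) write_shape_table(out, path)
  out
}

#' Generate a promoter sequence with an embedded CpG-bearing motif
#'
#' A random background sequence (the -1500..+500 promoter scan window by
#' default) with the motif consensus embedded at a recorded offset; the CpG
#' positions inside the embedded motif are returned for methylation encoding.
#'
#' @param length Promoter length (default 2000).
#' @param gc Background GC fraction (default 0.55, CpG-island-like).
#' @param consensus Motif consensus to embed (must contain at least one CpG).
#' @param seed Integer seed (mandatory).
#' @param motif_start 1-based insertion offset; default centers the motif.
#' @return A list: `seq`, `motif_start`, `motif_end`, `cpg_positions`
#'   (1-based, within the embedded motif), `consensus`.
#' @export
gen_promoter <- function(length = 2000L, gc = 0.55,
                         consensus = "GCCTGCGGCA", seed, motif_start = NULL) {
  if (!grepl("CG", consensus)) stop_bad("consensus must contain a CpG")
  set.seed(seed)
  bases <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  if (is.null(motif_start)) {
    motif_start <- as.integer((length - nchar(consensus)) %/% 2L) + 1L
  }
  motif_end <- motif_start + nchar(consensus) - 1L
  if (motif_start < 1L || motif_end > length) stop_bad("motif does not fit")
  bases[motif_start:motif_end] <- strsplit(consensus, "", fixed = TRUE)[[1]]
  seq <- paste(bases, collapse = "")
  cpg_local <- gregexpr("CG", consensus, fixed = TRUE)[[1]]
  list(seq = seq, motif_start = motif_start, motif_end = motif_end,
       cpg_positions = motif_start + as.integer(cpg_local) - 1L,
       consensus = consensus)
}

#' Emit a complete synthetic input bundle
#'
#' Runs every generator with one seed and writes FASTA, VCF, trace TSV, qPCR
#' plate TSV, site-set FASTA, shape-table TSV and signature TSV plus
#' ground-truth sidecars into a directory, so [run_pipeline()] can be
#' exercised end to end without downloads.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed (mandatory).
#' @param n_tumors Cohort size (default 16).
#' @param n_snvs SNVs per cohort VCF (default 2000).
#' @param p_instable Per-locus MSI instability probability (default 0.6,
#'   yielding mostly MSI-high samples).
#' @return Named list of file paths, invisibly.
#' @export
simulate_all <- function(out_dir, seed, n_tumors = 16L, n_snvs = 2000L,
                         p_instable = 0.6) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  genome <- gen_reference_fasta(120000L, 0.41, seed = seed, path = p("genome.fa"))
  sig <- synthetic_signature_matrix()
  write_signature_matrix(sig, p("signatures.tsv"))
  gen_variants(genome, n_snvs, sig[, "SBS6like"], seed = seed + 1L,
               path = p("cohort.vcf"))
  ids <- sprintf("T%02d", seq_len(n_tumors))
  gen_msi_traces(n_tumors, p_instable, seed = seed + 2L, sample_ids = ids,
                 path = p("traces.tsv"), truth_path = p("traces_truth.tsv"))
  cf <- gen_cohort_fractions(n_tumors, seed = seed + 3L)
  gen_qpcr_plate(cf$fractions, sigma = 0.2, seed = seed + 4L,
                 path = p("plate.tsv"), truth_path = p("plate_truth.tsv"))
  write_tsv_strict(cf$truth, p("cimp_truth.tsv"))
  table <- gen_shape_table(seed = seed + 5L, path = p("shape_table.tsv"))
  promoter <- gen_promoter(seed = seed + 6L)
  writeLines(c("# synthetic promoter with embedded motif",
               paste0("motif_start\t", promoter$motif_start),
               paste0("cpg_positions\t",
                      paste(promoter$cpg_positions, collapse = ","))),
             p("promoter_meta.txt"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(c(promoter = promoter$seq)), p("promoter.fa"))
  cpg_starts <- as.integer(gregexpr("CG", promoter$consensus, fixed = TRUE)[[1]])
  gen_motif_sites(promoter$consensus, 200L, seed = seed + 7L,
                  fixed = sort(unique(c(cpg_starts, cpg_starts + 1L))),
                  path = p("sites.fa"))
  invisible(list(genome = p("genome.fa"), signatures = p("signatures.tsv"),
                 vcf = p("cohort.vcf"), traces = p("traces.tsv"),
                 plate = p("plate.tsv"), shape_table = p("shape_table.tsv"),
                 promoter = p("promoter.fa"), sites = p("sites.fa")))
}
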