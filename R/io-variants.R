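#' Parse an HGVS-p style protein change token
#'
#' Accepted grammar: `p.<refAA><position><suffix>` where `refAA` is a single
#' amino-acid letter, `position` is an integer >= 1 and `suffix` is a single
#' amino-acid letter (missense), `*` (stop gain), or `_fs` appended to an
#' amino-acid letter (frameshift, e.g. `p.F173L_fs`). Anything else is
#' rejected.
#'
#' @param x Character vector of tokens such as `"p.G12D"`.
#' @return `data.frame` with columns `token`, `ref_aa`, `pos`, `alt_aa`
#'   (`"*"` for stop gain, the new residue otherwise) and logical `frameshift`.
#' @examples
#' parse_protein_change(c("p.G12D", "p.R273*", "p.F173L_fs"))
#' @export
parse_protein_change <- function(x) {
  m <- regmatches(x, regexec("^p\\.([A-Z])([0-9]+)([A-Z]_fs|[A-Z]|\\*)$", x))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop_bad("unparseable protein change: '", x[which(bad)[1]], "'")
  }
  pos <- as.integer(vapply(m, `[`, "", 3L))
  if (any(pos < 1L)) stop_bad("protein position must be >= 1")
  suffix <- vapply(m, `[`, "", 4L)
  fs <- grepl("_fs$", suffix)
  alt <- sub("_fs$", "", suffix)
  data.frame(token = x,
             ref_aa = vapply(m, `[`, "", 2L),
             pos = pos,
             alt_aa = alt,
             frameshift = fs,
             stringsAsFactors = FALSE)
}

#' Read a long-format variant table
#'
#' Expects a TSV with columns `sample`, `gene`, `protein_change`, `compartment`
#' (`somatic` or `germline`); optional genomic columns `chrom`, `pos` (1-based),
#' `ref`, `alt` are carried through when present. Protein changes are parsed
#' with [parse_protein_change()].
#'
#' @param path TSV file path.
#' @return `data.frame` with the input columns plus parsed `ref_aa`,
#'   `aa_pos`, `alt_aa`, `frameshift`.
#' @examples
#' v <- read_variant_table(dmmr_example("table2_variants.tsv"))
#' head(v)
#' @export
read_variant_table <- function(path) {
  raw <- read_tsv_strict(path)
  need <- c("sample", "gene", "protein_change", "compartment")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop_bad("variant table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw) == 0L) return(raw)
  if (!all(raw$compartment %in% c("somatic", "germline"))) {
    stop_bad("compartment must be 'somatic' or 'germline'")
  }
  parsed <- parse_protein_change(raw$protein_change)
  raw$ref_aa <- parsed$ref_aa
  raw$aa_pos <- parsed$pos
  raw$alt_aa <- parsed$alt_aa
  raw$frameshift <- parsed$frameshift
  raw
}

#' Write a long-format variant table
#'
#' @param variants `data.frame` with at least `sample`, `gene`,
#'   `protein_change`, `compartment`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  keep <- intersect(c("sample", "gene", "protein_change", "compartment",
                      "chrom", "pos", "ref", "alt"), names(variants))
  write_tsv_strict(variants[keep], path)
}

#' Read the packaged per-tumor variant fixture in wide (per-sample) layout
#'
#' The packaged transcription of the sequencing summary table has one row per
#' tumor (16 rows): a TMB column in mutations per megabase, per-gene somatic
#' columns and `<gene>_germline` columns holding `;`-separated protein-change
#' tokens (empty = no variant). This reader melts it to the long format of
#' [read_variant_table()].
#'
#' @param path Wide-layout TSV; defaults to the packaged fixture.
#' @return A list with `tmb` (`data.frame`: `sample`, `tmb`) and `variants`
#'   (long-format parsed `data.frame`).
#' @examples
#' tab2 <- read_table2_fixture()
#' mean(tab2$tmb$tmb)
#' @export
read_table2_fixture <- function(path = dmmr_example("table2_per_sample.tsv")) {
  wide <- read_tsv_strict(path)
  if (!all(c("sample", "tmb") %in% names(wide))) {
    stop_bad("wide variant fixture needs 'sample' and 'tmb' columns")
  }
  gene_cols <- setdiff(names(wide), c("sample", "tmb"))
  rows <- list()
  for (col in gene_cols) {
    germline <- grepl("_germline$", col)
    gene <- sub("_germline$", "", col)
    for (i in seq_len(nrow(wide))) {
      cell <- wide[[col]][i]
      if (is.na(cell) || !nzchar(cell)) next
      tokens <- trimws(strsplit(cell, ";", fixed = TRUE)[[1]])
      tokens <- tokens[nzchar(tokens)]
      if (!length(tokens)) next
      rows[[length(rows) + 1L]] <- data.frame(
        sample = wide$sample[i], gene = gene, protein_change = tokens,
        compartment = if (germline) "germline" else "somatic",
        stringsAsFactors = FALSE)
    }
  }
  variants <- do.call(rbind, rows)
  variants <- variants[order(variants$sample, variants$gene, variants$protein_change), ]
  rownames(variants) <- NULL
  parsed <- parse_protein_change(variants$protein_change)
  variants$ref_aa <- parsed$ref_aa
  variants$aa_pos <- parsed$pos
  variants$alt_aa <- parsed$alt_aa
  variants$frameshift <- parsed$frameshift
  list(tmb = data.frame(sample = wide$sample, tmb = wide$tmb,
                        stringsAsFactors = FALSE),
       variants = variants)
}
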