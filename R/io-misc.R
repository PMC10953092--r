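#' Read an aligned binding-site set from FASTA
#'
#' @param path FASTA of equal-length, uppercase DNA sequences (aligned binding
#'   sites, JASPAR-style).
#' @param motif Motif name; default the file base name.
#' @return A list with `motif` (name) and `sites` (character vector).
#' @export
read_site_set <- function(path, motif = tools::file_path_sans_ext(basename(path))) {
  seqs <- Biostrings::readDNAStringSet(path)
  sites <- toupper(as.character(seqs))
  if (!length(sites)) stop_bad("empty site set")
  if (length(unique(nchar(sites))) != 1L) {
    stop_bad("binding sites must all have the same length")
  }
  if (nchar(sites[1]) < 4L) stop_bad("binding sites must be >= 4 bp")
  if (any(grepl("[^ACGT]", sites))) stop_bad("site alphabet must be A/C/G/T")
  list(motif = motif, sites = unname(sites))
}

#' Read a pentamer DNA-shape query table
#'
#' TSV columns: `pentamer` (5 letters over the extended alphabet A,C,G,T,M,W
#' where M is 5-methylcytosine and W its paired guanine), `MGW` (minor groove
#' width, Angstrom), `ProT` (propeller twist, degrees), `HelT1`/`HelT2`
#' (helix twist of the two central steps, degrees), `Roll1`/`Roll2` (roll of
#' the two central steps, degrees). Lookup of a pentamer absent from the table
#' is an error, never a silent default.
#'
#' @param path TSV file path.
#' @return A `shape_table`: numeric matrix with pentamer rownames and columns
#'   `MGW`, `ProT`, `HelT1`, `HelT2`, `Roll1`, `Roll2`.
#' @export
read_shape_table <- function(path) {
  raw <- read_tsv_strict(path)
  need <- c("pentamer", "MGW", "ProT", "HelT1", "HelT2", "Roll1", "Roll2")
  if (!all(need %in% names(raw))) {
    stop_bad("shape table lacks column(s): ",
             paste(setdiff(need, names(raw)), collapse = ", "))
  }
  if (any(nchar(raw$pentamer) != 5L) || any(grepl("[^ACGTMW]", raw$pentamer))) {
    stop_bad("pentamers must be 5 letters over A/C/G/T/M/W")
  }
  if (anyDuplicated(raw$pentamer)) stop_bad("duplicate pentamer in shape table")
  mat <- as.matrix(raw[c("MGW", "ProT", "HelT1", "HelT2", "Roll1", "Roll2")])
  storage.mode(mat) <- "double"
  rownames(mat) <- raw$pentamer
  structure(mat, class = c("shape_table", "matrix"))
}

#' Write a pentamer shape table
#'
#' @param table `shape_table` matrix as returned by [read_shape_table()] or
#'   [gen_shape_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_shape_table <- function(table, path) {
  df <- data.frame(pentamer = rownames(table), unclass(table),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_strict(df, path)
}

#' Read a qPCR plate table
#'
#' TSV columns: `sample`, `tissue` (`tumor`, `normal` or `calibrator`),
#' `assay` (marker name), `role` (`methylation`, `control`, `expression` or
#' `reference`), `ct` (cycles; the token `undetermined` maps to `NA`), and
#' optional `replicate`.
#'
#' @param path TSV file path.
#' @return `data.frame` with numeric `ct` (`NA` = undetermined) and logical
#'   `undetermined`.
#' @export
read_qpcr_plate <- function(path) {
  raw <- read_tsv_strict(path)
  need <- c("sample", "tissue", "assay", "role", "ct")
  if (!all(need %in% names(raw))) {
    stop_bad("qPCR plate lacks column(s): ",
             paste(setdiff(need, names(raw)), collapse = ", "))
  }
  if (!all(raw$tissue %in% c("tumor", "normal", "calibrator"))) {
    stop_bad("tissue must be tumor/normal/calibrator")
  }
  if (!all(raw$role %in% c("methylation", "control", "expression", "reference"))) {
    stop_bad("role must be methylation/control/expression/reference")
  }
  ct_chr <- as.character(raw$ct)
  undet <- tolower(ct_chr) %in% c("undetermined", "undet", "na")
  ct <- suppressWarnings(as.numeric(ct_chr))
  if (any(is.na(ct) & !undet)) {
    stop_bad("unparseable Ct value: '", ct_chr[which(is.na(ct) & !undet)[1]], "'")
  }
  if (any(ct[!is.na(ct)] <= 0)) stop_bad("Ct values must be positive")
  raw$ct <- ct
  raw$undetermined <- undet | is.na(ct)
  if (!"replicate" %in% names(raw)) raw$replicate <- 1L
  raw
}

#' Write a qPCR plate table
#'
#' @param plate Plate `data.frame` (as from [read_qpcr_plate()] or
#'   [gen_qpcr_plate()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_qpcr_plate <- function(plate, path) {
  out <- plate[c("sample", "tissue", "assay", "role", "ct", "replicate")]
  out$ct <- ifelse(is.na(plate$ct), "undetermined",
                   format(plate$ct, trim = TRUE, digits = 10))
  write_tsv_strict(out, path)
}

#' Read electropherogram traces
#'
#' TSV columns: `sample`, `tissue` (`tumor`/`normal`), `locus`, `length_bp`,
#' `intensity`. Within one (sample, tissue, locus) trace the amplicon lengths
#' must be strictly increasing.
#'
#' @param path TSV file path.
#' @return `data.frame` of the trace points.
#' @export
read_msi_traces <- function(path) {
  raw <- read_tsv_strict(path)
  need <- c("sample", "tissue", "locus", "length_bp", "intensity")
  if (!all(need %in% names(raw))) {
    stop_bad("trace table lacks column(s): ",
             paste(setdiff(need, names(raw)), collapse = ", "))
  }
  raw$length_bp <- as.integer(raw$length_bp)
  raw$intensity <- as.numeric(raw$intensity)
  if (any(raw$length_bp <= 0L)) stop_bad("amplicon lengths must be positive")
  if (any(raw$intensity < 0)) stop_bad("intensities must be nonnegative")
  raw
}
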