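#' Read a mutational signature matrix
#'
#' TSV layout: first column holds the 96 SBS96 context labels (any order),
#' remaining columns one signature each, entries nonnegative fractions. Rows
#' are re-ordered to the canonical [sbs96_contexts()] order. Columns whose sum
#' deviates from 1 by less than `1e-3` are renormalized; larger deviations are
#' an error.
#'
#' @param path TSV file path.
#' @return Numeric matrix, 96 rows in canonical order, one column per
#'   signature, each column summing to 1.
#' @examples
#' sig <- read_signature_matrix(dmmr_example("signatures_synthetic.tsv"))
#' colnames(sig)
#' @export
read_signature_matrix <- function(path) {
  raw <- read_tsv_strict(path)
  if (ncol(raw) < 2L) stop_bad("signature matrix needs a label column plus >= 1 signature")
  labels <- raw[[1]]
  if (nrow(raw) != 96L) stop_bad("signature matrix must have 96 rows, got ", nrow(raw))
  canon <- sbs96_contexts()
  if (!setequal(labels, canon)) {
    stop_bad("context labels do not match the SBS96 catalog; first offender: ",
             setdiff(labels, canon)[1] %||% setdiff(canon, labels)[1])
  }
  mat <- as.matrix(raw[-1])
  storage.mode(mat) <- "double"
  if (any(mat < 0)) stop_bad("negative signature entry")
  rownames(mat) <- labels
  mat <- mat[canon, , drop = FALSE]
  sums <- colSums(mat)
  if (any(abs(sums - 1) >= 1e-3)) {
    j <- which(abs(sums - 1) >= 1e-3)[1]
    stop_bad("signature '", colnames(mat)[j], "' sums to ", format(sums[j]),
             "; more than 1e-3 from 1")
  }
  sweep(mat, 2, sums, "/")
}

#' Write a signature matrix
#'
#' @param mat 96-row matrix with canonical rownames.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_signature_matrix <- function(mat, path) {
  stopifnot(nrow(mat) == 96L)
  df <- data.frame(context = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_strict(df, path)
}
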