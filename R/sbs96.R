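#' Canonical SBS96 category labels
#'
#' The 96 pyrimidine-centered trinucleotide substitution categories in COSMIC
#' layout: substitution blocks C>A, C>G, C>T, T>A, T>C, T>G; within each block
#' the 5' flank cycles A,C,G,T slowest and the 3' flank A,C,G,T fastest, so the
#' block starts `A[C>A]A, A[C>A]C, A[C>A]G, A[C>A]T, C[C>A]A, ...`.
#'
#' @return Character vector of length 96, e.g. `"A[C>A]A"`.
#' @examples
#' head(sbs96_contexts())
#' @export
sbs96_contexts <- function() {
  bases <- c("A", "C", "G", "T")
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  unlist(lapply(subs, function(s) {
    unlist(lapply(bases, function(f5) paste0(f5, "[", s, "]", bases)))
  }), use.names = FALSE)
}

# Decompose "X[R>A]Y" labels into flanks, ref and alt.
sbs96_parts <- function(labels = sbs96_contexts()) {
  m <- regmatches(labels, regexec("^([ACGT])\\[([CT])>([ACGT])\\]([ACGT])$", labels))
  bad <- vapply(m, length, 1L) != 5L
  if (any(bad)) stop_bad("malformed SBS96 label(s): ", paste(labels[bad], collapse = ", "))
  data.frame(
    label = labels,
    f5  = vapply(m, `[`, "", 2L),
    ref = vapply(m, `[`, "", 3L),
    alt = vapply(m, `[`, "", 4L),
    f3  = vapply(m, `[`, "", 5L),
    stringsAsFactors = FALSE
  )
}

revcomp_chr <- function(x) {
  chartr("ACGT", "TGCA", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, ""))
}

# Map a genomic (trinucleotide, ref, alt) to its pyrimidine-centered SBS96
# label; purine-centered contexts are reverse-complemented.
sbs96_label <- function(tri, ref, alt) {
  stopifnot(nchar(tri) == 3L, substr(tri, 2, 2) == ref)
  if (ref %in% c("G", "A")) {
    tri <- revcomp_chr(tri)
    ref <- chartr("GA", "CT", ref)
    alt <- chartr("ACGT", "TGCA", alt)
  }
  paste0(substr(tri, 1, 1), "[", ref, ">", alt, "]", substr(tri, 3, 3))
}

#' Construct an empty SBS96 spectrum
#'
#' @return Named numeric vector of 96 zeros in canonical order.
#' @keywords internal
sbs96_empty <- function() setNames(numeric(96), sbs96_contexts())
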