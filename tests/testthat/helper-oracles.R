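# Independent brute-force oracles, kept free of the implementation paths they
# check.

# Spearman rho straight from the definition: average ranks, then the Pearson
# product-moment formula written out by hand.
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Benjamini-Hochberg step-up: adj_(i) = min over k >= i of p_(k) * m / k,
# capped at 1, mapped back to the input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Mid-rank percentile by direct counting over the reference values.
oracle_midrank <- function(ref, q) {
  100 * (sum(ref < q) + 0.5 * sum(ref == q)) / length(ref)
}

# A tiny deterministic shape table covering exactly the pentamers of the
# given sequences, with a fixed value per pentamer derived from its letters
# (so equal pentamers always agree, unequal ones almost surely differ).
toy_shape_table <- function(seqs, constant = NULL, strand_symmetric = FALSE) {
  pents <- unique(unlist(lapply(seqs, function(s) {
    starts <- seq_len(nchar(s) - 4L)
    substring(s, starts, starts + 4L)
  })))
  if (strand_symmetric) {
    pents <- unique(c(pents, dmmrkit::revcomp_extended(pents)))
  }
  score <- function(p) {
    v <- utils::head(as.integer(charToRaw(p)), 5)
    sum(v * c(1, 3, 7, 13, 29)) %% 97
  }
  vals <- vapply(pents, score, numeric(1))
  if (strand_symmetric) {
    # value shared between a pentamer and its reverse complement
    rc <- dmmrkit::revcomp_extended(pents)
    key <- pmin(pents, rc)
    vals <- vapply(key, score, numeric(1))
  }
  if (!is.null(constant)) vals[] <- constant
  mat <- cbind(MGW = 4 + vals / 50, ProT = -8 + vals / 20,
               HelT1 = 34 + vals / 40, HelT2 = 34 + rev(vals) / 40,
               Roll1 = vals / 30, Roll2 = -vals / 30)
  if (strand_symmetric) {
    # step features must swap under strand flip: use symmetric step values
    mat[, "HelT2"] <- mat[, "HelT1"]
    mat[, "Roll2"] <- mat[, "Roll1"]
  }
  rownames(mat) <- pents
  structure(mat, class = c("shape_table", "matrix"))
}
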