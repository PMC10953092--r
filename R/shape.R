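shape_features <- function() c("MGW", "ProT", "HelT", "Roll")

#' Encode symmetric CpG methylation into the extended alphabet
#'
#' Rewrites each listed CpG dinucleotide as `MW`, where `M` is
#' 5-methylcytosine on the forward strand and `W` the guanine paired to the
#' methylated cytosine of the opposite strand (symmetric CpG methylation;
#' hemimethylation is not modeled). Positions are 1-based CpG start positions.
#'
#' @param seq Plain DNA string over A/C/G/T.
#' @param cpg_positions Integer vector of 1-based positions at which a `CG`
#'   dinucleotide starts; every listed position must actually be a CpG.
#' @return A list of class `ext_seq`: `extended` (string over A/C/G/T/M/W),
#'   `plain`, `cpg_positions`.
#' @examples
#' encode_methylation("ACGT", 2)$extended  # "AMWT"
#' @export
encode_methylation <- function(seq, cpg_positions = integer(0)) {
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq)) stop_bad("sequence must be plain A/C/G/T DNA")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  cpg_positions <- as.integer(cpg_positions)
  for (p in cpg_positions) {
    if (p < 1L || p + 1L > length(chars)) {
      stop_bad("CpG position ", p, " outside the sequence")
    }
    if (chars[p] != "C" || chars[p + 1L] != "G") {
      stop_bad("position ", p, " does not start a CpG (found ",
               chars[p], chars[p + 1L], ")")
    }
    chars[p] <- "M"
    chars[p + 1L] <- "W"
  }
  structure(list(extended = paste(chars, collapse = ""), plain = seq,
                 cpg_positions = cpg_positions),
            class = "ext_seq")
}

#' Reverse complement over the extended alphabet
#'
#' A pairs T, C pairs G, and M (methylated C) pairs W (its opposite-strand
#' guanine mark).
#'
#' @param x Character vector over A/C/G/T/M/W.
#' @return Reverse-complemented strings.
#' @export
revcomp_extended <- function(x) {
  chartr("ACGTMW", "TGCAWM", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, "", USE.NAMES = FALSE))
}

#' Predict a DNA-shape profile by pentamer table lookup
#'
#' Slides a 5-bp window over the (possibly methylation-encoded) sequence.
#' Base-centered features (minor groove width MGW, propeller twist ProT) take
#' the value of the pentamer centered on each base, so they are defined for
#' positions `3 .. L-2` (1-based). Step-centered features (helix twist HelT,
#' roll Roll) live on the `L-1` base steps: each pentamer contributes its two
#' central steps, interior steps average the two covering pentamers, boundary
#' steps keep the single available value; defined steps are `2 .. L-3`.
#' To profile a motif in genomic context, pass the flank-extended sequence and
#' slice the central window from the result.
#'
#' @param seq An `ext_seq` from [encode_methylation()], or a plain string.
#' @param table A `shape_table` (see [read_shape_table()],
#'   [gen_shape_table()]). Every pentamer of the sequence must be present.
#' @return A list of class `shape_profile`: numeric vectors `MGW`, `ProT`
#'   (length `L`, `NA` at undefined edge positions) and `HelT`, `Roll`
#'   (length `L-1`, indexed by the step's left base, `NA` at edges), plus
#'   `length`.
#' @export
predict_shape <- function(seq, table) {
  s <- if (inherits(seq, "ext_seq")) seq$extended else toupper(seq)
  L <- nchar(s)
  if (L < 5L) stop_bad("sequence must be at least 5 bp")
  starts <- seq_len(L - 4L)
  pentamers <- substring(s, starts, starts + 4L)
  missing_p <- setdiff(unique(pentamers), rownames(table))
  if (length(missing_p)) {
    stop_bad("pentamer not in shape table: ", missing_p[1])
  }
  vals <- table[pentamers, , drop = FALSE]
  mgw <- prot <- rep(NA_real_, L)
  centers <- starts + 2L
  mgw[centers] <- vals[, "MGW"]
  prot[centers] <- vals[, "ProT"]
  helt_sum <- roll_sum <- numeric(L - 1L)
  nctr <- integer(L - 1L)
  # pentamer starting at w covers steps w+1 (central step 1) and w+2 (step 2)
  for (k in seq_along(starts)) {
    w <- starts[k]
    helt_sum[w + 1L] <- helt_sum[w + 1L] + vals[k, "HelT1"]
    roll_sum[w + 1L] <- roll_sum[w + 1L] + vals[k, "Roll1"]
    nctr[w + 1L] <- nctr[w + 1L] + 1L
    helt_sum[w + 2L] <- helt_sum[w + 2L] + vals[k, "HelT2"]
    roll_sum[w + 2L] <- roll_sum[w + 2L] + vals[k, "Roll2"]
    nctr[w + 2L] <- nctr[w + 2L] + 1L
  }
  helt <- ifelse(nctr > 0L, helt_sum / pmax(nctr, 1L), NA_real_)
  roll <- ifelse(nctr > 0L, roll_sum / pmax(nctr, 1L), NA_real_)
  structure(list(MGW = mgw, ProT = prot, HelT = helt, Roll = roll, length = L),
            class = "shape_profile")
}

#' Shape change upon CpG methylation
#'
#' Difference profile (methylated minus unmethylated) for a sequence with a
#' set of methylated CpGs. Nonzero entries are confined to positions whose
#' pentamer window overlaps a rewritten `M`/`W` base (locality).
#'
#' @param seq Plain DNA string.
#' @param cpg_positions 1-based CpG start positions to methylate.
#' @param table A `shape_table` covering the extended alphabet.
#' @return A list: per-feature difference vectors (same indexing as
#'   [predict_shape()]).
#' @export
methylation_delta <- function(seq, cpg_positions, table) {
  eseq <- encode_methylation(seq, cpg_positions)
  meth <- predict_shape(eseq, table)
  plain <- predict_shape(eseq$plain, table)
  out <- lapply(shape_features(), function(f) meth[[f]] - plain[[f]])
  names(out) <- shape_features()
  out$length <- meth$length
  out
}

#' Build a per-position percentile envelope from a binding-site set
#'
#' Predicts the shape profile of every site in an aligned, equal-length site
#' set and summarizes each position of each feature as mid-rank empirical
#' percentiles (5, 25, 50, 75, 95). The raw reference values are stored so
#' query ranks can later be computed against them.
#'
#' @param sites Character vector of equal-length sequences, or a site-set
#'   list from [read_site_set()].
#' @param table A `shape_table`.
#' @param min_sites Floor on the number of sites (default 20); fewer is an
#'   error unless `override = TRUE`.
#' @param override Allow fewer than `min_sites` sites.
#' @param motif Motif name to carry along.
#' @return A list of class `shape_envelope`: `motif`, `n`, `site_length`, and
#'   per feature a list with `positions` (defined indices), `ref` (n x
#'   positions matrix) and `percentiles` (5 x positions matrix, rows
#'   `P5`,`P25`,`P50`,`P75`,`P95`).
#' @export
build_envelope <- function(sites, table, min_sites = 20L, override = FALSE,
                           motif = NA_character_) {
  if (is.list(sites) && !is.null(sites$sites)) {
    motif <- if (is.na(motif)) sites$motif else motif
    sites <- sites$sites
  }
  if (length(unique(nchar(sites))) != 1L) {
    stop_bad("sites must all have the same length")
  }
  if (length(sites) < min_sites && !override) {
    stop_bad(length(sites), " sites is fewer than the floor of ", min_sites,
             "; pass override = TRUE to force")
  }
  profiles <- lapply(sites, predict_shape, table = table)
  features <- list()
  for (f in shape_features()) {
    mat <- do.call(rbind, lapply(profiles, `[[`, f))
    defined <- which(colSums(is.na(mat)) == 0L)
    ref <- mat[, defined, drop = FALSE]
    pct <- apply(ref, 2L, quantile, probs = c(.05, .25, .50, .75, .95),
                 type = 5, names = FALSE)
    rownames(pct) <- c("P5", "P25", "P50", "P75", "P95")
    features[[f]] <- list(positions = defined, ref = ref, percentiles = pct)
  }
  structure(c(list(motif = motif, n = length(sites),
                   site_length = nchar(sites[1])), features),
            class = "shape_envelope")
}

#' Departure of a query profile from a reference envelope
#'
#' At each defined position the query value's mid-rank within the stored
#' reference values is `100 * (count(ref < q) + 0.5 * count(ref == q)) / n`.
#' Two statistics are reported per feature: the mean normalized rank deviation
#' `mean(|rank - 50| / 50)` (0 iff the query sits at the per-position median
#' everywhere) and the envelope-exceedance fraction (share of positions with
#' the query strictly outside `[P5, P95]`). Both lie in `[0, 1]`.
#'
#' @param profile A `shape_profile` of the query (same site length as the
#'   envelope).
#' @param envelope A `shape_envelope` from [build_envelope()].
#' @return `data.frame` with one row per feature: `feature`,
#'   `mean_rank_deviation`, `exceedance`.
#' @export
departure_score <- function(profile, envelope) {
  if (profile$length != envelope$site_length) {
    stop_bad("query length ", profile$length, " does not match envelope site length ",
             envelope$site_length)
  }
  rows <- lapply(shape_features(), function(f) {
    env_f <- envelope[[f]]
    q <- profile[[f]][env_f$positions]
    if (anyNA(q)) stop_bad("query profile undefined at an envelope position (", f, ")")
    n <- envelope$n
    ranks <- vapply(seq_along(q), function(j) {
      refv <- env_f$ref[, j]
      100 * (sum(refv < q[j]) + 0.5 * sum(refv == q[j])) / n
    }, numeric(1))
    exceed <- q < env_f$percentiles["P5", ] | q > env_f$percentiles["P95", ]
    data.frame(feature = f,
               mean_rank_deviation = mean(abs(ranks - 50) / 50),
               exceedance = mean(exceed),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
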