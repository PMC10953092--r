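#' Default microsatellite locus panel
#'
#' Six rhesus microsatellite loci used for MSI typing.
#'
#' @return Character vector of six locus names.
#' @export
msi_panel <- function() {
  c("RheBAT25", "RheBAT26", "RheBAT40", "RheD10S197", "RheD18S58", "RheTGFbRII")
}

#' Detect peaks in an amplicon-length electropherogram
#'
#' A trace is a list of (amplicon length, intensity) points with strictly
#' increasing lengths. Peaks are local maxima whose intensity is at least
#' `rel_threshold` times the trace maximum; the relative filter suppresses the
#' polymerase stutter ladder.
#'
#' @param length_bp Integer vector of amplicon lengths (strictly increasing).
#' @param intensity Nonnegative intensities, same length.
#' @param rel_threshold Fraction of the maximum intensity a peak must reach
#'   (default 0.10, open interval (0, 1)).
#' @return Integer vector of peak lengths (bp).
#' @examples
#' detect_peaks(c(118L, 120L), c(8, 100))   # stutter filtered -> 120
#' @export
detect_peaks <- function(length_bp, intensity, rel_threshold = 0.10) {
  if (length(length_bp) != length(intensity) || !length(length_bp)) {
    stop_bad("length_bp and intensity must be nonempty and equal length")
  }
  if (is.unsorted(length_bp, strictly = TRUE)) {
    stop_bad("amplicon lengths must be strictly increasing")
  }
  if (any(intensity < 0)) stop_bad("intensities must be nonnegative")
  if (all(intensity == 0)) stop_bad("all-zero trace")
  if (rel_threshold <= 0 || rel_threshold >= 1) {
    stop_bad("rel_threshold must be in (0, 1)")
  }
  # compare only to bp-adjacent trace points: a stutter ladder climbs in 1-bp
  # steps, while alleles separated by a gap stand as their own maxima
  at <- function(l) {
    i <- match(l, length_bp)
    ifelse(is.na(i), -Inf, intensity[i])
  }
  is_peak <- intensity >= at(length_bp - 1L) & intensity >= at(length_bp + 1L) &
    intensity >= rel_threshold * max(intensity)
  as.integer(length_bp[is_peak])
}

#' Call one microsatellite locus from paired peak sets
#'
#' Overlays the healthy and tumor peak sets: the locus is `unstable` iff the
#' tumor shows at least one novel amplicon length, i.e. a peak farther than
#' `tol_bp` from every normal peak. Loss of a normal allele alone (LOH) does
#' not trigger instability.
#'
#' @param normal_peaks,tumor_peaks Integer vectors of peak lengths (bp) for
#'   the same locus; both nonempty.
#' @param tol_bp Matching tolerance in bp (default 1, the sizing resolution of
#'   chip electrophoresis).
#' @param locus Locus name carried into the call.
#' @return A list: `locus`, `status` (`"stable"`/`"unstable"`), `evidence`
#'   (novel tumor peak lengths, empty when stable).
#' @examples
#' call_locus(120L, c(120L, 116L))$status
#' @export
call_locus <- function(normal_peaks, tumor_peaks, tol_bp = 1L, locus = NA_character_) {
  if (!length(normal_peaks) || !length(tumor_peaks)) {
    stop_bad("both peak sets must be nonempty")
  }
  novel <- tumor_peaks[vapply(tumor_peaks, function(p) {
    min(abs(p - normal_peaks)) > tol_bp
  }, logical(1))]
  list(locus = locus,
       status = if (length(novel)) "unstable" else "stable",
       evidence = as.integer(novel))
}

#' Classify a sample's MSI status from per-locus calls
#'
#' 0 unstable loci of the panel gives `MSS`, exactly 1 gives `MSI-low`, and 2
#' or more give `MSI-high`. When fewer loci than `panel_size` were evaluated
#' the category is still computed but flagged `partial`.
#'
#' @param calls List of per-locus calls from [call_locus()].
#' @param panel_size Size of the full panel (default 6).
#' @return A list: `n_unstable`, `n_evaluated`, `category`
#'   (`"MSS"`/`"MSI-low"`/`"MSI-high"`), `partial`, and the per-locus `calls`.
#' @export
classify_msi <- function(calls, panel_size = 6L) {
  if (!length(calls)) stop_bad("no locus calls")
  statuses <- vapply(calls, `[[`, "", "status")
  n_unstable <- sum(statuses == "unstable")
  n_evaluated <- length(calls)
  category <- if (n_unstable == 0L) "MSS"
  else if (n_unstable == 1L) "MSI-low"
  else "MSI-high"
  list(n_unstable = n_unstable, n_evaluated = n_evaluated,
       category = category, partial = n_evaluated < panel_size,
       calls = calls)
}

#' Call MSI for every sample in a trace table
#'
#' Runs [detect_peaks()], [call_locus()] and [classify_msi()] over a long
#' trace table with paired `normal` and `tumor` tissues per (sample, locus).
#'
#' @param traces Trace `data.frame` from [read_msi_traces()] or
#'   [gen_msi_traces()].
#' @param tol_bp Peak-matching tolerance (default 1 bp).
#' @param rel_threshold Relative peak-intensity threshold (default 0.10).
#' @param panel_size Full panel size (default 6).
#' @return `data.frame`: one row per sample with `sample`, `n_unstable`,
#'   `n_evaluated`, `category`, `partial`, plus a list column `locus_calls`.
#' @export
call_msi_samples <- function(traces, tol_bp = 1L, rel_threshold = 0.10,
                             panel_size = 6L) {
  samples <- unique(traces$sample)
  rows <- lapply(samples, function(s) {
    sub <- traces[traces$sample == s, ]
    loci <- unique(sub$locus)
    calls <- list()
    for (loc in loci) {
      nt <- sub[sub$locus == loc & sub$tissue == "normal", ]
      tt <- sub[sub$locus == loc & sub$tissue == "tumor", ]
      if (!nrow(nt) || !nrow(tt)) next
      np <- detect_peaks(nt$length_bp, nt$intensity, rel_threshold)
      tp <- detect_peaks(tt$length_bp, tt$intensity, rel_threshold)
      calls[[loc]] <- call_locus(np, tp, tol_bp = tol_bp, locus = loc)
    }
    res <- classify_msi(calls, panel_size = panel_size)
    data.frame(sample = s, n_unstable = res$n_unstable,
               n_evaluated = res$n_evaluated, category = res$category,
               partial = res$partial, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
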