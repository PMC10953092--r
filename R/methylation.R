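#' CIMP marker panel
#'
#' The five promoter methylation markers of the CIMP panel. MLH1 is probed by
#' two independent assays (`MLH1_p1`, `MLH1_p2`); only probe 1 contributes to
#' the CIMP classification, probe 2 is confirmation-only.
#'
#' @return Character vector of the five panel markers (with `MLH1_p1`).
#' @export
cimp_panel <- function() {
  c("MLH1_p1", "CACNA1G", "CDKN2A", "CRABP1", "NEUROG1")
}

#' Percent methylation from normalized Ct values (MethyLight/PMR convention)
#'
#' Input-normalized delta-Ct is the methylation-specific Ct minus the Ct of a
#' methylation-unspecific control assay probing a CpG-free region (ACTB).
#' Percent methylation is then referenced to a fully methylated calibrator:
#' `100 * 2^-(dct_sample - dct_calibrator)`. An undetermined
#' methylation-specific Ct means no detectable methylated template and maps to
#' 0 %; an undetermined control Ct invalidates the measurement (error). Values
#' above 100 are clipped, with the raw value retained.
#'
#' @param dct_sample Sample delta-Ct (cycles), or `NA` if the
#'   methylation-specific Ct was undetermined.
#' @param dct_calibrator Calibrator delta-Ct (cycles).
#' @param meth_undetermined Was the sample's methylation-specific Ct
#'   undetermined? (then `dct_sample` is ignored).
#' @param control_undetermined Was the sample's control Ct undetermined?
#'   (error if `TRUE`).
#' @return A list: `percent` (clipped to `[0, 100]`) and `raw` (unclipped).
#' @examples
#' percent_methylation(3, 2)$percent  # one extra cycle -> 50 %
#' @export
percent_methylation <- function(dct_sample, dct_calibrator,
                                meth_undetermined = FALSE,
                                control_undetermined = FALSE) {
  if (control_undetermined) {
    stop_bad("undetermined control Ct invalidates the measurement")
  }
  if (meth_undetermined) {
    return(list(percent = 0, raw = 0))
  }
  if (is.na(dct_sample) || is.na(dct_calibrator)) {
    stop_bad("delta-Ct values must be determined")
  }
  raw <- 100 * 2^-(dct_sample - dct_calibrator)
  list(percent = min(raw, 100), raw = raw)
}

#' Paired tumor/normal marker call
#'
#' A marker is `methylated` iff tumor minus normal percent methylation exceeds
#' `threshold` percentage points (strict), the cutoff accounting for 30-80 %
#' tumor cell content in macrodissected tissue.
#'
#' @param tumor_percent,normal_percent Percent methylation in `[0, 100]`.
#' @param threshold Percentage-point cutoff (default 20, strict).
#' @param marker Marker name carried into the call.
#' @return A list: `marker`, `tumor`, `normal`, `delta`, `methylated`.
#' @examples
#' call_marker(30, 10)$methylated  # delta exactly 20 -> FALSE (strict)
#' @export
call_marker <- function(tumor_percent, normal_percent, threshold = 20,
                        marker = NA_character_) {
  if (is.na(tumor_percent) || is.na(normal_percent)) {
    stop_bad("both paired measurements must be valid")
  }
  delta <- tumor_percent - normal_percent
  list(marker = marker, tumor = tumor_percent, normal = normal_percent,
       delta = delta, methylated = delta > threshold)
}

#' CIMP classification from the five-marker panel
#'
#' `<= 2` methylated markers of 5 gives `negative`, exactly 3 gives `low`,
#' `>= 4` gives `high`.
#'
#' @param calls List of five [call_marker()] results, exactly one per panel
#'   marker (MLH1 via probe 1).
#' @param panel Marker panel (default [cimp_panel()]).
#' @return A list: `n_methylated`, `category`
#'   (`"negative"`/`"low"`/`"high"`), and the echoed `calls`.
#' @export
classify_cimp <- function(calls, panel = cimp_panel()) {
  markers <- vapply(calls, `[[`, "", "marker")
  if (length(markers) != length(panel) || !setequal(markers, panel) ||
      anyDuplicated(markers)) {
    stop_bad("need exactly one call per panel marker: ",
             paste(panel, collapse = ", "))
  }
  n_meth <- sum(vapply(calls, `[[`, logical(1), "methylated"))
  category <- if (n_meth <= 2L) "negative" else if (n_meth == 3L) "low" else "high"
  list(n_methylated = n_meth, category = category, calls = calls)
}

#' Concordance of the two MLH1 probes
#'
#' @param call_p1,call_p2 [call_marker()] results for MLH1 probe 1 and
#'   probe 2 of the same sample.
#' @return A list: `label` (`"concordant-methylated"`,
#'   `"concordant-unmethylated"` or `"discordant"`), `delta_p1`, `delta_p2`.
#' @export
dual_probe_concordance <- function(call_p1, call_p2) {
  m1 <- call_p1$methylated; m2 <- call_p2$methylated
  label <- if (m1 && m2) "concordant-methylated"
  else if (!m1 && !m2) "concordant-unmethylated"
  else "discordant"
  list(label = label, delta_p1 = call_p1$delta, delta_p2 = call_p2$delta)
}

#' Relative expression by the delta-delta-Ct method
#'
#' Fold change of a target transcript in a sample tissue versus a reference
#' tissue, each normalized to a reference gene:
#' `2^-((Ct_target,s - Ct_ref,s) - (Ct_target,r - Ct_ref,r))`.
#'
#' @param ct_target_sample,ct_reference_sample Target and reference-gene Ct in
#'   the sample tissue.
#' @param ct_target_calibrator,ct_reference_calibrator Same in the reference
#'   tissue.
#' @return Fold change (1 = unchanged, < 1 = downregulated).
#' @examples
#' relative_expression(22, 18, 20, 18)  # two extra cycles -> 0.25
#' @export
relative_expression <- function(ct_target_sample, ct_reference_sample,
                                ct_target_calibrator, ct_reference_calibrator) {
  cts <- c(ct_target_sample, ct_reference_sample,
           ct_target_calibrator, ct_reference_calibrator)
  if (anyNA(cts)) stop_bad("all four Ct values must be determined")
  ddct <- (ct_target_sample - ct_reference_sample) -
    (ct_target_calibrator - ct_reference_calibrator)
  2^-ddct
}

# Average replicate Cts on the Ct scale. All-undetermined -> NA (undetermined).
average_ct <- function(ct, undetermined) {
  det <- !undetermined & !is.na(ct)
  if (!any(det)) return(NA_real_)
  mean(ct[det])
}

plate_dct <- function(plate, sample, tissue, marker) {
  meth <- plate[plate$sample == sample & plate$tissue == tissue &
                  plate$assay == marker & plate$role == "methylation", ]
  ctrl <- plate[plate$sample == sample & plate$tissue == tissue &
                  plate$role == "control", ]
  if (!nrow(meth)) return(NULL)
  if (!nrow(ctrl)) {
    stop_bad("no control-assay wells for ", sample, "/", tissue)
  }
  ct_m <- average_ct(meth$ct, meth$undetermined)
  ct_c <- average_ct(ctrl$ct, ctrl$undetermined)
  if (is.na(ct_c)) {
    stop_bad("undetermined control Ct for ", sample, "/", tissue)
  }
  list(dct = if (is.na(ct_m)) NA_real_ else ct_m - ct_c,
       meth_undetermined = is.na(ct_m))
}

#' Percent methylation for every (sample, tissue, marker) on a plate
#'
#' In `"pmr"` mode each delta-Ct is referenced to the fully methylated
#' calibrator wells of the same assay (`tissue == "calibrator"`). In
#' `"paired-normal"` mode the tumor value is expressed relative to the paired
#' normal of the same sample (`100 * 2^-(dct_tumor - dct_normal)`), matching
#' overlay-style plots; normals are then 100 by construction.
#'
#' @param plate Plate `data.frame` from [read_qpcr_plate()] or
#'   [gen_qpcr_plate()].
#' @param mode `"pmr"` (default) or `"paired-normal"`.
#' @return `data.frame`: `sample`, `tissue`, `marker`, `percent`, `raw`.
#' @export
plate_percent_methylation <- function(plate, mode = c("pmr", "paired-normal")) {
  mode <- match.arg(mode)
  meth_rows <- plate[plate$role == "methylation", ]
  combos <- unique(meth_rows[meth_rows$tissue != "calibrator",
                             c("sample", "tissue", "assay")])
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    s <- combos$sample[i]; tis <- combos$tissue[i]; mk <- combos$assay[i]
    sdct <- plate_dct(plate, s, tis, mk)
    if (is.null(sdct)) next
    if (mode == "pmr") {
      cal_rows <- plate[plate$tissue == "calibrator" & plate$assay == mk &
                          plate$role == "methylation", ]
      if (!nrow(cal_rows)) stop_bad("no calibrator wells for assay ", mk)
      cal_sample <- cal_rows$sample[1]
      cdct <- plate_dct(plate, cal_sample, "calibrator", mk)
      pm <- percent_methylation(sdct$dct, cdct$dct,
                                meth_undetermined = sdct$meth_undetermined,
                                control_undetermined = FALSE)
    } else {
      ndct <- plate_dct(plate, s, "normal", mk)
      if (is.null(ndct) || ndct$meth_undetermined) {
        # no methylated template in normal: reference undefined, fall back to
        # calling the tumor fully methylated relative to background
        pm <- list(percent = if (sdct$meth_undetermined) 0 else 100,
                   raw = if (sdct$meth_undetermined) 0 else Inf)
      } else {
        pm <- percent_methylation(sdct$dct, ndct$dct,
                                  meth_undetermined = sdct$meth_undetermined)
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      sample = s, tissue = tis, marker = mk, percent = pm$percent,
      raw = pm$raw, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' MethyLight plate to per-sample marker calls and CIMP categories
#'
#' End-to-end convenience wrapper: quantifies percent methylation
#' ([plate_percent_methylation()]), makes paired tumor/normal calls per marker
#' ([call_marker()]), classifies CIMP on the five-marker panel
#' ([classify_cimp()]; MLH1 via probe 1), and reports MLH1 dual-probe
#' concordance when probe 2 is on the plate.
#'
#' @param plate Plate `data.frame`.
#' @param threshold Paired cutoff in percentage points (default 20).
#' @param mode Quantification mode, see [plate_percent_methylation()].
#' @return A list with `measurements` (the percent table), `marker_calls`
#'   (long `data.frame`), and `samples` (`data.frame`: `sample`,
#'   `n_methylated`, `cimp`, `mlh1_methylated`, `mlh1_concordance`).
#' @export
methylight <- function(plate, threshold = 20, mode = "pmr") {
  pct <- plate_percent_methylation(plate, mode = mode)
  samples <- unique(pct$sample[pct$tissue == "tumor"])
  call_rows <- list()
  sample_rows <- list()
  for (s in samples) {
    sub <- pct[pct$sample == s, ]
    markers <- unique(sub$marker)
    calls <- list()
    for (mk in markers) {
      tu <- sub$percent[sub$tissue == "tumor" & sub$marker == mk]
      no <- sub$percent[sub$tissue == "normal" & sub$marker == mk]
      if (!length(tu) || !length(no)) next
      calls[[mk]] <- call_marker(tu[1], no[1], threshold = threshold, marker = mk)
      call_rows[[length(call_rows) + 1L]] <- data.frame(
        sample = s, marker = mk, tumor = tu[1], normal = no[1],
        delta = calls[[mk]]$delta, methylated = calls[[mk]]$methylated,
        stringsAsFactors = FALSE)
    }
    panel_calls <- calls[intersect(cimp_panel(), names(calls))]
    cimp <- if (length(panel_calls) == length(cimp_panel())) {
      classify_cimp(unname(panel_calls))
    } else NULL
    conc <- if (all(c("MLH1_p1", "MLH1_p2") %in% names(calls))) {
      dual_probe_concordance(calls$MLH1_p1, calls$MLH1_p2)$label
    } else NA_character_
    sample_rows[[length(sample_rows) + 1L]] <- data.frame(
      sample = s,
      n_methylated = if (is.null(cimp)) NA_integer_ else cimp$n_methylated,
      cimp = if (is.null(cimp)) NA_character_ else cimp$category,
      mlh1_methylated = if ("MLH1_p1" %in% names(calls))
        calls$MLH1_p1$methylated else NA,
      mlh1_concordance = conc, stringsAsFactors = FALSE)
  }
  list(measurements = pct,
       marker_calls = do.call(rbind, call_rows),
       samples = do.call(rbind, sample_rows))
}
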