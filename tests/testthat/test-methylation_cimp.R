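test_that("percent methylation follows the PMR formula with clipping", {
  expect_equal(percent_methylation(2, 2)$percent, 100)   # calibrator identity
  expect_equal(percent_methylation(3, 2)$percent, 50)    # one-cycle halving
  r <- percent_methylation(1.5, 2)                       # ddCt = -0.5
  expect_equal(r$raw, 100 * 2^0.5)
  expect_equal(r$percent, 100)
  # monotone strictly decreasing in ddCt
  dd <- seq(-2, 6, by = 0.5)
  pct <- vapply(dd, function(d) percent_methylation(d, 0)$raw, numeric(1))
  expect_true(all(diff(pct) < 0))
  # undetermined handling
  expect_equal(percent_methylation(NA, 2, meth_undetermined = TRUE)$percent, 0)
  expect_error(percent_methylation(2, 2, control_undetermined = TRUE),
               "control")
})

test_that("paired marker call uses the strict > 20 point rule", {
  expect_true(call_marker(80, 10)$methylated)
  expect_false(call_marker(30, 10)$methylated)  # delta exactly 20
  expect_false(call_marker(5, 40)$methylated)
  expect_equal(call_marker(80, 10)$delta, 70)
  expect_error(call_marker(NA, 10), "valid")
})

test_that("CIMP boundaries are exact at 2 / 3 / 4 methylated markers", {
  mk <- function(n_meth) {
    panel <- cimp_panel()
    lapply(seq_along(panel), function(i) {
      call_marker(if (i <= n_meth) 60 else 5, 2, marker = panel[i])
    })
  }
  expect_equal(classify_cimp(mk(0))$category, "negative")
  expect_equal(classify_cimp(mk(2))$category, "negative")
  expect_equal(classify_cimp(mk(3))$category, "low")
  expect_equal(classify_cimp(mk(4))$category, "high")
  expect_equal(classify_cimp(mk(5))$category, "high")
  # wrong panel composition errors
  expect_error(classify_cimp(mk(5)[1:4]), "panel")
  dup <- mk(5); dup[[2]] <- dup[[1]]
  expect_error(classify_cimp(dup), "panel")
})

test_that("dual-probe concordance labels all three outcomes", {
  m <- call_marker(80, 5, marker = "MLH1_p1")
  u <- call_marker(10, 5, marker = "MLH1_p2")
  expect_equal(dual_probe_concordance(m, m)$label, "concordant-methylated")
  expect_equal(dual_probe_concordance(u, u)$label, "concordant-unmethylated")
  d <- dual_probe_concordance(m, u)
  expect_equal(d$label, "discordant")
  expect_equal(d$delta_p1, 75)
})

test_that("delta-delta-Ct relative expression", {
  expect_equal(relative_expression(20, 18, 22, 20), 1)
  expect_equal(relative_expression(22, 18, 20, 18), 0.25)  # two cycles up
  expect_equal(relative_expression(19, 18, 20, 18), 2)
  expect_error(relative_expression(NA, 18, 20, 18), "determined")
})

test_that("noiseless plates invert exactly and undetermined wells map to 0%", {
  fr <- data.frame(sample = c("s1", "s1", "s2", "s2"),
                   tissue = c("tumor", "normal", "tumor", "normal"),
                   marker = "MLH1_p1",
                   fraction = c(0.5, 0.01, 0, 0.25),
                   stringsAsFactors = FALSE)
  plate <- gen_qpcr_plate(fr, sigma = 0, seed = 1)$plate
  pct <- plate_percent_methylation(plate)
  get <- function(s, t) pct$percent[pct$sample == s & pct$tissue == t]
  expect_equal(get("s1", "tumor"), 50)
  expect_equal(get("s1", "normal"), 1)
  expect_equal(get("s2", "tumor"), 0)   # fraction 0 -> undetermined -> 0%
  expect_equal(get("s2", "normal"), 25)

  # paired-normal mode references the matched normal instead
  pp <- plate_percent_methylation(plate, mode = "paired-normal")
  expect_equal(pp$percent[pp$sample == "s1" & pp$tissue == "normal"], 100)

  # replicate averaging happens on the Ct scale
  p2 <- plate
  p2$ct[p2$sample == "s1" & p2$role == "methylation" &
          p2$tissue == "tumor"] <- c(25.0, 27.0)  # mean Ct 26 = 1 cycle up
  pct2 <- plate_percent_methylation(p2)
  expect_equal(pct2$percent[pct2$sample == "s1" & pct2$tissue == "tumor"], 50)
})

test_that("methylight wrapper reproduces the constructed cohort structure", {
  cf <- gen_cohort_fractions(8, seed = 21, n_high = 3, n_low = 2)
  plate <- gen_qpcr_plate(cf$fractions, sigma = 0, seed = 22)$plate
  res <- methylight(plate)
  expect_equal(nrow(res$samples), 8L)
  # noiseless: categories equal the generator's ground truth
  expect_equal(res$samples$cimp[match(cf$truth$sample, res$samples$sample)],
               cf$truth$cimp_expected)
  expect_true(all(res$samples$mlh1_methylated))
  expect_true(all(res$samples$mlh1_concordance == "concordant-methylated"))
})
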