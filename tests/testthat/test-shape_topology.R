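test_that("methylation encoding rewrites CpGs and validates positions", {
  expect_equal(encode_methylation("ACGT", 2)$extended, "AMWT")
  expect_equal(encode_methylation("ACGT")$extended, "ACGT")
  expect_error(encode_methylation("ACAT", 2), "CpG")
  expect_error(encode_methylation("ACGT", 4), "outside|CpG")
  # extended-alphabet reverse complement pairs M with W
  expect_equal(revcomp_extended("AMWT"), "AMWT")
  expect_equal(revcomp_extended("ACMWG"), "CMWGT")
})

test_that("profile window arithmetic: defined ranges for bases and steps", {
  tab <- toy_shape_table("ACGTT")
  p <- predict_shape("ACGTT", tab)
  expect_equal(sum(!is.na(p$MGW)), 1L)  # only the center base
  expect_equal(which(!is.na(p$MGW)), 3L)
  expect_equal(sum(!is.na(p$HelT)), 2L)  # the two central steps
  expect_equal(which(!is.na(p$HelT)), c(2L, 3L))
  expect_error(predict_shape("ACGT", tab), "at least 5")
  expect_error(predict_shape("ACGTTACGTT", toy_shape_table("ACGTT")),
               "not in shape table")

  # constant table -> constant profile on a homopolymer
  ctab <- toy_shape_table("AAAAAAAA", constant = 1)
  hp <- predict_shape("AAAAAAAA", ctab)
  expect_true(all(hp$MGW[!is.na(hp$MGW)] == ctab["AAAAA", "MGW"]))
  expect_equal(length(unique(hp$HelT[!is.na(hp$HelT)])), 1L)

  # interior steps average the two covering pentamers (checked by hand)
  tab6 <- toy_shape_table("AACGTT")
  p6 <- predict_shape("AACGTT", tab6)
  expect_equal(p6$HelT[3],
               (tab6["AACGT", "HelT2"] + tab6["ACGTT", "HelT1"]) / 2)
  expect_equal(p6$HelT[2], tab6["AACGT", "HelT1"])
})

test_that("strand-symmetric table gives mirrored profiles on the reverse complement", {
  seqs <- c("AACGTTAC", "GTAACGTT")
  tab <- toy_shape_table(seqs, strand_symmetric = TRUE)
  s <- "AACGTTAC"
  rc <- revcomp_extended(s)
  p <- predict_shape(s, tab)
  q <- predict_shape(rc, tab)
  expect_equal(q$MGW, rev(p$MGW))
  expect_equal(q$ProT, rev(p$ProT))
  # step i of the reverse complement mirrors step L-i
  expect_equal(q$HelT, rev(p$HelT))
  expect_equal(q$Roll, rev(p$Roll))
})

test_that("methylation deltas are local to windows touching a rewritten base", {
  tab <- gen_shape_table(seed = 3)
  set.seed(14)
  for (i in 1:10) {
    L <- sample(30:60, 1)
    s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    cg <- as.integer(gregexpr("CG", s, fixed = TRUE)[[1]])
    cg <- cg[cg > 0]
    if (!length(cg)) next
    pos <- cg[sample.int(length(cg), 1)]
    d <- methylation_delta(s, pos, tab)
    # base features: windows centered within 2 bp of the M/W pair
    affected_base <- max(1, pos - 2):min(L, pos + 3)
    outside <- setdiff(seq_len(L), affected_base)
    expect_true(all(d$MGW[outside] == 0 | is.na(d$MGW[outside])))
    expect_true(all(d$ProT[outside] == 0 | is.na(d$ProT[outside])))
    # step features: steps within the covering pentamer windows
    affected_step <- max(1, pos - 3):min(L - 1, pos + 4)
    outside_s <- setdiff(seq_len(L - 1), affected_step)
    expect_true(all(d$HelT[outside_s] == 0 | is.na(d$HelT[outside_s])))
    expect_true(all(d$Roll[outside_s] == 0 | is.na(d$Roll[outside_s])))
  }
  # no methylation -> all-zero delta
  d0 <- methylation_delta("ACGTACGTACGT", integer(0), tab)
  expect_true(all(unlist(d0[c("MGW", "ProT")]) == 0, na.rm = TRUE))
  # declared effect signs at affected positions (ProT down, Roll up)
  d <- methylation_delta("TTTTTCGTTTTT", 6, tab)
  expect_true(all(d$ProT[!is.na(d$ProT) & d$ProT != 0] < 0))
  expect_true(all(d$Roll[!is.na(d$Roll) & d$Roll != 0] > 0))
})

test_that("envelopes: percentile order, collapse on identical sites, floor, median oracle", {
  tab <- gen_shape_table(seed = 5)
  # identical sites -> all five percentiles equal everywhere
  env <- build_envelope(rep("ACGTACGTAC", 100), tab)
  for (f in c("MGW", "ProT", "HelT", "Roll")) {
    expect_true(all(apply(env[[f]]$percentiles, 2,
                          function(col) length(unique(col)) == 1L)))
  }
  # floor enforcement with override
  expect_error(build_envelope(c("ACGTA", "ACGTA"), tab), "floor")
  expect_silent(build_envelope(c("ACGTA", "ACGTA"), tab, override = TRUE))
  expect_error(build_envelope(c("ACGTA", "ACGTAA"), tab, override = TRUE),
               "same length")

  # random site set: monotone percentiles and medians equal the sort oracle
  sites <- gen_motif_sites("ACGTACGTACGT", 200, seed = 31, mut_rate = 0.4)
  env <- build_envelope(sites$sites, tab)
  for (f in c("MGW", "ProT", "HelT", "Roll")) {
    pc <- env[[f]]$percentiles
    expect_true(all(diff(pc) >= 0))  # P5 <= P25 <= P50 <= P75 <= P95 columnwise
    med_oracle <- apply(env[[f]]$ref, 2, function(col) {
      sv <- sort(col); n <- length(sv)
      if (n %% 2 == 1) sv[(n + 1) / 2] else mean(sv[n / 2 + 0:1])
    })
    expect_equal(unname(pc["P50", ]), unname(med_oracle))
  }
})

test_that("departure score is zero at the median, one above P95, and mid-rank exact", {
  # hand-built, tie-free envelope: 9 distinct reference values per position
  feats <- c("MGW", "ProT", "HelT", "Roll")
  set.seed(44)
  L <- 10L
  mk_feature <- function(npos, offset) {
    ref <- matrix(rnorm(9 * npos), nrow = 9)
    pct <- apply(ref, 2, quantile, probs = c(.05, .25, .5, .75, .95),
                 type = 5, names = FALSE)
    rownames(pct) <- c("P5", "P25", "P50", "P75", "P95")
    list(positions = offset + seq_len(npos), ref = ref, percentiles = pct)
  }
  env <- structure(c(list(motif = "toy", n = 9L, site_length = L),
                     setNames(list(mk_feature(6L, 2L), mk_feature(6L, 2L),
                                   mk_feature(6L, 1L), mk_feature(6L, 1L)),
                              feats)),
                   class = "shape_envelope")
  mk_profile <- function(value_fun) {
    prof <- list(length = L)
    for (f in feats) {
      v <- rep(NA_real_, if (f %in% c("HelT", "Roll")) L - 1L else L)
      v[env[[f]]$positions] <- value_fun(env[[f]])
      prof[[f]] <- v
    }
    structure(prof, class = "shape_profile")
  }

  # query at the per-position median everywhere -> 0 / 0
  sc <- departure_score(mk_profile(function(e) e$percentiles["P50", ]), env)
  expect_equal(sc$mean_rank_deviation, rep(0, 4), tolerance = 1e-12)
  expect_equal(sc$exceedance, rep(0, 4))

  # far above every reference value -> rank 100, exceedance 1
  sc <- departure_score(mk_profile(function(e) apply(e$ref, 2, max) + 1), env)
  expect_equal(sc$mean_rank_deviation, rep(1, 4))
  expect_equal(sc$exceedance, rep(1, 4))

  # mid-rank agrees with the direct counting oracle at each position
  qprof <- mk_profile(function(e) e$ref[3, ] + 0.1)
  ranks <- vapply(seq_along(env$ProT$positions), function(j) {
    oracle_midrank(env$ProT$ref[, j], qprof$ProT[env$ProT$positions][j])
  }, numeric(1))
  sc2 <- departure_score(qprof, env)
  expect_equal(sc2$mean_rank_deviation[sc2$feature == "ProT"],
               mean(abs(ranks - 50) / 50))

  # adding a reference site identical to the median leaves the median query
  # at zero deviation
  env2 <- env
  env2$n <- 10L
  for (f in feats) {
    env2[[f]]$ref <- rbind(env2[[f]]$ref, env2[[f]]$percentiles["P50", ])
  }
  sc3 <- departure_score(mk_profile(function(e) e$percentiles["P50", ]), env2)
  expect_equal(sc3$mean_rank_deviation, rep(0, 4), tolerance = 1e-12)

  # length mismatch errors
  tab <- gen_shape_table(seed = 6)
  expect_error(departure_score(predict_shape("ACGTA", tab), env), "length")
})
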