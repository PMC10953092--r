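test_that("generators are pure functions of (config, seed)", {
  g1 <- gen_reference_fasta(2000, 0.5, seed = 1)
  g2 <- gen_reference_fasta(2000, 0.5, seed = 1)
  expect_identical(as.character(g1), as.character(g2))
  expect_false(identical(as.character(g1),
                         as.character(gen_reference_fasta(2000, 0.5, seed = 2))))

  w <- synthetic_signature_matrix()[, "SBS6like"]
  v1 <- gen_variants(g1, 100, w, seed = 3)
  v2 <- gen_variants(g1, 100, w, seed = 3)
  expect_identical(v1, v2)

  t1 <- gen_msi_traces(5, 0.5, seed = 4)
  t2 <- gen_msi_traces(5, 0.5, seed = 4)
  expect_identical(t1, t2)

  tab1 <- gen_shape_table(seed = 5)
  tab2 <- gen_shape_table(seed = 5)
  expect_identical(unclass(tab1), unclass(tab2))
})

test_that("reference generator respects GC bounds and validates input", {
  pure_gc <- gen_reference_fasta(1000, 1, seed = 6)
  expect_true(grepl("^[GC]+$", as.character(pure_gc[[1]])))
  expect_error(gen_reference_fasta(1000, 1.5, seed = 6), "gc")
  expect_error(gen_reference_fasta(10, 0.5, seed = 6), "length")
})

test_that("variant generator honors one-hot weights and errors on absent contexts", {
  genome <- gen_reference_fasta(5000, 0.5, seed = 7)
  w <- setNames(rep(0, 96), sbs96_contexts())
  w["A[C>T]G"] <- 1
  v <- gen_variants(genome, 50, w, seed = 8)
  expect_equal(nrow(v), 50L)
  sp <- compute_spectrum(v, genome)
  expect_equal(unname(sp[["A[C>T]G"]]), 50)
  expect_equal(sum(sp), 50)

  # n = 0 -> empty table / VCF
  expect_equal(nrow(gen_variants(genome, 0, w, seed = 8)), 0L)

  # a weighted category with no available context names the category
  gonly <- Biostrings::DNAStringSet(c(chrG = paste(rep("G", 1500), collapse = "")))
  expect_error(gen_variants(gonly, 5, w, seed = 8), "A\\[C>T\\]G")
})

test_that("trace generator hits the requested instability rate", {
  # binomial check: p = 0.25, 200 samples x 6 loci
  tr <- gen_msi_traces(200, 0.25, seed = 3)
  rate <- mean(tr$truth$unstable)
  expect_lt(abs(rate - 0.25), 0.05)
  # calls recover the ground truth exactly in the noiseless trace model
  res <- call_msi_samples(tr$traces)
  per_sample <- tapply(tr$truth$unstable, tr$truth$sample, sum)
  expect_equal(res$n_unstable, as.vector(per_sample[res$sample]))
})

test_that("qPCR generator inverts exactly without noise and recovers means with noise", {
  fr <- data.frame(sample = "s", tissue = "tumor", marker = "m", fraction = 0.5)
  plate <- gen_qpcr_plate(fr, sigma = 0, seed = 10)$plate
  expect_equal(plate_percent_methylation(plate)$percent[1], 50)
  expect_error(gen_qpcr_plate(fr, sigma = -1, seed = 10), "sigma")

  # Monte-Carlo: mean over 200 independent replicate plates (each with its
  # own calibrator) recovers 80% within +-5 points
  fr <- data.frame(sample = "r", tissue = "tumor", marker = "m", fraction = 0.8)
  rec <- vapply(1:200, function(k) {
    plate <- gen_qpcr_plate(fr, sigma = 0.2, seed = 1000 + k)$plate
    plate_percent_methylation(plate)$percent[1]
  }, numeric(1))
  expect_lt(abs(mean(rec) - 80), 5)
})

test_that("shape table effects carry the declared sizes and zero effect vanishes", {
  tab0 <- gen_shape_table(seed = 12, prot_shift = 0, roll_shift = 0)
  d <- methylation_delta("TTACGTTTTT", 4, tab0)
  expect_true(all(unlist(d[c("MGW", "ProT", "HelT", "Roll")]) == 0, na.rm = TRUE))

  tab <- gen_shape_table(seed = 12, prot_shift = -2.5, roll_shift = 4)
  # a pentamer with a mark differs from its demethylated twin by the shift
  expect_equal(unname(tab["AMWTA", "ProT"] - tab["ACGTA", "ProT"]), -2.5)
  expect_equal(unname(tab["AMWTA", "Roll1"] - tab["ACGTA", "Roll1"]), 4)
  expect_equal(unname(tab["AMWTA", "MGW"] - tab["ACGTA", "MGW"]), 0)
})

test_that("promoter generator embeds the motif with recorded CpG coordinates", {
  pr <- gen_promoter(seed = 13)
  expect_equal(substr(pr$seq, pr$motif_start, pr$motif_end), pr$consensus)
  for (p in pr$cpg_positions) {
    expect_equal(substr(pr$seq, p, p + 1), "CG")
  }
  expect_error(gen_promoter(consensus = "AATTAA", seed = 13), "CpG")
})

test_that("motif-site generator collapses envelopes when degeneracy is zero", {
  tab <- gen_shape_table(seed = 14)
  sites <- gen_motif_sites("ACGTACGTAC", 100, seed = 15, mut_rate = 0)
  expect_true(all(sites$sites == "ACGTACGTAC"))
  env <- build_envelope(sites, tab)
  expect_true(all(apply(env$ProT$percentiles, 2,
                        function(col) length(unique(col)) == 1L)))
})

test_that("simulate_all writes a complete, ground-truthed bundle", {
  out <- withr::local_tempdir()
  paths <- simulate_all(out, seed = 16, n_tumors = 4L, n_snvs = 200L)
  for (p in paths) expect_true(file.exists(p))
  expect_true(file.exists(file.path(out, "traces_truth.tsv")))
  expect_true(file.exists(file.path(out, "cimp_truth.tsv")))
})
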