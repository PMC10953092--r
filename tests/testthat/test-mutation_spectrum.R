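test_that("SBS96 catalog has the canonical layout", {
  ctx <- sbs96_contexts()
  expect_length(ctx, 96L)
  expect_false(anyDuplicated(ctx) > 0)
  expect_equal(ctx[1:5], c("A[C>A]A", "A[C>A]C", "A[C>A]G", "A[C>A]T", "C[C>A]A"))
  expect_equal(ctx[96], "T[T>G]T")
})

test_that("spectrum assigns contexts with strand collapse and conserves counts", {
  # pyrimidine-centered SNV
  sp <- compute_spectrum(
    data.frame(chrom = "c", pos = 3L, ref = "C", alt = "T", class = "SNV"),
    c(c = "AACGT"))
  expect_equal(unname(sp[["A[C>T]G"]]), 1)
  expect_equal(sum(sp), 1)

  # purine-centered SNV is reverse-complemented: CGA context, G>A -> T[C>T]G
  sp <- compute_spectrum(
    data.frame(chrom = "c", pos = 3L, ref = "G", alt = "A", class = "SNV"),
    c(c = "ACGAT"))
  expect_equal(unname(sp[["T[C>T]G"]]), 1)

  # empty input -> all zero
  sp <- compute_spectrum(
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), class = character(0)), c(c = "ACGAT"))
  expect_equal(sum(sp), 0)

  # REF mismatch is an error naming the position
  expect_error(compute_spectrum(
    data.frame(chrom = "c", pos = 3L, ref = "T", alt = "A", class = "SNV"),
    c(c = "AACGT")), "c:3")

  # contig-edge variant skipped with a warning, not counted
  expect_warning(
    sp <- compute_spectrum(
      data.frame(chrom = "c", pos = c(1L, 3L), ref = c("A", "C"),
                 alt = c("T", "T"), class = c("SNV", "SNV")),
      c(c = "AACGT")),
    "skipped")
  expect_equal(sum(sp), 1)
  expect_equal(attr(sp, "n_skipped"), 1L)
})

test_that("spectrum invariants hold on random variant sets", {
  set.seed(9)
  genome <- gen_reference_fasta(5000, 0.5, seed = 9)
  gstr <- as.character(genome[[1]])
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  genome_rc <- c(chrS = rc(gstr))
  L <- nchar(gstr)
  for (i in 1:10) {
    n <- sample(10:60, 1)
    pos <- sample(2:(L - 1), n)
    ref <- substring(gstr, pos, pos)
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
    v <- data.frame(chrom = "chrS", pos = pos, ref = ref, alt = unname(alt),
                    class = "SNV", stringsAsFactors = FALSE)
    sp <- compute_spectrum(v, genome)
    # conservation: total equals the eligible SNV count
    expect_equal(sum(sp), n)
    # strand collapse: reverse-complementing genome and variants is a no-op
    v_rc <- data.frame(chrom = "chrS", pos = L - pos + 1L,
                       ref = chartr("ACGT", "TGCA", ref),
                       alt = chartr("ACGT", "TGCA", unname(alt)),
                       class = "SNV", stringsAsFactors = FALSE)
    expect_equal(as.numeric(compute_spectrum(v_rc, genome_rc)), as.numeric(sp))
  }
})

test_that("cosine similarity and signature ranking behave as defined", {
  v <- runif(96)
  expect_equal(cosine_similarity(v, 2 * v), 1)
  one1 <- replace(numeric(96), 1, 1); one2 <- replace(numeric(96), 2, 1)
  expect_equal(cosine_similarity(one1, one2), 0)
  expect_equal(cosine_similarity(c(1, 1, rep(0, 94)),
                                 c(1, 0, 1, rep(0, 93))), 0.5)
  expect_error(cosine_similarity(numeric(96), v), "zero vector")
  expect_error(cosine_similarity(-v, v), "nonnegative")

  sig <- synthetic_signature_matrix()
  hit <- best_signature(sig[, "CtoAheavy"], sig)
  expect_equal(hit$best, "CtoAheavy")
  expect_equal(hit$similarity, 1)
  expect_false(hit$tied)

  # uniform spectrum vs one-hot signatures ties and is flagged
  onehots <- diag(96)[, 1:3]
  rownames(onehots) <- sbs96_contexts()
  colnames(onehots) <- c("h1", "h2", "h3")
  tie <- best_signature(rep(1, 96), onehots)
  expect_true(tie$tied)
  expect_equal(tie$best, "h1")  # lexicographic tie-break
})

test_that("TMB arithmetic, strict threshold, linearity, and fixture mean", {
  r <- compute_tmb(1200, 40)
  expect_equal(r$tmb, 30)
  expect_true(r$high)
  expect_false(compute_tmb(100, 10)$high)  # exactly 10 is not high
  expect_equal(compute_tmb(2400, 40)$tmb, 2 * compute_tmb(1200, 40)$tmb)
  expect_error(compute_tmb(10, 0), "positive")

  tab2 <- read_table2_fixture()
  expect_equal(round(mean(tab2$tmb$tmb), 2), 29.71)

  # SNV-only mode
  v <- data.frame(class = c("SNV", "SNV", "insertion"))
  expect_equal(compute_tmb(v, 1)$n_mutations, 3L)
  expect_equal(compute_tmb(v, 1, snv_only = TRUE)$n_mutations, 2L)
})

test_that("hotspot matching reports the three nested fractions", {
  catalog <- data.frame(gene = c("TP53", "KRAS"), pos = c(175L, 12L),
                        ref_aa = c("R", "G"), alt_aa = c("H", "D"),
                        stringsAsFactors = FALSE)
  v <- data.frame(gene = c("TP53", "KRAS", "KRAS", "APC"),
                  aa_pos = c(175L, 14L, 19L, 100L),
                  ref_aa = c("R", "G", "G", "A"),
                  alt_aa = c("H", "D", "D", "T"), stringsAsFactors = FALSE)
  st <- match_hotspots(v, catalog, window = 5L)
  expect_equal(st$n, 4L)
  # TP53 p.R175H: exact; KRAS p.G14D: window only (offset 2);
  # KRAS offset 7: unmatched; APC absent from catalog: unmatched
  expect_equal(st$n_exact, 1L)
  expect_equal(st$n_same_residue, 1L)
  expect_equal(st$n_window, 2L)
  expect_equal(st$detail$offset[2], 2L)
  expect_true(st$f_exact <= st$f_same_residue)
  expect_true(st$f_same_residue <= st$f_window)
})
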