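#' Build an SBS96 trinucleotide spectrum from SNVs
#'
#' Counts every single-nucleotide variant into its pyrimidine-centered
#' trinucleotide category; variants whose reference base is a purine are
#' reverse-complemented into the C/T-centered frame. Non-SNV records are
#' ignored. Variants at a contig edge (no flanking base on either side) are
#' skipped; their number is reported in the `n_skipped` attribute.
#'
#' @param variants `data.frame` with `chrom`, `pos` (1-based), `ref`, `alt`
#'   and optionally `class` (rows with class other than `"SNV"` are dropped;
#'   without a `class` column, single-base ref/alt rows are used).
#' @param genome Named character vector or `Biostrings::DNAStringSet`.
#' @return Named numeric vector of 96 counts in canonical order, with
#'   attribute `n_skipped`. The counts sum to the number of contributing SNVs.
#' @export
compute_spectrum <- function(variants, genome) {
  genome <- as_genome(genome)
  spec <- sbs96_empty()
  if (!is.null(variants$class)) {
    variants <- variants[variants$class == "SNV", , drop = FALSE]
  } else if (nrow(variants)) {
    variants <- variants[nchar(variants$ref) == 1L & nchar(variants$alt) == 1L, ,
                         drop = FALSE]
  }
  skipped <- 0L
  if (nrow(variants)) {
    bad_contig <- !(variants$chrom %in% names(genome))
    if (any(bad_contig)) {
      stop_bad("contig absent from genome: ", variants$chrom[which(bad_contig)[1]])
    }
    if (any(variants$ref == variants$alt)) {
      i <- which(variants$ref == variants$alt)[1]
      stop_bad("SNV with ref == alt at ", variants$chrom[i], ":", variants$pos[i])
    }
    lens <- setNames(Biostrings::width(genome), names(genome))
    at_edge <- variants$pos < 2L | variants$pos > lens[variants$chrom] - 1L
    skipped <- sum(at_edge)
    v <- variants[!at_edge, , drop = FALSE]
    seq_chars <- lapply(setNames(nm = unique(v$chrom)),
                        function(ch) as.character(genome[[ch]]))
    tri <- character(nrow(v))
    for (ch in unique(v$chrom)) {
      sel <- v$chrom == ch
      tri[sel] <- substring(seq_chars[[ch]], v$pos[sel] - 1L, v$pos[sel] + 1L)
    }
    center <- substr(tri, 2, 2)
    if (any(center != v$ref)) {
      i <- which(center != v$ref)[1]
      stop_bad("REF mismatch at ", v$chrom[i], ":", v$pos[i], " (VCF says ",
               v$ref[i], ", genome says ", center[i], ")")
    }
    pyr <- v$ref %in% c("C", "T")
    tri[!pyr] <- revcomp_chr(tri[!pyr])
    ref2 <- ifelse(pyr, v$ref, chartr("GA", "CT", v$ref))
    alt2 <- ifelse(pyr, v$alt, chartr("ACGT", "TGCA", v$alt))
    labs <- paste0(substr(tri, 1, 1), "[", ref2, ">", alt2, "]",
                   substr(tri, 3, 3))
    tab <- table(factor(labs, levels = names(spec)))
    spec <- spec + as.numeric(tab)
    names(spec) <- sbs96_contexts()
  }
  if (skipped > 0L) {
    warning(skipped, " variant(s) skipped at contig edges", call. = FALSE)
  }
  attr(spec, "n_skipped") <- skipped
  spec
}

#' Cosine similarity between two nonnegative spectra
#'
#' @param x,y Nonnegative numeric vectors of equal length; neither all-zero.
#' @return Similarity in `[0, 1]`; 1 for proportional vectors.
#' @examples
#' cosine_similarity(c(1, 1, 0), c(2, 2, 0))
#' @export
cosine_similarity <- function(x, y) {
  if (length(x) != length(y)) stop_bad("vectors differ in length")
  if (any(x < 0) || any(y < 0)) stop_bad("vectors must be nonnegative")
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop_bad("zero vector has no direction")
  sum(x * y) / (nx * ny)
}

#' Rank signatures by cosine similarity to a spectrum
#'
#' @param spectrum SBS96 count (or fraction) vector, canonical order.
#' @param signatures 96-row signature matrix from [read_signature_matrix()].
#' @param tie_tol Two signatures within this similarity difference of the top
#'   hit are reported as tied (default 1e-9).
#' @return A list: `best` (signature name, lexicographically first on ties),
#'   `similarity`, `tied` (logical), and `ranking` (`data.frame` sorted by
#'   decreasing similarity).
#' @export
best_signature <- function(spectrum, signatures, tie_tol = 1e-9) {
  if (!ncol(signatures)) stop_bad("empty signature matrix")
  if (!is.null(names(spectrum)) &&
      !identical(names(spectrum), rownames(signatures))) {
    spectrum <- spectrum[rownames(signatures)]
  }
  sims <- vapply(seq_len(ncol(signatures)), function(j) {
    cosine_similarity(as.numeric(spectrum), signatures[, j])
  }, numeric(1))
  names(sims) <- colnames(signatures)
  ranking <- data.frame(signature = names(sims), similarity = unname(sims),
                        stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$similarity, ranking$signature), ]
  rownames(ranking) <- NULL
  top <- ranking$similarity[1]
  tied <- sum(ranking$similarity >= top - tie_tol) > 1L
  list(best = ranking$signature[1], similarity = top, tied = tied,
       ranking = ranking)
}

#' Tumor mutational burden
#'
#' TMB = mutation count / callable megabases. By convention the numerator
#' includes filtered-pass SNVs and indels; `snv_only = TRUE` restricts it to
#' SNVs. A sample is flagged TMB-high strictly above `threshold`.
#'
#' @param variants Either a variant `data.frame` (with a `class` column) or a
#'   single mutation count.
#' @param callable_mbp Callable genome size in megabases (> 0).
#' @param threshold TMB-high cutoff in mutations per megabase (default 10,
#'   strict inequality).
#' @param snv_only Count only SNVs (default `FALSE`).
#' @return A list: `n_mutations`, `callable_mbp`, `tmb`, `high`.
#' @examples
#' compute_tmb(1200, 40)$tmb
#' @export
compute_tmb <- function(variants, callable_mbp, threshold = 10, snv_only = FALSE) {
  if (!is.numeric(callable_mbp) || length(callable_mbp) != 1L ||
      callable_mbp <= 0) {
    stop_bad("callable_mbp must be a positive number")
  }
  n <- if (is.data.frame(variants)) {
    if (snv_only && !is.null(variants$class)) {
      sum(variants$class == "SNV")
    } else {
      nrow(variants)
    }
  } else {
    if (length(variants) != 1L || variants < 0) stop_bad("invalid mutation count")
    as.numeric(variants)
  }
  tmb <- n / callable_mbp
  list(n_mutations = n, callable_mbp = callable_mbp, tmb = tmb,
       high = tmb > threshold)
}

#' Cross-species hotspot codon matching
#'
#' For each query variant with a parsed protein change, searches a per-gene
#' catalog of (codon position, reference residue, variant residue) entries and
#' reports three nested statistics: the fraction of variants with a catalog
#' entry for the same gene within `window` codons, the fraction hitting the
#' same residue at the same position, and the fraction matching the exact
#' amino-acid change. Variants whose gene is absent from the catalog count as
#' unmatched.
#'
#' @param variants `data.frame` with `gene`, `aa_pos`, `ref_aa`, `alt_aa`
#'   (e.g. from [read_variant_table()]).
#' @param catalog `data.frame` with `gene`, `pos`, `ref_aa`, `alt_aa`.
#' @param window Codon window for the positional match (default 5).
#' @return A list: `n`, `n_window`, `n_same_residue`, `n_exact`,
#'   `f_window`, `f_same_residue`, `f_exact`, `window`, and a per-variant
#'   `detail` `data.frame`.
#' @export
match_hotspots <- function(variants, catalog, window = 5L) {
  need <- c("gene", "aa_pos", "ref_aa", "alt_aa")
  if (!all(need %in% names(variants))) {
    stop_bad("variants need columns gene, aa_pos, ref_aa, alt_aa")
  }
  if (!all(c("gene", "pos", "ref_aa", "alt_aa") %in% names(catalog))) {
    stop_bad("catalog needs columns gene, pos, ref_aa, alt_aa")
  }
  n <- nrow(variants)
  in_window <- same_res <- exact <- logical(n)
  offset <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    cat_g <- catalog[catalog$gene == variants$gene[i], , drop = FALSE]
    if (!nrow(cat_g)) next
    d <- abs(cat_g$pos - variants$aa_pos[i])
    in_window[i] <- any(d <= window)
    if (in_window[i]) offset[i] <- min(d)
    same_res[i] <- any(cat_g$pos == variants$aa_pos[i] &
                         cat_g$ref_aa == variants$ref_aa[i])
    exact[i] <- any(cat_g$pos == variants$aa_pos[i] &
                      cat_g$ref_aa == variants$ref_aa[i] &
                      cat_g$alt_aa == variants$alt_aa[i])
  }
  detail <- data.frame(gene = variants$gene, aa_pos = variants$aa_pos,
                       in_window = in_window, same_residue = same_res,
                       exact = exact, offset = offset,
                       stringsAsFactors = FALSE)
  list(n = n,
       n_window = sum(in_window), n_same_residue = sum(same_res),
       n_exact = sum(exact),
       f_window = if (n) mean(in_window) else NA_real_,
       f_same_residue = if (n) mean(same_res) else NA_real_,
       f_exact = if (n) mean(exact) else NA_real_,
       window = window, detail = detail)
}
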