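#' Summarize a clinical cohort
#'
#' Counts and age statistics over a decoded cohort table. Missing values are
#' excluded from each count's numerator; both the non-missing denominator and
#' the cohort size are reported so fractions can be quoted either way.
#'
#' @param cohort Cohort `data.frame` from [read_cohort_table()].
#' @return A list: `n`, `n_female`, `n_male`, `age_arrival`
#'   (`mean`/`min`/`max` at full precision plus `mean_2dp`), `fob`
#'   (`pos`/`neg`/`n_missing`), `fibrosis` (`pos`/`neg`), `diagnosis`
#'   (`biopsy`/`necropsy`), per-stage tallies `t_stage`, `n_stage`, `m_stage`,
#'   `grade`, and imaging modality counts.
#' @examples
#' s <- summarize_cohort(read_cohort_table(dmmr_example("table1_cohort.tsv")))
#' s$age_arrival$mean_2dp
#' @export
summarize_cohort <- function(cohort) {
  if (!nrow(cohort)) stop_bad("empty cohort")
  age <- cohort$age_arrival[!is.na(cohort$age_arrival)]
  tally <- function(x) table(x, useNA = "no")
  imaging_tags <- unlist(cohort$imaging, use.names = FALSE)
  list(
    n = nrow(cohort),
    n_female = sum(cohort$sex == "f", na.rm = TRUE),
    n_male = sum(cohort$sex == "m", na.rm = TRUE),
    age_arrival = list(
      mean = mean(age), min = min(age), max = max(age),
      mean_2dp = round(mean(age), 2), n = length(age)),
    fob = list(pos = sum(cohort$fob == "pos", na.rm = TRUE),
               neg = sum(cohort$fob == "neg", na.rm = TRUE),
               n_missing = sum(is.na(cohort$fob))),
    fibrosis = list(pos = sum(cohort$fibrosis == "pos", na.rm = TRUE),
                    neg = sum(cohort$fibrosis == "neg", na.rm = TRUE)),
    diagnosis = list(biopsy = sum(cohort$diagnosis == "biopsy", na.rm = TRUE),
                     necropsy = sum(cohort$diagnosis == "necropsy", na.rm = TRUE)),
    t_stage = tally(cohort$t_stage),
    n_stage = tally(cohort$n_stage),
    m_stage = tally(cohort$m_stage),
    grade = tally(cohort$grade),
    imaging = if (length(imaging_tags)) table(imaging_tags) else table(character(0))
  )
}

rank_avg <- function(x) rank(x, ties.method = "average", na.last = "keep")

spearman_pair <- function(x, y, exact_max_n = 0L) {
  ok <- stats::complete.cases(x, y)
  n <- sum(ok)
  if (n < 3L) return(list(rho = NA_real_, p = NA_real_, n = n))
  x <- x[ok]; y <- y[ok]
  if (sd(x) == 0 || sd(y) == 0) return(list(rho = NA_real_, p = NA_real_, n = n))
  rho <- cor(rank_avg(x), rank_avg(y))
  if (n <= exact_max_n) {
    # exact two-sided permutation p over all n! orderings of y
    perms <- permutations_all(n)
    rx <- rank_avg(x); ry <- rank_avg(y)
    rhos <- apply(perms, 1L, function(ix) cor(rx, ry[ix]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tt), df = n - 2)
    p <- min(max(p, .Machine$double.xmin), 1)
  }
  list(rho = rho, p = p, n = n)
}

permutations_all <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_all(n - 1L)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  r <- 1L
  for (k in seq_len(n)) {
    block <- cbind(k, ifelse(sub >= k, sub + 1L, sub))
    out[r:(r + nrow(sub) - 1L), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Pairwise Spearman correlation matrix (long form)
#'
#' Spearman's rho computed as Pearson correlation of average ranks on
#' pairwise-complete observations; two-sided p-values from the t
#' approximation with `n - 2` degrees of freedom, or an exact permutation
#' distribution when `n <= exact_max_n`. Pairs with fewer than 3 complete
#' observations or a constant column are reported as missing (never as 0).
#' Raw and Benjamini-Hochberg-adjusted p-values are both reported because the
#' multiplicity handling of the original analysis tool is unstated.
#'
#' @param features `data.frame`/matrix of numeric or ordinal-coded columns,
#'   one row per sample.
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @param exact_max_n Use exact permutation p-values for pairs with at most
#'   this many complete observations (default 0 = never; 8 is feasible).
#' @return `data.frame` with `feature1`, `feature2`, `rho`, `p`, `p_adj`,
#'   `n`, `significant` for every unordered pair.
#' @export
spearman_matrix <- function(features, alpha = 0.05, exact_max_n = 0L) {
  features <- as.data.frame(features)
  nm <- names(features)
  if (length(nm) < 2L) stop_bad("need at least two feature columns")
  pairs <- utils::combn(nm, 2L)
  res <- apply(pairs, 2L, function(pr) {
    st <- spearman_pair(features[[pr[1]]], features[[pr[2]]],
                        exact_max_n = exact_max_n)
    data.frame(feature1 = pr[1], feature2 = pr[2], rho = st$rho, p = st$p,
               n = st$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$significant <- !is.na(out$p) & out$p < alpha
  out[c("feature1", "feature2", "rho", "p", "p_adj", "n", "significant")]
}

#' Differential-expression threshold filter with BH adjustment
#'
#' Applies Benjamini-Hochberg adjustment across all rows, then partitions
#' genes into `up` (adjusted p < `alpha` and log2 fold change > `lfc`),
#' `down` (adjusted p < `alpha` and log2 fold change < `-lfc`), and
#' `unchanged`.
#'
#' @param deg `data.frame` with columns `gene`, `log2fc`, `p`.
#' @param lfc Absolute log2 fold-change threshold (default 1).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return Input `data.frame` plus `p_adj` and `status`, with attributes
#'   `n_up` and `n_down`.
#' @export
filter_deg <- function(deg, lfc = 1, alpha = 0.05) {
  need <- c("gene", "log2fc", "p")
  if (!all(need %in% names(deg))) {
    stop_bad("deg table needs columns gene, log2fc, p")
  }
  if (!nrow(deg)) {
    out <- deg
    out$p_adj <- numeric(0)
    out$status <- character(0)
    attr(out, "n_up") <- 0L
    attr(out, "n_down") <- 0L
    return(out)
  }
  if (any(deg$p < 0 | deg$p > 1, na.rm = TRUE) || anyNA(deg$p)) {
    stop_bad("p-values must lie in [0, 1]")
  }
  deg$p_adj <- p.adjust(deg$p, method = "BH")
  deg$status <- "unchanged"
  deg$status[deg$p_adj < alpha & deg$log2fc > lfc] <- "up"
  deg$status[deg$p_adj < alpha & deg$log2fc < -lfc] <- "down"
  attr(deg, "n_up") <- sum(deg$status == "up")
  attr(deg, "n_down") <- sum(deg$status == "down")
  deg
}
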