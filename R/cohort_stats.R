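#' Contingency and correlation statistics for cohort characterization
#'
#' Odds ratios of a diagnosis within a cluster relative to the full cohort,
#' Fisher exact tests of categorical composition, unpaired two-sided t
#' tests, and one-sided Pearson correlation tests.
#'
#' @name cohort-stats
NULL

#' Odds ratio of a diagnosis in a group versus the cohort
#'
#' Default reading (`mode = "vs_cohort"`): group odds of the diagnosis
#' relative to the odds in the *full* cohort (group included),
#' `OR = [k_g/(n_g - k_g)] / [k_c/(n_c - k_c)]` — the reading that
#' reproduces the printed group 1 value for triple-negative enrichment.
#' `mode = "vs_reference"` instead compares the diagnosis count against a
#' reference-category count (pass reference counts as `k_cohort`/`n_cohort`
#' totals of diagnosis + reference only). The 95% CI is the Woolf
#' log-odds-ratio interval; no continuity correction is applied, so all
#' four cells must be positive.
#'
#' @param k_group diagnosis count in the group
#' @param n_group group size
#' @param k_cohort diagnosis count in the cohort (or reference reading)
#' @param n_cohort cohort size
#' @param mode `"vs_cohort"` (default) or `"vs_reference"`
#' @return list with `or`, `lower`, `upper`, `counts`, `mode`
#' @export
odds_ratio_vs_cohort <- function(k_group, n_group, k_cohort, n_cohort,
                                 mode = c("vs_cohort", "vs_reference")) {
  mode <- match.arg(mode)
  stopifnot(k_group >= 0, k_group <= n_group, k_cohort >= 0,
            k_cohort <= n_cohort)
  cells <- c(k_group, n_group - k_group, k_cohort, n_cohort - k_cohort)
  if (any(cells == 0)) {
    stop("zero cell count; odds ratio undefined without correction",
         call. = FALSE)
  }
  or <- (k_group / (n_group - k_group)) / (k_cohort / (n_cohort - k_cohort))
  se <- sqrt(sum(1 / cells))
  list(or = or,
       lower = exp(log(or) - 1.96 * se),
       upper = exp(log(or) + 1.96 * se),
       counts = stats::setNames(cells, c("k_group", "rest_group",
                                         "k_cohort", "rest_cohort")),
       mode = mode)
}

#' Fisher exact test of group composition versus population
#'
#' 2x2 tables are tested exactly; larger tables fall back to the
#' Monte-Carlo exact test with an explicit seed (flagged in the result).
#'
#' @param group_counts counts per category in the group
#' @param population_counts counts per category in the population
#' @param B Monte-Carlo replicates for tables larger than 2x2
#' @param seed seed for the Monte-Carlo fallback
#' @return list with `p_value`, `method`, `table`
#' @export
categorical_vs_population_test <- function(group_counts, population_counts,
                                           B = 1e5, seed = 1L) {
  if (length(group_counts) != length(population_counts) ||
      length(group_counts) < 2L) {
    stop("need matched counts over >= 2 categories", call. = FALSE)
  }
  if (any(group_counts < 0) || any(population_counts < 0)) {
    stop("negative counts", call. = FALSE)
  }
  tab <- rbind(group = group_counts, population = population_counts)
  if (ncol(tab) == 2L) {
    list(p_value = stats::fisher.test(tab)$p.value, method = "fisher_exact",
         table = tab)
  } else {
    set.seed(seed)
    list(p_value = stats::fisher.test(tab, simulate.p.value = TRUE,
                                      B = B)$p.value,
         method = "fisher_monte_carlo", table = tab)
  }
}

#' Unpaired two-sided t test
#'
#' @param a,b numeric samples (each with >= 2 values)
#' @param var_equal pooled-variance test (default `TRUE`); `FALSE` gives
#'   Welch
#' @return list with `t`, `p_value`, `df`, `mean_diff`
#' @export
ttest_unpaired <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("each sample needs >= 2 values", call. = FALSE)
  }
  tt <- stats::t.test(a, b, var.equal = var_equal,
                      alternative = "two.sided")
  list(t = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), mean_diff = mean(a) - mean(b))
}

#' Pearson correlation with one-sided test
#'
#' @param x,y numeric vectors (n >= 3, finite, nonzero variance)
#' @param side `"positive"`, `"negative"`, or `"two.sided"`
#' @return list with `r`, `p_value`, `n`, `side`
#' @export
pearson_correlation <- function(x, y,
                                side = c("positive", "negative",
                                         "two.sided")) {
  side <- match.arg(side)
  if (length(x) != length(y) || length(x) < 3L) {
    stop("need paired vectors of length >= 3", call. = FALSE)
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("non-finite values", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance", call. = FALSE)
  }
  alt <- switch(side, positive = "greater", negative = "less",
                two.sided = "two.sided")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = alt)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       side = side)
}

#' Benjamini-Hochberg adjustment utility
#'
#' Provided for convenience; the cohort workflow reports unadjusted
#' p-values by default.
#'
#' @param p vector of p-values
#' @return adjusted p-values
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
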