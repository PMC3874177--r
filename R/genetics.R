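#' Haldane map function
#'
#' Converts a recombinant fraction to map distance assuming no interference:
#' `d = -50 * ln(1 - 2R)` centimorgans; [haldane_R()] is the inverse,
#' `R = (1 - exp(-d/50)) / 2`.
#'
#' @param R recombinant fraction(s) in [0, 0.5).
#' @return map distance in cM.
#' @export
haldane <- function(R) {
  if (any(R < 0)) stop("recombinant fraction must be >= 0")
  if (any(R >= 0.5)) stop("distance undefined for R >= 0.5")
  -50 * log(1 - 2 * R)
}

#' @rdname haldane
#' @param d map distance(s) in cM (>= 0).
#' @return recombinant fraction.
#' @export
haldane_R <- function(d) {
  if (any(d < 0)) stop("distance must be >= 0")
  (1 - exp(-d / 50)) / 2
}

#' Fold change and percent change between two values
#'
#' @param a,b reference and comparison values (means, frequencies or map
#'   distances); `a` must be non-zero.
#' @return list with `ratio` (b/a) and `percent_change` (100 * (b-a)/a).
#' @export
fold_change <- function(a, b) {
  if (any(a == 0)) stop("reference value must be non-zero")
  list(ratio = b / a, percent_change = 100 * (b - a) / a)
}

#' Unpaired t-test from summary statistics
#'
#' Two-sample t statistic computed from group means and standard errors:
#' `t = |mean_b - mean_a| / sqrt(sem_a^2 + sem_b^2)`.  Degrees of freedom
#' follow either the pooled-count rule `n_a + n_b - 2` (default) or the
#' Welch-Satterthwaite approximation from the SEMs.  The p-value is
#' two-sided from the central t distribution.
#'
#' @param mean_a,sem_a,n_a,mean_b,sem_b,n_b group summaries (n >= 2,
#'   sem >= 0, not both SEMs 0 unless the means are equal).
#' @param df_rule `"pooled-count"` or `"welch"`.
#' @return list with `t`, `df`, `p`.
#' @export
ttest_from_summary <- function(mean_a, sem_a, n_a, mean_b, sem_b, n_b,
                               df_rule = c("pooled-count", "welch")) {
  df_rule <- match.arg(df_rule)
  if (n_a < 2 || n_b < 2) stop("need n >= 2 in both groups")
  if (sem_a < 0 || sem_b < 0) stop("SEMs must be >= 0")
  if (sem_a == 0 && sem_b == 0) {
    if (mean_a == mean_b) {
      return(list(t = 0, df = if (df_rule == "pooled-count") n_a + n_b - 2 else NA,
                  p = 1))
    }
    stop("t undefined: both SEMs are 0 but means differ")
  }
  se <- sqrt(sem_a^2 + sem_b^2)
  t <- abs(mean_b - mean_a) / se
  df <- if (df_rule == "pooled-count") {
    n_a + n_b - 2
  } else {
    (sem_a^2 + sem_b^2)^2 / (sem_a^4 / (n_a - 1) + sem_b^4 / (n_b - 1))
  }
  list(t = t, df = df, p = 2 * stats::pt(-t, df))
}

#' Contingency chi-square on a 2x2 table
#'
#' Pearson chi-square with 1 degree of freedom, without continuity
#' correction by default (Yates correction by flag); a thin wrapper around
#' [stats::chisq.test()].
#'
#' @param table 2x2 matrix of counts, or a length-4 vector filled by row.
#' @param correct apply the Yates continuity correction.
#' @return list with `statistic`, `df`, `p`.
#' @export
chisq_2x2 <- function(table, correct = FALSE) {
  if (!is.matrix(table)) {
    if (length(table) != 4) stop("need a 2x2 table")
    table <- matrix(table, 2, 2, byrow = TRUE)
  }
  if (any(table < 0)) stop("counts must be >= 0")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("both margins must be > 0")
  }
  ct <- stats::chisq.test(table, correct = correct)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Summary of replicate cross frequencies
#'
#' @param frequencies recombinant frequencies of replicate crosses.
#' @return list with `mean`, `sem`, `n`.
#' @export
cross_summary <- function(frequencies) {
  n <- length(frequencies)
  if (n < 1) stop("need at least one cross")
  list(mean = mean(frequencies),
       sem = if (n > 1) stats::sd(frequencies) / sqrt(n) else 0,
       n = n)
}
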