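#' Mean and sample standard deviation of a numeric vector
#'
#' @param x Numeric values.
#' @return A tibble with columns `n`, `mean`, `sd` (n - 1 denominator;
#'   `sd` is `NA` when `n < 2`).
#' @examples
#' group_summary(c(44, 39, 43, 41, 48, 45, 59, 61, 40, 47, 70, 138))
#' @export
group_summary <- function(x) {
  x <- x[!is.na(x)]
  tibble::tibble(n = length(x), mean = mean(x),
                 sd = if (length(x) >= 2) sd(x) else NA_real_)
}

#' Welch two-sample t-test
#'
#' Unequal-variance (Welch) t-test with Welch-Satterthwaite degrees of
#' freedom and a two-sided p-value; the pooled-variance test is available
#' via `pooled = TRUE`.
#'
#' @param x,y Numeric samples (each of size >= 2).
#' @param pooled Use the equal-variance pooled test instead of Welch.
#' @return A tibble with `estimate` (mean(x) - mean(y)), `t`, `df`,
#'   `p_value`.
#' @export
welch_t_test <- function(x, y, pooled = FALSE) {
  if (length(x) < 2 || length(y) < 2) abort("each group needs n >= 2")
  if (sd(x) == 0 && sd(y) == 0) abort("zero variance in both groups")
  fit <- t.test(x, y, var.equal = pooled)
  tibble::tibble(estimate = unname(fit$estimate[1] - fit$estimate[2]),
                 t = unname(fit$statistic), df = unname(fit$parameter),
                 p_value = fit$p.value)
}

#' Wilcoxon rank-sum test
#'
#' Two-sided Wilcoxon (Mann-Whitney) rank-sum test. The default uses the
#' normal approximation with midranks, tie-corrected variance and a
#' continuity correction; `exact = TRUE` requests the exact distribution
#' (available without ties).
#'
#' @param x,y Numeric samples.
#' @param exact `NULL` (default: approximation), or `TRUE` for the exact
#'   test.
#' @return A tibble with `W` (Mann-Whitney U for the first sample) and
#'   `p_value`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact = NULL) {
  if (length(x) < 1 || length(y) < 1) abort("each group needs n >= 1")
  fit <- suppressWarnings(
    wilcox.test(x, y, exact = isTRUE(exact), correct = TRUE))
  p <- fit$p.value
  # all observations tied across both groups: no evidence either way
  if (is.nan(p)) p <- 1
  tibble::tibble(W = unname(fit$statistic), p_value = p)
}

#' Group-level cohort summary with onset-age comparisons
#'
#' Summarises a cohort table per phenotype group (onset age and follow-up
#' mean +/- sd, sex and motor-delay counts) and compares seizure-onset age
#' between the groups with the Welch t-test and the Wilcoxon rank-sum
#' test.
#'
#' @param cohort Cohort tibble with columns `group`, `sex`, `motor_delay`,
#'   `onset_months`, `followup_months` (see [dravet_cohort()]).
#' @return A list with `summary` (one row per group) and `tests` (one row
#'   per test on onset age).
#' @examples
#' cohort_stats(dravet_cohort())
#' @export
cohort_stats <- function(cohort) {
  groups <- sort(unique(cohort$group))
  if (length(groups) != 2) abort("cohort must contain exactly two groups")
  summary <- cohort |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      onset_mean = mean(.data$onset_months),
      onset_sd = sd(.data$onset_months),
      followup_mean = mean(.data$followup_months),
      followup_sd = sd(.data$followup_months),
      n_male = sum(.data$sex == "M"),
      n_motor_delay = sum(.data$motor_delay),
      .groups = "drop")
  x <- cohort$onset_months[cohort$group == groups[1]]
  y <- cohort$onset_months[cohort$group == groups[2]]
  tests <- dplyr::bind_rows(
    dplyr::mutate(welch_t_test(x, y)[, c("p_value")], test = "welch_t",
                  .before = 1),
    dplyr::mutate(wilcoxon_rank_sum(x, y)[, c("p_value")], test = "wilcoxon",
                  .before = 1))
  list(summary = summary, tests = tests)
}
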