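#' Mann-Whitney area under the ROC curve
#'
#' AUC as the probability that a randomly chosen case scores higher than a
#' randomly chosen control, with ties counting one half: the mean over all
#' case/control pairs of 1, 1/2 or 0. Computed via midranks (equivalent to
#' the trapezoidal area under the empirical ROC curve).
#'
#' @param case_scores,control_scores Numeric score vectors (higher = more
#'   pathogenic), both non-empty.
#' @return The AUC in [0, 1].
#' @examples
#' auc(c(3, 4), c(1, 2))
#' @export
auc <- function(case_scores, control_scores) {
  m <- length(case_scores); n <- length(control_scores)
  if (m < 1 || n < 1) abort("both score vectors must be non-empty")
  r <- rank(c(case_scores, control_scores))
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

# placement values: for each case, fraction of controls it beats (ties 1/2),
# and for each control, fraction of cases beating it
placement_values <- function(cases, controls) {
  v10 <- vapply(cases, function(x)
    mean((x > controls) + 0.5 * (x == controls)), numeric(1))
  v01 <- vapply(controls, function(y)
    mean((cases > y) + 0.5 * (cases == y)), numeric(1))
  list(v10 = v10, v01 = v01)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two predictors scored on the same variants using
#' DeLong's structural-components (placement-value) estimate of the
#' variance of the AUC difference. Variants not scored by both predictors
#' are dropped pairwise with a message.
#'
#' @param scored Tibble with a `label` column
#'   (`"pathogenic_case"`/`"population_control"`, or a logical where
#'   `TRUE` = case) and one numeric score column per predictor.
#' @param predictor_a,predictor_b Names of the two score columns; the
#'   one-sided alternative `"greater"` tests AUC(a) > AUC(b).
#' @param alternative `"greater"` (default, matching the
#'   first-predictor-superiority test), `"less"` or `"two_sided"`.
#' @return A one-row tibble: `auc_a`, `auc_b`, `diff`, `se`, `z`,
#'   `p_value`, `n_cases`, `n_controls`, `alternative`.
#' @export
delong_test <- function(scored, predictor_a, predictor_b,
                        alternative = c("greater", "less", "two_sided")) {
  alternative <- match.arg(alternative)
  d <- scored_complete(scored, c(predictor_a, predictor_b))
  ca <- d$scores[d$case, predictor_a]; cb <- d$scores[d$case, predictor_b]
  ua <- d$scores[!d$case, predictor_a]; ub <- d$scores[!d$case, predictor_b]
  m <- sum(d$case); n <- sum(!d$case)
  if (m < 2 || n < 2) abort("need >= 2 cases and >= 2 controls scored by both predictors")
  pa <- placement_values(ca, ua)
  pb <- placement_values(cb, ub)
  auc_a <- mean(pa$v10); auc_b <- mean(pb$v10)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  if (var_diff <= 0) abort("zero variance of the AUC difference (degenerate scores)")
  z <- (auc_a - auc_b) / sqrt(var_diff)
  p <- switch(alternative,
              greater = pnorm(z, lower.tail = FALSE),
              less = pnorm(z),
              two_sided = 2 * pnorm(-abs(z)))
  tibble::tibble(auc_a = auc_a, auc_b = auc_b, diff = auc_a - auc_b,
                 se = sqrt(var_diff), z = z, p_value = p,
                 n_cases = m, n_controls = n, alternative = alternative)
}

scored_complete <- function(scored, predictors) {
  lab <- scored$label
  case <- if (is.logical(lab)) lab else lab == "pathogenic_case"
  sc <- as.matrix(scored[, predictors, drop = FALSE])
  keep <- complete.cases(sc)
  if (any(!keep)) {
    inform(paste0(sum(!keep), " variant(s) unscored by at least one predictor dropped"))
  }
  list(case = case[keep], scores = sc[keep, , drop = FALSE])
}

#' Stratified bootstrap test for an AUC difference
#'
#' Resamples cases and controls separately (keeping the two predictors
#' paired within each resampled variant), forms the bootstrap standard
#' error of the AUC difference, and refers the observed difference to a
#' normal reference: z = diff / se_boot.
#'
#' @inheritParams delong_test
#' @param n_boot Number of bootstrap resamples (>= 200).
#' @param seed Integer seed.
#' @return A one-row tibble: `diff`, `se_boot`, `z`, `p_value`,
#'   `alternative`.
#' @export
bootstrap_auc_test <- function(scored, predictor_a, predictor_b,
                               n_boot = 2000, seed = 1,
                               alternative = c("greater", "less", "two_sided")) {
  alternative <- match.arg(alternative)
  if (n_boot < 200) abort("n_boot must be >= 200")
  d <- scored_complete(scored, c(predictor_a, predictor_b))
  ci <- which(d$case); ui <- which(!d$case)
  diff_obs <- auc(d$scores[ci, predictor_a], d$scores[ui, predictor_a]) -
    auc(d$scores[ci, predictor_b], d$scores[ui, predictor_b])
  set.seed(seed)
  diffs <- vapply(seq_len(n_boot), function(b) {
    cb <- sample(ci, replace = TRUE); ub <- sample(ui, replace = TRUE)
    auc(d$scores[cb, predictor_a], d$scores[ub, predictor_a]) -
      auc(d$scores[cb, predictor_b], d$scores[ub, predictor_b])
  }, numeric(1))
  se <- sd(diffs)
  if (se == 0) {
    # identical predictors: the difference is identically zero and the
    # one-sided test carries no evidence either way
    if (diff_obs != 0) abort("zero bootstrap variance with a non-zero AUC difference")
    z <- 0
    p <- switch(alternative, greater = 0.5, less = 0.5, two_sided = 1)
  } else {
    z <- diff_obs / se
    p <- switch(alternative,
                greater = pnorm(z, lower.tail = FALSE),
                less = pnorm(z),
                two_sided = 2 * pnorm(-abs(z)))
  }
  tibble::tibble(diff = diff_obs, se_boot = se, z = z, p_value = p,
                 alternative = alternative)
}

#' Empirical ROC curve points
#'
#' @param case_scores,control_scores Numeric score vectors.
#' @return Tibble with `threshold`, `tpr`, `fpr`, one row per distinct
#'   threshold (plus the endpoints).
#' @export
roc_points <- function(case_scores, control_scores) {
  thr <- c(Inf, sort(unique(c(case_scores, control_scores)), decreasing = TRUE))
  tibble::tibble(
    threshold = thr,
    tpr = vapply(thr, function(t) mean(case_scores >= t), numeric(1)),
    fpr = vapply(thr, function(t) mean(control_scores >= t), numeric(1)))
}
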