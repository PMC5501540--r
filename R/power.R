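#' Poisson mutational-load power model specification
#'
#' The power framework for distinguishing phenotypic classes by mutational
#' load: group-total mutation counts are modelled as Poisson with means
#' theta0 = n0 * mu0 (severe) and theta1 = n1 * mu1 (mild), with load
#' ratio r = mu1 / mu0 <= 1 under the alternative. Three test
#' constructions are available:
#' \describe{
#'   \item{one_sample_exact}{the mild-group total is referred to the exact
#'     Poisson(theta0) null (severe-group mean treated as known); reject
#'     when the total is at or below the largest c with
#'     P(Poisson(theta0) <= c) <= alpha.}
#'   \item{two_sample_conditional}{conditional on the combined total T,
#'     the mild share is Binomial(T, n1/(n0+n1)) under the null; reject at
#'     the alpha-level binomial quantile, power averaged over
#'     T ~ Poisson(theta0 + theta1).}
#'   \item{normal_approx}{z-based rule on the mild total with null mean
#'     and variance theta0.}
#' }
#' All constructions are conservative (achieved size <= alpha) by
#' discreteness.
#'
#' @param theta0 Severe-group total Poisson mean (> 0).
#' @param r Load ratio mu1/mu0 in (0, 1].
#' @param alpha Significance level (default 0.01).
#' @param target_power Target power for threshold searches (default 0.8).
#' @param n0,n1 Group sizes (default equal; only their ratio matters).
#' @param fn_rate P(deleterious classified benign) (default 0.10).
#' @param fp_rate P(benign classified damaging) (default 0.40).
#' @param benign_load_ratio Benign-to-damaging load ratio rho (default 1).
#' @param construction Test construction (see above).
#' @return A list of class `power_spec`.
#' @export
power_spec <- function(theta0 = NULL, r = 0.5, alpha = 0.01,
                       target_power = 0.8, n0 = 1, n1 = 1,
                       fn_rate = 0.10, fp_rate = 0.40,
                       benign_load_ratio = 1,
                       construction = c("one_sample_exact",
                                        "two_sample_conditional",
                                        "normal_approx")) {
  construction <- match.arg(construction)
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie in (0, 1)")
  stopifnot(r > 0, r <= 1, fn_rate >= 0, fn_rate <= 1,
            fp_rate >= 0, fp_rate <= 1, benign_load_ratio >= 0)
  structure(list(theta0 = theta0, r = r, alpha = alpha,
                 target_power = target_power, n0 = n0, n1 = n1,
                 fn_rate = fn_rate, fp_rate = fp_rate,
                 benign_load_ratio = benign_load_ratio,
                 construction = construction),
            class = "power_spec")
}

#' Rejection rule for a mutational-load test
#'
#' @param spec A [power_spec()] with `theta0` set.
#' @return For `one_sample_exact`: a list with the integer critical value
#'   `c` (reject when the mild total is <= c; `c = -1` means the test
#'   never rejects) and the achieved size. For `two_sample_conditional`: a
#'   function `c_of_total(T)` plus the null success probability `p0`. For
#'   `normal_approx`: the real critical value.
#' @export
critical_region <- function(spec) {
  theta0 <- spec$theta0
  if (is.null(theta0) || theta0 <= 0) abort("theta0 must be > 0")
  alpha <- spec$alpha
  switch(spec$construction,
    one_sample_exact = {
      c <- qpois(alpha, theta0)
      while (c >= 0 && ppois(c, theta0) > alpha) c <- c - 1L
      list(construction = "one_sample_exact", c = c,
           size = if (c >= 0) ppois(c, theta0) else 0)
    },
    two_sample_conditional = {
      p0 <- spec$n1 / (spec$n0 + spec$n1)
      c_of_total <- function(total) {
        c <- qbinom_le(alpha, total, p0)
        c
      }
      list(construction = "two_sample_conditional", p0 = p0,
           c_of_total = c_of_total)
    },
    normal_approx = {
      list(construction = "normal_approx",
           c = theta0 + qnorm(alpha) * sqrt(theta0))
    })
}

# largest integer c with P(Binomial(n, p) <= c) <= alpha, or -1
qbinom_le <- function(alpha, n, p) {
  c <- stats::qbinom(alpha, n, p)
  while (c >= 0 && pbinom(c, n, p) > alpha) c <- c - 1L
  c
}

#' Power of a mutational-load test
#'
#' Exact tail sum of the alternative distribution over the rejection
#' region; for the conditional construction the binomial power is averaged
#' over the Poisson-distributed combined total, truncated where the
#' remaining mass is below 1e-12.
#'
#' @param spec A [power_spec()] with `theta0` set.
#' @param r Optional load ratio overriding `spec$r` (`r = 1` gives the
#'   achieved size).
#' @return The rejection probability under the alternative.
#' @export
poisson_power <- function(spec, r = NULL) {
  r <- r %||% spec$r
  theta0 <- spec$theta0
  theta1 <- r * theta0 * spec$n1 / spec$n0
  cr <- critical_region(spec)
  switch(spec$construction,
    one_sample_exact = if (cr$c < 0) 0 else ppois(cr$c, theta1),
    two_sample_conditional = {
      tot_mean <- theta0 + theta1
      p1 <- theta1 / tot_mean
      lo <- qpois(1e-13, tot_mean)
      hi <- qpois(1 - 1e-13, tot_mean)
      tt <- lo:hi
      cs <- vapply(tt, cr$c_of_total, numeric(1))
      sum(dpois(tt, tot_mean) *
            ifelse(cs >= 0, pbinom(cs, tt, p1), 0))
    },
    normal_approx = pnorm((cr$c - theta1) / sqrt(theta1)))
}

#' Smallest theta0 achieving the target power
#'
#' Scans theta0 on an integer grid (mutation counts are integers in
#' spirit) and returns the smallest value whose power at load ratio `r`
#' reaches `target_power`. Because the exact constructions are not
#' perfectly monotone in theta0 (the critical value moves in discrete
#' jumps), the scan verifies the bracketing: the returned theta0 achieves
#' the target and its predecessor on the grid does not.
#'
#' @param spec A [power_spec()] (`theta0` ignored; `r` must be < 1).
#' @param step Grid step (default 1).
#' @param theta_max Upper search bound (default 5000).
#' @return The smallest grid theta0 with power >= `target_power`.
#' @export
min_theta0 <- function(spec, step = 1, theta_max = 5000) {
  if (spec$r >= 1) abort("r must be < 1 for a threshold search")
  grid <- seq(step, theta_max, by = step)
  for (t0 in grid) {
    s <- spec; s$theta0 <- t0
    if (poisson_power(s) >= spec$target_power) return(t0)
  }
  abort("no theta0 below theta_max reaches the target power")
}

#' Misclassification-adjusted load parameters
#'
#' With a false-negative rate fn (deleterious called benign), a
#' false-positive rate fp (benign called damaging) and a benign load equal
#' to rho times the severe-group damaging load in both groups, the
#' observed damaging load becomes theta0' = theta0 ((1 - fn) + fp rho) in
#' the severe group, and the observed load ratio is diluted toward the
#' null: r' = ((1 - fn) r + fp rho) / ((1 - fn) + fp rho) >= r.
#'
#' @param spec A [power_spec()].
#' @return A list with `theta0_obs` (`NULL` when `spec$theta0` is), `r_obs`
#'   and `inflation` (the factor (1 - fn) + fp rho).
#' @examples
#' adjust_misclassification(power_spec(r = 0.5))$r_obs  # 17/26
#' @export
adjust_misclassification <- function(spec) {
  fn <- spec$fn_rate; fp <- spec$fp_rate; rho <- spec$benign_load_ratio
  infl <- (1 - fn) + fp * rho
  r_obs <- ((1 - fn) * spec$r + fp * rho) / infl
  list(theta0_obs = if (is.null(spec$theta0)) NULL else spec$theta0 * infl,
       r_obs = r_obs, inflation = infl)
}

#' Misclassification-adjusted minimum observed load
#'
#' The smallest observed-scale theta0 achieving the target power once
#' classification noise has diluted the load ratio; this is the quantity
#' that rises sharply when pathogenicity calls are imperfect.
#'
#' @inheritParams min_theta0
#' @return Smallest observed theta0 with power >= target at the diluted
#'   ratio.
#' @export
min_theta0_adjusted <- function(spec, step = 1, theta_max = 5000) {
  adj <- adjust_misclassification(spec)
  s <- spec
  s$r <- adj$r_obs
  s$fn_rate <- 0; s$fp_rate <- 0
  min_theta0(s, step = step, theta_max = theta_max)
}

#' Power curve over a theta0 grid
#'
#' @param spec A [power_spec()] (`theta0` ignored).
#' @param theta0_grid Grid of theta0 values.
#' @param r_values Load ratios to evaluate.
#' @return Tidy tibble: `theta0`, `r`, `construction`, `power`.
#' @export
power_curve <- function(spec, theta0_grid = seq(5, 300, by = 5),
                        r_values = c(0.5, 2 / 3)) {
  tidyr::expand_grid(theta0 = theta0_grid, r = r_values) |>
    dplyr::mutate(construction = spec$construction,
                  power = purrr::map2_dbl(.data$theta0, .data$r, function(t0, r) {
                    s <- spec; s$theta0 <- t0
                    poisson_power(s, r = r)
                  }))
}
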