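#' Tidy the per-SNP components of a region score test
#'
#' @param x A `score_test_result`.
#' @param ... Unused.
#' @return Tibble with one row per SNP: `site_id`, score `S`, `weight`,
#'   `partial` contribution.
#' @export
tidy.score_test_result <- function(x, ...) x$snp

#' One-row summary of a region score test
#'
#' @param x A `score_test_result`.
#' @param ... Unused.
#' @return Tibble with `region`, `Q`, `p_value`, `partial_mean`,
#'   `partial_sd`, `n_snps`, `n`.
#' @export
glance.score_test_result <- function(x, ...) {
  tibble::tibble(region = x$region, Q = x$Q, p_value = x$p_value,
                 partial_mean = x$partial_mean, partial_sd = x$partial_sd,
                 n_snps = nrow(x$snp), n = x$n)
}

#' @exportS3Method base::print
print.score_test_result <- function(x, ...) {
  cat("Region score test '", x$region, "': Q = ", signif(x$Q, 4),
      " (partial mean = ", signif(x$partial_mean, 3), " +/- ",
      signif(x$partial_sd, 3), "), p = ", signif(x$p_value, 3), "\n", sep = "")
  invisible(x)
}

#' Tidy the coefficients of a logistic null model
#'
#' @param x A `null_model`.
#' @param ... Unused.
#' @return Coefficient tibble: `term`, `estimate`, `std_error`,
#'   `statistic`, `p_value`.
#' @export
tidy.null_model <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(co), estimate = co[, 1], std_error = co[, 2],
                 statistic = co[, 3], p_value = co[, 4])
}

#' One-row summary of a logistic null model
#'
#' @param x A `null_model`.
#' @param ... Unused.
#' @return Tibble with `n`, `df_residual`, `deviance`, `null_deviance`,
#'   `converged`, `quasi_separated`.
#' @export
glance.null_model <- function(x, ...) {
  tibble::tibble(n = length(x$y), df_residual = x$fit$df.residual,
                 deviance = x$fit$deviance, null_deviance = x$fit$null.deviance,
                 converged = x$converged, quasi_separated = x$quasi_separated)
}

#' Tidy a burden table into one row per class/category/group
#'
#' @param x A `burden_table`.
#' @param ... Unused.
#' @return The class-level count tibble with group sizes joined.
#' @export
tidy.burden_table <- function(x, ...) {
  dplyr::left_join(x$counts, x$groups, by = "group")
}

#' Category/group totals of a burden table as a one-step summary
#'
#' @param x A `burden_table`.
#' @param ... Unused.
#' @return The [burden_totals()] tibble.
#' @export
glance.burden_table <- function(x, ...) burden_totals(x)
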