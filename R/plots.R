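#' Manhattan plot of a genotype scan
#'
#' @param scan Result of [genotype_scan()] with `chrom` and `pos` columns.
#' @return A ggplot object: -log10(p) by position, faceted free-x by
#'   chromosome.
#' @export
plot_manhattan <- function(scan) {
  stopifnot(all(c("chrom", "pos", "p_value") %in% names(scan)))
  ggplot2::ggplot(scan, ggplot2::aes(x = .data$pos, y = -log10(.data$p_value))) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "position", y = expression(-log[10](p))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.spacing = ggplot2::unit(0.1, "lines"))
}

#' Bar chart of burden allele frequencies by category and group
#'
#' @param burden A `burden_table` from [aggregate_burden()].
#' @return A ggplot object mirroring the damaging-vs-benign frequency
#'   comparison across phenotype groups.
#' @export
plot_burden_frequencies <- function(burden) {
  burden_totals(burden) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$pathogenicity, y = .data$frequency,
                                 fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "alternate-allele frequency", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Empirical ROC curves for one or more predictors
#'
#' @param scored Tibble with `label` and one numeric column per predictor.
#' @param predictors Score columns to draw (default: all numeric columns).
#' @return A ggplot object with one ROC curve per predictor and the
#'   chance diagonal.
#' @export
plot_roc <- function(scored, predictors = NULL) {
  predictors <- predictors %||%
    names(scored)[vapply(scored, is.numeric, logical(1))]
  case <- if (is.logical(scored$label)) scored$label else
    scored$label == "pathogenic_case"
  pts <- purrr::map_dfr(predictors, function(p) {
    s <- scored[[p]]
    ok <- !is.na(s)
    dplyr::mutate(roc_points(s[ok & case], s[ok & !case]), predictor = p)
  })
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                    colour = .data$predictor)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Power curves of the Poisson mutational-load model
#'
#' @param curve Tibble from [power_curve()] (may stack several
#'   constructions).
#' @param target Horizontal reference line (default 0.8).
#' @return A ggplot object: power against theta0, coloured by load ratio,
#'   line-typed by construction.
#' @export
plot_power_curve <- function(curve, target = 0.8) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$theta0, y = .data$power,
                                      colour = factor(round(.data$r, 3)),
                                      linetype = .data$construction)) +
    ggplot2::geom_hline(yintercept = target, linetype = 3, colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(theta[0]), y = "power",
                  colour = "load ratio r", linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Per-SNP partial-score contributions of a region score test
#'
#' @param result A `score_test_result`.
#' @return A ggplot bar chart of partial contributions q_j per site.
#' @export
plot_partial_scores <- function(result) {
  tidy(result) |>
    ggplot2::ggplot(ggplot2::aes(x = stats::reorder(.data$site_id, -.data$partial),
                                 y = .data$partial)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "partial score contribution") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
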