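#' Fisher exact test for a 2x2 contingency table
#'
#' Exact conditional (hypergeometric) test. The two-sided p-value sums the
#' probabilities of all tables, with the observed margins, whose point
#' probability does not exceed the observed one (within a small relative
#' tolerance for ties); one-tailed alternatives refer to the first cell:
#' `"less"` tests for a deficit of the first-row/first-column category in
#' the first group.
#'
#' @param tbl A 2x2 matrix of non-negative integer counts (rows = groups,
#'   columns = category present / absent), or a length-4 vector
#'   `c(a, b, c, d)` filled row-wise.
#' @param alternative `"two_sided"` (default), `"less"` or `"greater"`.
#' @return The exact p-value (scalar). An all-zero table returns 1 with a
#'   warning.
#' @examples
#' fisher_exact_2x2(c(18, 918, 46, 1202), alternative = "less")
#' fisher_exact_2x2(c(35, 1225, 48, 1632))
#' @export
fisher_exact_2x2 <- function(tbl, alternative = c("two_sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (!is.matrix(tbl)) tbl <- matrix(tbl, nrow = 2, byrow = TRUE)
  if (any(tbl < 0) || any(tbl != round(tbl))) {
    abort("table cells must be non-negative integers")
  }
  if (sum(tbl) == 0) {
    warn("all-zero contingency table; p = 1 by convention")
    return(1)
  }
  alt <- switch(alternative, two_sided = "two.sided", less = "less",
                greater = "greater")
  fisher.test(tbl, alternative = alt)$p.value
}

#' Smallest attainable two-sided Fisher p-value for two group sizes
#'
#' With groups of size `n1` and `n2`, complete separation (fixation of
#' opposite genotypes in the two groups) gives the most extreme 2x2 table
#' attainable, with two-sided p = 1 / C(n1 + n2, n1) when the group sizes
#' differ. With equal group sizes the opposite separation table has
#' exactly the same point probability, the two tie, and the minimum
#' attainable two-sided p doubles to 2 / C(2n, n). Either way the value
#' agrees with [fisher_exact_2x2()] on the separation table and is the
#' floor on any per-site p-value in a genotype scan.
#'
#' @param n1,n2 Group sizes (>= 1).
#' @return The minimum attainable two-sided p-value.
#' @examples
#' min_attainable_p(9, 12)  # 1 / 293930 = 3.4e-6
#' @export
min_attainable_p <- function(n1, n2) {
  stopifnot(n1 >= 1, n2 >= 1)
  (1 + (n1 == n2)) / choose(n1 + n2, n1)
}

#' Per-site Fisher exact genotype scan between phenotype groups
#'
#' Tests every site for a genotype-frequency difference between the two
#' phenotype groups. The default carrier coding collapses genotypes to
#' carries-alternate vs does-not (2x2 table); `coding = "genotype3"` uses
#' the full 2x3 genotype table with the Freeman-Halton extension of the
#' Fisher test. Missing genotypes are excluded per site; sites with no
#' non-missing genotype in one of the groups are skipped with a message.
#'
#' @param genotypes Genotype tibble.
#' @param cohort Cohort tibble with `id` and `group`.
#' @param variants Optional variant tibble; if given, `chrom` and `pos`
#'   are joined onto the result for plotting.
#' @param coding `"carrier"` (default) or `"genotype3"`.
#' @return A tibble sorted ascending by `p_value` with columns `site_id`,
#'   (`chrom`, `pos`,) carrier counts, `p_value`, `rank` and a Bonferroni
#'   column (informational only; nothing is filtered on it).
#' @export
genotype_scan <- function(genotypes, cohort, variants = NULL,
                          coding = c("carrier", "genotype3")) {
  coding <- match.arg(coding)
  grp <- setNames(cohort$group, cohort$id)
  groups <- sort(unique(cohort$group))
  if (length(groups) != 2) abort("cohort must contain exactly two groups")
  df <- genotypes |>
    dplyr::mutate(group = grp[.data$sample_id]) |>
    dplyr::filter(.data$gt != "missing")

  one_site <- function(d) {
    if (length(unique(d$group)) < 2) return(NA_real_)
    if (coding == "carrier") {
      carrier <- d$gt %in% c("het", "hom_alt")
      tab <- table(factor(d$group, levels = groups),
                   factor(carrier, levels = c(TRUE, FALSE)))
      if (sum(tab[, 1]) == 0 || sum(tab[, 1]) == sum(tab)) return(1)
      fisher.test(tab)$p.value
    } else {
      tab <- table(factor(d$group, levels = groups),
                   factor(d$gt, levels = c("hom_ref", "het", "hom_alt")))
      tab <- tab[, colSums(tab) > 0, drop = FALSE]
      if (ncol(tab) < 2) return(1)
      fisher.test(tab)$p.value
    }
  }

  res <- df |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(
      n_carrier_1 = sum(.data$group == groups[1] & .data$gt %in% c("het", "hom_alt")),
      n_carrier_2 = sum(.data$group == groups[2] & .data$gt %in% c("het", "hom_alt")),
      p_value = one_site(dplyr::pick(dplyr::everything())),
      .groups = "drop")
  skipped <- res$site_id[is.na(res$p_value)]
  if (length(skipped) > 0) {
    inform(paste0(length(skipped),
                  " site(s) with genotypes in only one group skipped"))
    res <- res[!is.na(res$p_value), , drop = FALSE]
  }
  res <- res |>
    dplyr::arrange(.data$p_value) |>
    dplyr::mutate(rank = dplyr::row_number(),
                  p_bonferroni = pmin(1, .data$p_value * dplyr::n()))
  if (!is.null(variants)) {
    res <- dplyr::left_join(res, variants[, c("site_id", "chrom", "pos")],
                            by = "site_id") |>
      dplyr::relocate("chrom", "pos", .after = "site_id")
  }
  res
}

#' Compare cohort counts against an external reference population
#'
#' Generic two-group contingency comparison of a genotype (or allele)
#' category between the study cohort and an external reference for which
#' only counts are available, e.g. a risk-genotype frequency of 0.19 in 21
#' patients against 0.05 in 504 reference individuals.
#'
#' @param k_cohort,n_cohort Category count and total in the cohort.
#' @param k_ref,n_ref Category count and total in the reference.
#' @param alternative Passed to [fisher_exact_2x2()].
#' @return The Fisher exact p-value.
#' @examples
#' cohort_vs_reference(4, 21, 25, 504)
#' @export
cohort_vs_reference <- function(k_cohort, n_cohort, k_ref, n_ref,
                                alternative = "two_sided") {
  fisher_exact_2x2(c(k_cohort, n_cohort - k_cohort, k_ref, n_ref - k_ref),
                   alternative = alternative)
}
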