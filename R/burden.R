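#' Normalise pathogenicity annotations to damaging / benign
#'
#' Collapses categorical predictor calls to the two-level damaging/benign
#' factor used by the burden analysis: `"possibly_damaging"` and
#' `"probably_damaging"` (and `"damaging"`) map to damaging, `"benign"` to
#' benign. Alternatively a numeric score column is dichotomised at a
#' cutpoint (score >= cutpoint is damaging; the boundary is inclusive).
#' Unscored variants are excluded with a message.
#'
#' @param variants Variant tibble with a `patho_call` column, or a numeric
#'   column named by `score_col`.
#' @param score_col Optional name of a numeric score column.
#' @param cutpoint Damaging cutpoint for `score_col` (inclusive).
#' @return The variant tibble with `patho_call` in `{"damaging","benign"}`,
#'   unscored rows removed.
#' @export
classify_pathogenicity <- function(variants, score_col = NULL, cutpoint = NULL) {
  if (!is.null(score_col)) {
    if (is.null(cutpoint)) abort("cutpoint required with score_col")
    s <- variants[[score_col]]
    call <- ifelse(is.na(s), "unscored", ifelse(s >= cutpoint, "damaging", "benign"))
  } else {
    raw <- tolower(variants$patho_call %||% rep(NA_character_, nrow(variants)))
    call <- dplyr::case_when(
      raw %in% c("damaging", "possibly_damaging", "probably_damaging") ~ "damaging",
      raw %in% "benign" ~ "benign",
      TRUE ~ "unscored")
  }
  n_un <- sum(call == "unscored")
  if (n_un > 0) inform(paste0(n_un, " unscored variant(s) excluded"))
  out <- variants[call != "unscored", , drop = FALSE]
  out$patho_call <- call[call != "unscored"]
  out
}

#' Aggregate rare-variant allele counts by gene class, category and group
#'
#' Counts alternate alleles (het = 1, hom-alt = 2, missing = 0) per
#' (gene class, pathogenicity category, phenotype group) for a genotype
#' matrix already restricted to qualifying rare variants in the candidate
#' panel. Variants mapping to no gene class are excluded with a message.
#'
#' @param genotypes Genotype tibble.
#' @param variants Variant tibble with `gene` and a two-level
#'   `patho_call` (see [classify_pathogenicity()]).
#' @param gene_sets Gene-set tibble from [load_gene_sets()].
#' @param cohort Cohort tibble (`id`, `group`).
#' @return An object of class `burden_table`: a list with `counts`
#'   (tibble `gene_class` x `pathogenicity` x `group` -> `alt_alleles`,
#'   complete grid), `sites` (sites per pathogenicity category) and
#'   `groups` (individuals per group).
#' @export
aggregate_burden <- function(genotypes, variants, gene_sets, cohort) {
  variants <- classify_pathogenicity(variants)
  v <- dplyr::left_join(variants, gene_sets, by = "gene")
  orphan <- is.na(v$class)
  if (any(orphan)) {
    inform(paste0(sum(orphan), " variant(s) outside the gene panel excluded"))
    v <- v[!orphan, , drop = FALSE]
  }
  grp <- setNames(cohort$group, cohort$id)
  dose <- c(hom_ref = 0, het = 1, hom_alt = 2, missing = 0)
  counts <- genotypes |>
    dplyr::inner_join(v[, c("site_id", "class", "patho_call")], by = "site_id") |>
    dplyr::mutate(group = grp[.data$sample_id], alt = dose[.data$gt]) |>
    dplyr::group_by(gene_class = .data$class, pathogenicity = .data$patho_call,
                    group = .data$group) |>
    dplyr::summarise(alt_alleles = sum(.data$alt), .groups = "drop")
  grid <- tidyr::expand_grid(
    gene_class = intersect(GENE_CLASSES, unique(gene_sets$class)),
    pathogenicity = c("damaging", "benign"),
    group = sort(unique(cohort$group)))
  counts <- grid |>
    dplyr::left_join(counts, by = c("gene_class", "pathogenicity", "group")) |>
    dplyr::mutate(alt_alleles = as.integer(tidyr::replace_na(.data$alt_alleles, 0L)))
  sites <- v |>
    dplyr::count(pathogenicity = .data$patho_call, name = "n_sites") |>
    tidyr::complete(pathogenicity = c("damaging", "benign"),
                    fill = list(n_sites = 0L))
  groups <- dplyr::count(cohort, .data$group, name = "n_individuals")
  structure(list(counts = counts, sites = sites, groups = groups),
            class = "burden_table")
}

#' @exportS3Method base::print
print.burden_table <- function(x, ...) {
  cat("Burden table:",
      sum(x$sites$n_sites), "qualifying sites,",
      sum(x$groups$n_individuals), "individuals\n")
  print(burden_totals(x))
  invisible(x)
}

#' Category-by-group allele totals of a burden table
#'
#' Sums a burden table over gene classes and attaches the site-by-2N
#' allele denominators and frequencies.
#'
#' @param burden A `burden_table` from [aggregate_burden()].
#' @return Tibble with one row per (pathogenicity, group): `alt_alleles`,
#'   `n_sites`, `n_individuals`, `total_alleles`, `ref_alleles`,
#'   `frequency`.
#' @export
burden_totals <- function(burden) {
  burden$counts |>
    dplyr::group_by(.data$pathogenicity, .data$group) |>
    dplyr::summarise(alt_alleles = sum(.data$alt_alleles), .groups = "drop") |>
    dplyr::left_join(burden$sites, by = "pathogenicity") |>
    dplyr::left_join(burden$groups, by = "group") |>
    dplyr::mutate(
      total_alleles = .data$n_sites * 2L * .data$n_individuals,
      ref_alleles = .data$total_alleles - .data$alt_alleles,
      frequency = ifelse(.data$total_alleles > 0,
                         .data$alt_alleles / .data$total_alleles, NaN))
}

#' Class-level allele frequency under the site-by-2N convention
#'
#' The total number of alleles in a pathogenicity category is the number
#' of distinct qualifying variant sites times two chromosomes times the
#' number of individuals; the frequency is the alternate-allele count over
#' that denominator. This is the convention under which the published
#' reference-allele counts (918, 1202, 1225, 1632) and frequencies
#' (0.019, 0.037, 0.031, 0.030) are reproduced.
#'
#' @param alt_count Alternate-allele count.
#' @param n_sites Number of distinct qualifying variant sites.
#' @param n_individuals Number of individuals in the group.
#' @return `alt_count / (n_sites * 2 * n_individuals)`.
#' @examples
#' allele_frequency(46, 52, 12)  # 0.037
#' @export
allele_frequency <- function(alt_count, n_sites, n_individuals) {
  stopifnot(all(n_sites >= 1), all(n_individuals >= 1))
  alt_count / (n_sites * 2 * n_individuals)
}

#' Burden Fisher test between two groups for one pathogenicity category
#'
#' Builds the 2x2 table of alternate vs non-alternate alleles for the
#' chosen category (non-alternate = site-by-2N total minus alternate) and
#' delegates to [fisher_exact_2x2()]. The default one-tailed direction
#' tests for a deficit of alternate alleles in the first group (the
#' published contrast: fewer damaging alleles in the mild group).
#'
#' @param burden A `burden_table`, or `NULL` if counts are given directly.
#' @param category `"damaging"` or `"benign"`.
#' @param groups Length-2 character: which groups to compare (first group
#'   is the deficit side under `alternative = "less"`).
#' @param alternative Passed to [fisher_exact_2x2()].
#' @param counts Optional direct specification, bypassing `burden`: a list
#'   with `alt` (length 2) and `total` (length 2) allele counts.
#' @return The Fisher exact p-value.
#' @examples
#' burden_fisher(counts = list(alt = c(18, 46), total = c(936, 1248)),
#'               alternative = "less")
#' @export
burden_fisher <- function(burden = NULL, category = "damaging",
                          groups = c("mild", "severe"),
                          alternative = "less", counts = NULL) {
  if (is.null(counts)) {
    tot <- burden_totals(burden) |>
      dplyr::filter(.data$pathogenicity == category,
                    .data$group %in% groups) |>
      dplyr::arrange(match(.data$group, groups))
    if (nrow(tot) != 2) abort("need exactly two groups for the comparison")
    if (any(tot$n_sites == 0)) abort(paste0("no qualifying sites in category '",
                                            category, "'"))
    counts <- list(alt = tot$alt_alleles, total = tot$total_alleles)
  }
  fisher_exact_2x2(c(counts$alt[1], counts$total[1] - counts$alt[1],
                     counts$alt[2], counts$total[2] - counts$alt[2]),
                   alternative = alternative)
}

#' Per-variant carrier counts and recurrence
#'
#' Reports, for every variant, the number of carriers in each phenotype
#' group and whether it is a singleton (exactly one carrier overall).
#' Mirrors the published observation that nearly all qualifying rare
#' variants were singletons, with a handful shared among severely
#' affected individuals (e.g. a KCNQ2 variant in three severe carriers).
#'
#' @param genotypes Genotype tibble.
#' @param cohort Cohort tibble (`id`, `group`).
#' @return Tibble with `site_id`, one carrier-count column per group,
#'   `n_carriers`, `singleton`.
#' @export
recurrence_report <- function(genotypes, cohort) {
  grp <- setNames(cohort$group, cohort$id)
  genotypes |>
    dplyr::mutate(group = grp[.data$sample_id],
                  carrier = .data$gt %in% c("het", "hom_alt")) |>
    dplyr::group_by(.data$site_id, .data$group) |>
    dplyr::summarise(k = sum(.data$carrier), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "group", values_from = "k",
                       names_prefix = "carriers_", values_fill = 0L) |>
    dplyr::mutate(n_carriers = rowSums(dplyr::across(dplyr::starts_with("carriers_"))),
                  singleton = .data$n_carriers == 1)
}
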