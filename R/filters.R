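#' Filter configuration for rare-variant quality control
#'
#' Bundles the thresholds of the four-stage filter: per-site missingness,
#' functional impact class, reference-population minor allele frequency,
#' and the exact binomial allelic-balance test on heterozygous calls.
#' Defaults reproduce the published pipeline: sites with more than 2
#' missing genotypes removed, protein-altering impacts only, MAF at most
#' 1% (inclusive), and a 1% lower probability limit on allelic balance.
#'
#' @param max_missing_individuals Maximum tolerated number of missing
#'   genotypes per site (default 2; sites exceeding it are dropped).
#' @param maf_threshold Reference-population MAF cutoff, inclusive
#'   (default 0.01).
#' @param ab_alpha Lower limit on the two-sided exact binomial probability
#'   of the observed allele-depth split at a het call (default 0.01).
#' @param qualifying_impacts Impact classes retained by the impact filter.
#' @param keep_unscored_impact Retain variants whose impact annotation is
#'   missing (default `FALSE`; dropped with a message).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(max_missing_individuals = 2,
                          maf_threshold = 0.01,
                          ab_alpha = 0.01,
                          qualifying_impacts = QUALIFYING_IMPACTS,
                          keep_unscored_impact = FALSE) {
  stopifnot(max_missing_individuals >= 0,
            maf_threshold > 0, maf_threshold <= 1,
            ab_alpha > 0, ab_alpha < 1)
  structure(list(max_missing_individuals = max_missing_individuals,
                 maf_threshold = maf_threshold,
                 ab_alpha = ab_alpha,
                 qualifying_impacts = qualifying_impacts,
                 keep_unscored_impact = keep_unscored_impact),
            class = "filter_config")
}

#' Drop sites with too many missing genotypes
#'
#' Removes every site at which the number of missing genotype calls
#' exceeds `max_missing_individuals` (boundary inclusive: a site with
#' exactly that many missing calls is retained). Site order is preserved.
#'
#' @param genotypes Genotype tibble (`sample_id`, `site_id`, `gt`, ...).
#' @param config A [filter_config()].
#' @return The filtered genotype tibble; dropped site ids are attached as
#'   attribute `"dropped_sites"`.
#' @export
missingness_filter <- function(genotypes, config = filter_config()) {
  miss <- genotypes |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(n_missing = sum(.data$gt == "missing"), .groups = "drop")
  drop <- miss$site_id[miss$n_missing > config$max_missing_individuals]
  out <- dplyr::filter(genotypes, !(.data$site_id %in% drop))
  attr(out, "dropped_sites") <- drop
  out
}

#' Keep protein-altering variants only
#'
#' Retains variants whose impact class is in
#' `config$qualifying_impacts` (default: missense, stop-gain, stop-loss,
#' frameshift, splice-junction). Variants with a missing impact annotation
#' are dropped (with a message) unless `config$keep_unscored_impact`.
#'
#' @param variants Variant tibble.
#' @inheritParams missingness_filter
#' @return Filtered variant tibble.
#' @export
impact_filter <- function(variants, config = filter_config()) {
  unscored <- is.na(variants$impact)
  if (any(unscored) && !config$keep_unscored_impact) {
    inform(paste0(sum(unscored), " variant(s) without impact annotation dropped"))
  }
  keep <- variants$impact %in% config$qualifying_impacts |
    (unscored & config$keep_unscored_impact)
  variants[keep, , drop = FALSE]
}

#' Keep rare variants by reference-population frequency
#'
#' Retains sites whose reference-population allele frequency is at most
#' `maf_threshold` (inclusive). A missing frequency means the variant is
#' absent from the reference database and is treated as novel (frequency
#' 0), hence retained.
#'
#' @inheritParams impact_filter
#' @return Filtered variant tibble.
#' @export
maf_filter <- function(variants, config = filter_config()) {
  f <- variants$ref_pop_freq
  variants[is.na(f) | f <= config$maf_threshold, , drop = FALSE]
}

#' Exact binomial allelic-balance test for heterozygous calls
#'
#' Under a correct heterozygous call, the alternate-read count at read
#' depth n is Binomial(n, 1/2). The test doubles the smaller exact tail,
#' p = min(1, 2 P(X <= min(alt, n - alt))), and passes the call when
#' p >= `ab_alpha`. Strong skew toward either allele signals a likely
#' genotyping artifact. Vectorised over calls.
#'
#' @param alt_reads Alternate-allele read counts.
#' @param total_reads Total read depths (must be >= 1).
#' @param ab_alpha Probability lower limit (default 0.01).
#' @return Logical vector: `TRUE` where the call passes.
#' @examples
#' allelic_balance_pass(15, 30)  # balanced: pass
#' allelic_balance_pass(2, 30)   # heavily skewed: fail
#' @export
allelic_balance_pass <- function(alt_reads, total_reads, ab_alpha = 0.01) {
  if (any(total_reads < 1)) abort("total_reads must be >= 1")
  if (any(alt_reads < 0 | alt_reads > total_reads)) {
    abort("alt_reads must lie in [0, total_reads]")
  }
  k <- pmin(alt_reads, total_reads - alt_reads)
  p <- pmin(1, 2 * pbinom(k, total_reads, 0.5))
  p >= ab_alpha
}

#' Set allelic-balance failures to missing
#'
#' Applies [allelic_balance_pass()] to every heterozygous call with
#' recorded allele depths; failing calls are set to `missing` (treated as
#' uncallable rather than reference), after which the missingness filter
#' should be re-applied.
#'
#' @inheritParams missingness_filter
#' @return Genotype tibble with failing het calls set to missing; the
#'   failed (sample, site) pairs are attached as attribute `"ab_failures"`.
#' @export
allelic_balance_filter <- function(genotypes, config = filter_config()) {
  is_het <- genotypes$gt == "het" &
    !is.na(genotypes$ad_ref) & !is.na(genotypes$ad_alt) &
    (genotypes$ad_ref + genotypes$ad_alt) >= 1
  fail <- rep(FALSE, nrow(genotypes))
  if (any(is_het)) {
    fail[is_het] <- !allelic_balance_pass(
      genotypes$ad_alt[is_het],
      genotypes$ad_ref[is_het] + genotypes$ad_alt[is_het],
      config$ab_alpha)
  }
  out <- genotypes
  out$gt[fail] <- "missing"
  attr(out, "ab_failures") <- genotypes[fail, c("sample_id", "site_id")]
  out
}

#' Run the full variant-filter pipeline
#'
#' Applies, in order: impact filter, MAF filter, allelic-balance filter
#' (failing het calls become missing), and the missingness filter
#' (re-applied after allelic balance so sites with too many uncallable
#' genotypes drop out). The three site-level filters commute; the order
#' only affects the audit log.
#'
#' @param variants Variant tibble.
#' @param genotypes Genotype tibble.
#' @param config A [filter_config()].
#' @return A list with `variants`, `genotypes` (restricted to surviving
#'   sites) and `audit`, a tibble of dropped sites/calls with reasons.
#' @export
apply_filters <- function(variants, genotypes, config = filter_config()) {
  audit <- list()
  v1 <- impact_filter(variants, config)
  audit$impact <- tibble::tibble(
    site_id = setdiff(variants$site_id, v1$site_id), reason = "impact")
  v2 <- maf_filter(v1, config)
  audit$maf <- tibble::tibble(
    site_id = setdiff(v1$site_id, v2$site_id), reason = "maf")
  g <- dplyr::filter(genotypes, .data$site_id %in% v2$site_id)
  g <- allelic_balance_filter(g, config)
  ab <- attr(g, "ab_failures")
  if (!is.null(ab) && nrow(ab) > 0) {
    audit$ab <- tibble::tibble(
      site_id = paste(ab$site_id, ab$sample_id, sep = "@"),
      reason = "allelic_balance")
  }
  g2 <- missingness_filter(g, config)
  audit$missing <- tibble::tibble(
    site_id = attr(g2, "dropped_sites") %||% character(), reason = "missingness")
  v3 <- dplyr::filter(v2, .data$site_id %in% unique(g2$site_id))
  list(variants = v3, genotypes = g2, audit = dplyr::bind_rows(audit))
}
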