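#' Simulation specification for a synthetic extreme-phenotype study
#'
#' Collects every parameter of the synthetic-data generators. The defaults
#' reproduce the structure of the study design this package emulates:
#' 9 mild and 12 severe individuals; 52 damaging and 70 benign rare
#' missense sites across the 237-gene candidate panel; per-site mild-group
#' damaging carrier probability 18 / (52 x 9) and severe-to-mild
#' enrichment (46/12) / (18/9) = 23/12, so the expected damaging allele
#' totals are (18, 46); a group-homogeneous benign carrier probability
#' 83 / (70 x 21) giving expected benign totals (35.5, 47.4); per-site
#' reference-population MAF log-uniform on [1e-4, 1e-2]; mean read depth
#' 60 with no injected false hets by default.
#'
#' @param n_mild,n_severe Group sizes (>= 1).
#' @param n_damaging_sites,n_benign_sites Rare qualifying sites per
#'   pathogenicity category.
#' @param n_common_sites Extra common sites (`ref_pop_freq` > 1%) included
#'   to exercise the MAF filter.
#' @param n_nonqualifying_sites Extra synonymous sites to exercise the
#'   impact filter.
#' @param maf_range Interval within (0, 0.01] for rare-site
#'   reference-population frequencies (drawn log-uniform).
#' @param damaging_rate_mild Per-site per-individual damaging het carrier
#'   probability in the mild group.
#' @param damaging_enrichment Relative damaging carrier rate, severe vs
#'   mild (>= 1).
#' @param benign_rate Per-site benign carrier probability, common to the
#'   groups.
#' @param mean_depth Expected reads per site (> 0).
#' @param false_het_rate Fraction of het calls that are injected false
#'   positives with skewed allele depths.
#' @param p_skew Alternate-read probability for injected false hets
#'   (<= 0.1).
#' @param onset_mild,onset_severe,followup_mild,followup_severe Lists
#'   `list(mean=, sd=)` for the integer onset-age and follow-up
#'   distributions (rounded normal, truncated at 1; `sd = 0` is
#'   degenerate at the mean).
#' @param p_male_mild,p_male_severe,p_motor_mild,p_motor_severe Bernoulli
#'   rates for sex and motor delay per group.
#' @param auc_target Default binormal AUC for [simulate_scores()].
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_mild = 9, n_severe = 12,
                            n_damaging_sites = 52, n_benign_sites = 70,
                            n_common_sites = 15, n_nonqualifying_sites = 10,
                            maf_range = c(1e-4, 1e-2),
                            damaging_rate_mild = 18 / (52 * 9),
                            damaging_enrichment = (46 / 12) / (18 / 9),
                            benign_rate = 83 / (70 * 21),
                            mean_depth = 60, false_het_rate = 0, p_skew = 0.02,
                            onset_mild = list(mean = 7.6, sd = 3.0),
                            onset_severe = list(mean = 5.2, sd = 2.3),
                            followup_mild = list(mean = 186.1, sd = 39.4),
                            followup_severe = list(mean = 56.3, sd = 27.5),
                            p_male_mild = 5 / 9, p_male_severe = 4 / 12,
                            p_motor_mild = 3 / 9, p_motor_severe = 11 / 12,
                            auc_target = 0.798) {
  stopifnot(n_mild >= 1, n_severe >= 1,
            damaging_enrichment >= 1,
            damaging_rate_mild >= 0, damaging_rate_mild <= 1,
            damaging_rate_mild * damaging_enrichment <= 1,
            benign_rate >= 0, benign_rate <= 1,
            false_het_rate >= 0, false_het_rate <= 1,
            p_skew > 0, p_skew <= 0.1,
            maf_range[1] > 0, maf_range[2] <= 0.01,
            maf_range[1] <= maf_range[2])
  if (auc_target < 0.5 || auc_target > 1) abort("auc_target must lie in [0.5, 1]")
  structure(as.list(environment()), class = "simulation_spec")
}

# submodules derive independent streams from one global seed by fixed
# offsets; offsets stay far below 2^31
seed_offset <- c(cohort = 101L, genotypes = 202L, depths = 303L, scores = 404L)

rint_trunc <- function(n, mean, sd) {
  if (sd == 0) return(rep(as.integer(round(mean)), n))
  pmax(1L, as.integer(round(rnorm(n, mean, sd))))
}

#' Simulate a phenotype cohort table
#'
#' Draws a cohort with the structure of the study's Table-1 analogue:
#' group labels, sex and motor-delay Bernoulli flags with group-specific
#' rates, and integer onset ages and follow-up months from rounded-normal
#' distributions truncated at 1. Deterministic given `(spec, seed)`.
#'
#' @param spec A [simulation_spec()].
#' @param seed Integer seed.
#' @return Cohort tibble (`id`, `group`, `sex`, `motor_delay`,
#'   `onset_months`, `followup_months`).
#' @export
simulate_cohort <- function(spec = simulation_spec(), seed = 1) {
  if (spec$n_mild < 1 || spec$n_severe < 1) abort("group sizes must be >= 1")
  set.seed(seed + seed_offset[["cohort"]])
  n <- spec$n_mild + spec$n_severe
  tibble::tibble(
    id = c(sprintf("M%02d", seq_len(spec$n_mild)),
           sprintf("S%02d", seq_len(spec$n_severe))),
    group = rep(c("mild", "severe"), c(spec$n_mild, spec$n_severe)),
    sex = ifelse(runif(n) < rep(c(spec$p_male_mild, spec$p_male_severe),
                                c(spec$n_mild, spec$n_severe)), "M", "F"),
    motor_delay = runif(n) < rep(c(spec$p_motor_mild, spec$p_motor_severe),
                                 c(spec$n_mild, spec$n_severe)),
    onset_months = c(rint_trunc(spec$n_mild, spec$onset_mild$mean, spec$onset_mild$sd),
                     rint_trunc(spec$n_severe, spec$onset_severe$mean, spec$onset_severe$sd)),
    followup_months = c(rint_trunc(spec$n_mild, spec$followup_mild$mean, spec$followup_mild$sd),
                        rint_trunc(spec$n_severe, spec$followup_severe$mean, spec$followup_severe$sd))
  )
}

#' Simulate rare-variant genotypes over a candidate gene panel
#'
#' Generates variant records and a genotype table with the statistical
#' structure the burden analysis assumes. Rare qualifying sites
#' (`ref_pop_freq` <= 1%, missense) are assigned to panel genes in
#' proportion to class size; at damaging sites each mild individual is a
#' het carrier with probability `damaging_rate_mild` and each severe
#' individual with `damaging_rate_mild * damaging_enrichment`; benign
#' carrier probability is `benign_rate` in both groups. Carriers are
#' singleton hets per draw; sharing arises only through independent
#' carriage of the same site. Additional common (frequency > 1%) and
#' synonymous sites are included so the MAF and impact filters have work
#' to do. Deterministic given `(spec, seed)`.
#'
#' @param cohort Cohort tibble from [simulate_cohort()].
#' @param gene_sets Gene-set tibble from [load_gene_sets()] (non-empty).
#' @param spec A [simulation_spec()].
#' @param seed Integer seed.
#' @return A list with `variants` and `genotypes` (no allele depths yet;
#'   see [simulate_read_depths()]).
#' @export
simulate_genotypes <- function(cohort, gene_sets, spec = simulation_spec(),
                               seed = 1) {
  if (nrow(gene_sets) == 0) abort("gene set must be non-empty")
  set.seed(seed + seed_offset[["genotypes"]])
  n_rare <- spec$n_damaging_sites + spec$n_benign_sites
  n_tot <- n_rare + spec$n_common_sites + spec$n_nonqualifying_sites
  genes <- sample(gene_sets$gene, n_tot, replace = TRUE,
                  prob = rep(1, nrow(gene_sets)))
  lu <- function(n, lo, hi) exp(runif(n, log(lo), log(hi)))
  variants <- tibble::tibble(
    chrom = sample(paste0("chr", 1:22), n_tot, replace = TRUE),
    pos = sample.int(5e7, n_tot),
    ref = sample(c("A", "C", "G", "T"), n_tot, replace = TRUE),
    gene = genes,
    kind = rep(c("damaging", "benign", "common", "synonymous"),
               c(spec$n_damaging_sites, spec$n_benign_sites,
                 spec$n_common_sites, spec$n_nonqualifying_sites))
  ) |>
    dplyr::mutate(
      alt = purrr::map_chr(.data$ref, function(r)
        sample(setdiff(c("A", "C", "G", "T"), r), 1)),
      impact = ifelse(.data$kind == "synonymous", "synonymous", "missense"),
      ref_pop_freq = dplyr::case_when(
        kind == "common" ~ runif(n_tot, 0.011, 0.5),
        TRUE ~ lu(n_tot, spec$maf_range[1], spec$maf_range[2])),
      patho_call = dplyr::case_when(
        kind == "damaging" ~ sample(c("probably_damaging", "possibly_damaging"),
                                    n_tot, replace = TRUE),
        kind == "benign" ~ "benign",
        kind == "common" ~ sample(c("probably_damaging", "benign"), n_tot,
                                  replace = TRUE),
        TRUE ~ "unscored"),
      site_id = site_key(.data$chrom, .data$pos, .data$ref, .data$alt)) |>
    dplyr::relocate("site_id") |>
    dplyr::select(-"kind") |>
    dplyr::mutate(category = rep(c("damaging", "benign", "common", "synonymous"),
                                 c(spec$n_damaging_sites, spec$n_benign_sites,
                                   spec$n_common_sites, spec$n_nonqualifying_sites)))

  p_sev <- spec$damaging_rate_mild * spec$damaging_enrichment
  carrier_prob <- function(category, group) {
    dplyr::case_when(
      category == "damaging" & group == "mild" ~ spec$damaging_rate_mild,
      category == "damaging" & group == "severe" ~ p_sev,
      category == "benign" ~ spec$benign_rate,
      category == "common" ~ 0.2,
      TRUE ~ spec$benign_rate)
  }
  grid <- tidyr::expand_grid(sample_id = cohort$id, site_id = variants$site_id) |>
    dplyr::left_join(cohort[, c("id", "group")], by = c(sample_id = "id")) |>
    dplyr::left_join(variants[, c("site_id", "category")], by = "site_id")
  p <- carrier_prob(grid$category, grid$group)
  gt <- ifelse(runif(nrow(grid)) < p, "het", "hom_ref")
  genotypes <- tibble::tibble(sample_id = grid$sample_id,
                              site_id = grid$site_id, gt = gt,
                              ad_ref = NA_integer_, ad_alt = NA_integer_)
  variants$category <- NULL
  list(variants = variants, genotypes = genotypes)
}

#' Simulate read depths and allele depths for called genotypes
#'
#' Draws per-call read depth from a Poisson(`mean_depth`) truncated at 1.
#' True het calls draw alternate reads Binomial(depth, 1/2); a fraction
#' `false_het_rate` of het calls are relabelled as injected false
#' positives whose alternate reads are Binomial(depth, `p_skew`) — the
#' allelic-balance artifact the filter is designed to remove. Hom-ref and
#' hom-alt calls get all reads on their allele. Deterministic given
#' `(spec, seed)`.
#'
#' @param genotypes Genotype tibble with `gt` assigned.
#' @param spec A [simulation_spec()] (`mean_depth` must be > 0).
#' @param seed Integer seed.
#' @return The genotype tibble with `ad_ref`, `ad_alt` filled and a
#'   logical `false_het` column marking injected artifacts.
#' @export
simulate_read_depths <- function(genotypes, spec = simulation_spec(), seed = 1) {
  if (spec$mean_depth <= 0) abort("mean_depth must be > 0")
  set.seed(seed + seed_offset[["depths"]])
  n <- nrow(genotypes)
  depth <- rpois(n, spec$mean_depth)
  depth[depth < 1] <- 1L
  out <- genotypes
  out$false_het <- FALSE
  het <- which(out$gt == "het")
  false_het <- het[runif(length(het)) < spec$false_het_rate]
  out$false_het[false_het] <- TRUE
  alt <- integer(n)
  true_het <- setdiff(het, false_het)
  alt[true_het] <- rbinom(length(true_het), depth[true_het], 0.5)
  alt[false_het] <- rbinom(length(false_het), depth[false_het], spec$p_skew)
  alt[out$gt == "hom_alt"] <- depth[out$gt == "hom_alt"]
  alt[out$gt == "missing"] <- NA_integer_
  out$ad_alt <- as.integer(alt)
  out$ad_ref <- as.integer(depth - alt)
  out$ad_ref[out$gt == "missing"] <- NA_integer_
  out
}

#' Simulate binormal predictor scores with a target AUC
#'
#' Positive (pathogenic-case) scores are Normal(delta, 1) and negative
#' (population-control) scores Normal(0, 1) with
#' delta = sqrt(2) * qnorm(auc_target), the binormal model whose
#' theoretical AUC equals `auc_target`.
#'
#' @param n_pos,n_neg Sample sizes (>= 1).
#' @param auc_target Target AUC in [0.5, 1] (0.5 is the no-signal
#'   boundary; 1 is degenerate perfect separation).
#' @param seed Integer seed.
#' @return Tibble with columns `label`
#'   (`"pathogenic_case"`/`"population_control"`) and `score`.
#' @export
simulate_scores <- function(n_pos, n_neg, auc_target = 0.798, seed = 1) {
  stopifnot(n_pos >= 1, n_neg >= 1)
  if (auc_target < 0.5 || auc_target > 1) {
    abort("auc_target must lie in [0.5, 1]")
  }
  delta <- sqrt(2) * qnorm(auc_target)
  set.seed(seed + seed_offset[["scores"]])
  tibble::tibble(
    label = rep(c("pathogenic_case", "population_control"), c(n_pos, n_neg)),
    score = c(rnorm(n_pos, delta, 1), rnorm(n_neg, 0, 1)))
}

#' Simulate a complete synthetic study dataset
#'
#' Convenience wrapper: cohort, panel genotypes and read depths from one
#' global seed (submodules use fixed offsets, so the three stages are
#' independent streams).
#'
#' @param spec A [simulation_spec()].
#' @param seed Integer seed.
#' @param gene_sets Gene-set tibble (default: packaged panel).
#' @return A list with `cohort`, `variants`, `genotypes`.
#' @export
simulate_dataset <- function(spec = simulation_spec(), seed = 1,
                             gene_sets = load_gene_sets()) {
  cohort <- simulate_cohort(spec, seed)
  gm <- simulate_genotypes(cohort, gene_sets, spec, seed)
  genotypes <- simulate_read_depths(gm$genotypes, spec, seed)
  list(cohort = cohort, variants = gm$variants, genotypes = genotypes)
}
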