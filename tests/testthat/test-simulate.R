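test_that("generators are deterministic given (spec, seed)", {
  spec <- simulation_spec(n_mild = 5, n_severe = 6, n_damaging_sites = 10,
                          n_benign_sites = 10, n_common_sites = 3,
                          n_nonqualifying_sites = 2, false_het_rate = 0.2)
  a <- simulate_dataset(spec, seed = 123)
  b <- simulate_dataset(spec, seed = 123)
  expect_equal(a$cohort, b$cohort)
  expect_equal(a$variants, b$variants)
  expect_equal(a$genotypes, b$genotypes)
  c <- simulate_dataset(spec, seed = 124)
  expect_false(identical(a$genotypes$gt, c$genotypes$gt))
})

test_that("cohort generator respects sizes and degenerate distributions", {
  spec <- simulation_spec()
  cohort <- simulate_cohort(spec, seed = 1)
  expect_equal(nrow(cohort), 21)
  expect_equal(sum(cohort$group == "mild"), 9)
  expect_equal(sum(cohort$group == "severe"), 12)

  degen <- simulation_spec(onset_mild = list(mean = 6, sd = 0),
                           onset_severe = list(mean = 6, sd = 0))
  expect_true(all(simulate_cohort(degen, seed = 2)$onset_months == 6))
  expect_error(simulate_cohort(simulation_spec(n_mild = 0)), "n_mild")
})

test_that("rare sites never exceed 1% reference frequency; zero rates give no carriers", {
  spec <- simulation_spec(n_common_sites = 0, n_nonqualifying_sites = 0)
  sim <- simulate_dataset(spec, seed = 5)
  expect_true(all(sim$variants$ref_pop_freq <= 0.01))

  null_spec <- simulation_spec(damaging_rate_mild = 0, damaging_enrichment = 1,
                               benign_rate = 0, n_common_sites = 0,
                               n_nonqualifying_sites = 0)
  sim0 <- simulate_dataset(null_spec, seed = 5)
  expect_true(all(sim0$genotypes$gt == "hom_ref"))
})

test_that("burden Fisher p is uniform under a no-enrichment simulation", {
  spec <- simulation_spec(damaging_enrichment = 1,
                          damaging_rate_mild = 46 / (52 * 12),
                          n_common_sites = 0, n_nonqualifying_sites = 0)
  gs <- load_gene_sets()
  ps <- vapply(1:200, function(s) {
    cohort <- simulate_cohort(spec, seed = 1000 + s)
    gm <- simulate_genotypes(cohort, gs, spec, seed = 1000 + s)
    bt <- aggregate_burden(gm$genotypes, gm$variants, gs, cohort)
    burden_fisher(bt, "damaging", c("mild", "severe"), "less")
  }, numeric(1))
  med <- stats::median(ps)
  expect_gte(med, 0.3)
  expect_lte(med, 0.7)
})

test_that("study-scale damaging enrichment is detected in most replicates", {
  spec <- simulation_spec(n_common_sites = 0, n_nonqualifying_sites = 0)
  gs <- load_gene_sets()
  rej <- vapply(1:200, function(s) {
    cohort <- simulate_cohort(spec, seed = 5000 + s)
    gm <- simulate_genotypes(cohort, gs, spec, seed = 5000 + s)
    bt <- aggregate_burden(gm$genotypes, gm$variants, gs, cohort)
    burden_fisher(bt, "damaging", c("mild", "severe"), "less") < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.5)
})

test_that("carrier-rate ratio is recovered from a large simulated cohort", {
  spec <- simulation_spec(n_mild = 400, n_severe = 400,
                          n_damaging_sites = 200, n_benign_sites = 10,
                          n_common_sites = 0, n_nonqualifying_sites = 0,
                          damaging_rate_mild = 0.02, damaging_enrichment = 2)
  cohort <- simulate_cohort(spec, seed = 31)
  gm <- simulate_genotypes(cohort, load_gene_sets(), spec, seed = 31)
  grp <- stats::setNames(cohort$group, cohort$id)
  dam <- gm$variants$site_id[gm$variants$patho_call != "benign"]
  g <- gm$genotypes[gm$genotypes$site_id %in% dam, ]
  rate <- tapply(g$gt == "het", grp[g$sample_id], mean)
  expect_equal(unname(rate[["mild"]] / rate[["severe"]]), 1 / 2,
               tolerance = 0.12)
})

test_that("read-depth generator matches its model at the edges", {
  spec <- simulation_spec(n_mild = 3, n_severe = 3, n_damaging_sites = 40,
                          n_benign_sites = 0, n_common_sites = 0,
                          n_nonqualifying_sites = 0,
                          damaging_rate_mild = 0.5, damaging_enrichment = 1,
                          mean_depth = 1e-9)
  expect_error(simulate_read_depths(tibble::tibble(), simulation_spec(mean_depth = 0)),
               "mean_depth")
  sim <- simulate_dataset(spec, seed = 8)
  hets <- dplyr::filter(sim$genotypes, gt == "het")
  # depth ~ truncated Poisson(~0) is 1: every het is (1,0) or (0,1)
  expect_true(all(hets$ad_ref + hets$ad_alt == 1))
})

test_that("binormal score generator hits its target AUC", {
  sc <- simulate_scores(10000, 10000, auc_target = 0.798, seed = 2)
  a <- auc(sc$score[sc$label == "pathogenic_case"],
           sc$score[sc$label == "population_control"])
  expect_equal(a, 0.798, tolerance = 0.011)

  sc0 <- simulate_scores(10000, 10000, auc_target = 0.5, seed = 3)
  a0 <- auc(sc0$score[sc0$label == "pathogenic_case"],
            sc0$score[sc0$label == "population_control"])
  expect_gte(a0, 0.48); expect_lte(a0, 0.52)

  sc1 <- simulate_scores(2000, 2000, auc_target = 1 - 1e-12, seed = 4)
  a1 <- auc(sc1$score[sc1$label == "pathogenic_case"],
            sc1$score[sc1$label == "population_control"])
  expect_gte(a1, 0.999)

  expect_error(simulate_scores(10, 10, auc_target = 0.4), "auc_target")
  expect_error(simulate_scores(10, 10, auc_target = 1.01), "auc_target")
})
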