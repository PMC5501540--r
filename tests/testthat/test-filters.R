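test_that("missingness filter drops sites with more than the tolerated missing calls", {
  geno <- tidyr::expand_grid(sample_id = sprintf("s%02d", 1:21),
                             site_id = c("v1", "v2", "v3")) |>
    dplyr::mutate(gt = "hom_ref", ad_ref = 30L, ad_alt = 0L)
  geno$gt[geno$site_id == "v1"][1:3] <- "missing"  # 3 missing: dropped
  geno$gt[geno$site_id == "v2"][1:2] <- "missing"  # 2 missing: boundary, kept
  out <- missingness_filter(geno)
  expect_setequal(unique(out$site_id), c("v2", "v3"))
  expect_equal(attr(out, "dropped_sites"), "v1")

  complete <- dplyr::mutate(geno, gt = "hom_ref")
  expect_equal(nrow(missingness_filter(complete)), nrow(complete))
})

test_that("impact filter keeps protein-altering classes only", {
  v <- tibble::tibble(site_id = paste0("v", 1:4),
                      impact = c("synonymous", "frameshift", "missense", NA))
  out <- suppressMessages(impact_filter(v))
  expect_setequal(out$site_id, c("v2", "v3"))
  expect_message(impact_filter(v), "without impact annotation")
  kept <- impact_filter(v, filter_config(keep_unscored_impact = TRUE))
  expect_setequal(kept$site_id, c("v2", "v3", "v4"))
  expect_equal(nrow(impact_filter(v[0, ])), 0)
})

test_that("MAF filter is inclusive at the threshold and keeps novel variants", {
  v <- tibble::tibble(site_id = paste0("v", 1:3),
                      ref_pop_freq = c(0.010, 0.011, NA))
  out <- maf_filter(v)
  expect_setequal(out$site_id, c("v1", "v3"))
})

test_that("allelic-balance exact boundary matches closed-form 2 * 2^-n arithmetic", {
  expect_true(allelic_balance_pass(0, 7))    # 2 * 2^-7 = 0.015625 >= 0.01
  expect_false(allelic_balance_pass(0, 8))   # 2 * 2^-8 = 0.0078125 < 0.01
  expect_true(allelic_balance_pass(15, 30))  # perfectly balanced
  expect_false(allelic_balance_pass(2, 30))  # tail ~ 8.7e-7
  expect_error(allelic_balance_pass(0, 0), "total_reads")
})

test_that("allelic-balance test is symmetric in the two alleles", {
  for (n in c(5, 17, 40, 80)) {
    k <- 0:n
    expect_equal(allelic_balance_pass(k, n), allelic_balance_pass(n - k, n))
  }
})

test_that("true balanced hets fail at no more than the test size", {
  set.seed(42)
  n <- 20000
  depth <- pmax(1, rpois(n, 60))
  alt <- rbinom(n, depth, 0.5)
  frac_fail <- mean(!allelic_balance_pass(alt, depth))
  expect_lte(frac_fail, 0.012)  # conservative by discreteness; near 0.01
})

test_that("failing het calls become missing and the pipeline removes skewed calls", {
  spec <- simulation_spec(n_mild = 9, n_severe = 12, n_damaging_sites = 30,
                          n_benign_sites = 30, n_common_sites = 0,
                          n_nonqualifying_sites = 0,
                          damaging_rate_mild = 0.3, damaging_enrichment = 1,
                          benign_rate = 0.3,
                          false_het_rate = 0.5, p_skew = 0.02, mean_depth = 60)
  sim <- simulate_dataset(spec, seed = 11)
  filtered <- allelic_balance_filter(sim$genotypes)
  injected <- sim$genotypes$false_het
  removed <- filtered$gt == "missing" & sim$genotypes$gt == "het"
  expect_gte(sum(removed & injected) / sum(injected), 0.90)
  # true hets survive at roughly the test size
  true_het <- sim$genotypes$gt == "het" & !injected
  expect_gte(sum(!removed & true_het) / sum(true_het), 0.98)
})

test_that("the three site-level filters commute", {
  spec <- simulation_spec(n_mild = 4, n_severe = 5, n_damaging_sites = 15,
                          n_benign_sites = 15, n_common_sites = 8,
                          n_nonqualifying_sites = 8)
  sim <- simulate_dataset(spec, seed = 3)
  cfg <- filter_config()
  perms <- list(c(1, 2), c(2, 1))
  apply_two <- function(v, ord) {
    fs <- list(function(x) suppressMessages(impact_filter(x, cfg)),
               function(x) maf_filter(x, cfg))
    for (k in ord) v <- fs[[k]](v)
    sort(v$site_id)
  }
  expect_equal(apply_two(sim$variants, c(1, 2)),
               apply_two(sim$variants, c(2, 1)))
})

test_that("full pipeline returns consistent variant and genotype site sets", {
  spec <- simulation_spec(n_mild = 5, n_severe = 6, n_damaging_sites = 20,
                          n_benign_sites = 20, n_common_sites = 5,
                          n_nonqualifying_sites = 5, false_het_rate = 0.2)
  sim <- simulate_dataset(spec, seed = 9)
  out <- suppressMessages(apply_filters(sim$variants, sim$genotypes))
  expect_setequal(out$variants$site_id, unique(out$genotypes$site_id))
  expect_true(all(out$variants$impact %in%
                    c("missense", "stop_gain", "stop_loss", "frameshift",
                      "splice_junction")))
  expect_true(all(is.na(out$variants$ref_pop_freq) |
                    out$variants$ref_pop_freq <= 0.01))
  expect_true(all(c("reason") %in% names(out$audit)))
})
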