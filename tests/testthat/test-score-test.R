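test_that("null model closed forms, separation detection and recovery", {
  cohort <- dravet_cohort()
  nm0 <- fit_null_logistic(cohort, covariates = character(0))
  expect_equal(nm0$mu, rep(12 / 21, 21), tolerance = 1e-8)
  expect_lt(abs(sum(nm0$residuals)), 1e-6)

  sep <- dplyr::mutate(cohort, bad = as.integer(group == "severe"))
  expect_error(fit_null_logistic(sep, covariates = "bad"),
               "perfect separation.*bad")

  # coefficient recovery on simulated data
  sim <- make_sim_cohort(2000, seed = 21)
  nm <- fit_null_logistic(sim)
  co <- tidy(nm)
  truth <- c(`(Intercept)` = -0.3, onset_months = 0.4, followup_months = -0.3,
             sexM = 0.5, motor_delayTRUE = 0.3)
  for (term in names(truth)) {
    row <- co[co$term == term, ]
    expect_lt(abs(row$estimate - truth[[term]]), 3 * row$std_error)
  }
})

test_that("residuals sum to zero with an intercept and Q is label-stable", {
  cohort <- dravet_cohort()
  nm <- fit_null_logistic(cohort)
  expect_lt(abs(sum(nm$residuals)), 1e-6)
  # adding a constant to a covariate leaves Q unchanged
  set.seed(42)
  G <- rand_region(21, 5)
  q1 <- region_score(G, nm)$Q
  shifted <- dplyr::mutate(cohort, onset_months = onset_months + 100)
  q2 <- region_score(G, fit_null_logistic(shifted))$Q
  expect_equal(q1, q2, tolerance = 1e-6)
})

test_that("region statistic equals brute-force summation on random 13-SNP regions", {
  for (s in 1:5) {
    sim <- make_sim_cohort(60, seed = 300 + s)
    nm <- fit_null_logistic(sim)
    set.seed(400 + s)
    G <- rand_region(60, 13)
    res <- region_score(G, nm)
    expect_equal(res$Q, q_bruteforce(G, rep(1, 13), nm$residuals),
                 tolerance = 1e-10)
    expect_equal(res$Q, sum(res$snp$partial), tolerance = 1e-12)
    # beta-MAF weights too
    resw <- region_score(G, nm, weights = "beta_maf")
    expect_equal(resw$Q, q_bruteforce(G, resw$snp$weight, nm$residuals),
                 tolerance = 1e-8)
  }
})

test_that("degenerate regions give Q = 0 and p = 1", {
  sim <- make_sim_cohort(40, seed = 1)
  nm <- fit_null_logistic(sim)
  G <- matrix(0, 40, 4, dimnames = list(NULL, paste0("z", 1:4)))
  res <- suppressMessages(region_score(G, nm))
  expect_equal(res$Q, 0)
  expect_equal(res$p_value, 1)
})

test_that("single-SNP region matches the closed-form 1-df score test", {
  sim <- make_sim_cohort(300, seed = 17)
  nm0 <- fit_null_logistic(sim, covariates = character(0))
  set.seed(18)
  G <- rand_region(300, 1)
  res <- region_score(G, nm0)
  # with a single eigenvalue, Q / lambda ~ chi^2_1
  p_closed <- pchisq(res$Q / res$lambda, df = 1, lower.tail = FALSE)
  expect_equal(res$p_value, p_closed, tolerance = 1e-6)
  expect_equal(analytic_pvalue(res, method = "liu"), p_closed, tolerance = 1e-6)
})

test_that("Liu and characteristic-function p-values agree", {
  set.seed(55)
  for (s in 1:50) {
    lambda <- runif(sample(2:10, 1), 0.2, 3)
    q <- sum(lambda) + runif(1, 0, 3) * sqrt(2 * sum(lambda^2))
    pd <- analytic_pvalue(q, lambda, method = "davies")
    pl <- analytic_pvalue(q, lambda, method = "liu")
    if (pd > 1e-4) {
      expect_lt(abs(log10(pd) - log10(pl)), 0.2)
    }
  }
})

test_that("analytic p-values are calibrated on synthetic null regions", {
  sim <- make_sim_cohort(200, seed = 99)
  nm <- fit_null_logistic(sim)
  set.seed(100)
  ps <- vapply(1:2000, function(b) {
    region_score(rand_region(200, 10), nm)$p_value
  }, numeric(1))
  t1 <- mean(ps < 0.05)
  expect_gte(t1, 0.035)
  expect_lte(t1, 0.065)
})

test_that("permutation and analytic p-values agree within Monte-Carlo error", {
  sim <- make_sim_cohort(150, seed = 12)
  nm <- fit_null_logistic(sim)
  set.seed(13)
  for (s in 1:3) {
    res <- region_score(rand_region(150, 8), nm)
    pp <- permutation_pvalue(res, n_perm = 2000, seed = 500 + s)
    se <- sqrt(res$p_value * (1 - res$p_value) / 2000)
    expect_lt(abs(pp - res$p_value), 4 * se + 0.01)
    # determinism
    expect_equal(pp, permutation_pvalue(res, n_perm = 2000, seed = 500 + s))
  }
})

test_that("strong synthetic signals reach the permutation floor", {
  sim <- make_sim_cohort(120, seed = 7)
  nm <- fit_null_logistic(sim)
  G <- matrix(rep(nm$y, 3), ncol = 3,
              dimnames = list(NULL, paste0("g", 1:3)))
  res <- region_score(G, nm)
  pp <- permutation_pvalue(res, n_perm = 200, seed = 2)
  expect_lte(pp, 0.05)
})

test_that("influence analysis flags the sole carrier and is stable otherwise", {
  cohort <- dravet_cohort()
  nm <- fit_null_logistic(cohort)
  # every minor allele carried by one individual
  G <- matrix(0, 21, 4, dimnames = list(cohort$id, paste0("v", 1:4)))
  G[7, ] <- 1
  res <- region_score(G, nm)
  infl <- influence_analysis(res)
  expect_equal(nrow(infl), 21)
  expect_equal(infl$q_loo[7], 0, tolerance = 1e-9)
  expect_gt(infl$q_drop[7], 0)
})

test_that("missing genotypes are mean-imputed per site", {
  sim <- make_sim_cohort(50, seed = 3)
  nm <- fit_null_logistic(sim)
  set.seed(4)
  G <- rand_region(50, 3)
  Gna <- G
  Gna[1:5, 2] <- NA
  Gimp <- Gna
  Gimp[1:5, 2] <- mean(Gna[-(1:5), 2])
  expect_equal(region_score(Gna, nm)$Q, region_score(Gimp, nm)$Q,
               tolerance = 1e-10)
})

test_that("rho-grid combination behaves at its endpoints", {
  sim <- make_sim_cohort(100, seed = 44)
  nm <- fit_null_logistic(sim)
  set.seed(45)
  G <- rand_region(100, 6)
  comb <- skat_o(G, nm)
  expect_equal(comb$grid$Q[comb$grid$rho == 0], region_score(G, nm)$Q,
               tolerance = 1e-9)
  S <- region_score(G, nm)$snp$S
  expect_equal(comb$grid$Q[comb$grid$rho == 1], sum(S)^2, tolerance = 1e-9)
  expect_equal(comb$min_p, min(comb$grid$p_value))
})

test_that("tidiers expose per-SNP components and one-row summaries", {
  sim <- make_sim_cohort(40, seed = 6)
  nm <- fit_null_logistic(sim)
  set.seed(7)
  res <- region_score(rand_region(40, 5), nm, region = "geneA")
  td <- tidy(res)
  expect_equal(nrow(td), 5)
  gl <- glance(res)
  expect_equal(gl$region, "geneA")
  expect_equal(gl$Q, res$Q)
  expect_equal(glance(nm)$n, 40)
})
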