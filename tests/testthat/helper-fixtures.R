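# deterministic fixture whose class-level allele counts reproduce the
# published burden table: singleton het carriers except a quota of
# two-carrier (shared) sites in the severe group, so the qualifying-site
# totals are exactly 52 damaging and 70 benign
make_burden_fixture <- function() {
  counts <- dravet_burden_counts()
  gs <- load_gene_sets()
  cohort <- dravet_cohort()
  mild_ids <- cohort$id[cohort$group == "mild"]
  sev_ids <- cohort$id[cohort$group == "severe"]
  site_counts <- c(damaging = 52L, benign = 70L)

  var_rows <- list()
  carr_rows <- list()
  for (cat in c("damaging", "benign")) {
    cm <- counts[[paste0(cat, "_mild")]]
    cs <- counts[[paste0(cat, "_severe")]]
    n_doubletons <- sum(cm) + sum(cs) - site_counts[[cat]]
    stopifnot(n_doubletons >= 0)
    capacity <- floor(cs / 2)
    dbl <- integer(length(cs))
    left <- n_doubletons
    for (k in order(capacity, decreasing = TRUE)) {
      take <- min(capacity[k], left)
      dbl[k] <- take
      left <- left - take
    }
    stopifnot(left == 0)
    idx <- 0L
    for (k in seq_len(nrow(counts))) {
      cls <- counts$gene_class[k]
      genes <- gs$gene[gs$class == cls]
      add_site <- function(carrier_ids) {
        idx <<- idx + 1L
        sid <- paste0(cat, "_", idx)
        var_rows[[length(var_rows) + 1L]] <<- tibble::tibble(
          site_id = sid, chrom = "chr1",
          pos = 1000000L * match(cat, c("damaging", "benign")) + idx,
          ref = "A", alt = "G", gene = genes[1 + (idx %% length(genes))],
          impact = "missense", ref_pop_freq = 0.005, patho_call = cat)
        carr_rows[[length(carr_rows) + 1L]] <<- tibble::tibble(
          site_id = sid, sample_id = carrier_ids)
      }
      si <- 0L; mi <- 0L
      sev_left <- cs[k]; mild_left <- cm[k]
      for (d in seq_len(dbl[k])) {
        add_site(sev_ids[c(si, si + 1L) %% length(sev_ids) + 1L])
        si <- si + 2L; sev_left <- sev_left - 2L
      }
      while (sev_left > 0) {
        add_site(sev_ids[si %% length(sev_ids) + 1L])
        si <- si + 1L; sev_left <- sev_left - 1L
      }
      while (mild_left > 0) {
        add_site(mild_ids[mi %% length(mild_ids) + 1L])
        mi <- mi + 1L; mild_left <- mild_left - 1L
      }
    }
  }
  variants <- dplyr::bind_rows(var_rows)
  carr <- dplyr::bind_rows(carr_rows)
  genotypes <- tidyr::expand_grid(sample_id = cohort$id,
                                  site_id = variants$site_id) |>
    dplyr::left_join(dplyr::mutate(carr, is_carrier = TRUE),
                     by = c("sample_id", "site_id")) |>
    dplyr::mutate(gt = ifelse(is.na(is_carrier), "hom_ref", "het"),
                  ad_ref = 30L, ad_alt = ifelse(gt == "het", 28L, 0L)) |>
    dplyr::select(sample_id, site_id, gt, ad_ref, ad_alt)
  list(variants = variants, genotypes = genotypes, cohort = cohort,
       gene_sets = gs)
}

# O(n^2) pair-counting oracle for the AUC
auc_bruteforce <- function(cases, controls) {
  s <- 0
  for (x in cases) for (y in controls) {
    s <- s + (x > y) + 0.5 * (x == y)
  }
  s / (length(cases) * length(controls))
}

# direct-summation oracle for the region score statistic
q_bruteforce <- function(G, w, resid) {
  q <- 0
  for (j in seq_len(ncol(G))) {
    sj <- 0
    for (i in seq_len(nrow(G))) sj <- sj + G[i, j] * resid[i]
    q <- q + (w[j] * sj)^2
  }
  unname(q)
}

# sample one element of x (sample() treats a length-1 integer as 1:x)
resample1 <- function(x) x[sample.int(length(x), 1)]

# half-up rounding, the convention used for the printed summary values
# (R's round() is half-even: round(56.25, 1) == 56.2)
round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}

# enumeration oracle for the 2x2 Fisher exact test over the
# hypergeometric support at fixed margins
fisher_enumerate <- function(a, b, c, d, alternative) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  xs <- lo:hi
  probs <- stats::dhyper(xs, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  switch(alternative,
         less = sum(probs[xs <= a]),
         greater = sum(probs[xs >= a]),
         two_sided = sum(probs[probs <= obs * (1 + 1e-7)]))
}

# random logistic-model cohort for score-test calibration
make_sim_cohort <- function(n, seed, beta = c(-0.3, 0.4, -0.3, 0.5, 0.3)) {
  set.seed(seed)
  x1 <- rnorm(n); x2 <- rnorm(n)
  sex <- sample(c("M", "F"), n, replace = TRUE)
  md <- runif(n) < 0.4
  eta <- beta[1] + beta[2] * x1 + beta[3] * x2 + beta[4] * (sex == "M") +
    beta[5] * md
  y <- runif(n) < stats::plogis(eta)
  tibble::tibble(id = sprintf("I%03d", seq_len(n)),
                 group = ifelse(y, "severe", "mild"),
                 onset_months = x1, followup_months = x2,
                 sex = sex, motor_delay = md)
}

rand_region <- function(n, m, maf_range = c(0.05, 0.4)) {
  maf <- runif(m, maf_range[1], maf_range[2])
  G <- sapply(maf, function(p) rbinom(n, 2, p))
  colnames(G) <- paste0("snp", seq_len(m))
  G
}
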