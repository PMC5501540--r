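# modburden

Rare-variant modifier-gene burden analysis for extreme-phenotype
sequencing designs.

## The problem

In monogenic disease, patients carrying the same primary mutation can
have very different clinical outcomes. One way to look for *modifier*
variation with a small cohort is an extreme-phenotype design: sequence
individuals from both tails of the outcome distribution (for example,
mildly vs severely affected carriers of the same class of
loss-of-function mutation) and ask whether rare, putatively damaging
alleles in a candidate gene panel are enriched in one tail. This package
implements that analysis end to end, modelled on a study of SCN1A
truncation-positive Dravet syndrome in which 9 mildly and 12 severely
affected children were exome-sequenced and compared over a 237-gene
neuronal-excitability panel.

`modburden` provides, as ordinary tidyverse-style functions over tibbles:

- **Variant QC filters** — per-site missingness (more than 2 missing
  genotypes drops the site), protein-altering impact classes,
  reference-population MAF ≤ 1 % (inclusive; absent = novel = kept), and
  an exact binomial allelic-balance filter for heterozygous calls: with
  depth *n* and alternate reads *k*, the call fails when
  min(1, 2·P(X ≤ min(k, n−k))) < 0.01 for X ~ Binomial(n, ½).
- **Gene-class burden tests** — alternate-allele counts per gene class ×
  pathogenicity category × phenotype group; allele frequencies under the
  site-by-2N convention (denominator = qualifying sites × 2 ×
  individuals); Fisher exact contrasts of damaging vs benign allele
  loads between groups or against a jointly processed reference cohort;
  recurrence (singleton/shared variant) reporting.
- **Per-site genotype scans** — Fisher exact tests per site
  (carrier or full-genotype coding), ranked p-values, and the minimum
  attainable p given the group sizes (1/C(n1+n2, n1) for unequal
  groups: 3.4 × 10⁻⁶ at 9 vs 12).
- **Covariate-adjusted region score tests** — a logistic null model
  (outcome ~ onset age + time since onset + sex + motor delay), the
  SKAT-style variance-component statistic Q = Σⱼ (wⱼ Sⱼ)² with per-SNP
  scores Sⱼ = Σᵢ Gᵢⱼ(yᵢ − μ̂ᵢ), analytic p-values from the
  mixture-of-χ² null (characteristic-function inversion or Liu moment
  matching), stratified permutation p-values, leave-one-out influence
  analysis, and an adaptive burden/SKAT rho-grid combination.
- **Predictor benchmarking** — Mann–Whitney AUC, the paired DeLong test
  for correlated AUCs, and a stratified bootstrap alternative.
- **A Poisson mutational-load power model** — group-total mutation
  counts Poisson with means θ₀ = n₀μ₀ and θ₁ = n₁μ₁; exact critical
  values, power, the smallest θ₀ reaching 80 % power at α = 0.01, and a
  misclassification adjustment (false-negative/false-positive
  pathogenicity calls dilute the observed load ratio toward the null).
- **Synthetic data generators** for all of the above, so every stage is
  testable without patient data.

## Worked example

```r
library(modburden)

sim <- simulate_dataset(simulation_spec(), seed = 42)   # 9 mild + 12 severe
flt <- apply_filters(sim$variants, sim$genotypes)       # QC filters
bt  <- aggregate_burden(flt$genotypes, flt$variants, load_gene_sets(), sim$cohort)
bt
#> Burden table: 122 qualifying sites, 21 individuals
#> # A tibble: 4 x 8
#>   pathogenicity group  alt_alleles n_sites n_individuals total_alleles ...
#> 1 benign        mild            27      70             9          1260
#> 2 benign        severe          48      70            12          1680
#> 3 damaging      mild            18      52             9           936
#> 4 damaging      severe          43      52            12          1248

burden_fisher(bt, "damaging", c("mild", "severe"), "less")       # 0.021
burden_fisher(bt, "benign", c("mild", "severe"), "two_sided")    # 0.239
```

The damaging-allele load is significantly lower in the simulated mild
group (18/936 vs 43/1248 alleles, one-tailed Fisher p = 0.021) while the
benign load is not (p = 0.24) — the qualitative contrast the design is
built to detect, at the study's sample sizes.

A covariate-adjusted region score test on the first 13 filtered sites:

```r
nm  <- fit_null_logistic(sim$cohort,
                         covariates = c("onset_months", "sex", "motor_delay"))
G   <- region_matrix(flt$genotypes, sites = flt$variants$site_id[1:13],
                     samples = sim$cohort$id)
res <- region_score(G, nm, region = "panel-head")
res
#> Region score test 'panel-head': Q = 1.694 (partial mean = 0.13 +/- 0.197), p = 0.283
permutation_pvalue(res, n_perm = 1000, seed = 42)
#> [1] 0.2557443
```

The analytic and permutation p-values agree within Monte-Carlo error.
`tidy(res)` gives the per-SNP partial scores, `influence_analysis(res)`
the leave-one-out statistics.

Power planning for a future cohort:

```r
min_theta0(power_spec(r = 0.5))   # 32: total mutation count needed at
                                  # half load, alpha 0.01, 80% power
```

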