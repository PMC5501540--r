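test_that("pathogenicity calls collapse to damaging/benign with inclusive cutpoints", {
  v <- tibble::tibble(site_id = paste0("v", 1:4),
                      patho_call = c("probably_damaging", "possibly_damaging",
                                     "benign", NA))
  out <- suppressMessages(classify_pathogenicity(v))
  expect_equal(out$patho_call, c("damaging", "damaging", "benign"))
  expect_message(classify_pathogenicity(v), "unscored")

  vs <- tibble::tibble(site_id = paste0("v", 1:3), pp2 = c(0.85, 0.84999, NA))
  out <- suppressMessages(classify_pathogenicity(vs, score_col = "pp2",
                                                 cutpoint = 0.85))
  expect_equal(out$patho_call, c("damaging", "benign"))
})

test_that("burden aggregation reproduces the published class-level table", {
  fx <- make_burden_fixture()
  bt <- aggregate_burden(fx$genotypes, fx$variants, fx$gene_sets, fx$cohort)
  tot <- burden_totals(bt)
  get <- function(p, g) tot$alt_alleles[tot$pathogenicity == p & tot$group == g]
  expect_equal(get("damaging", "mild"), 18L)
  expect_equal(get("damaging", "severe"), 46L)
  expect_equal(get("benign", "mild"), 35L)
  expect_equal(get("benign", "severe"), 48L)
  expect_equal(bt$sites$n_sites[bt$sites$pathogenicity == "damaging"], 52L)
  expect_equal(bt$sites$n_sites[bt$sites$pathogenicity == "benign"], 70L)

  # class-level counts match the published table cell by cell
  ref <- dravet_burden_counts()
  counts <- tidyr::pivot_wider(
    bt$counts, names_from = c("pathogenicity", "group"),
    values_from = "alt_alleles") |>
    dplyr::arrange(match(gene_class, ref$gene_class))
  expect_equal(counts$damaging_mild, ref$damaging_mild)
  expect_equal(counts$damaging_severe, ref$damaging_severe)
  expect_equal(counts$benign_mild, ref$benign_mild)
  expect_equal(counts$benign_severe, ref$benign_severe)
})

test_that("burden conservation and reference-allele counts hold", {
  fx <- make_burden_fixture()
  bt <- aggregate_burden(fx$genotypes, fx$variants, fx$gene_sets, fx$cohort)
  tot <- burden_totals(bt)
  # class sums equal cohort totals (checked in aggregate) and the four
  # site-by-2N reference counts come out exactly
  expect_setequal(tot$ref_alleles, c(918L, 1202L, 1225L, 1632L))
  # hom-alt counts two alleles
  g2 <- fx$genotypes
  hit <- which(g2$gt == "het")[1]
  g2$gt[hit] <- "hom_alt"
  t2 <- burden_totals(aggregate_burden(g2, fx$variants, fx$gene_sets, fx$cohort))
  expect_equal(sum(t2$alt_alleles), sum(tot$alt_alleles) + 1)
})

test_that("empty genotype input gives an all-zero burden table", {
  fx <- make_burden_fixture()
  empty <- dplyr::mutate(fx$genotypes, gt = "hom_ref")
  bt <- aggregate_burden(empty, fx$variants, fx$gene_sets, fx$cohort)
  expect_true(all(bt$counts$alt_alleles == 0))
})

test_that("site-by-2N allele frequencies reproduce the published values", {
  expect_equal(round(allele_frequency(18, 52, 9), 3), 0.019)
  expect_equal(round(allele_frequency(46, 52, 12), 3), 0.037)
  expect_equal(round(allele_frequency(56, 41, 22), 3), 0.031)
  expect_equal(round(allele_frequency(104, 79, 22), 3), 0.030)
  expect_equal(allele_frequency(0, 10, 5), 0)
})

test_that("burden Fisher contrasts reproduce the published headline result", {
  fx <- make_burden_fixture()
  bt <- aggregate_burden(fx$genotypes, fx$variants, fx$gene_sets, fx$cohort)
  p_dam <- burden_fisher(bt, "damaging", c("mild", "severe"), "less")
  p_ben <- burden_fisher(bt, "benign", c("mild", "severe"), "two_sided")
  expect_equal(round(p_dam, 4), 0.0100)
  expect_equal(round(p_ben, 4), 0.9111)
  expect_lte(p_dam, 0.05)
  expect_gte(p_ben, 0.9)
})

test_that("burden Fisher on identical frequencies is far from significant", {
  p <- burden_fisher(counts = list(alt = c(50, 50), total = c(1000, 1000)),
                     alternative = "two_sided")
  expect_gte(p, 0.9)
})

test_that("recurrence report identifies shared variants and conserves carriers", {
  fx <- make_burden_fixture()
  rec <- recurrence_report(fx$genotypes, fx$cohort)
  # doubleton sites exist by construction (12 damaging + 13 benign)
  expect_equal(sum(!rec$singleton), 25)
  expect_true(all(rec$n_carriers[!rec$singleton] == 2))
  # shared sites sit in the severe group
  expect_true(all(rec$carriers_mild[!rec$singleton] == 0))
  # conservation: carrier counts sum to total carrying calls
  expect_equal(sum(rec$n_carriers),
               sum(fx$genotypes$gt %in% c("het", "hom_alt")))

  # three-severe-carrier variant is reported as shared (0, 3)
  g3 <- fx$genotypes
  g3$gt[g3$site_id == "damaging_1"] <- "hom_ref"
  g3$gt[g3$site_id == "damaging_1" & g3$sample_id %in% c("S1", "S2", "S3")] <- "het"
  rec3 <- recurrence_report(g3, fx$cohort)
  row <- rec3[rec3$site_id == "damaging_1", ]
  expect_equal(row$carriers_mild, 0)
  expect_equal(row$carriers_severe, 3)
  expect_false(row$singleton)
})

test_that("variants outside the panel are excluded with a message", {
  fx <- make_burden_fixture()
  v <- fx$variants
  v$gene[1] <- "NOT_A_PANEL_GENE"
  expect_message(aggregate_burden(fx$genotypes, v, fx$gene_sets, fx$cohort),
                 "outside the gene panel")
})
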