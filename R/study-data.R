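#' Characteristics of the published extreme-phenotype Dravet cohort
#'
#' The per-patient table of the published study this package's methods are
#' designed around: 9 mildly and 12 severely affected individuals, all
#' heterozygous for a de novo SCN1A truncation variant, with sex, diagnosis,
#' IQ band, motor-delay status, truncation class, seizure-onset age and
#' follow-up time. Follow-up means: for mild patients, months from seizure
#' onset to the last assessment as mild; for severe patients, months from
#' onset to the first diagnosis as severe.
#'
#' @return A tibble with one row per individual and columns `id`, `group`
#'   (`"mild"`/`"severe"`), `sex` (`"M"`/`"F"`), `diagnosis`, `iq_band`,
#'   `motor_delay` (logical), `mutation_class`, `onset_months`,
#'   `followup_months`.
#' @examples
#' cohort <- dravet_cohort()
#' dplyr::count(cohort, group)
#' @export
dravet_cohort <- function() {
  tibble::tibble(
    id = c(paste0("M", 1:9), paste0("S", 1:12)),
    group = rep(c("mild", "severe"), c(9, 12)),
    sex = c("M", "M", "F", "F", "M", "F", "F", "M", "M",
            "F", "M", "F", "F", "M", "F", "M", "F", "M", "F", "F", "F"),
    diagnosis = c("DS border", "GEFS+", "DS", "DS", "DS", "FS+", "DS", "DS",
                  "DS border",
                  "DS", "DS", "DS", "DS", "DS", "DS", "Epilepsy/ID", "DS",
                  "DS", "DS", "DS", "DS"),
    iq_band = c("61", "50-75", "70-85", "50-70", "59", "66", "65", "50", "81",
                rep("<24", 12)),
    motor_delay = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE,
                    FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                    TRUE, TRUE, TRUE),
    mutation_class = c("microdel", "nonsense", "nonsense", "splicing",
                       "frameshift", "frameshift", "frameshift", "frameshift",
                       "nonsense",
                       "frameshift", "frameshift", "frameshift", "frameshift",
                       "nonsense", "frameshift", "microdel", "frameshift",
                       "nonsense", "nonsense", "nonsense", "microdel"),
    onset_months = c(6L, 6L, 15L, 5L, 8L, 8L, 7L, 6L, 7L,
                     6L, 4L, 6L, 6L, 9L, 5L, 2L, 6L, 2L, 8L, 2L, 6L),
    followup_months = c(261L, 189L, 180L, 190L, 187L, 187L, 188L, 189L, 104L,
                        44L, 39L, 43L, 41L, 48L, 45L, 59L, 61L, 40L, 47L,
                        70L, 138L)
  )
}

#' Published gene-class burden counts for the candidate panel
#'
#' The rare-missense burden table of the study this package emulates:
#' alternate-allele counts per gene class, pathogenicity category
#' (PolyPhen-2 damaging vs benign) and phenotype group, over 237
#' neuronal-excitability candidate genes in 17 classes. Column totals are
#' 18 (mild damaging), 46 (severe damaging), 35 (mild benign) and 48
#' (severe benign), from 52 damaging and 70 benign variant sites.
#'
#' @return A tibble with columns `gene_class`, `n_genes`, `damaging_mild`,
#'   `damaging_severe`, `benign_mild`, `benign_severe`.
#' @examples
#' counts <- dravet_burden_counts()
#' colSums(counts[, 3:6])
#' @export
dravet_burden_counts <- function() {
  tibble::tibble(
    gene_class = GENE_CLASSES,
    n_genes = c(16L, 5L, 20L, 9L, 14L, 8L, 16L, 26L, 9L, 50L, 14L, 8L, 14L,
                14L, 4L, 3L, 7L),
    damaging_mild   = c(3L, 0L, 0L, 0L, 0L, 1L, 3L, 0L, 2L, 5L, 1L, 0L, 2L, 0L, 0L, 1L, 0L),
    damaging_severe = c(4L, 0L, 5L, 0L, 3L, 3L, 3L, 6L, 1L, 9L, 2L, 0L, 4L, 0L, 1L, 4L, 1L),
    benign_mild     = c(2L, 2L, 3L, 1L, 1L, 1L, 3L, 3L, 4L, 5L, 4L, 0L, 1L, 1L, 0L, 4L, 0L),
    benign_severe   = c(3L, 2L, 5L, 0L, 1L, 1L, 3L, 8L, 4L, 5L, 7L, 2L, 0L, 1L, 1L, 3L, 2L)
  )
}

#' Qualifying-site counts behind the published burden table
#'
#' Site counts used by the site-by-2N allele-frequency convention: separate
#' calling of the patient cohort (52 damaging / 70 benign sites of 122 rare
#' missense variants), joint calling with a 22-sample healthy reference
#' subset (46 / 72 sites of 118 in the patients), and the jointly called
#' reference itself, whose published allele frequencies 56/1804 and
#' 104/3476 imply 41 damaging and 79 benign sites at 2N = 44.
#'
#' @return A tibble with columns `analysis`, `cohort`, `pathogenicity`,
#'   `n_sites`, `n_individuals` and the allele totals `alt_mild`,
#'   `alt_severe`, `alt_total`.
#' @export
dravet_site_counts <- function() {
  tibble::tibble(
    analysis = c("separate", "separate", "joint", "joint", "joint", "joint"),
    cohort = c("patients", "patients", "patients", "patients",
               "reference", "reference"),
    pathogenicity = rep(c("damaging", "benign"), 3),
    n_sites = c(52L, 70L, 46L, 72L, 41L, 79L),
    n_individuals = c(21L, 21L, 21L, 21L, 22L, 22L),
    alt_mild = c(18L, 35L, 15L, NA, NA, NA),
    alt_severe = c(46L, 48L, 40L, NA, NA, NA),
    alt_total = c(64L, 83L, 55L, NA, 56L, 104L)
  )
}
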