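#' Read a VCF file into a variant table and genotype table
#'
#' Parses a VCF v4.x file (GT required, AD optional) into the pair of tidy
#' tables the rest of the pipeline consumes: one row per ALT allele in the
#' variant table (multi-allelic records are decomposed), and one row per
#' (sample, site) in the genotype table. Annotation fields (gene symbol,
#' functional impact, reference-population allele frequency and categorical
#' pathogenicity call) are read from INFO keys; the defaults match the
#' fields this package writes.
#'
#' For a decomposed multi-allelic record the genotype of each derived
#' biallelic site counts only the tracked ALT allele; read depth for any
#' untracked allele is folded into the reference depth so every downstream
#' test stays biallelic.
#'
#' @param path Path to an (uncompressed or gzipped) VCF file.
#' @param info_keys Named list mapping the annotation slots `gene`, `impact`,
#'   `freq` and `patho` to INFO keys.
#' @return A list with elements `variants` (tibble: `site_id`, `chrom`,
#'   `pos`, `ref`, `alt`, `gene`, `impact`, `ref_pop_freq`, `patho_call`)
#'   and `genotypes` (tibble: `sample_id`, `site_id`, `gt`, `ad_ref`,
#'   `ad_alt`).
#' @examples
#' sim <- simulate_dataset(simulation_spec(), seed = 1)
#' f <- tempfile(fileext = ".vcf")
#' write_vcf(sim$variants, sim$genotypes, f)
#' vcf <- read_vcf(f)
#' @export
read_vcf <- function(path,
                     info_keys = list(gene = "GENE", impact = "IMPACT",
                                      freq = "EXT_AF", patho = "PP2_CALL")) {
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) abort(paste0("malformed VCF '", path, "': ", conditionMessage(e)))
  )
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  samples <- colnames(vcf@gt)[-1]
  if (nrow(fix) == 0) {
    return(list(
      variants = tibble::tibble(site_id = character(), chrom = character(),
                                pos = integer(), ref = character(), alt = character(),
                                gene = character(), impact = character(),
                                ref_pop_freq = double(), patho_call = character()),
      genotypes = tibble::tibble(sample_id = character(), site_id = character(),
                                 gt = character(), ad_ref = integer(), ad_alt = integer())
    ))
  }

  gt_raw <- vcf@gt
  fmt <- strsplit(gt_raw[, 1], ":", fixed = TRUE)

  var_rows <- list()
  gt_rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    keys <- fmt[[i]]
    gt_idx <- match("GT", keys)
    ad_idx <- match("AD", keys)
    if (is.na(gt_idx)) {
      abort(paste0("VCF record ", i, " (", fix$CHROM[i], ":", fix$POS[i],
                   "): FORMAT has no GT field"))
    }
    cells <- strsplit(gt_raw[i, -1], ":", fixed = TRUE)
    gts <- vapply(cells, function(x) x[gt_idx], character(1))
    alleles <- strsplit(gsub("\\|", "/", gts), "/", fixed = TRUE)
    bad <- !vapply(alleles, function(a)
      length(a) == 2L && all(a %in% c(".", as.character(0:length(alts)))), logical(1))
    if (any(bad)) {
      abort(paste0("VCF record ", i, " (", fix$CHROM[i], ":", fix$POS[i],
                   "): non-conforming GT '", gts[which(bad)[1]], "' for sample ",
                   samples[which(bad)[1]]))
    }
    ads <- if (!is.na(ad_idx)) {
      lapply(cells, function(x) {
        v <- suppressWarnings(as.integer(strsplit(x[ad_idx], ",", fixed = TRUE)[[1]]))
        if (all(is.na(v))) NULL else v
      })
    } else rep(list(NULL), length(cells))

    info <- fix$INFO[i] %||% NA_character_
    ann <- lapply(info_keys, function(k) extract_info(info, k))
    for (a in seq_along(alts)) {
      sid <- site_key(fix$CHROM[i], fix$POS[i], fix$REF[i], alts[a])
      var_rows[[length(var_rows) + 1L]] <- tibble::tibble(
        site_id = sid, chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[a],
        gene = ann$gene %||% NA_character_,
        impact = ann$impact %||% NA_character_,
        ref_pop_freq = suppressWarnings(as.numeric(ann$freq)),
        patho_call = ann$patho %||% NA_character_
      )
      dose <- vapply(alleles, function(al) {
        if (any(al == ".")) NA_integer_ else sum(al == as.character(a))
      }, integer(1))
      ad_pair <- t(vapply(ads, function(v) {
        if (is.null(v)) c(NA_integer_, NA_integer_)
        else {
          alt_d <- v[a + 1L]
          c(sum(v[-(a + 1L)], na.rm = TRUE), alt_d)
        }
      }, integer(2)))
      gt_rows[[length(gt_rows) + 1L]] <- tibble::tibble(
        sample_id = samples, site_id = sid,
        gt = unname(dplyr::case_when(is.na(dose) ~ "missing", dose == 0 ~ "hom_ref",
                                     dose == 1 ~ "het", TRUE ~ "hom_alt")),
        ad_ref = unname(ad_pair[, 1]), ad_alt = unname(ad_pair[, 2])
      )
    }
  }
  variants <- dplyr::bind_rows(var_rows)
  genotypes <- dplyr::bind_rows(gt_rows)
  validate_variants(variants)
  list(variants = variants, genotypes = genotypes)
}

extract_info <- function(info, key) {
  if (is.na(info)) return(NA_character_)
  fields <- strsplit(info, ";", fixed = TRUE)[[1]]
  hit <- grep(paste0("^", key, "="), fields, value = TRUE)
  if (length(hit) == 0) NA_character_ else sub(paste0("^", key, "="), "", hit[1])
}

validate_variants <- function(variants) {
  if (nrow(variants) == 0) return(invisible(variants))
  if (any(variants$pos < 1)) abort("variant positions must be >= 1")
  if (any(variants$ref == variants$alt)) abort("ref and alt alleles must differ")
  f <- variants$ref_pop_freq
  if (any(!is.na(f) & (f < 0 | f > 1))) abort("ref_pop_freq must lie in [0, 1]")
  invisible(variants)
}

#' Write a variant table and genotype table as VCF 4.2
#'
#' Emits an uncompressed VCF with GT:AD sample fields and the package's
#' INFO annotation keys (GENE, IMPACT, EXT_AF, PP2_CALL). Round-trips with
#' [read_vcf()]: genotypes and allele depths are preserved exactly.
#'
#' @param variants Variant tibble as produced by [read_vcf()] or
#'   [simulate_genotypes()].
#' @param genotypes Matching genotype tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, genotypes, path) {
  samples <- unique(genotypes$sample_id)
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=IMPACT,Number=1,Type=String,Description=\"Functional impact class\">",
    "##INFO=<ID=EXT_AF,Number=1,Type=Float,Description=\"Reference-population allele frequency\">",
    "##INFO=<ID=PP2_CALL,Number=1,Type=String,Description=\"Pathogenicity call\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")
  gt_wide <- genotypes |>
    dplyr::mutate(cell = paste0(
      gt_code[.data$gt], ":",
      ifelse(is.na(.data$ad_ref) | is.na(.data$ad_alt), ".",
             paste0(.data$ad_ref, ",", .data$ad_alt)))) |>
    dplyr::select("sample_id", "site_id", "cell") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "cell")

  rows <- variants |>
    dplyr::left_join(gt_wide, by = "site_id") |>
    dplyr::arrange(.data$chrom, .data$pos, .data$alt)
  info <- paste0(
    ifelse(is.na(rows$gene), "", paste0("GENE=", rows$gene, ";")),
    ifelse(is.na(rows$impact), "", paste0("IMPACT=", rows$impact, ";")),
    ifelse(is.na(rows$ref_pop_freq), "", paste0("EXT_AF=", rows$ref_pop_freq, ";")),
    ifelse(is.na(rows$patho_call), "", paste0("PP2_CALL=", rows$patho_call, ";")))
  info <- sub(";$", "", info)
  info[info == ""] <- "."
  body <- paste(rows$chrom, rows$pos, ".", rows$ref, rows$alt, ".", "PASS",
                info, "GT:AD", sep = "\t")
  cells <- as.matrix(rows[, samples, drop = FALSE])
  body <- paste(body, apply(cells, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Load a gene-set annotation (gene symbol to gene class)
#'
#' Reads a two-column TSV (`gene`, `class`) mapping candidate genes to
#' functional classes, or, with `path = NULL`, the packaged default panel:
#' a synthetic 237-gene neuronal-excitability panel whose 17 class sizes
#' (16, 5, 20, 9, 14, 8, 16, 26, 9, 50, 14, 8, 14, 14, 4, 3, 7) match the
#' published candidate-gene panel this package emulates. The packaged gene
#' symbols are synthetic placeholders, not the published symbols.
#'
#' @param path Path to a TSV with columns `gene` and `class`, or `NULL` for
#'   the packaged default.
#' @param strict Validate class names against the canonical 17-class
#'   vocabulary (default `TRUE`).
#' @return A tibble with columns `gene` and `class`.
#' @examples
#' gs <- load_gene_sets()
#' gene_class_sizes(gs)
#' @export
load_gene_sets <- function(path = NULL, strict = TRUE) {
  if (is.null(path)) {
    path <- system.file("extdata", "gene_classes.tsv", package = "modburden",
                        mustWork = TRUE)
  }
  df <- tibble::as_tibble(read.delim(path, stringsAsFactors = FALSE,
                                     check.names = FALSE))
  if (!all(c("gene", "class") %in% names(df))) {
    abort("gene-set file must have columns 'gene' and 'class'")
  }
  dup <- unique(df$gene[duplicated(df$gene)])
  if (length(dup) > 0) {
    abort(paste0("duplicate gene symbols in gene-set file: ",
                 paste(dup, collapse = ", ")))
  }
  if (strict) {
    bad <- setdiff(unique(df$class), GENE_CLASSES)
    if (length(bad) > 0) {
      abort(paste0("unknown gene class(es): ", paste(bad, collapse = ", ")))
    }
  }
  df[, c("gene", "class")]
}

#' Count genes per class in a gene-set annotation
#'
#' @param gene_sets A gene-set tibble from [load_gene_sets()].
#' @return Tibble with columns `class` and `n_genes`.
#' @export
gene_class_sizes <- function(gene_sets) {
  gene_sets |>
    dplyr::count(.data$class, name = "n_genes") |>
    dplyr::arrange(factor(.data$class, levels = GENE_CLASSES))
}

#' Write a pipeline result table as TSV
#'
#' Writes any tabular pipeline output to a tab-separated file; tables with a
#' `p_value` column are sorted ascending by p-value first. The write is
#' round-trip stable with [read_report()].
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  x <- tibble::as_tibble(x)
  if ("p_value" %in% names(x)) x <- dplyr::arrange(x, .data$p_value)
  ok <- tryCatch({
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) {
    abort(paste0("cannot write report to '", path, "': ", conditionMessage(e)))
  })
  invisible(path)
}

#' Read back a TSV report written by [write_report()]
#' @param path Path to a TSV file.
#' @return A tibble.
#' @export
read_report <- function(path) {
  tibble::as_tibble(read.delim(path, stringsAsFactors = FALSE, check.names = FALSE))
}
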