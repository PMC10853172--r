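#' Cohort container: dosages, variants, phenotypes, covariates
#'
#' A `multipgs_cohort` bundles one cohort's genotype dosages (samples x
#' variants numeric matrix with values in `[0, 2]`), the per-variant metadata
#' (`variant_id`, `chr`, `pos`, `effect_allele`, `other_allele`, `maf`; the
#' dosage counts copies of `effect_allele`), per-sample binary phenotypes (one
#' column per trait), and per-sample covariates (age, sex, principal
#' components).
#'
#' @param dosage Numeric matrix, samples x variants, values in `[0, 2]`
#'   (NA allowed; scoring mean-imputes by `2 * maf`).
#' @param variant_meta Data frame with columns `variant_id`, `chr`, `pos`,
#'   `effect_allele`, `other_allele`, `maf`; `variant_id` unique and matching
#'   `colnames(dosage)`.
#' @param phenotypes Optional data frame of 0/1 outcomes, one row per sample.
#' @param covariates Optional data frame of covariates, one row per sample.
#' @param sample_ids Character vector of sample identifiers.
#' @return An object of class `multipgs_cohort`.
#' @export
new_cohort <- function(dosage, variant_meta, phenotypes = NULL,
                       covariates = NULL, sample_ids = NULL) {
  stop_if(!is.matrix(dosage) || !is.numeric(dosage),
          "`dosage` must be a numeric matrix (samples x variants).")
  rng <- range(dosage, na.rm = TRUE)
  stop_if(rng[1] < 0 || rng[2] > 2, "dosage values must lie in [0, 2].")
  variant_meta <- tibble::as_tibble(variant_meta)
  need <- c("variant_id", "chr", "pos", "effect_allele", "other_allele", "maf")
  miss <- setdiff(need, names(variant_meta))
  stop_if(length(miss) > 0, "variant_meta is missing column(s): %s",
          paste(miss, collapse = ", "))
  stop_if(anyDuplicated(variant_meta$variant_id) > 0,
          "variant ids must be unique.")
  stop_if(nrow(variant_meta) != ncol(dosage),
          "variant_meta rows (%d) must match dosage columns (%d).",
          nrow(variant_meta), ncol(dosage))
  if (is.null(sample_ids)) {
    sample_ids <- rownames(dosage) %||% sprintf("S%05d", seq_len(nrow(dosage)))
  }
  stop_if(length(sample_ids) != nrow(dosage),
          "sample_ids length must match dosage rows.")
  rownames(dosage) <- sample_ids
  colnames(dosage) <- variant_meta$variant_id
  if (!is.null(phenotypes)) {
    phenotypes <- tibble::as_tibble(phenotypes)
    stop_if(nrow(phenotypes) != nrow(dosage),
            "phenotypes must have one row per sample.")
    bad <- !vapply(phenotypes, is_binary01, logical(1))
    stop_if(any(bad), "phenotype column(s) not coded 0/1: %s",
            paste(names(phenotypes)[bad], collapse = ", "))
  }
  if (!is.null(covariates)) {
    covariates <- tibble::as_tibble(covariates)
    stop_if(nrow(covariates) != nrow(dosage),
            "covariates must have one row per sample.")
  }
  structure(list(sample_ids = sample_ids, dosage = dosage,
                 variant_meta = variant_meta, phenotypes = phenotypes,
                 covariates = covariates),
            class = "multipgs_cohort")
}

#' @export
print.multipgs_cohort <- function(x, ...) {
  cat("<multipgs_cohort>\n")
  cat(sprintf("  %d samples x %d variants\n", nrow(x$dosage), ncol(x$dosage)))
  if (!is.null(x$phenotypes))
    cat(sprintf("  phenotypes: %s\n", paste(names(x$phenotypes), collapse = ", ")))
  if (!is.null(x$covariates))
    cat(sprintf("  covariates: %s\n", paste(names(x$covariates), collapse = ", ")))
  invisible(x)
}

#' Number of samples / variants in a cohort
#' @param cohort A `multipgs_cohort`.
#' @return Integer count.
#' @export
n_samples <- function(cohort) nrow(cohort$dosage)

#' @rdname n_samples
#' @export
n_variants <- function(cohort) ncol(cohort$dosage)

#' Write a cohort to plain-text files
#'
#' Writes the dosage matrix as TSV (`<prefix>_dosage.tsv`: sample_id then one
#' column per variant), variant metadata (`<prefix>_variants.tsv`), and, when
#' present, phenotypes plus covariates (`<prefix>_pheno.tsv`). Optionally also
#' writes a minimal VCF with per-sample dosages in a `DS` FORMAT field
#' (`<prefix>.vcf`), readable by standard VCF tooling.
#'
#' @param cohort A `multipgs_cohort`.
#' @param prefix Output path prefix.
#' @param vcf Also write the dosage VCF? Default `FALSE`.
#' @return Invisibly, a character vector of the files written.
#' @export
write_cohort <- function(cohort, prefix, vcf = FALSE) {
  files <- character(0)
  dos <- tibble::as_tibble(cohort$dosage)
  dos <- dplyr::bind_cols(tibble::tibble(sample_id = cohort$sample_ids), dos)
  f <- paste0(prefix, "_dosage.tsv")
  readr::write_tsv(dos, f)
  files <- c(files, f)
  f <- paste0(prefix, "_variants.tsv")
  readr::write_tsv(cohort$variant_meta, f)
  files <- c(files, f)
  if (!is.null(cohort$phenotypes) || !is.null(cohort$covariates)) {
    ph <- dplyr::bind_cols(
      tibble::tibble(sample_id = cohort$sample_ids),
      cohort$phenotypes %||% tibble::tibble(.rows = length(cohort$sample_ids)),
      cohort$covariates %||% tibble::tibble(.rows = length(cohort$sample_ids)))
    f <- paste0(prefix, "_pheno.tsv")
    readr::write_tsv(ph, f)
    files <- c(files, f)
  }
  if (vcf) {
    f <- paste0(prefix, ".vcf")
    write_dosage_vcf(cohort, f)
    files <- c(files, f)
  }
  invisible(files)
}

#' Write cohort dosages as a VCF with a DS FORMAT field
#'
#' Emits a minimal VCFv4.2 file: one record per variant, REF = other allele,
#' ALT = effect allele, and per-sample `DS` values equal to the effect-allele
#' dosage. Coordinates are 1-based.
#'
#' @param cohort A `multipgs_cohort`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_dosage_vcf <- function(cohort, path) {
  vm <- cohort$variant_meta
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage of the ALT (effect) allele\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", cohort$sample_ids), collapse = "\t"))
  body <- vapply(seq_len(nrow(vm)), function(j) {
    ds <- formatC(cohort$dosage[, j], format = "g", digits = 6)
    ds[is.na(cohort$dosage[, j])] <- "."
    paste(c(vm$chr[j], vm$pos[j], vm$variant_id[j], vm$other_allele[j],
            vm$effect_allele[j], ".", "PASS", ".", "DS", ds), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a dosage VCF into dosage matrix + variant metadata
#'
#' Reads a VCF carrying per-sample dosages in a `DS` FORMAT field (as written
#' by [write_dosage_vcf()] or by imputation servers) via the vcfR package.
#' ALT is taken as the effect (dosage-counted) allele, REF as the other.
#'
#' @param path VCF path.
#' @return A `multipgs_cohort` with dosage and variant metadata only.
#' @export
read_dosage_vcf <- function(path) {
  stop_if(!requireNamespace("vcfR", quietly = TRUE),
          "reading VCF requires the vcfR package.")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE))
  dosage <- t(ds)
  vm <- tibble::tibble(
    variant_id = fix$ID, chr = fix$CHROM, pos = as.integer(fix$POS),
    effect_allele = fix$ALT, other_allele = fix$REF,
    maf = pmin(colMeans(dosage, na.rm = TRUE) / 2,
               1 - colMeans(dosage, na.rm = TRUE) / 2))
  new_cohort(dosage, vm, sample_ids = rownames(dosage))
}

#' Read a TSV dosage matrix (+ variant metadata) as a cohort
#'
#' @param dosage_path TSV with `sample_id` then one numeric column per variant.
#' @param variants_path TSV of variant metadata as written by [write_cohort()].
#' @param pheno_path Optional TSV with `sample_id`, phenotype and covariate
#'   columns; phenotype columns are those named in `pheno_cols`.
#' @param pheno_cols Character vector naming the 0/1 outcome columns in
#'   `pheno_path` (default: columns starting with `"trait"`).
#' @return A `multipgs_cohort`.
#' @export
read_dosage_tsv <- function(dosage_path, variants_path, pheno_path = NULL,
                            pheno_cols = NULL) {
  dos <- readr::read_tsv(dosage_path, show_col_types = FALSE)
  vm <- readr::read_tsv(variants_path, show_col_types = FALSE)
  ids <- dos$sample_id
  m <- as.matrix(dos[setdiff(names(dos), "sample_id")])
  phenotypes <- covariates <- NULL
  if (!is.null(pheno_path)) {
    ph <- readr::read_tsv(pheno_path, show_col_types = FALSE)
    ph <- ph[match(ids, ph$sample_id), , drop = FALSE]
    cols <- pheno_cols %||% grep("^trait", names(ph), value = TRUE)
    phenotypes <- ph[cols]
    covariates <- ph[setdiff(names(ph), c("sample_id", cols))]
    if (ncol(covariates) == 0) covariates <- NULL
  }
  new_cohort(m, vm, phenotypes = phenotypes, covariates = covariates,
             sample_ids = ids)
}
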