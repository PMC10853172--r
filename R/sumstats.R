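# Summary-statistics preparation: effective sample sizes, QC, genomic
# control, and fixed-effects inverse-variance meta-analysis.

SUMSTATS_COLS <- c("variant_id", "chr", "pos", "effect_allele", "other_allele",
                   "eaf", "beta", "se", "p", "n_cases", "n_controls")

new_sumstats <- function(x, trait = NA_character_, source = NA_character_) {
  x <- tibble::as_tibble(x)
  miss <- setdiff(SUMSTATS_COLS, names(x))
  stop_if(length(miss) > 0, "summary statistics missing column(s): %s",
          paste(miss, collapse = ", "))
  stop_if(anyDuplicated(x$variant_id) > 0,
          "variant_id must be unique within a summary-statistics table.")
  ok <- !is.na(x$se) & !is.na(x$eaf)
  stop_if(any(x$se[ok] <= 0), "se must be > 0 for every complete row.")
  stop_if(any(x$eaf[ok] <= 0 | x$eaf[ok] >= 1),
          "eaf must lie strictly inside (0, 1).")
  attr(x, "trait") <- trait
  attr(x, "source") <- source
  class(x) <- c("multipgs_sumstats", class(x))
  x
}

#' Read / write a summary-statistics TSV
#'
#' The on-disk dialect is a plain TSV with header
#' `variant_id, chr, pos, effect_allele, other_allele, eaf, beta, se, p,
#' n_cases, n_controls` (extra columns such as `info`, `call_rate`, `hwe_p`
#' or `status` pass through).
#'
#' @param path File path.
#' @param trait,source Optional metadata recorded on the table.
#' @return `read_sumstats()`: a `multipgs_sumstats` tibble.
#' @export
read_sumstats <- function(path, trait = NA_character_, source = NA_character_) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(chr = readr::col_character()))
  new_sumstats(x, trait = trait, source = source)
}

#' @rdname read_sumstats
#' @param x A summary-statistics tibble.
#' @return `write_sumstats()`: invisibly, `path`.
#' @export
write_sumstats <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path)
  invisible(path)
}

#' Total effective sample size of a case-control GWAS
#'
#' `4 p (1 - p) N` with `p` the case proportion and `N = n_cases +
#' n_controls`: the size of the balanced study with equivalent power.
#'
#' @param n_cases,n_controls Case and control counts (vectorized; both >= 1).
#' @return Effective sample size(s).
#' @export
#' @examples
#' total_effective_n(500, 500)   # 1000: balanced design
#' total_effective_n(100, 300)   # 300
total_effective_n <- function(n_cases, n_controls) {
  stop_if(any(n_cases < 1) || any(n_controls < 1),
          "n_cases and n_controls must both be >= 1 (case proportion degenerate).")
  n <- n_cases + n_controls
  p <- n_cases / n
  4 * p * (1 - p) * n
}

#' Per-variant effective sample size with clamping
#'
#' `4 / (2 f (1 - f) SE^2)` with `f` the allele frequency and `SE` the
#' per-variant standard error, bounded between 0.5 and 1.1 times the study's
#' total effective sample size. The raw formula inverts the approximate
#' variance of a marginal case-control log-odds estimate; the clamp guards
#' against unreliable SEs at frequency extremes.
#'
#' @param eaf Effect-allele frequency in (0, 1) (vectorized).
#' @param se Standard error (> 0).
#' @param total_eff_n Total effective sample size of the study (> 0).
#' @return Clamped per-variant effective sample size(s).
#' @export
#' @examples
#' per_snp_effective_n(0.5, 0.1, 1000)  # raw 800, within bounds
#' per_snp_effective_n(0.5, 0.1, 500)   # clamped to 1.1 * 500 = 550
per_snp_effective_n <- function(eaf, se, total_eff_n) {
  stop_if(any(eaf <= 0 | eaf >= 1), "eaf must lie strictly inside (0, 1).")
  stop_if(any(se <= 0), "se must be positive.")
  stop_if(any(total_eff_n <= 0), "total_eff_n must be positive.")
  raw <- 4 / (2 * eaf * (1 - eaf) * se^2)
  pmin(pmax(raw, 0.5 * total_eff_n), 1.1 * total_eff_n)
}

# chi-square(1 df) median, documented to 7 digits for reproducibility.
CHISQ1_MEDIAN <- 0.4549364

#' Genomic-control inflation factor
#'
#' `lambda_GC = median((beta/se)^2) / 0.4549364`, the median association
#' chi-square relative to the chi-square(1) median. Values near 1 indicate a
#' well-calibrated null; inflation beyond 1 suggests stratification or
#' polygenicity.
#'
#' @param stats A summary-statistics tibble with `beta` and `se` (incomplete
#'   rows ignored).
#' @return The inflation factor (>= 0).
#' @export
genomic_control_lambda <- function(stats) {
  z2 <- (stats$beta / stats$se)^2
  z2 <- z2[is.finite(z2)]
  stop_if(length(z2) == 0, "no complete rows; cannot compute lambda.")
  median(z2) / CHISQ1_MEDIAN
}

#' Apply genomic control to a study
#'
#' When `lambda > 1`, inflates every SE by `sqrt(lambda)` (and recomputes
#' p-values); deflation is never applied. This is the per-study convention
#' used before fixed-effects meta-analysis.
#'
#' @param stats A summary-statistics tibble.
#' @return The corrected table, with attribute `"lambda_gc"`.
#' @export
apply_genomic_control <- function(stats) {
  lam <- genomic_control_lambda(stats)
  if (lam > 1) {
    stats$se <- stats$se * sqrt(lam)
    stats$p <- 2 * pnorm(-abs(stats$beta / stats$se))
  }
  attr(stats, "lambda_gc") <- lam
  stats
}

#' Fixed-effects inverse-variance meta-analysis
#'
#' Combines two or more summary-statistics tables per shared variant with
#' weights `w_i = 1/se_i^2`: combined `beta = sum(w beta) / sum(w)`,
#' `se = 1/sqrt(sum(w))`, two-sided normal p-value; case/control counts are
#' summed and the combined `eaf` is the weight-averaged frequency. Alleles
#' are aligned to the first table carrying each variant: exact match keeps the
#' effect as-is, swapped effect/other alleles flip the beta sign (and
#' `eaf -> 1 - eaf`); irreconcilable allele pairs drop the variant with a
#' logged count (strand flips are deliberately not attempted here). Variants
#' present in a single table are carried through unchanged and flagged
#' `n_studies = 1`.
#'
#' @param tables List of summary-statistics tibbles (>= 1; a single table is
#'   returned as-is with `n_studies = 1`).
#' @param apply_gc Apply per-study genomic control (only when lambda > 1)
#'   before combining?
#' @return A `multipgs_sumstats` tibble with an extra `n_studies` column and
#'   attribute `"n_allele_mismatch"` counting dropped variants.
#' @export
ivw_meta <- function(tables, apply_gc = FALSE) {
  stop_if(!is.list(tables) || length(tables) < 1, "`tables` must be a non-empty list.")
  if (apply_gc) tables <- lapply(tables, apply_genomic_control)
  tagged <- purrr::imap(tables, function(t, i) {
    t <- tibble::as_tibble(t)[intersect(c(SUMSTATS_COLS), names(t))]
    t$.study <- i
    t
  })
  all_rows <- dplyr::bind_rows(tagged)
  # Align each variant's rows to the alleles of its first-seen row.
  aligned <- all_rows |>
    dplyr::group_by(.data$variant_id) |>
    dplyr::mutate(
      .ea = dplyr::first(.data$effect_allele),
      .oa = dplyr::first(.data$other_allele),
      .match = dplyr::case_when(
        .data$effect_allele == .data$.ea & .data$other_allele == .data$.oa ~ "exact",
        .data$effect_allele == .data$.oa & .data$other_allele == .data$.ea ~ "swap",
        TRUE ~ "mismatch")) |>
    dplyr::ungroup()
  n_mismatch_variants <- aligned |>
    dplyr::filter(.data$.match == "mismatch") |>
    dplyr::distinct(.data$variant_id) |>
    nrow()
  if (n_mismatch_variants > 0)
    rlang::inform(sprintf(
      "ivw_meta: dropped %d variant(s) with irreconcilable alleles.",
      n_mismatch_variants))
  aligned <- aligned |>
    dplyr::group_by(.data$variant_id) |>
    dplyr::filter(!any(.data$.match == "mismatch")) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      beta = ifelse(.data$.match == "swap", -.data$beta, .data$beta),
      eaf = ifelse(.data$.match == "swap", 1 - .data$eaf, .data$eaf),
      effect_allele = .data$.ea, other_allele = .data$.oa)
  combined <- aligned |>
    dplyr::filter(!is.na(.data$beta), !is.na(.data$se)) |>
    dplyr::group_by(.data$variant_id, .data$chr, .data$pos,
                    .data$effect_allele, .data$other_allele) |>
    dplyr::summarise(
      eaf = sum((1 / .data$se^2) * .data$eaf) / sum(1 / .data$se^2),
      beta = sum(.data$beta / .data$se^2) / sum(1 / .data$se^2),
      se = 1 / sqrt(sum(1 / .data$se^2)),
      n_cases = sum(.data$n_cases), n_controls = sum(.data$n_controls),
      n_studies = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(p = 2 * pnorm(-abs(.data$beta / .data$se))) |>
    dplyr::select(dplyr::all_of(c(SUMSTATS_COLS, "n_studies")))
  # Preserve first-seen variant order.
  combined <- combined[match(unique(aligned$variant_id), combined$variant_id), ]
  combined <- combined[!is.na(combined$variant_id), ]
  out <- new_sumstats(combined,
                      trait = attr(tables[[1]], "trait") %||% NA_character_,
                      source = sprintf("ivw_meta(%d studies)", length(tables)))
  attr(out, "n_allele_mismatch") <- n_mismatch_variants
  out
}

#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' One-degree-of-freedom chi-square test of observed genotype counts against
#' the HWE expectation at the sample allele frequency. Monomorphic sites are
#' defined to pass (p = 1): no test is possible.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts (vectorized,
#'   non-negative, total >= 1).
#' @return p-value(s).
#' @export
#' @examples
#' hwe_test(25, 50, 25)   # exact HWE proportions: p = 1
#' hwe_test(50, 0, 50)    # complete heterozygote deficit: p << 1e-6
hwe_test <- function(n_hom_ref, n_het, n_hom_alt) {
  stop_if(any(c(n_hom_ref, n_het, n_hom_alt) < 0), "genotype counts must be non-negative.")
  n <- n_hom_ref + n_het + n_hom_alt
  stop_if(any(n < 1), "total genotype count must be >= 1.")
  f <- (2 * n_hom_alt + n_het) / (2 * n)
  exp_rr <- n * (1 - f)^2
  exp_het <- n * 2 * f * (1 - f)
  exp_aa <- n * f^2
  mono <- f == 0 | f == 1
  chisq <- ifelse(mono, 0,
                  (n_hom_ref - exp_rr)^2 / pmax(exp_rr, .Machine$double.eps) +
                  (n_het - exp_het)^2 / pmax(exp_het, .Machine$double.eps) +
                  (n_hom_alt - exp_aa)^2 / pmax(exp_aa, .Machine$double.eps))
  pchisq(chisq, df = 1, lower.tail = FALSE)
}

#' Variant quality-control thresholds
#'
#' Defaults follow standard biobank practice for imputed case-control data:
#' MAF >= 1%, imputation info >= 0.3, call rate >= 0.99, HWE p >= 1e-6.
#'
#' @param maf_min,info_min,call_rate_min,hwe_p_min Thresholds in `[0, 1]`.
#' @return A `multipgs_qc_thresholds` list.
#' @export
qc_thresholds <- function(maf_min = 0.01, info_min = 0.3,
                          call_rate_min = 0.99, hwe_p_min = 1e-6) {
  vals <- c(maf_min, info_min, call_rate_min, hwe_p_min)
  stop_if(any(vals < 0 | vals > 1), "all QC thresholds must lie in [0, 1].")
  structure(list(maf_min = maf_min, info_min = info_min,
                 call_rate_min = call_rate_min, hwe_p_min = hwe_p_min),
            class = "multipgs_qc_thresholds")
}

#' Filter variants by QC thresholds
#'
#' Removes rows failing any active filter and reports a per-filter exclusion
#' tally. A filter is active only when its column is present: MAF uses
#' `maf` or `min(eaf, 1 - eaf)`, the others use `info`, `call_rate`, and
#' `hwe_p`. Absent columns deactivate the corresponding filter with a
#' warning. Rows failing several filters are tallied once per filter, in the
#' order maf, info, call rate, HWE. Input order is preserved.
#'
#' @param stats A variant table (summary statistics or variant metadata).
#' @param thresholds A [qc_thresholds()] object.
#' @return The filtered table with attribute `"qc_tally"` (named integer
#'   vector of per-filter exclusion counts, plus `n_removed`/`n_kept`);
#'   retrieve it with [qc_tally()].
#' @export
qc_filter <- function(stats, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "multipgs_qc_thresholds"))
  x <- tibble::as_tibble(stats)
  n0 <- nrow(x)
  maf <- if ("maf" %in% names(x)) x$maf
         else if ("eaf" %in% names(x)) pmin(x$eaf, 1 - x$eaf)
         else NULL
  checks <- list(
    maf = if (!is.null(maf)) maf >= thresholds$maf_min,
    info = if ("info" %in% names(x)) x$info >= thresholds$info_min,
    call_rate = if ("call_rate" %in% names(x)) x$call_rate >= thresholds$call_rate_min,
    hwe = if ("hwe_p" %in% names(x)) x$hwe_p >= thresholds$hwe_p_min)
  inactive <- names(checks)[vapply(checks, is.null, logical(1))]
  if (length(inactive) > 0)
    rlang::warn(sprintf("qc_filter: no column for filter(s) %s; skipped.",
                        paste(inactive, collapse = ", ")))
  tally <- integer(0)
  keep <- rep(TRUE, n0)
  for (nm in names(checks)) {
    if (is.null(checks[[nm]])) next
    pass <- checks[[nm]] | is.na(checks[[nm]])   # NA in a QC column: no evidence to exclude
    tally[nm] <- sum(keep & !pass)
    keep <- keep & pass
  }
  out <- x[keep, ]
  attr(out, "qc_tally") <- c(tally, n_removed = n0 - nrow(out), n_kept = nrow(out))
  if (inherits(stats, "multipgs_sumstats")) {
    attr(out, "trait") <- attr(stats, "trait")
    class(out) <- c("multipgs_sumstats", class(out))
  }
  out
}

#' @rdname qc_filter
#' @param x A table returned by `qc_filter()`.
#' @export
qc_tally <- function(x) attr(x, "qc_tally")
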