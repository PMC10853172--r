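# Weight collapse: turn a fitted PGS combination into a single variant-level
# scoring file, and verify the algebraic identity it implies.

#' Collapse component scoring files into one multi-PGS scoring file
#'
#' For each variant j in the union of component variants, the combined weight
#' is `w_j = sum_k (beta_k / sigma_k) * w_jk`, where `beta_k` is the lasso
#' coefficient of PGS k (standardized scale), `sigma_k` its standard
#' deviation in the tuning cohort, and `w_jk` its weight for variant j — zero
#' when the variant is absent from component k. Components with `beta_k = 0`
#' contribute nothing and are dropped. Before summation each site's allele
#' orientation is reconciled to its first occurrence (swapped effect/other
#' alleles negate that component's weight); strand-ambiguous rows (A/T, C/G)
#' and within-component duplicate sites are removed first, mirroring
#' [harmonize()] so that scoring the combined file reproduces the weighted
#' component scores exactly. Sites with irreconcilable allele pairs across
#' components are dropped with a logged tally.
#'
#' @param scoring_files Named list of `multipgs_scoring` tibbles (one per
#'   component PGS).
#' @param coefficients Named numeric vector `beta_k`, names matching
#'   `scoring_files`.
#' @param pgs_sds Named numeric vector `sigma_k` (> 0 for every component
#'   with nonzero coefficient), names matching `scoring_files`.
#' @param pgs_id,trait Metadata for the combined file.
#' @return A `multipgs_scoring` tibble covering the union of component
#'   variants with nonzero combined relevance; provenance (per-component
#'   `beta_k`, `sigma_k`) is stored in its metadata, and attribute
#'   `"n_allele_conflict"` counts dropped sites.
#' @export
collapse_weights <- function(scoring_files, coefficients, pgs_sds,
                             pgs_id = "multiPGS", trait = "combined") {
  stop_if(is.null(names(scoring_files)), "`scoring_files` must be named.")
  ids <- names(scoring_files)
  stop_if(!all(ids %in% names(coefficients)),
          "`coefficients` must carry a value for every scoring file.")
  stop_if(!all(ids %in% names(pgs_sds)),
          "`pgs_sds` must carry a value for every scoring file.")
  keep <- ids[coefficients[ids] != 0]
  stop_if(any(pgs_sds[keep] <= 0),
          "pgs_sds must be > 0 for every component with nonzero coefficient.")

  if (length(keep) == 0) {
    out <- new_scoring_file(
      tibble::tibble(chr_name = character(), chr_position = integer(),
                     effect_allele = character(), other_allele = character(),
                     effect_weight = numeric()),
      metadata = list(pgs_id = pgs_id, trait = trait, n_components = 0))
    attr(out, "n_allele_conflict") <- 0L
    return(out)
  }

  rows <- purrr::map(keep, function(id) {
    s <- tibble::as_tibble(scoring_files[[id]])
    # same pre-filters as harmonize(): site duplicates and ambiguous pairs
    site <- paste(s$chr_name, s$chr_position)
    s <- s[!duplicated(site), ]
    amb <- !is.na(s$other_allele) &
      is_ambiguous_pair(s$effect_allele, s$other_allele)
    s <- s[!amb, ]
    factor_k <- coefficients[[id]] / pgs_sds[[id]]
    dplyr::mutate(s, effect_weight = .data$effect_weight * factor_k,
                  component = id)
  }) |> dplyr::bind_rows()

  aligned <- rows |>
    dplyr::group_by(.data$chr_name, .data$chr_position) |>
    dplyr::mutate(
      .ea = dplyr::first(.data$effect_allele),
      .oa = dplyr::first(.data$other_allele),
      .match = dplyr::case_when(
        .data$effect_allele == .data$.ea &
          (is.na(.data$other_allele) | is.na(.data$.oa) |
             .data$other_allele == .data$.oa) ~ "exact",
        !is.na(.data$other_allele) & !is.na(.data$.oa) &
          .data$effect_allele == .data$.oa &
          .data$other_allele == .data$.ea ~ "swap",
        TRUE ~ "conflict")) |>
    dplyr::ungroup()
  n_conflict <- aligned |>
    dplyr::filter(.data$.match == "conflict") |>
    dplyr::distinct(.data$chr_name, .data$chr_position) |>
    nrow()
  if (n_conflict > 0)
    rlang::inform(sprintf(
      "collapse_weights: dropped %d site(s) with conflicting allele pairs.",
      n_conflict))
  combined <- aligned |>
    dplyr::group_by(.data$chr_name, .data$chr_position) |>
    dplyr::filter(!any(.data$.match == "conflict")) |>
    dplyr::summarise(
      effect_allele = dplyr::first(.data$.ea),
      other_allele = dplyr::first(.data$.oa),
      effect_weight = sum(ifelse(.data$.match == "swap",
                                 -.data$effect_weight, .data$effect_weight)),
      .groups = "drop") |>
    dplyr::arrange(.data$chr_name, .data$chr_position)

  provenance <- paste(sprintf("%s:beta=%.10g,sd=%.10g", keep,
                              coefficients[keep], pgs_sds[keep]),
                      collapse = ";")
  out <- new_scoring_file(
    combined,
    metadata = list(pgs_id = pgs_id, trait = trait,
                    n_components = length(keep), components = provenance))
  attr(out, "n_allele_conflict") <- n_conflict
  out
}

#' Collapse directly from a fitted lasso combination
#'
#' Convenience wrapper around [collapse_weights()] taking the coefficients
#' and tuning-cohort PGS standard deviations from a `multipgs_lasso` fit.
#'
#' @param fit A `multipgs_lasso` fit.
#' @param scoring_files Named list of the component scoring files, names
#'   matching `fit$pgs_ids`.
#' @param ... Passed to [collapse_weights()].
#' @return A combined `multipgs_scoring` tibble.
#' @export
collapse_fit <- function(fit, scoring_files, ...) {
  collapse_weights(scoring_files, fit$coefficients, fit$pgs_sds, ...)
}

#' Verify the weight-collapse identity on a cohort
#'
#' The pipeline's core self-check: scoring a cohort with the combined file
#' must reproduce `sum_k (beta_k / sigma_k) * PGS_k` exactly (up to floating
#' point). Returns the maximum absolute per-sample discrepancy; anything
#' materially above ~1e-8 indicates a corrupted collapse (missing component,
#' allele mix-up, wrong SD).
#'
#' @param cohort A `multipgs_cohort`.
#' @param scoring_files Named list of component scoring files.
#' @param coefficients,pgs_sds Named vectors as in [collapse_weights()].
#' @param combined The combined scoring file to verify.
#' @return Maximum absolute discrepancy (a single number).
#' @export
verify_collapse <- function(cohort, scoring_files, coefficients, pgs_sds,
                            combined) {
  ids <- names(scoring_files)
  keep <- ids[coefficients[ids] != 0]
  target <- numeric(n_samples(cohort))
  for (id in keep) {
    h <- harmonize(scoring_files[[id]], cohort$variant_meta)
    target <- target +
      (coefficients[[id]] / pgs_sds[[id]]) * compute_pgs(cohort, h$weights)$score
  }
  hc <- harmonize(combined, cohort$variant_meta)
  got <- compute_pgs(cohort, hc$weights)$score
  max(abs(got - target))
}
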