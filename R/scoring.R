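# Scoring module: PGS Catalog style scoring files, variant harmonization
# against cohort genotypes, and per-sample score computation.

SCORING_COLS <- c("chr_name", "chr_position", "effect_allele", "effect_weight")

new_scoring_file <- function(rows, metadata = list()) {
  rows <- tibble::as_tibble(rows)
  miss <- setdiff(SCORING_COLS, names(rows))
  stop_if(length(miss) > 0, "scoring file missing column(s): %s",
          paste(miss, collapse = ", "))
  if (!"other_allele" %in% names(rows)) rows$other_allele <- NA_character_
  stop_if(any(!is.finite(rows$effect_weight)),
          "effect_weight must be finite for every row.")
  rows$chr_name <- as.character(rows$chr_name)
  key <- paste(rows$chr_name, rows$chr_position, rows$effect_allele,
               rows$other_allele)
  if (anyDuplicated(key) > 0) {
    rlang::warn(sprintf(
      "scoring file: %d exact duplicate row(s) dropped (first kept).",
      sum(duplicated(key))))
    rows <- rows[!duplicated(key), ]
  }
  attr(rows, "metadata") <- metadata
  class(rows) <- c("multipgs_scoring", class(rows))
  rows
}

#' Metadata of a scoring file
#' @param x A `multipgs_scoring` tibble.
#' @return Named list of `#key=value` header metadata.
#' @export
scoring_metadata <- function(x) attr(x, "metadata") %||% list()

#' Read a PGS Catalog style scoring file
#'
#' Parses the harmonized scoring-file dialect: leading `#key=value` comment
#' lines become metadata, followed by a tab-separated table with columns
#' `chr_name`, `chr_position`, `effect_allele`, `effect_weight` (required)
#' and `other_allele` (optional). Coordinates are 1-based.
#'
#' @param path File path.
#' @return A `multipgs_scoring` tibble; metadata via [scoring_metadata()].
#' @export
read_scoring_file <- function(path) {
  stop_if(!file.exists(path), "scoring file not found: %s", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  hdr <- hdr[hdr == seq_along(hdr)]          # only the leading comment block
  metadata <- list()
  for (ln in lines[hdr]) {
    kv <- sub("^#+\\s*", "", ln)
    if (grepl("=", kv, fixed = TRUE)) {
      k <- sub("=.*$", "", kv)
      v <- sub("^[^=]*=", "", kv)
      metadata[[trimws(k)]] <- trimws(v)
    }
  }
  body <- lines[setdiff(seq_along(lines), hdr)]
  stop_if(length(body) < 1, "scoring file has no table: %s", path)
  tab <- utils::read.delim(text = paste(body, collapse = "\n"),
                           colClasses = "character", check.names = FALSE)
  miss <- setdiff(SCORING_COLS, names(tab))
  stop_if(length(miss) > 0, "scoring file %s is missing required column(s): %s",
          path, paste(miss, collapse = ", "))
  w <- suppressWarnings(as.numeric(tab$effect_weight))
  bad <- which(is.na(w) | !is.finite(w))
  stop_if(length(bad) > 0,
          "unparseable effect_weight in %s at data line %d ('%s').",
          path, bad[1], tab$effect_weight[bad[1]])
  rows <- tibble::tibble(
    chr_name = as.character(tab$chr_name),
    chr_position = as.integer(tab$chr_position),
    effect_allele = toupper(tab$effect_allele),
    other_allele = if ("other_allele" %in% names(tab))
      toupper(tab$other_allele) else NA_character_,
    effect_weight = w)
  new_scoring_file(rows, metadata = metadata)
}

#' Write a scoring file in the PGS Catalog TSV dialect
#'
#' @param scoring A `multipgs_scoring` tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_scoring_file <- function(scoring, path) {
  md <- scoring_metadata(scoring)
  hdr <- purrr::imap_chr(md, ~ sprintf("#%s=%s", .y, as.character(.x)))
  cols <- c("chr_name", "chr_position", "effect_allele", "other_allele",
            "effect_weight")
  body <- tibble::as_tibble(scoring)[cols]
  con <- file(path, "w")
  on.exit(close(con))
  if (length(hdr) > 0) writeLines(unname(hdr), con)
  utils::write.table(body, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

is_ambiguous_pair <- function(a1, a2) {
  p <- paste0(a1, a2)
  p %in% c("AT", "TA", "CG", "GC")
}

#' Harmonize a scoring file against cohort variants
#'
#' Matches scoring rows to cohort variants on (chr, pos) with allele
#' verification, producing a weight vector aligned to the cohort's variant
#' order plus an audit report. Rules, applied in order:
#' \itemize{
#'   \item duplicated scoring rows at the same (chr, pos) site: first kept,
#'     rest removed (`n_duplicate_removed`);
#'   \item strand-ambiguous rows (effect/other alleles A/T or C/G):
#'     removed (`n_ambiguous_removed`), since strand cannot be resolved from
#'     alleles alone;
#'   \item cohort sites represented more than once (multiallelic): removed
#'     (`n_multiallelic_removed`);
#'   \item exact allele match: weight kept as-is (`n_matched`); swapped
#'     effect/other alleles: weight negated (`n_flipped`), because the cohort
#'     dosage counts the opposite allele;
#'   \item variants absent from the cohort, or present with irreconcilable
#'     alleles, get weight 0 and are counted in `n_absent`.
#' }
#' A scoring row without `other_allele` matches only when its effect allele
#' equals the cohort's counted allele.
#'
#' @param scoring A `multipgs_scoring` tibble.
#' @param variant_meta Cohort variant metadata (`variant_id`, `chr`, `pos`,
#'   `effect_allele`, `other_allele`), e.g. `cohort$variant_meta`.
#' @return A list with `weights` (named numeric vector over the cohort's
#'   variants, zero where unmatched) and `report` (one-row tibble with the
#'   counts above).
#' @export
harmonize <- function(scoring, variant_meta) {
  vm <- tibble::as_tibble(variant_meta)
  rows <- tibble::as_tibble(scoring)
  n_in <- nrow(rows)

  site <- paste(rows$chr_name, rows$chr_position)
  dup <- duplicated(site)
  n_duplicate <- sum(dup)
  rows <- rows[!dup, ]
  site <- site[!dup]

  amb <- !is.na(rows$other_allele) &
    is_ambiguous_pair(rows$effect_allele, rows$other_allele)
  n_ambiguous <- sum(amb)
  rows <- rows[!amb, ]
  site <- site[!amb]

  vsite <- paste(vm$chr, vm$pos)
  multi_sites <- unique(vsite[duplicated(vsite)])
  in_multi <- site %in% multi_sites
  n_multiallelic <- sum(in_multi)
  rows <- rows[!in_multi, ]
  site <- site[!in_multi]

  idx <- match(site, vsite)
  weights <- setNames(numeric(nrow(vm)), vm$variant_id)
  n_matched <- 0L; n_flipped <- 0L; n_absent <- sum(is.na(idx))
  hit <- which(!is.na(idx))
  for (k in hit) {
    j <- idx[k]
    ea <- rows$effect_allele[k]; oa <- rows$other_allele[k]
    cea <- vm$effect_allele[j]; coa <- vm$other_allele[j]
    if (ea == cea && (is.na(oa) || oa == coa)) {
      weights[j] <- weights[j] + rows$effect_weight[k]
      n_matched <- n_matched + 1L
    } else if (!is.na(oa) && ea == coa && oa == cea) {
      weights[j] <- weights[j] - rows$effect_weight[k]
      n_flipped <- n_flipped + 1L
    } else {
      n_absent <- n_absent + 1L   # alleles irreconcilable with the cohort site
    }
  }
  report <- tibble::tibble(
    n_input = n_in, n_matched = n_matched, n_flipped = n_flipped,
    n_ambiguous_removed = n_ambiguous,
    n_multiallelic_removed = n_multiallelic,
    n_duplicate_removed = n_duplicate, n_absent = n_absent)
  list(weights = weights, report = report)
}

#' Compute per-sample polygenic scores
#'
#' The score of sample i is `sum_j dosage_ij * w_j` over the cohort's
#' variants. Missing dosages are mean-imputed as `2 * maf` (so an absent
#' genotype contributes the population-average dosage).
#'
#' @param cohort A `multipgs_cohort`.
#' @param weights Numeric weight vector aligned to the cohort's variant order
#'   (as produced by [harmonize()]).
#' @return A tibble with `sample_id` and `score`.
#' @export
compute_pgs <- function(cohort, weights) {
  stop_if(length(weights) != n_variants(cohort),
          "weights length (%d) must match cohort variants (%d).",
          length(weights), n_variants(cohort))
  X <- cohort$dosage
  if (anyNA(X)) {
    fill <- matrix(rep(2 * cohort$variant_meta$maf, each = nrow(X)), nrow(X))
    X[is.na(X)] <- fill[is.na(X)]
  }
  tibble::tibble(sample_id = cohort$sample_ids,
                 score = unname(drop(X %*% weights)))
}

#' Standardize a score vector
#'
#' Centers and scales by the sample (n - 1) standard deviation, returning the
#' mean and SD for later reuse — the SD is exactly the `sigma_k` that enters
#' the multi-PGS weight collapse, so odds ratios per SD and collapsed weights
#' share one convention.
#'
#' @param scores Numeric vector (non-constant).
#' @return A list with `scores` (standardized), `mean`, and `sd`.
#' @export
#' @examples
#' standardize_scores(c(1, 2, 3))  # mean 2, sd 1, scores -1 0 1
standardize_scores <- function(scores) {
  stop_if(anyNA(scores), "scores contain NA.")
  s <- sd_strict(scores)
  m <- mean(scores)
  list(scores = (scores - m) / s, mean = m, sd = s)
}

#' Score a cohort with many scoring files at once
#'
#' Harmonizes and applies each scoring file, returning one score column per
#' PGS plus the per-file harmonization reports.
#'
#' @param cohort A `multipgs_cohort`.
#' @param scoring_files Named list of `multipgs_scoring` tibbles (names
#'   default to each file's `pgs_id` metadata).
#' @return A list with `scores` (tibble: `sample_id` + one column per PGS)
#'   and `reports` (tibble of harmonization counts, one row per PGS).
#' @export
score_cohort <- function(cohort, scoring_files) {
  if (is.null(names(scoring_files)) || any(names(scoring_files) == "")) {
    names(scoring_files) <- purrr::imap_chr(
      scoring_files,
      ~ scoring_metadata(.x)$pgs_id %||% paste0("PGS", .y))
  }
  harm <- purrr::map(scoring_files, harmonize,
                     variant_meta = cohort$variant_meta)
  scores <- purrr::map(harm, ~ compute_pgs(cohort, .x$weights)$score)
  reports <- purrr::imap(harm, ~ dplyr::mutate(.x$report, pgs_id = .y,
                                               .before = 1)) |>
    dplyr::bind_rows()
  list(scores = dplyr::bind_cols(
         tibble::tibble(sample_id = cohort$sample_ids),
         tibble::as_tibble(scores)),
       reports = reports)
}

#' Write per-sample scores as a long TSV
#'
#' Long layout `sample_id, pgs_id, score`, one row per sample per PGS.
#'
#' @param scores Wide score tibble from [score_cohort()] (`sample_id` + one
#'   column per PGS).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_scores <- function(scores, path) {
  long <- tidyr::pivot_longer(scores, -"sample_id",
                              names_to = "pgs_id", values_to = "score")
  readr::write_tsv(long, path)
  invisible(path)
}
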