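# Pipeline orchestration: one seeded end-to-end run from simulated cohorts
# to an evaluated, collapsed multi-PGS, with a reproducibility manifest.

#' Build (or read) a pipeline configuration
#'
#' A validated list with four blocks: `simulate` (architecture and cohort
#' sizes), `qc` (variant thresholds), `combine` (CV folds, penalty path) and
#' `evaluate` (bootstrap replicates, covariate names). A single master `seed`
#' propagates to every stage through [split_seed()].
#'
#' @param simulate List overriding the simulation defaults: `n_traits`,
#'   `m_variants`, `causal_fraction`, `genetic_corr` (scalar off-diagonal or
#'   matrix), `h2_liability`, `prevalence`, `maf_range`, `n_gwas`, `n_tune`,
#'   `n_eval`, `n_pcs`, `p_threshold`, `shrink`.
#' @param qc List overriding [qc_thresholds()] defaults.
#' @param combine List: `n_folds`, `nlambda`, `lambda_min_ratio`.
#' @param evaluate List: `n_boot`, `auc_ci`.
#' @param seed Master seed.
#' @param out Output directory (`NULL`: keep results in memory only).
#' @return A `multipgs_config` list.
#' @export
pipeline_config <- function(simulate = list(), qc = list(), combine = list(),
                            evaluate = list(), seed = 1L, out = NULL) {
  sim <- modifyList(list(
    n_traits = 6L, m_variants = 2000L, causal_fraction = 0.1,
    genetic_corr = 0.5, h2_liability = 0.3, prevalence = 0.1,
    maf_range = c(0.05, 0.5), n_gwas = 4000L, n_tune = 4000L,
    n_eval = 4000L, n_pcs = 10L, p_threshold = 1, shrink = 1), simulate)
  qcl <- modifyList(list(maf_min = 0.01, info_min = 0.3,
                         call_rate_min = 0.99, hwe_p_min = 1e-6), qc)
  cmb <- modifyList(list(n_folds = 10L, nlambda = 100L,
                         lambda_min_ratio = 1e-4), combine)
  evl <- modifyList(list(n_boot = 1000L, auc_ci = "delong"), evaluate)
  structure(list(simulate = sim, qc = qcl, combine = cmb, evaluate = evl,
                 seed = as.integer(seed), out = out),
            class = "multipgs_config")
}

#' @rdname pipeline_config
#' @param path YAML file with the same blocks (`simulate:`, `qc:`,
#'   `combine:`, `evaluate:`, `seed:`, `out:`).
#' @export
read_pipeline_config <- function(path) {
  stop_if(!file.exists(path), "config file not found: %s", path)
  y <- yaml::read_yaml(path)
  pipeline_config(simulate = y$simulate %||% list(), qc = y$qc %||% list(),
                  combine = y$combine %||% list(),
                  evaluate = y$evaluate %||% list(),
                  seed = y$seed %||% 1L, out = y$out)
}

#' Run the full multi-PGS pipeline on synthetic data
#'
#' Executes simulate -> summary statistics (+ QC) -> weight files -> scoring
#' -> lasso combination -> weight collapse -> collapse verification ->
#' evaluation, entirely from the configuration and master seed. Three
#' disjoint cohorts share one genetic architecture: a GWAS cohort per trait
#' (summary statistics), a tuning cohort (lasso), and an evaluation cohort
#' (held-out metrics). Trait 1 plays the role of the target disease; the
#' remaining traits are the auxiliary GWAS. Evaluation compares three nested
#' models on the held-out cohort: base covariates only, base + the
#' single-trait PGS, and base + the collapsed multi-PGS.
#'
#' @param config A `multipgs_config` from [pipeline_config()] /
#'   [read_pipeline_config()].
#' @param write Write stage outputs and the manifest under `config$out`?
#'   Defaults to `TRUE` when `config$out` is set.
#' @return A list with `spec`, `sumstats` (per trait, post-QC),
#'   `scoring_files`, `fit` (`multipgs_lasso`), `combined`
#'   (`multipgs_scoring`), `collapse_discrepancy`, `reports` (named list of
#'   `multipgs_eval`: base, single_pgs, multi_pgs), `manifest` (tibble of
#'   written artifacts; empty when `write = FALSE`).
#' @export
run_pipeline <- function(config, write = !is.null(config$out)) {
  stopifnot(inherits(config, "multipgs_config"))
  sm <- config$simulate
  stop_if(write && is.null(config$out), "`config$out` must be set to write outputs.")
  if (write) dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  t0 <- Sys.time()
  inform_stage <- function(s) rlang::inform(sprintf("[multipgs] %s", s))

  inform_stage("simulate: architecture and cohorts")
  spec <- arch_spec(n_traits = sm$n_traits, m_variants = sm$m_variants,
                    causal_fraction = sm$causal_fraction,
                    genetic_corr = sm$genetic_corr,
                    h2_liability = sm$h2_liability, prevalence = sm$prevalence,
                    maf_range = sm$maf_range, seed = split_seed(seed, 1L))
  vm <- variant_grid(spec)
  effects <- simulate_effects(spec, maf = vm$maf)
  tune <- simulate_cohort(sm$n_tune, spec, effects = effects,
                          seed = split_seed(seed, 2L), n_pcs = sm$n_pcs)
  eval_ <- simulate_cohort(sm$n_eval, spec, effects = effects,
                           seed = split_seed(seed, 3L), n_pcs = sm$n_pcs)

  inform_stage("sumstats: per-trait GWAS + QC")
  thresholds <- qc_thresholds(maf_min = config$qc$maf_min,
                              info_min = config$qc$info_min,
                              call_rate_min = config$qc$call_rate_min,
                              hwe_p_min = config$qc$hwe_p_min)
  sumstats <- purrr::map(seq_len(sm$n_traits), function(t_) {
    gw <- simulate_cohort(sm$n_gwas, spec, effects = effects,
                          seed = split_seed(seed, 100L + t_), n_pcs = 0L)
    ss <- simulate_sumstats(gw, trait_index = t_)
    qc_filter(ss, thresholds)
  })
  names(sumstats) <- paste0("trait", seq_len(sm$n_traits))

  inform_stage("scoring: weight files and per-sample PGS")
  scoring_files <- purrr::imap(sumstats, function(ss, nm) {
    make_weight_file(ss, p_threshold = sm$p_threshold, shrink = sm$shrink,
                     pgs_id = paste0("PGS_", nm), trait = nm)
  })
  sc_tune <- score_cohort(tune, scoring_files)
  sc_eval <- score_cohort(eval_, scoring_files)
  pgs_tune <- as.matrix(sc_tune$scores[-1])
  pgs_eval <- as.matrix(sc_eval$scores[-1])

  inform_stage("combine: lasso combination and weight collapse")
  y_tune <- tune$phenotypes$trait1
  fit <- fit_lasso_logistic(y_tune, pgs_tune, tune$covariates,
                            n_folds = config$combine$n_folds,
                            seed = split_seed(seed, 4L),
                            nlambda = config$combine$nlambda,
                            lambda_min_ratio = config$combine$lambda_min_ratio)
  combined <- collapse_fit(fit, scoring_files)
  discrepancy <- verify_collapse(tune, scoring_files, fit$coefficients,
                                 fit$pgs_sds, combined)
  stop_if(discrepancy > 1e-6,
          "collapse verification failed: max discrepancy %.3g.", discrepancy)

  inform_stage("evaluate: held-out cohort")
  y_eval <- eval_$phenotypes$trait1
  multi_scores <- compute_pgs(eval_, harmonize(combined, eval_$variant_meta)$weights)$score
  single_scores <- pgs_eval[, "trait1"]
  n_boot <- config$evaluate$n_boot
  reports <- list(
    base = evaluate_model(y_eval, NULL, eval_$covariates, label = "base",
                          n_boot = n_boot, seed = split_seed(seed, 5L),
                          auc_ci = config$evaluate$auc_ci),
    single_pgs = evaluate_model(y_eval, single_scores, eval_$covariates,
                                label = "single_pgs", n_boot = n_boot,
                                seed = split_seed(seed, 6L),
                                auc_ci = config$evaluate$auc_ci),
    multi_pgs = evaluate_model(y_eval, multi_scores, eval_$covariates,
                               label = "multi_pgs", n_boot = n_boot,
                               seed = split_seed(seed, 7L),
                               auc_ci = config$evaluate$auc_ci))

  manifest <- tibble::tibble(stage = character(), file = character(),
                             md5 = character())
  if (write) {
    outdir <- config$out
    for (nm in names(sumstats)) {
      f <- file.path(outdir, sprintf("sumstats_%s.tsv", nm))
      write_sumstats(sumstats[[nm]], f)
      manifest <- dplyr::add_row(manifest, stage = "sumstats", file = f, md5 = "")
    }
    for (nm in names(scoring_files)) {
      f <- file.path(outdir, sprintf("weights_%s.tsv", nm))
      write_scoring_file(scoring_files[[nm]], f)
      manifest <- dplyr::add_row(manifest, stage = "scoring", file = f, md5 = "")
    }
    f <- file.path(outdir, "scores_tune.tsv"); write_scores(sc_tune$scores, f)
    manifest <- dplyr::add_row(manifest, stage = "scoring", file = f, md5 = "")
    f <- file.path(outdir, "lasso_fit.json"); write_lasso_fit(fit, f)
    manifest <- dplyr::add_row(manifest, stage = "combine", file = f, md5 = "")
    f <- file.path(outdir, "multipgs_weights.tsv"); write_scoring_file(combined, f)
    manifest <- dplyr::add_row(manifest, stage = "combine", file = f, md5 = "")
    f <- file.path(outdir, "eval_report.json"); write_eval_report(reports, f)
    manifest <- dplyr::add_row(manifest, stage = "evaluate", file = f, md5 = "")
    f <- file.path(outdir, "deciles_multi_pgs.tsv")
    readr::write_tsv(reports$multi_pgs$decile_prevalence, f)
    manifest <- dplyr::add_row(manifest, stage = "evaluate", file = f, md5 = "")
    manifest$md5 <- unname(tools::md5sum(manifest$file))
    mf <- list(seed = seed, created = format(t0, "%Y-%m-%dT%H:%M:%S"),
               r_version = as.character(getRversion()),
               package_version = as.character(utils::packageVersion("multipgs")),
               config = unclass(config),
               collapse_discrepancy = discrepancy,
               artifacts = as.list(setNames(manifest$md5, manifest$file)))
    jsonlite::write_json(mf, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(spec = spec, sumstats = sumstats, scoring_files = scoring_files,
       fit = fit, combined = combined, collapse_discrepancy = discrepancy,
       reports = reports, manifest = manifest)
}
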