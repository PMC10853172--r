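# End-to-end replicate used by the pleiotropy property and its acceptance
# check: one full pass from simulated GWAS cohorts to held-out AUCs.
#
# Study conditions (fixed): 10 traits (trait 1 = target disease; traits 2-4
# genetically correlated with it at `rg`; traits 5-10 uncorrelated),
# m = 500 variants, causal fraction 0.1, liability h2 = 0.3, prevalence 0.1,
# GWAS cohorts of 3000, tuning and evaluation cohorts of 4000 samples each.
pleiotropy_replicate <- function(seed, rg, n_aux_corr = 3L, n_traits = 10L,
                                 m = 500L, n_gwas = 3000L,
                                 n_tune = 4000L, n_eval = 4000L) {
  S <- diag(n_traits)
  block <- seq_len(1L + n_aux_corr)
  S[block, block] <- rg
  diag(S) <- 1
  spec <- arch_spec(n_traits, m, causal_fraction = 0.1, genetic_corr = S,
                    h2_liability = 0.3, prevalence = 0.1,
                    seed = split_seed(seed, 1L))
  vm <- variant_grid(spec)
  eff <- simulate_effects(spec, maf = vm$maf)
  tune <- simulate_cohort(n_tune, spec, effects = eff,
                          seed = split_seed(seed, 2L), n_pcs = 5L)
  ev <- simulate_cohort(n_eval, spec, effects = eff,
                        seed = split_seed(seed, 3L), n_pcs = 5L)
  sfs <- lapply(seq_len(n_traits), function(t_) {
    gw <- simulate_cohort(n_gwas, spec, effects = eff,
                          seed = split_seed(seed, 100L + t_), n_pcs = 0L)
    make_weight_file(simulate_sumstats(gw, t_),
                     pgs_id = paste0("PGS_trait", t_))
  })
  names(sfs) <- paste0("trait", seq_len(n_traits))
  st <- score_cohort(tune, sfs)$scores
  se <- score_cohort(ev, sfs)$scores
  fit <- fit_lasso_logistic(tune$phenotypes$trait1, as.matrix(st[-1]),
                            tune$covariates, n_folds = 10L,
                            seed = split_seed(seed, 4L))
  comb <- collapse_fit(fit, sfs)
  multi <- compute_pgs(ev, harmonize(comb, ev$variant_meta)$weights)$score
  y <- ev$phenotypes$trait1
  # held-out base model: covariate-only fit on the tuning cohort
  fb <- fit_logistic(tune$phenotypes$trait1, as.matrix(tune$covariates))
  eta_base <- drop(cbind(1, as.matrix(ev$covariates)) %*% fb$coefficients)
  list(auc_multi = auc_mw(y, multi),
       auc_single = auc_mw(y, se$trait1),
       auc_base = auc_mw(y, eta_base),
       n_active = sum(fit$coefficients != 0),
       fit = fit, scoring_files = sfs, tune = tune, combined = comb)
}
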