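# Synthetic-data module: liability-threshold cohorts with pleiotropic
# genetic architectures, marginal GWAS summary statistics, and weight files.

#' Simulate Hardy-Weinberg genotype dosages
#'
#' Draws each variant's dosages as two independent Bernoulli allele draws at
#' its allele frequency (Hardy-Weinberg equilibrium, no LD). The dosage counts
#' copies of the effect allele.
#'
#' @param n_samples Number of samples (>= 1).
#' @param variant_meta Either a data frame of variant metadata (needs a `maf`
#'   column; ids/positions filled in if absent) or a `multipgs_arch_spec`, in
#'   which case `m_variants` MAFs are drawn uniformly from `maf_range`.
#' @param seed Integer seed.
#' @return A `multipgs_cohort` with dosage and variant metadata only.
#' @export
#' @examples
#' cohort <- simulate_genotypes(100, arch_spec(m_variants = 20), seed = 1)
simulate_genotypes <- function(n_samples, variant_meta, seed = 1L) {
  stop_if(length(n_samples) != 1L || n_samples < 1,
          "`n_samples` must be a positive count.")
  n_samples <- as.integer(n_samples)
  if (inherits(variant_meta, "multipgs_arch_spec")) {
    variant_meta <- variant_grid(variant_meta)
  } else {
    variant_meta <- tibble::as_tibble(variant_meta)
    stop_if(!"maf" %in% names(variant_meta), "variant_meta needs a `maf` column.")
    m <- nrow(variant_meta)
    if (!"variant_id" %in% names(variant_meta))
      variant_meta$variant_id <- sprintf("var%05d", seq_len(m))
    if (!"chr" %in% names(variant_meta)) variant_meta$chr <- "1"
    if (!"pos" %in% names(variant_meta)) variant_meta$pos <- 1000L * seq_len(m)
    if (!"effect_allele" %in% names(variant_meta)) variant_meta$effect_allele <- "A"
    if (!"other_allele" %in% names(variant_meta)) variant_meta$other_allele <- "G"
  }
  maf <- variant_meta$maf
  stop_if(any(maf <= 0 | maf > 0.5), "MAFs must lie in (0, 0.5].")
  withr::local_seed(split_seed(seed, 0L))
  m <- length(maf)
  # Two allele draws per sample per variant: binomial(2, maf), HWE by design.
  dosage <- matrix(rbinom(n_samples * m, size = 2L,
                          prob = rep(maf, each = n_samples)),
                   nrow = n_samples, ncol = m)
  storage.mode(dosage) <- "double"
  new_cohort(dosage, variant_meta)
}

#' Variant metadata implied by an architecture spec
#'
#' Deterministic given `spec$seed`: MAFs drawn uniformly from `maf_range`,
#' synthetic ids and 1-based positions, alleles fixed A (effect) / G (other).
#' All cohorts simulated under one spec share this grid, so their variants
#' are comparable.
#'
#' @param spec A `multipgs_arch_spec`.
#' @return A variant-metadata tibble.
#' @export
variant_grid <- function(spec) {
  stopifnot(inherits(spec, "multipgs_arch_spec"))
  withr::local_seed(split_seed(spec$seed, 7L))
  m <- spec$m_variants
  tibble::tibble(
    variant_id = sprintf("var%05d", seq_len(m)),
    chr = as.character(1L + (seq_len(m) - 1L) %/% 1000L),
    pos = 1000L * (((seq_len(m) - 1L) %% 1000L) + 1L),
    effect_allele = "A", other_allele = "G",
    maf = runif(m, spec$maf_range[1], spec$maf_range[2]))
}

#' Simulate pleiotropic per-variant effect sizes
#'
#' A `causal_fraction` subset of variants (shared across traits) receives
#' effects drawn from a zero-mean multivariate normal whose cross-trait
#' correlation is `genetic_corr`; all other variants get exact zeros. The
#' per-trait effect variance is set to `h2 / (m_causal * E[2f(1-f)])` so raw
#' genetic values have approximately the target liability-scale variance;
#' [simulate_phenotypes()] standardizes the realized genetic values, so this
#' scaling governs the realism of summary-statistic effect sizes rather than
#' the phenotype model itself.
#'
#' @param spec A `multipgs_arch_spec`.
#' @param maf Optional vector of the cohort's variant MAFs (length
#'   `m_variants`); defaults to the midpoint expectation from `maf_range`.
#' @return A `m_variants x n_traits` matrix of per-allele effects, with
#'   attribute `"causal"` giving the causal variant indices.
#' @export
simulate_effects <- function(spec, maf = NULL) {
  stopifnot(inherits(spec, "multipgs_arch_spec"))
  withr::local_seed(split_seed(spec$seed, 1L))
  m <- spec$m_variants
  t_ <- spec$n_traits
  m_causal <- max(1L, round(spec$causal_fraction * m))
  causal <- sort(sample.int(m, m_causal))
  if (is.null(maf)) maf <- rep(mean(spec$maf_range), m)
  e2pq <- mean(2 * maf * (1 - maf))
  # Correlated rows: B = Z %*% L' with L a (pivoted) Cholesky factor of the
  # correlation; eigendecomposition fallback covers singular PSD matrices.
  S <- spec$genetic_corr
  L <- tryCatch(t(chol(S)), error = function(e) {
    eg <- eigen(S, symmetric = TRUE)
    eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), t_)
  })
  Z <- matrix(rnorm(m_causal * t_), m_causal, t_)
  B <- Z %*% t(L)
  scale_t <- sqrt(spec$h2_liability / (m_causal * e2pq))
  B <- sweep(B, 2, scale_t, `*`)
  effects <- matrix(0, m, t_,
                    dimnames = list(NULL, paste0("trait", seq_len(t_))))
  effects[causal, ] <- B
  attr(effects, "causal") <- causal
  effects
}

#' Simulate liability-threshold phenotypes and covariates
#'
#' For each trait, the liability is `sqrt(h2) * scale(G) + sqrt(1 - h2) * e`
#' with `G` the cohort's genetic value (`dosage %*% effects`) standardized to
#' mean 0 and unit variance, and `e` independent standard normal noise. A
#' sample is a case when its liability exceeds `qnorm(1 - prevalence)`.
#' Covariates (age ~ N(55, 8), sex ~ Bernoulli(0.5), `n_pcs` standard-normal
#' PCs) are generated independently of the outcome, so score effects are
#' identifiable in tests.
#'
#' @param cohort A `multipgs_cohort` with dosages.
#' @param effects Effect matrix from [simulate_effects()] (variants x traits).
#' @param spec The `multipgs_arch_spec` used to generate `effects`.
#' @param n_pcs Number of principal-component covariates to simulate.
#' @return The cohort with `phenotypes` (`trait1..traitT`), `covariates`
#'   (`age`, `sex`, `PC1..PCk`), and attribute-free tibble
#'   `genetic_values` (true per-trait scaled genetic liabilities, for
#'   oracle checks) stored in the cohort list.
#' @export
simulate_phenotypes <- function(cohort, effects, spec, n_pcs = 10L) {
  stopifnot(inherits(cohort, "multipgs_cohort"),
            inherits(spec, "multipgs_arch_spec"))
  stop_if(nrow(effects) != n_variants(cohort) || ncol(effects) != spec$n_traits,
          "`effects` must be %d variants x %d traits.",
          n_variants(cohort), spec$n_traits)
  withr::local_seed(split_seed(spec$seed, 2L))
  n <- n_samples(cohort)
  G <- cohort$dosage %*% effects
  Gs <- apply(G, 2, function(g) {
    s <- stats::sd(g)
    if (!is.finite(s) || s == 0) rep(0, n) else (g - mean(g)) / s
  })
  h2 <- spec$h2_liability
  liab <- sweep(Gs, 2, sqrt(h2), `*`) +
    sweep(matrix(rnorm(n * spec$n_traits), n), 2, sqrt(1 - h2), `*`)
  thr <- qnorm(1 - spec$prevalence)
  pheno <- tibble::as_tibble(as.data.frame(
    sweep(liab, 2, thr, `>`) * 1.0))
  names(pheno) <- paste0("trait", seq_len(spec$n_traits))
  covar <- tibble::tibble(age = rnorm(n, 55, 8),
                          sex = rbinom(n, 1L, 0.5) * 1.0)
  if (n_pcs > 0) {
    pcs <- matrix(rnorm(n * n_pcs), n)
    colnames(pcs) <- paste0("PC", seq_len(n_pcs))
    covar <- dplyr::bind_cols(covar, tibble::as_tibble(pcs))
  }
  out <- new_cohort(cohort$dosage, cohort$variant_meta,
                    phenotypes = pheno, covariates = covar,
                    sample_ids = cohort$sample_ids)
  gv <- tibble::as_tibble(as.data.frame(sweep(Gs, 2, sqrt(h2), `*`)))
  names(gv) <- names(pheno)
  out$genetic_values <- gv
  out
}

#' Simulate GWAS summary statistics by marginal logistic regression
#'
#' Regresses one trait's case/control status on each variant's dosage in turn
#' (single-variant logistic regression with intercept), returning the
#' estimated log-odds ratio, its standard error and a two-sided Wald p-value
#' per variant, together with effect-allele frequency and case/control counts.
#' All variants are fit simultaneously by a vectorized Newton-Raphson, so the
#' per-variant estimates equal what `glm(y ~ x, family = binomial)` returns.
#' Monomorphic variants are flagged (`status = "monomorphic"`) with missing
#' beta/SE rather than dropped.
#'
#' @param cohort A `multipgs_cohort` with phenotypes.
#' @param trait_index Which phenotype column to use (default 1).
#' @param max_iter Newton iteration cap (near-separated variants stop here and
#'   are flagged `"not_converged"`).
#' @return A summary-statistics tibble (class `multipgs_sumstats`) with
#'   columns `variant_id, chr, pos, effect_allele, other_allele, eaf, beta,
#'   se, p, n_cases, n_controls, status`.
#' @export
simulate_sumstats <- function(cohort, trait_index = 1L, max_iter = 25L) {
  stopifnot(inherits(cohort, "multipgs_cohort"))
  stop_if(is.null(cohort$phenotypes), "cohort has no phenotypes; run simulate_phenotypes() first.")
  stop_if(trait_index < 1L || trait_index > ncol(cohort$phenotypes),
          "`trait_index` out of range.")
  y <- cohort$phenotypes[[trait_index]]
  X <- cohort$dosage
  n <- length(y)
  m <- ncol(X)
  ncase <- sum(y)
  nctrl <- n - ncase
  stop_if(ncase == 0 || nctrl == 0, "trait %d has a single outcome class.", trait_index)

  xbar <- colMeans(X)
  xvar <- colMeans(X^2) - xbar^2
  poly <- xvar > 0
  # Per-variant 2-parameter Newton, vectorized across variants: each column j
  # has its own (a_j, b_j); score and Hessian entries are column sums. Each
  # iteration operates only on the columns still unconverged, so the work
  # shrinks as estimates settle.
  a <- rep(qlogis(ncase / n), m)
  b <- numeric(m)
  converged <- rep(FALSE, m)
  active <- which(poly)
  for (it in seq_len(max_iter)) {
    if (length(active) == 0) break
    Xa <- X[, active, drop = FALSE]
    eta <- Xa * rep(b[active], each = n) + rep(a[active], each = n)
    p <- 1 / (1 + exp(-eta))
    w <- p * (1 - p)
    r <- y - p                      # y recycles down columns
    s0 <- colSums(r)
    s1 <- colSums(Xa * r)
    h00 <- colSums(w)
    Xw <- Xa * w
    h01 <- colSums(Xw)
    h11 <- colSums(Xa * Xw)
    det <- h00 * h11 - h01^2
    ok <- det > 1e-12
    da <- ifelse(ok, (h11 * s0 - h01 * s1) / det, 0)
    db <- ifelse(ok, (h00 * s1 - h01 * s0) / det, 0)
    # Damp huge steps (near-separation) to keep the iteration stable.
    step <- pmax(abs(da), abs(db))
    damp <- ifelse(step > 5, 5 / step, 1)
    a[active] <- a[active] + da * damp
    b[active] <- b[active] + db * damp
    done <- step < 1e-10
    converged[active[done]] <- TRUE
    active <- active[!done & ok]
  }
  eta <- X * rep(b, each = n) + rep(a, each = n)
  p <- 1 / (1 + exp(-eta)); w <- p * (1 - p)
  Xw <- X * w
  h00 <- colSums(w); h01 <- colSums(Xw); h11 <- colSums(X * Xw)
  det <- h00 * h11 - h01^2
  se <- sqrt(ifelse(det > 1e-12, h00 / det, NA_real_))
  beta <- b
  z <- beta / se
  pval <- 2 * pnorm(-abs(z))
  status <- dplyr::case_when(!poly ~ "monomorphic",
                             !converged ~ "not_converged",
                             TRUE ~ "ok")
  beta[!poly] <- NA_real_; se[!poly] <- NA_real_; pval[!poly] <- NA_real_

  vm <- cohort$variant_meta
  # QC columns: simulated dosages are fully observed hard calls, so info and
  # call rate are exactly 1; HWE is tested on the realized genotype counts.
  hwe_p <- hwe_test(colSums(X == 0), colSums(X == 1), colSums(X == 2))
  out <- tibble::tibble(
    variant_id = vm$variant_id, chr = vm$chr, pos = vm$pos,
    effect_allele = vm$effect_allele, other_allele = vm$other_allele,
    eaf = unname(xbar) / 2, beta = unname(beta), se = unname(se),
    p = unname(pval),
    n_cases = ncase, n_controls = nctrl,
    info = 1, call_rate = 1, hwe_p = unname(hwe_p), status = status)
  new_sumstats(out, trait = names(cohort$phenotypes)[trait_index],
               source = "multipgs simulation")
}

#' Build a scoring file from summary statistics by threshold-and-shrink
#'
#' A deliberately simple weight rule: variants with `p <= p_threshold` get
#' weight `beta * shrink`, all others are excluded. With `p_threshold = 1`
#' and `shrink = 1` the weights are the marginal log-odds ratios. This is the
#' package's plumbing rule for turning GWAS output into a scoring file; it is
#' not a linkage-disequilibrium-aware shrinkage method.
#'
#' @param sumstats A summary-statistics tibble (complete rows are used).
#' @param p_threshold Retain variants with `p <= p_threshold`.
#' @param shrink Multiplicative shrinkage factor applied to betas.
#' @param pgs_id,trait Metadata recorded in the scoring file.
#' @return A scoring-file tibble (class `multipgs_scoring`) with columns
#'   `chr_name, chr_position, effect_allele, other_allele, effect_weight`.
#' @export
make_weight_file <- function(sumstats, p_threshold = 1, shrink = 1,
                             pgs_id = "PGSsim", trait = NULL) {
  stop_if(p_threshold < 0 || p_threshold > 1, "`p_threshold` must be in [0, 1].")
  ok <- !is.na(sumstats$beta) & !is.na(sumstats$p)
  keep <- ok & sumstats$p <= p_threshold
  stop_if(!any(keep), "no variants pass p <= %g; scoring file would be empty.",
          p_threshold)
  s <- sumstats[keep, ]
  new_scoring_file(
    tibble::tibble(chr_name = s$chr, chr_position = s$pos,
                   effect_allele = s$effect_allele,
                   other_allele = s$other_allele,
                   effect_weight = s$beta * shrink),
    metadata = list(pgs_id = pgs_id,
                    trait = trait %||% attr(sumstats, "trait") %||% "NA",
                    method = sprintf("threshold_shrink(p<=%g, shrink=%g)",
                                     p_threshold, shrink)))
}

#' Simulate a complete multi-trait study in one call
#'
#' Convenience wrapper: draws genotypes, effects, phenotypes and covariates
#' for one cohort under an architecture spec.
#'
#' @param n_samples Cohort size.
#' @param spec A `multipgs_arch_spec`.
#' @param effects Optional precomputed effect matrix (so several cohorts can
#'   share one architecture); defaults to `simulate_effects(spec)`.
#' @param seed Seed for the genotype/phenotype draws (defaults to
#'   `spec$seed`); pass distinct seeds to get distinct cohorts with the same
#'   architecture.
#' @param n_pcs Number of simulated PC covariates.
#' @return A `multipgs_cohort` with phenotypes and covariates.
#' @export
simulate_cohort <- function(n_samples, spec, effects = NULL, seed = NULL,
                            n_pcs = 10L) {
  seed <- seed %||% spec$seed
  vm <- variant_grid(spec)   # shared across cohorts under this spec
  if (is.null(effects)) effects <- simulate_effects(spec, maf = vm$maf)
  spec2 <- spec
  spec2$seed <- as.integer(seed)
  cohort <- simulate_genotypes(n_samples, vm, seed = split_seed(seed, 10L))
  simulate_phenotypes(cohort, effects, spec2, n_pcs = n_pcs)
}
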