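# Shared fixture builders. Everything is generated in code at test time.

# Tiny deterministic cohort with hand-set dosages and alleles.
toy_cohort <- function() {
  dosage <- matrix(c(0, 1, 2, 1,
                     2, 0, 1, 1,
                     1, 1, 0, 2,
                     0, 2, 1, 0,
                     1, 0, 2, 1), nrow = 5, byrow = TRUE)
  vm <- tibble::tibble(
    variant_id = paste0("v", 1:4),
    chr = c("1", "1", "2", "2"),
    pos = c(100L, 200L, 100L, 300L),
    effect_allele = c("A", "C", "G", "T"),
    other_allele = c("G", "T", "A", "C"),
    maf = c(0.3, 0.4, 0.2, 0.45))
  new_cohort(dosage, vm, sample_ids = paste0("S", 1:5))
}

# A scoring tibble matching toy_cohort exactly (no flips, no removals).
toy_scoring <- function(weights = c(0.5, -0.2, 0.1, 0.3)) {
  new_scoring_file(tibble::tibble(
    chr_name = c("1", "1", "2", "2"),
    chr_position = c(100L, 200L, 100L, 300L),
    effect_allele = c("A", "C", "G", "T"),
    other_allele = c("G", "T", "A", "C"),
    effect_weight = weights),
    metadata = list(pgs_id = "TOY", trait = "toy"))
}

# Write a scoring file to a temp path and return the path.
write_temp_scoring <- function(scoring, lines_extra = NULL) {
  path <- tempfile(fileext = ".txt")
  write_scoring_file(scoring, path)
  if (!is.null(lines_extra)) {
    writeLines(c(lines_extra, readLines(path)), path)
  }
  path
}

# Minimal one-variant sumstats row, for meta-analysis fixtures.
sumstats_row <- function(variant_id = "v1", beta = 0.1, se = 0.1, eaf = 0.3,
                         effect_allele = "A", other_allele = "G",
                         n_cases = 100, n_controls = 100, chr = "1",
                         pos = 1L) {
  tibble::tibble(variant_id = variant_id, chr = chr, pos = pos,
                 effect_allele = effect_allele, other_allele = other_allele,
                 eaf = eaf, beta = beta, se = se,
                 p = 2 * stats::pnorm(-abs(beta / se)),
                 n_cases = n_cases, n_controls = n_controls)
}

# Many-variant sumstats table with given betas (shared se), for GC tests.
new_sumstats_for_test <- function(beta, se = 1) {
  n <- length(beta)
  tibble::tibble(variant_id = paste0("v", seq_len(n)), chr = "1",
                 pos = seq_len(n), effect_allele = "A", other_allele = "G",
                 eaf = 0.3, beta = beta, se = se,
                 p = 2 * stats::pnorm(-abs(beta / se)),
                 n_cases = 100, n_controls = 100)
}

# Small labelled case-control data with informative and null scores.
sim_scores_data <- function(n = 600, seed = 42, beta_signal = 0.8) {
  withr::local_seed(seed)
  signal <- rnorm(n)
  noise <- rnorm(n)
  y <- rbinom(n, 1, plogis(-2 + beta_signal * signal))
  covar <- cbind(age = rnorm(n, 55, 8), sex = rbinom(n, 1, 0.5))
  list(y = y, signal = signal, noise = noise, covariates = covar)
}
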