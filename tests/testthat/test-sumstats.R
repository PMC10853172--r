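# Summary-statistics preparation: effective sample sizes, genomic control,
# IVW meta-analysis, HWE test, QC filtering.

test_that("total effective sample size follows 4p(1-p)N", {
  expect_equal(total_effective_n(500, 500), 1000)
  expect_equal(total_effective_n(100, 300), 300)   # 4 * 0.25 * 0.75 * 400
  expect_error(total_effective_n(0, 100), ">= 1")
  expect_error(total_effective_n(100, 0), ">= 1")
})

test_that("per-variant effective sample size clamps at 0.5x and 1.1x", {
  # raw = 4 / (2 * 0.25 * 0.01) = 800, inside the bounds
  expect_equal(per_snp_effective_n(0.5, 0.1, 1000), 800)
  # upper clamp: raw 800 vs 1.1 * 500 = 550
  expect_equal(per_snp_effective_n(0.5, 0.1, 500), 550)
  # lower clamp: raw 8 vs 0.5 * 1000 = 500
  expect_equal(per_snp_effective_n(0.5, 1.0, 1000), 500)
  expect_error(per_snp_effective_n(0, 0.1, 100), "eaf")
  expect_error(per_snp_effective_n(0.5, 0, 100), "se")
})

test_that("per-variant effective N recovers the study total on simulated case-control data", {
  # With a marginal logistic SE, 4/(2f(1-f)SE^2) ~ 4 p (1-p) n: check at the
  # true simulation parameters within 15%.
  spec <- arch_spec(n_traits = 1, m_variants = 60, causal_fraction = 1,
                    h2_liability = 1e-12, prevalence = 0.3,
                    maf_range = c(0.45, 0.5), seed = 31)
  co <- simulate_cohort(4000, spec, n_pcs = 0)
  ss <- simulate_sumstats(co, 1)
  tot <- total_effective_n(ss$n_cases[1], ss$n_controls[1])
  eff <- per_snp_effective_n(ss$eaf, ss$se, tot)
  expect_lt(median(abs(eff - tot)) / tot, 0.15)
})

test_that("genomic-control lambda is the median chi-square over 0.4549364", {
  base <- sumstats_row()
  t_zero <- dplyr::bind_rows(lapply(1:5, function(i)
    sumstats_row(variant_id = paste0("v", i), beta = 0)))
  expect_equal(genomic_control_lambda(t_zero), 0)
  # z^2 exactly at the chi-square(1) median -> lambda 1
  t_one <- dplyr::mutate(t_zero, beta = sqrt(0.4549364) * se)
  expect_equal(genomic_control_lambda(t_one), 1, tolerance = 1e-7)
  # Monte-Carlo: 10000 null z-scores
  withr::local_seed(99)
  t_mc <- tibble::tibble(beta = rnorm(10000), se = 1)
  expect_gt(genomic_control_lambda(t_mc), 0.95)
  expect_lt(genomic_control_lambda(t_mc), 1.05)
  expect_error(genomic_control_lambda(tibble::tibble(beta = numeric(), se = numeric())),
               "no complete rows")
})

test_that("genomic control inflates SEs only when lambda > 1", {
  withr::local_seed(100)
  infl <- new_sumstats_for_test(beta = 2 * rnorm(500), se = 1)
  out <- apply_genomic_control(infl)
  lam <- attr(out, "lambda_gc")
  expect_gt(lam, 1)
  expect_equal(out$se, infl$se * sqrt(lam))
  defl <- new_sumstats_for_test(beta = 0.1 * rnorm(500), se = 1)
  out2 <- apply_genomic_control(defl)
  expect_lt(attr(out2, "lambda_gc"), 1)
  expect_equal(out2$se, defl$se)
})

test_that("inverse-variance meta-analysis matches hand-computed weights", {
  t1 <- sumstats_row(beta = 0.1, se = 0.1)
  t2 <- sumstats_row(beta = 0.3, se = 0.2)
  m <- ivw_meta(list(t1, t2))
  # weights 100 and 25: beta = (10 + 7.5)/125 = 0.14, se = sqrt(1/125)
  expect_equal(m$beta, 0.14)
  expect_equal(m$se, sqrt(1 / 125))
  expect_equal(m$n_cases, 200)
  # two identical studies: same beta, se / sqrt(2)
  t3 <- sumstats_row(beta = 0.2, se = 0.1)
  m2 <- ivw_meta(list(t3, t3))
  expect_equal(m2$beta, 0.2)
  expect_equal(m2$se, 0.1 / sqrt(2))
  # single study: identity
  m1 <- ivw_meta(list(t1))
  expect_equal(m1$beta, t1$beta)
  expect_equal(m1$se, t1$se)
  expect_equal(m1$n_studies, 1)
})

test_that("meta-analysis aligns swapped alleles and drops irreconcilable ones", {
  t1 <- sumstats_row(beta = 0.2, se = 0.1, effect_allele = "A", other_allele = "G",
                     eaf = 0.3)
  t2 <- sumstats_row(beta = -0.2, se = 0.1, effect_allele = "G", other_allele = "A",
                     eaf = 0.7)
  m <- ivw_meta(list(t1, t2))
  # after the sign flip the studies agree exactly
  expect_equal(m$beta, 0.2)
  expect_equal(m$eaf, 0.3)
  bad <- sumstats_row(beta = 0.2, se = 0.1, effect_allele = "C", other_allele = "T")
  expect_message(m2 <- ivw_meta(list(t1, bad)), "irreconcilable")
  expect_equal(nrow(m2), 0)
  expect_equal(attr(m2, "n_allele_mismatch"), 1)
})

test_that("meta-analysis is commutative and never inflates the combined SE", {
  withr::local_seed(12)
  mk <- function(k) dplyr::bind_rows(lapply(1:20, function(i)
    sumstats_row(variant_id = paste0("v", i), pos = i,
                 beta = rnorm(1, 0, 0.1), se = runif(1, 0.05, 0.3))))
  tabs <- lapply(1:3, mk)
  m123 <- ivw_meta(tabs)
  m321 <- ivw_meta(rev(tabs))
  expect_equal(m123$beta, m321$beta[match(m123$variant_id, m321$variant_id)])
  # adding a study can only decrease the SE at shared variants
  m12 <- ivw_meta(tabs[1:2])
  expect_true(all(m123$se <= m12$se[match(m123$variant_id, m12$variant_id)] + 1e-12))
})

test_that("HWE chi-square matches hand computation and handles edge cases", {
  expect_equal(hwe_test(25, 50, 25), 1)
  # complete heterozygote deficit at f = 0.5: chi-square = n = 100
  expect_equal(hwe_test(50, 0, 50), pchisq(100, 1, lower.tail = FALSE))
  expect_lt(hwe_test(50, 0, 50), 1e-6)
  expect_equal(hwe_test(100, 0, 0), 1)    # monomorphic: defined as pass
  expect_error(hwe_test(-1, 5, 5), "non-negative")
})

test_that("HWE chi-square p agrees with an exact multinomial enumeration", {
  # Exact oracle: enumerate all genotype configurations with the same total
  # and allele count; p = sum of probabilities of configurations with
  # chi-square >= observed, under multinomial HWE at the MLE frequency.
  exact_hwe <- function(rr, het, aa) {
    n <- rr + het + aa
    f <- (2 * aa + het) / (2 * n)
    probs <- c((1 - f)^2, 2 * f * (1 - f), f^2)
    chi_of <- function(v) {
      e <- n * probs
      sum((v - e)^2 / pmax(e, .Machine$double.eps))
    }
    obs <- chi_of(c(rr, het, aa))
    tot <- 0
    for (a in 0:n) for (h in 0:(n - a)) {
      v <- c(n - a - h, h, a)
      if (chi_of(v) >= obs - 1e-9)
        tot <- tot + stats::dmultinom(v, prob = probs)
    }
    tot
  }
  # moderate-deviation cases: in the extreme tail the chi-square
  # approximation is known to drift beyond 10x from the exact test
  cases <- list(c(10, 12, 8), c(20, 5, 5), c(4, 16, 10), c(12, 6, 12))
  for (cs in cases) {
    p_chi <- hwe_test(cs[1], cs[2], cs[3])
    p_exact <- exact_hwe(cs[1], cs[2], cs[3])
    # agreement within an order of magnitude
    expect_lt(abs(log10(p_chi) - log10(p_exact)), 1)
  }
})

test_that("QC filtering removes failing variants and tallies by filter", {
  tab <- tibble::tibble(
    variant_id = paste0("v", 1:5),
    maf = c(0.005, 0.02, 0.008, 0.3, 0.4),
    info = c(0.9, 0.9, 0.9, 0.2, 0.9),
    call_rate = c(1, 1, 1, 1, 0.95),
    hwe_p = c(0.5, 0.5, 0.5, 0.5, 0.5))
  out <- qc_filter(tab, qc_thresholds())
  expect_equal(out$variant_id, "v2")
  tl <- qc_tally(out)
  expect_equal(unname(tl["maf"]), 2L)
  expect_equal(unname(tl["info"]), 1L)
  expect_equal(unname(tl["call_rate"]), 1L)
  expect_equal(unname(tl["n_kept"]), 1L)
  # paper's MAF < 1% rule
  expect_false("v1" %in% out$variant_id)
  # all-zero thresholds: identity
  out2 <- qc_filter(tab, qc_thresholds(maf_min = 0, info_min = 0,
                                       call_rate_min = 0, hwe_p_min = 0))
  expect_equal(nrow(out2), 5)
  # absent columns deactivate their filters with a warning
  expect_warning(out3 <- qc_filter(tab["maf"], qc_thresholds()), "skipped")
  expect_equal(nrow(out3), 3)
})

test_that("sumstats TSV round-trips", {
  t1 <- dplyr::bind_rows(lapply(1:4, function(i)
    sumstats_row(variant_id = paste0("v", i), pos = i, beta = i / 10)))
  path <- tempfile(fileext = ".tsv")
  write_sumstats(t1, path)
  t2 <- read_sumstats(path)
  expect_equal(t2$beta, t1$beta)
  expect_equal(t2$variant_id, t1$variant_id)
})
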