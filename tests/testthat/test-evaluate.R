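# Evaluation battery: logistic fits, OR per SD, Nagelkerke R2, AUC,
# bootstrap, LRT, decile prevalence, FDR scan.

test_that("logistic MLE matches closed forms and a generic optimizer", {
  # intercept-only at prevalence 0.1: intercept = log(1/9)
  y <- rep(c(1, 0), c(10, 90))
  f0 <- fit_logistic(y, NULL)
  expect_equal(unname(f0$coefficients[1]), log(1 / 9), tolerance = 1e-8)
  # 2x2 table: coefficient equals the log odds ratio (30*40)/(20*10) = 6
  y2 <- rep(c(1, 0, 1, 0), c(30, 20, 10, 40))
  x2 <- rep(c(1, 1, 0, 0), c(30, 20, 10, 40))
  f2 <- fit_logistic(y2, cbind(x = x2))
  expect_equal(unname(f2$coefficients["x"]), log(6), tolerance = 1e-8)
  # 5-predictor simulated set vs optim on the log-likelihood
  withr::local_seed(5)
  n <- 400
  X <- matrix(rnorm(n * 5), n); colnames(X) <- paste0("x", 1:5)
  y3 <- rbinom(n, 1, plogis(-1 + X %*% c(0.5, -0.3, 0, 0.2, 0)))
  f3 <- fit_logistic(y3, X)
  nld <- function(b) {
    eta <- cbind(1, X) %*% b
    -sum(y3 * eta - log1p(exp(eta)))
  }
  o <- optim(rep(0, 6), nld, method = "BFGS",
             control = list(maxit = 1000, reltol = 1e-14))
  expect_equal(unname(f3$coefficients), o$par, tolerance = 1e-6)
  expect_equal(f3$loglik, -o$value, tolerance = 1e-8)
})

test_that("separation triggers the ridge-stabilized fallback with a warning", {
  y <- rep(c(0, 1), each = 20)
  x <- c(rnorm(20, -3), rnorm(20, 3))
  expect_warning(f <- fit_logistic(y, cbind(x = x)), "separation")
  expect_true(f$separation)
  expect_true(is.finite(f$coefficients["x"]))
})

test_that("OR per SD is scale-invariant and detects signal", {
  d <- sim_scores_data(n = 2000, seed = 9)
  o1 <- or_per_sd(d$y, d$signal, d$covariates)
  o2 <- or_per_sd(d$y, 2 * d$signal, d$covariates)
  expect_equal(o1$or, o2$or, tolerance = 1e-10)
  expect_gt(o1$or, 1)
  expect_gt(o1$ci_lo, 1)   # strong signal at n = 2000
})

test_that("null OR-per-SD confidence intervals cover 1 about 95% of the time", {
  covered <- vapply(1:200, function(s) {
    withr::local_seed(5000 + s)
    n <- 400
    y <- rbinom(n, 1, 0.2)
    score <- rnorm(n)
    o <- or_per_sd(y, score)
    o$ci_lo <= 1 && o$ci_hi >= 1
  }, logical(1))
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.99)
})

test_that("Nagelkerke R2 endpoints and a hand-computed value are exact", {
  expect_equal(nagelkerke_r2(-50, -50, 100), 0)
  expect_equal(nagelkerke_r2(-50, 0, 100), 1)
  # scalar formula oracle: n = 10, ll_null = -6.7301, ll_full = -5
  cs <- 1 - exp(2 * (-6.7301 + 5) / 10)
  expected <- cs / (1 - exp(2 * -6.7301 / 10))
  expect_equal(nagelkerke_r2(-6.7301, -5, 10), expected)
  expect_equal(expected, 0.3954190, tolerance = 1e-6)
  expect_error(nagelkerke_r2(-5, -6, 10), "not nested")
  # monotone in ll_full
  r <- sapply(seq(-6, -1, by = 1), function(llf) nagelkerke_r2(-6.5, llf, 20))
  expect_true(all(diff(r) > 0))
})

test_that("AUC equals the brute-force all-pairs count and handles ties", {
  y <- c(1, 0, 1, 0, 1, 0)
  s <- c(0.9, 0.3, 0.6, 0.6, 0.2, 0.1)
  brute <- function(y, s) {
    num <- 0; den <- 0
    for (i in which(y == 1)) for (j in which(y == 0)) {
      den <- den + 1
      num <- num + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
    }
    num / den
  }
  expect_equal(auc_mw(y, s), brute(y, s))
  withr::local_seed(10)
  y2 <- rbinom(40, 1, 0.4)
  s2 <- sample(1:5, 40, replace = TRUE)  # heavy ties
  expect_equal(auc_mw(y2, s2), brute(y2, s2))
  # perfect separation and all-tied conventions
  expect_equal(auc_mw(c(0, 0, 1, 1), c(1, 2, 3, 4)), 1)
  expect_equal(auc_mw(c(0, 1, 0, 1), rep(2, 4)), 0.5)
  expect_error(auc_mw(rep(1, 5), rnorm(5)), "both")
})

test_that("AUC is invariant under strictly monotone transforms", {
  withr::local_seed(11)
  y <- rbinom(300, 1, 0.3)
  s <- rnorm(300)
  a <- auc_mw(y, s)
  expect_equal(auc_mw(y, exp(s)), a)
  expect_equal(auc_mw(y, 5 * s - 2), a)
  expect_equal(auc_mw(y, pnorm(s)), a)
})

test_that("the DeLong interval brackets the Mann-Whitney point estimate", {
  d <- sim_scores_data(n = 800, seed = 12)
  ci <- auc_ci_delong(d$y, d$signal)
  expect_equal(ci$auc, auc_mw(d$y, d$signal), tolerance = 1e-10)
  expect_lt(ci$ci_lo, ci$auc)
  expect_gt(ci$ci_hi, ci$auc)
})

test_that("bootstrap CI matches the CLT on a simple mean and is seeded", {
  dat <- data.frame(x = 1:100)
  stat <- function(d) mean(d$x)
  ci <- bootstrap_ci(dat, stat, n_boot = 1000, seed = 5)
  se <- sd(1:100) / 10
  expect_lt(abs(ci$ci_lo - (50.5 - 1.96 * se)), 1.5)
  expect_lt(abs(ci$ci_hi - (50.5 + 1.96 * se)), 1.5)
  expect_identical(ci, bootstrap_ci(dat, stat, n_boot = 1000, seed = 5))
  # degenerate data: zero-width interval
  ci0 <- bootstrap_ci(data.frame(x = rep(3, 20)), stat, n_boot = 100, seed = 1)
  expect_equal(ci0$ci_lo, ci0$ci_hi)
})

test_that("bootstrap CI width scales like 1/sqrt(n)", {
  widths <- vapply(c(500, 2000, 8000), function(n) {
    withr::local_seed(n)
    dat <- data.frame(x = rnorm(n))
    ci <- bootstrap_ci(dat, function(d) mean(d$x), n_boot = 400, seed = 2)
    ci$ci_hi - ci$ci_lo
  }, numeric(1))
  expect_equal(widths[1] / widths[2], 2, tolerance = 0.35)
  expect_equal(widths[2] / widths[3], 2, tolerance = 0.35)
})

test_that("likelihood-ratio test is exact for identical models and powerful for signal", {
  d <- sim_scores_data(n = 5000, seed = 13)
  Cb <- d$covariates
  fb <- fit_logistic(d$y, Cb)
  expect_equal(lr_test(fb, fb), 1)
  ff <- fit_logistic(d$y, cbind(score = d$signal, Cb))
  expect_lt(lr_test(fb, ff), 1e-10)
  expect_error(lr_test(ff, fb), "at least as many")
})

test_that("decile prevalences partition the cohort and conserve the mean", {
  d <- sim_scores_data(n = 1003, seed = 14)
  dp <- decile_prevalence(d$y, d$signal)
  expect_equal(sum(dp$n), 1003)
  expect_lte(diff(range(dp$n)), 1)
  expect_equal(sum(dp$n_cases) / sum(dp$n), mean(d$y))
  expect_equal(sum(dp$prevalence * dp$n) / sum(dp$n), mean(d$y))
  # monotone risk: top decile enriched
  expect_gt(dp$prevalence[10], dp$prevalence[1])
  # constructed fixture: outcome = indicator(score above the 90th percentile)
  score <- 1:1000
  y_top <- as.numeric(score > 900)
  dp2 <- decile_prevalence(y_top, score)
  expect_equal(dp2$prevalence, c(rep(0, 9), 1))
})

test_that("the PGS scan applies BH step-up correctly", {
  # the five-p fixture: BH at q = 0.05 rejects exactly the two smallest
  # (0.039 * 5/3 and 0.041 * 5/4 both exceed 0.05), matching stats::p.adjust
  p <- c(0.001, 0.008, 0.039, 0.041, 0.6)
  expect_equal(sum(p.adjust(p, "BH") <= 0.05), 2)
  # hand step-up oracle
  step_up <- function(p, q) {
    s <- sort(p); m <- length(p)
    k <- max(c(0, which(s <= seq_len(m) / m * q)))
    sum(p <= if (k == 0) -1 else s[k])
  }
  expect_equal(step_up(p, 0.05), 2)
  # a fixture where exactly 4 are rejected: p4 = 0.040 = 4/5 * 0.05
  p4 <- c(0.001, 0.008, 0.030, 0.040, 0.6)
  expect_equal(step_up(p4, 0.05), 4)
  expect_equal(sum(p.adjust(p4, "BH") <= 0.05), 4)
  # all p = 1: nothing discovered
  expect_equal(step_up(rep(1, 5), 0.05), 0)

  # scan wiring: the q column equals p.adjust on the tested columns
  d <- sim_scores_data(n = 500, seed = 16)
  X <- cbind(S1 = d$signal, N1 = d$noise, N2 = rnorm(500), FLAT = rep(1, 500))
  expect_message(res <- pgs_scan(d$y, X, d$covariates), "constant")
  expect_equal(res$status[4], "skipped_constant")
  tested <- !is.na(res$p)
  expect_equal(res$q[tested], p.adjust(res$p[tested], "BH"))
  expect_true(res$discovery[1])
})

test_that("evaluate_model assembles a coherent report", {
  d <- sim_scores_data(n = 800, seed = 17)
  rep1 <- evaluate_model(d$y, d$signal, d$covariates, label = "signal",
                         n_boot = 60, seed = 3)
  expect_s3_class(rep1, "multipgs_eval")
  expect_gt(rep1$or_per_sd$or, 1)
  expect_gte(rep1$auc$auc, 0); expect_lte(rep1$auc$auc, 1)
  expect_gte(rep1$r2_nagelkerke$r2, 0); expect_lte(rep1$r2_nagelkerke$r2, 1)
  expect_equal(sum(rep1$decile_prevalence$n), 800)
  expect_lt(rep1$lrt_p_vs_base, 0.01)
  base <- evaluate_model(d$y, NULL, d$covariates, label = "base",
                         n_boot = 60, seed = 3)
  expect_true(is.na(base$or_per_sd$or))
  expect_equal(base$lrt_p_vs_base, 1)
  expect_gte(rep1$auc$auc, base$auc$auc)
  td <- tidy(rep1)
  expect_equal(nrow(td), 3)
  gl <- glance(rep1)
  expect_equal(gl$n_cases + gl$n_controls, 800)
  p <- autoplot(rep1)
  expect_s3_class(p, "ggplot")
  # JSON + text table
  path <- tempfile(fileext = ".json")
  write_eval_report(list(base, rep1), path)
  j <- jsonlite::read_json(path)
  expect_named(j, c("base", "signal"))
  expect_true(file.exists(sub("\\.json$", ".txt", path)))
})
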