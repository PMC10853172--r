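# Lasso logistic combination: optimizer correctness, CV behaviour,
# KKT conditions, path properties.

make_lasso_data <- function(n = 200, K = 3, seed = 7, beta1 = 0.8) {
  withr::local_seed(seed)
  X <- matrix(rnorm(n * K), n)
  colnames(X) <- paste0("P", seq_len(K))
  C <- cbind(age = rnorm(n, 55, 8), sex = rbinom(n, 1, 0.5))
  eta <- -2 + beta1 * (X[, 1] - mean(X[, 1])) / sd(X[, 1]) +
    0.02 * (C[, "age"] - 55)
  y <- rbinom(n, 1, plogis(eta))
  list(y = y, X = X, C = C)
}

test_that("soft-threshold coordinate update matches the closed form", {
  # one-variable weighted lasso: minimize (1/2n) sum w (z - x b)^2 + lam |b|
  withr::local_seed(3)
  n <- 80
  x <- rnorm(n); z <- 0.4 * x + rnorm(n); w <- runif(n, 0.5, 1)
  lam <- 0.1
  num <- sum(w * x * z) / n
  den <- sum(w * x^2) / n
  closed <- sign(num) * max(abs(num) - lam, 0) / den
  obj <- function(b) sum(w * (z - x * b)^2) / (2 * n) + lam * abs(b)
  opt <- optimize(obj, c(-5, 5))$minimum
  expect_equal(closed, opt, tolerance = 1e-5)
})

test_that("at lambda = 0 the fit equals the unpenalized logistic MLE", {
  d <- make_lasso_data()
  fit <- fit_lasso_logistic(d$y, d$X, d$C, lambda = 0)
  Xs <- scale(d$X)
  g <- glm(d$y ~ Xs + d$C, family = binomial,
           control = glm.control(epsilon = 1e-12, maxit = 100))
  expect_equal(unname(fit$coefficients), unname(coef(g)[2:4]), tolerance = 1e-6)
  expect_equal(unname(fit$unpenalized_coefs),
               unname(coef(g)[c(1, 5, 6)]), tolerance = 1e-6)
})

test_that("at lambda > 0 the penalized objective matches a generic convex optimizer", {
  withr::local_seed(8)
  n <- 50
  X <- matrix(rnorm(n * 2), n); colnames(X) <- c("P1", "P2")
  y <- rbinom(n, 1, plogis(0.5 * scale(X[, 1])))
  lam <- 0.05
  fit <- fit_lasso_logistic(y, X, covariates = NULL, lambda = lam)
  Xs <- scale(X)
  nllf <- function(eta) {
    lse <- ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta)))
    -mean(y * eta - lse)
  }
  # independent oracle: L-BFGS-B on the split-positive-negative formulation
  obj_split <- function(par) {
    eta <- par[1] + Xs %*% (par[2:3] - par[4:5])
    nllf(eta) + lam * sum(par[2:5])
  }
  o <- optim(rep(0, 5), obj_split, method = "L-BFGS-B",
             lower = c(-Inf, 0, 0, 0, 0),
             control = list(maxit = 5000, factr = 1e1))
  obj_mine <- nllf(fit$intercept + Xs %*% fit$coefficients) +
    lam * sum(abs(fit$coefficients))
  expect_equal(obj_mine, o$value, tolerance = 1e-6)
})

test_that("at lambda_max all PGS coefficients are zero and covariates hit their MLE", {
  d <- make_lasso_data(seed = 15)
  fit <- fit_lasso_logistic(d$y, d$X, d$C, n_folds = 5, seed = 1, nlambda = 30)
  b_at_max <- fit$beta_path[, 1]
  expect_true(all(b_at_max == 0))
  g0 <- glm(d$y ~ d$C, family = binomial,
            control = glm.control(epsilon = 1e-12, maxit = 100))
  expect_equal(unname(fit$theta_path[, 1]), unname(coef(g0)), tolerance = 1e-6)
  # just below lambda_max at least one coefficient activates along the path
  expect_gt(sum(fit$beta_path[, ncol(fit$beta_path)] != 0), 0)
})

test_that("KKT conditions hold along the path", {
  d <- make_lasso_data(n = 300, K = 5, seed = 22)
  fit <- fit_lasso_logistic(d$y, d$X, d$C, n_folds = 5, seed = 2, nlambda = 25)
  for (lam in fit$lambda[c(5, 13, 25)]) {
    k <- kkt_check(fit, d$y, d$X, d$C, lambda = lam, tol = 1e-4)
    expect_true(all(k$ok), info = sprintf("lambda = %g", lam))
  }
})

test_that("the active set grows as lambda decreases (nesting, statistically)", {
  d <- make_lasso_data(n = 400, K = 8, seed = 31, beta1 = 1)
  fit <- fit_lasso_logistic(d$y, d$X, d$C, n_folds = 5, seed = 3, nlambda = 40)
  n_active <- colSums(fit$beta_path != 0)
  # allow rare exchanges: non-decreasing up to one transient drop
  drops <- sum(diff(n_active) < 0)
  expect_lte(drops, 2)
  expect_equal(n_active[1], 0)
  expect_gte(n_active[length(n_active)], n_active[1])
})

test_that("cross-validation selects the signal and is seed-deterministic", {
  d <- make_lasso_data(n = 500, K = 6, seed = 44, beta1 = 1)
  fit <- fit_lasso_logistic(d$y, d$X, d$C, n_folds = 5, seed = 9, nlambda = 40)
  expect_true(fit$coefficients["P1"] != 0)
  cv1 <- cv_curve(d$y, d$X, d$C, lambda = fit$lambda, n_folds = 5, seed = 9)
  cv2 <- cv_curve(d$y, d$X, d$C, lambda = fit$lambda, n_folds = 5, seed = 9)
  expect_identical(cv1, cv2)
  # lambda_min is on the path and minimizes the CV deviance
  expect_true(fit$lambda_min %in% fit$lambda)
  expect_equal(min(fit$cv$mean_deviance),
               fit$cv$mean_deviance[fit$cv$lambda == fit$lambda_min])
})

test_that("pure-noise PGS yield an all-zero (or near-empty) model at lambda_min", {
  # over seeds, the null model should be competitive: majority rule
  hits <- vapply(1:10, function(s) {
    withr::local_seed(1000 + s)
    n <- 300
    X <- matrix(rnorm(n * 5), n); colnames(X) <- paste0("P", 1:5)
    y <- rbinom(n, 1, 0.15)
    fit <- fit_lasso_logistic(y, X, NULL, n_folds = 5, seed = s, nlambda = 30)
    # all-zero model within 1 CV SE of the minimum
    dev_at_max <- fit$cv$mean_deviance[1]
    best <- min(fit$cv$mean_deviance)
    se_best <- fit$cv$se_deviance[which.min(fit$cv$mean_deviance)]
    dev_at_max <= best + se_best
  }, logical(1))
  expect_gte(mean(hits), 0.7)
})

test_that("a strongly informative PGS is selected in nearly every replicate", {
  hits <- vapply(1:20, function(s) {
    d <- make_lasso_data(n = 400, K = 5, seed = 2000 + s, beta1 = 1)
    fit <- fit_lasso_logistic(d$y, d$X, d$C, n_folds = 5, seed = s, nlambda = 30)
    fit$coefficients["P1"] != 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("informative PGS are recovered at lambda.min with bounded false inclusions", {
  # 10 PGS: 3 carry independent components of the outcome liability, 7 are
  # pure noise. lambda.min reliably recovers all informative scores; it is
  # deliberately liberal (CV deviance, not selection consistency), so some
  # noise scores enter — the test bounds their average count rather than
  # demanding near-exact support recovery.
  res <- vapply(1:20, function(s) {
    withr::local_seed(3000 + s)
    n <- 1500
    g <- matrix(rnorm(n * 3), n)
    liab <- g %*% rep(1 / sqrt(3), 3) * sqrt(0.5) + rnorm(n, 0, sqrt(0.5))
    X <- cbind(g + matrix(rnorm(n * 3), n) * 0.8, matrix(rnorm(n * 7), n))
    colnames(X) <- paste0("P", 1:10)
    y <- as.numeric(liab > qnorm(0.85))
    fit <- fit_lasso_logistic(y, X, NULL, n_folds = 10, seed = s, nlambda = 40)
    act <- which(fit$coefficients != 0)
    c(all(1:3 %in% act), sum(act > 3))
  }, numeric(2))
  expect_gte(mean(res[1, ] == 1), 0.8)   # all informative PGS selected
  expect_lte(mean(res[2, ]), 5)          # noise inclusions stay bounded
})

test_that("single-class outcomes and degenerate inputs are rejected", {
  X <- matrix(rnorm(40), 20); colnames(X) <- c("A", "B")
  expect_error(fit_lasso_logistic(rep(0, 20), X), "single outcome class")
  expect_error(fit_lasso_logistic(c(rep(1, 19), 0), cbind(A = rep(2, 20))),
               "zero variance")
})

test_that("tidy, glance, predict and serialization work on a fit", {
  d <- make_lasso_data(seed = 77)
  fit <- fit_lasso_logistic(d$y, d$X, d$C, n_folds = 5, seed = 4, nlambda = 20)
  td <- tidy(fit)
  expect_named(td, c("pgs_id", "estimate", "pgs_sd", "collapse_factor", "active"))
  expect_equal(td$collapse_factor, td$estimate / td$pgs_sd)
  gl <- glance(fit)
  expect_equal(gl$n, 200)
  pr <- predict(fit, d$X, d$C, type = "response")
  expect_true(all(pr > 0 & pr < 1))
  path <- tempfile(fileext = ".json")
  write_lasso_fit(fit, path)
  fit2 <- read_lasso_fit(path)
  expect_equal(fit2$coefficients, fit$coefficients)
  expect_equal(fit2$lambda_min, fit$lambda_min)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
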