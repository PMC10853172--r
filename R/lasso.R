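# Penalized combination module: lasso logistic regression of a binary
# outcome on many PGS, with unpenalized covariates, solved by IRLS with
# cyclic coordinate descent and soft-thresholding.

soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

# -(1/n) sum(y*eta - log(1+e^eta)), computed stably
nll <- function(y, eta) {
  lse <- ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta)))
  -mean(y * eta - lse)
}

penalized_objective <- function(y, eta, beta_pen, lambda) {
  nll(y, eta) + lambda * sum(abs(beta_pen))
}

# Core path solver. y: 0/1; Xs: standardized penalized matrix; C: unpenalized
# design (includes intercept column); lambda: decreasing path.
# Returns beta (K x L), theta (q x L), convergence flags.
lasso_path_engine <- function(y, Xs, C, lambda, tol = 1e-7,
                              maxit_irls = 100L, maxit_cd = 250L,
                              w_floor = 1e-5) {
  n <- length(y)
  K <- ncol(Xs)
  q <- ncol(C)
  L <- length(lambda)
  beta_out <- matrix(0, K, L)
  theta_out <- matrix(0, q, L)
  conv <- logical(L)

  # warm start: covariate-only MLE
  fit0 <- glm.fit(C, y, family = binomial())
  theta <- coef_or_zero(fit0, q)
  beta <- numeric(K)

  for (l in seq_len(L)) {
    lam <- lambda[l]
    eta <- drop(C %*% theta) + if (K > 0) drop(Xs %*% beta) else 0
    obj <- penalized_objective(y, eta, beta, lam)
    for (it in seq_len(maxit_irls)) {
      p <- 1 / (1 + exp(-eta))
      w <- pmax(p * (1 - p), w_floor)
      z <- eta + (y - p) / w
      theta_old <- theta; beta_old <- beta
      # Inner penalized weighted least squares, solved with covariance
      # updating: all sufficient statistics are (K+q)-sized Gram blocks, so
      # each coordinate update is O(K) rather than O(n).
      wC <- C * w
      D <- crossprod(C, wC) / n                 # q x q
      v <- drop(crossprod(wC, z)) / n           # q
      if (K > 0) {
        wXs <- Xs * w
        A <- crossprod(Xs, wXs) / n             # K x K
        B <- crossprod(wXs, C) / n              # K x q
        u <- drop(crossprod(wXs, z)) / n        # K
        Ab <- drop(A %*% beta)
        theta <- drop(solve(D, v - crossprod(B, beta)))
        Bth <- drop(B %*% theta)
        diagA <- diag(A)
        for (sweep_i in seq_len(maxit_cd)) {
          max_d <- 0
          for (k in seq_len(K)) {
            bk <- beta[k]
            num <- u[k] - Bth[k] - Ab[k] + diagA[k] * bk
            bnew <- if (num > lam) (num - lam) / diagA[k]
                    else if (num < -lam) (num + lam) / diagA[k]
                    else 0
            if (bnew != bk) {
              Ab <- Ab + A[, k] * (bnew - bk)
              beta[k] <- bnew
              d <- abs(bnew - bk)
              if (d > max_d) max_d <- d
            }
          }
          # refresh the unpenalized block within the same quadratic problem
          theta_new <- drop(solve(D, v - crossprod(B, beta)))
          d <- max(abs(theta_new - theta))
          if (d > max_d) max_d <- d
          theta <- theta_new
          Bth <- drop(B %*% theta)
          if (max_d < tol) break
        }
      } else {
        theta <- drop(solve(D, v))
      }
      eta_new <- drop(C %*% theta) + if (K > 0) drop(Xs %*% beta) else 0
      obj_new <- penalized_objective(y, eta_new, beta, lam)
      # Step-halving: the quadratic approximation can overshoot; keep the
      # penalized deviance non-increasing across outer iterations.
      halvings <- 0L
      while (obj_new > obj + 1e-12 && halvings < 10L) {
        theta <- (theta + theta_old) / 2
        beta <- (beta + beta_old) / 2
        eta_new <- drop(C %*% theta) + if (K > 0) drop(Xs %*% beta) else 0
        obj_new <- penalized_objective(y, eta_new, beta, lam)
        halvings <- halvings + 1L
      }
      delta <- max(abs(c(theta - theta_old, beta - beta_old)))
      eta <- eta_new
      obj <- obj_new
      if (delta < tol) { conv[l] <- TRUE; break }
    }
    if (!conv[l])
      rlang::warn(sprintf(
        "lasso: IRLS iteration cap reached at lambda = %.3g (possible separation); coefficients capped.",
        lam))
    beta_out[, l] <- beta
    theta_out[, l] <- theta
  }
  list(beta = beta_out, theta = theta_out, converged = conv)
}

coef_or_zero <- function(fit, q) {
  th <- coef(fit)
  th[is.na(th)] <- 0
  if (length(th) < q) th <- c(th, numeric(q - length(th)))
  th
}

build_designs <- function(y, pgs, covariates) {
  stop_if(!is_binary01(y), "`y` must be a 0/1 vector without NA.")
  stop_if(sum(y) == 0 || sum(y) == length(y), "`y` has a single outcome class.")
  X <- as_matrix_named(pgs, "PGS")
  stop_if(nrow(X) != length(y), "`pgs` rows must match length(y).")
  stop_if(anyNA(X), "`pgs` contains missing values.")
  C <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    Cm <- as_matrix_named(covariates, "covar")
    stop_if(anyNA(Cm), "`covariates` contains missing values.")
    stop_if(nrow(Cm) != length(y), "`covariates` rows must match length(y).")
    C <- cbind(C, Cm)
  }
  mu <- colMeans(X)
  sds <- apply(X, 2, sd)
  stop_if(any(sds == 0), "PGS column(s) with zero variance: %s",
          paste(colnames(X)[sds == 0], collapse = ", "))
  Xs <- sweep(sweep(X, 2, mu, `-`), 2, sds, `/`)
  list(Xs = Xs, C = C, mu = mu, sds = sds, pgs_ids = colnames(X))
}

lambda_path_from <- function(y, Xs, C, nlambda, lambda_min_ratio) {
  n <- length(y)
  fit0 <- glm.fit(C, y, family = binomial())
  p0 <- fit0$fitted.values
  # smallest lambda at which every penalized coefficient is zero: the max
  # absolute deviance gradient at the covariate-only fit
  lmax <- max(abs(crossprod(Xs, y - p0)) / n)
  lmax <- max(lmax, .Machine$double.eps)
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = nlambda))
}

#' Fit a lasso logistic combination of polygenic scores
#'
#' Minimizes `-(1/n) loglik(y | eta) + lambda * sum(|beta_k|)` over the PGS
#' coefficients, with the intercept and covariates (age, sex, PCs) left
#' unpenalized, by iteratively reweighted least squares with cyclic
#' coordinate descent and soft-thresholding. PGS columns are standardized
#' internally (mean 0, sample SD 1) and coefficients are reported on that
#' standardized scale, so `beta_k / sigma_k` applies directly to raw
#' scoring-file weights in [collapse_weights()]; covariates stay on their
#' native scale. The penalty path holds `nlambda` values geometrically spaced
#' from `lambda_max` (the smallest penalty giving an all-zero PGS model) down
#' to `lambda_min_ratio * lambda_max`. The optimal penalty `lambda.min` is
#' chosen by k-fold cross-validation with binomial deviance as the loss; when
#' several penalties tie, the largest (sparsest model) wins.
#'
#' @param y Binary 0/1 outcome vector.
#' @param pgs Numeric matrix or data frame of PGS columns (samples x scores).
#' @param covariates Optional matrix/data frame of unpenalized covariates.
#' @param n_folds Number of CV folds (default 10); folds are stratified by
#'   case status and assigned by a seeded shuffle.
#' @param seed Integer seed controlling fold assignment.
#' @param nlambda,lambda_min_ratio Penalty path controls (defaults 100 and
#'   1e-4).
#' @param lambda Optional explicit penalty path (overrides `nlambda`); a
#'   single value skips cross-validation and fits at that penalty.
#' @param tol Convergence tolerance on the maximum coefficient change
#'   (default 1e-7).
#' @param maxit_irls Cap on outer IRLS iterations per penalty value.
#' @return An object of class `multipgs_lasso`: coefficients at `lambda.min`
#'   (standardized-PGS scale), unpenalized coefficients, the full path, the
#'   CV curve (`lambda`, `mean_deviance`, `se_deviance`), `lambda_min`,
#'   per-PGS means/SDs, and the seed. Methods: [predict.multipgs_lasso()],
#'   `tidy()`, `glance()`, `autoplot()`.
#' @export
fit_lasso_logistic <- function(y, pgs, covariates = NULL, n_folds = 10L,
                               seed = 1L, nlambda = 100L,
                               lambda_min_ratio = 1e-4, lambda = NULL,
                               tol = 1e-7, maxit_irls = 100L) {
  d <- build_designs(y, pgs, covariates)
  if (is.null(lambda)) {
    lambda <- lambda_path_from(y, d$Xs, d$C, nlambda, lambda_min_ratio)
  } else {
    lambda <- sort(as.numeric(lambda), decreasing = TRUE)
  }
  path <- lasso_path_engine(y, d$Xs, d$C, lambda, tol = tol,
                            maxit_irls = maxit_irls)
  if (length(lambda) > 1L && n_folds > 1L) {
    cv <- cv_curve(y, pgs, covariates, lambda = lambda, n_folds = n_folds,
                   seed = seed, tol = tol, maxit_irls = maxit_irls)
    best <- min(cv$mean_deviance)
    lambda_min <- max(cv$lambda[cv$mean_deviance <= best + 1e-12])
  } else {
    cv <- NULL
    lambda_min <- lambda[length(lambda)]
  }
  l_idx <- which.min(abs(lambda - lambda_min))
  structure(
    list(pgs_ids = d$pgs_ids,
         coefficients = setNames(path$beta[, l_idx], d$pgs_ids),
         unpenalized_coefs = setNames(path$theta[, l_idx], colnames(d$C)),
         intercept = path$theta[1, l_idx],
         lambda = lambda, beta_path = path$beta, theta_path = path$theta,
         converged = path$converged,
         cv = cv, lambda_min = lambda_min,
         pgs_means = d$mu, pgs_sds = setNames(d$sds, d$pgs_ids),
         n_folds = n_folds, seed = as.integer(seed),
         n = length(y), n_cases = sum(y)),
    class = "multipgs_lasso")
}

make_folds <- function(y, n_folds, seed, max_retries = 20L) {
  n <- length(y)
  for (try in 0:max_retries) {
    withr::local_seed(split_seed(seed, 20L + try))
    fold <- integer(n)
    for (cls in c(0, 1)) {
      idx <- which(y == cls)
      fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
    ok <- all(vapply(seq_len(n_folds), function(f) {
      yt <- y[fold != f]
      sum(yt) > 0 && sum(yt) < length(yt)
    }, logical(1)))
    if (ok) {
      if (try > 0)
        rlang::inform(sprintf("cv folds: refolded %d time(s) to avoid single-class folds.", try))
      return(fold)
    }
  }
  rlang::abort("could not build folds with both classes present; too few cases.")
}

#' Cross-validated deviance curve for the lasso combination
#'
#' Out-of-fold binomial deviance (`-2 * mean log-likelihood` per held-out
#' observation) along the penalty path, with mean and standard error across
#' folds. Folds are stratified by case status and assigned by a seeded
#' shuffle; a fold that would leave a single outcome class in its training
#' split triggers a refold with an offset seed (logged).
#'
#' @inheritParams fit_lasso_logistic
#' @param lambda Penalty path (required here).
#' @return A tibble with `lambda`, `mean_deviance`, `se_deviance`,
#'   `n_active` (nonzero PGS coefficients in the full-data path at that
#'   penalty is *not* included here; see `tidy()` on the fit).
#' @export
cv_curve <- function(y, pgs, covariates = NULL, lambda, n_folds = 10L,
                     seed = 1L, tol = 1e-7, maxit_irls = 100L) {
  d <- build_designs(y, pgs, covariates)
  X <- as_matrix_named(pgs, "PGS")
  Cfull <- d$C
  fold <- make_folds(y, n_folds, seed)
  L <- length(lambda)
  dev_fold <- matrix(NA_real_, n_folds, L)
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    mu <- colMeans(X[tr, , drop = FALSE])
    sds <- apply(X[tr, , drop = FALSE], 2, sd)
    sds[sds == 0] <- 1
    Xs_tr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu, `-`), 2, sds, `/`)
    Xs_te <- sweep(sweep(X[!tr, , drop = FALSE], 2, mu, `-`), 2, sds, `/`)
    path <- lasso_path_engine(y[tr], Xs_tr, Cfull[tr, , drop = FALSE],
                              lambda, tol = tol, maxit_irls = maxit_irls)
    eta_te <- Cfull[!tr, , drop = FALSE] %*% path$theta + Xs_te %*% path$beta
    yte <- y[!tr]
    for (l in seq_len(L)) dev_fold[f, l] <- 2 * nll(yte, eta_te[, l])
  }
  tibble::tibble(
    lambda = lambda,
    mean_deviance = colMeans(dev_fold),
    se_deviance = apply(dev_fold, 2, sd) / sqrt(n_folds))
}

#' Predict from a fitted lasso combination
#'
#' @param object A `multipgs_lasso` fit.
#' @param pgs New PGS matrix/data frame (raw scale, same columns as fitted).
#' @param covariates New covariates (same columns as fitted, or `NULL` if the
#'   fit had none).
#' @param type `"link"` (linear predictor) or `"response"` (probability).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.multipgs_lasso <- function(object, pgs, covariates = NULL,
                                   type = c("link", "response"), ...) {
  type <- match.arg(type)
  X <- as_matrix_named(pgs, "PGS")
  X <- X[, object$pgs_ids, drop = FALSE]
  Xs <- sweep(sweep(X, 2, object$pgs_means, `-`), 2, object$pgs_sds, `/`)
  C <- matrix(1, nrow(X), 1)
  if (length(object$unpenalized_coefs) > 1) {
    Cm <- as_matrix_named(covariates, "covar")
    C <- cbind(C, Cm[, names(object$unpenalized_coefs)[-1], drop = FALSE])
  }
  eta <- drop(C %*% object$unpenalized_coefs) + drop(Xs %*% object$coefficients)
  if (type == "response") plogis(eta) else eta
}

#' Karush-Kuhn-Tucker optimality check for a lasso fit
#'
#' At the solution, the deviance gradient for each penalized coefficient must
#' satisfy `|g_k| <= lambda` when `beta_k = 0` and `g_k = -lambda *
#' sign(beta_k)` when active (all on the standardized-PGS scale).
#'
#' @param fit A `multipgs_lasso` fit.
#' @param y,pgs,covariates The data the model was fitted to.
#' @param lambda Penalty at which to check (default `fit$lambda_min`).
#' @param tol Slack allowed on the conditions (default 1e-4).
#' @return A tibble per PGS with the gradient, the active flag, the violation
#'   magnitude, and `ok`.
#' @export
kkt_check <- function(fit, y, pgs, covariates = NULL,
                      lambda = fit$lambda_min, tol = 1e-4) {
  d <- build_designs(y, pgs, covariates)
  l_idx <- which.min(abs(fit$lambda - lambda))
  beta <- fit$beta_path[, l_idx]
  theta <- fit$theta_path[, l_idx]
  eta <- drop(d$C %*% theta) + drop(d$Xs %*% beta)
  g <- drop(crossprod(d$Xs, plogis(eta) - y)) / length(y)
  active <- beta != 0
  viol <- ifelse(active, abs(g + lambda * sign(beta)),
                 pmax(abs(g) - lambda, 0))
  tibble::tibble(pgs_id = fit$pgs_ids, gradient = g, beta = beta,
                 active = active, violation = viol, ok = viol <= tol)
}

#' @export
print.multipgs_lasso <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat("<multipgs_lasso>\n")
  cat(sprintf("  %d PGS (%d active at lambda.min), %d unpenalized terms\n",
              length(x$pgs_ids), nz, length(x$unpenalized_coefs)))
  cat(sprintf("  lambda.min = %.4g over a path of %d values; %d-fold CV; n = %d (%d cases)\n",
              x$lambda_min, length(x$lambda), x$n_folds, x$n, x$n_cases))
  invisible(x)
}

#' @rdname fit_lasso_logistic
#' @param x A `multipgs_lasso` fit.
#' @param ... Unused.
#' @export
tidy.multipgs_lasso <- function(x, ...) {
  tibble::tibble(pgs_id = x$pgs_ids,
                 estimate = unname(x$coefficients),
                 pgs_sd = unname(x$pgs_sds),
                 collapse_factor = unname(x$coefficients / x$pgs_sds),
                 active = x$coefficients != 0)
}

#' @rdname fit_lasso_logistic
#' @export
glance.multipgs_lasso <- function(x, ...) {
  cvmin <- if (!is.null(x$cv)) min(x$cv$mean_deviance) else NA_real_
  tibble::tibble(n = x$n, n_cases = x$n_cases,
                 n_pgs = length(x$pgs_ids),
                 n_active = sum(x$coefficients != 0),
                 lambda_min = x$lambda_min,
                 cv_deviance_min = cvmin,
                 n_folds = x$n_folds, seed = x$seed)
}

#' @rdname fit_lasso_logistic
#' @param object A `multipgs_lasso` fit (for `autoplot`).
#' @export
autoplot.multipgs_lasso <- function(object, ...) {
  stop_if(is.null(object$cv), "fit has no CV curve to plot.")
  ggplot2::ggplot(object$cv, ggplot2::aes(x = log(.data$lambda),
                                          y = .data$mean_deviance)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean_deviance - .data$se_deviance,
      ymax = .data$mean_deviance + .data$se_deviance), alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = log(object$lambda_min), linetype = 2) +
    ggplot2::labs(x = "log(lambda)", y = "CV binomial deviance",
                  title = "Cross-validated deviance along the penalty path") +
    ggplot2::theme_minimal()
}

#' Serialize / restore a lasso fit as JSON
#'
#' @param fit A `multipgs_lasso` fit.
#' @param path JSON path.
#' @return `write_lasso_fit()` invisibly returns `path`;
#'   `read_lasso_fit()` returns the restored fit (path matrices included).
#' @export
write_lasso_fit <- function(fit, path) {
  obj <- unclass(fit)
  obj$cv <- if (!is.null(fit$cv)) as.list(fit$cv)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lasso_fit
#' @export
read_lasso_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$coefficients <- setNames(as.numeric(obj$coefficients), obj$pgs_ids)
  obj$pgs_sds <- setNames(as.numeric(obj$pgs_sds), obj$pgs_ids)
  obj$pgs_means <- as.numeric(obj$pgs_means)
  obj$beta_path <- matrix(unlist(obj$beta_path), nrow = length(obj$pgs_ids))
  if (!is.null(obj$cv)) obj$cv <- tibble::as_tibble(obj$cv)
  class(obj) <- "multipgs_lasso"
  obj
}
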