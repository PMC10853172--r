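# Evaluation battery: logistic models with base covariates, OR per SD,
# Nagelkerke R2, AUC, bootstrap CIs, likelihood-ratio tests, decile
# prevalence, and FDR-controlled many-PGS association scans.

#' Logistic-regression MLE with separation fallback
#'
#' Fits a binomial GLM by IRLS (via `stats::glm.fit`). If the fit does not
#' converge or shows quasi-separation (fitted probabilities at the 0/1
#' boundary), it is refit with a small ridge stabilizer (penalty
#' `ridge * ||beta||^2` excluding the intercept) and flagged.
#'
#' @param y Binary 0/1 outcome.
#' @param design Numeric design matrix *without* an intercept column (one is
#'   added), or `NULL` for intercept-only.
#' @param ridge Ridge stabilizer used by the fallback (default 1e-6).
#' @return A list with `coefficients`, `vcov`, `loglik`, `df` (number of
#'   parameters), `n`, `converged`, `separation` (flag), `fitted`.
#' @export
fit_logistic <- function(y, design = NULL, ridge = 1e-6) {
  stop_if(!is_binary01(y), "`y` must be a 0/1 vector without NA.")
  stop_if(sum(y) == 0 || sum(y) == length(y), "`y` has a single outcome class.")
  n <- length(y)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(design) && NCOL(design) > 0) {
    D <- as_matrix_named(design, "x")
    stop_if(anyNA(D), "`design` contains missing values.")
    stop_if(nrow(D) != n, "`design` rows must match length(y).")
    X <- cbind(X, D)
  }
  stop_if(qr(X)$rank < ncol(X), "`design` is rank-deficient.")
  fit <- suppressWarnings(glm.fit(X, y, family = binomial(),
                                  control = list(maxit = 100, epsilon = 1e-10)))
  separation <- !fit$converged ||
    any(fit$fitted.values > 1 - 1e-8 | fit$fitted.values < 1e-8)
  if (separation) {
    rlang::warn("fit_logistic: possible separation; using ridge-stabilized fallback.")
    fit <- irls_ridge(X, y, ridge = ridge)
  }
  eta <- drop(X %*% fit$coefficients)
  p <- plogis(eta)
  w <- pmax(p * (1 - p), 1e-10)
  vcov <- solve(crossprod(X, X * w))
  ll <- sum(y * eta - log1p(exp(eta)))
  list(coefficients = setNames(fit$coefficients, colnames(X)),
       vcov = vcov, loglik = ll, df = ncol(X), n = n,
       converged = fit$converged, separation = separation, fitted = p)
}

# Newton iteration for logistic regression with an L2 stabilizer on the
# non-intercept coefficients; used only as a separation fallback.
irls_ridge <- function(X, y, ridge = 1e-6, maxit = 100L, tol = 1e-8) {
  n <- nrow(X); q <- ncol(X)
  pen <- diag(c(0, rep(ridge, q - 1)), q)
  beta <- numeric(q)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    score <- crossprod(X, y - p) - 2 * n * pen %*% beta
    H <- crossprod(X, X * w) + 2 * n * pen
    delta <- solve(H, score)
    beta <- beta + drop(delta)
    if (max(abs(score)) < 1e-8 || max(abs(delta)) < tol) { converged <- TRUE; break }
  }
  list(coefficients = beta, converged = converged)
}

#' Odds ratio per 1 SD of a score
#'
#' Standardizes the score to unit sample SD, fits a logistic model of the
#' outcome on the standardized score plus covariates, and reports
#' `exp(beta)` with a Wald 95% CI (`exp(beta +/- 1.96 se)`).
#'
#' @param y Binary 0/1 outcome.
#' @param score Numeric score vector (non-constant).
#' @param covariates Optional covariate matrix/data frame.
#' @return A one-row tibble: `or`, `ci_lo`, `ci_hi`, `beta`, `se`, `p`.
#' @export
or_per_sd <- function(y, score, covariates = NULL) {
  z <- standardize_scores(score)$scores
  D <- cbind(score_std = z,
             if (!is.null(covariates)) as_matrix_named(covariates, "covar"))
  fit <- fit_logistic(y, D)
  b <- fit$coefficients["score_std"]
  se <- sqrt(fit$vcov["score_std", "score_std"])
  tibble::tibble(or = exp(b), ci_lo = exp(b - 1.96 * se),
                 ci_hi = exp(b + 1.96 * se),
                 beta = unname(b), se = se, p = 2 * pnorm(-abs(b / se)))
}

#' Nagelkerke pseudo-R-squared
#'
#' Cox-Snell `1 - exp(2 (ll_null - ll_full) / n)` rescaled by its maximum
#' `1 - exp(2 ll_null / n)` so a saturated model reaches 1.
#'
#' @param ll_null,ll_full Log-likelihoods of the nested null and full models
#'   (`ll_full >= ll_null`).
#' @param n Sample size.
#' @return A value in `[0, 1]`.
#' @export
#' @examples
#' nagelkerke_r2(-100, -100, 200)  # identical models: 0
#' nagelkerke_r2(-100, 0, 200)     # perfect prediction: 1
nagelkerke_r2 <- function(ll_null, ll_full, n) {
  stop_if(n < 1, "`n` must be >= 1.")
  stop_if(ll_full < ll_null - 1e-8,
          "ll_full < ll_null: models are not nested as assumed.")
  cox_snell <- 1 - exp(2 * (ll_null - ll_full) / n)
  r2_max <- 1 - exp(2 * ll_null / n)
  if (r2_max <= 0) return(0)
  min(max(cox_snell / r2_max, 0), 1)
}

#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' `P(score_case > score_control) + 0.5 P(tie)`, computed from midranks in
#' O(n log n); identical to the all-pairs count.
#'
#' @param y Binary 0/1 outcome (both classes present).
#' @param score Numeric score vector.
#' @return AUC in `[0, 1]`.
#' @export
auc_mw <- function(y, score) {
  stop_if(!is_binary01(y), "`y` must be a 0/1 vector without NA.")
  n1 <- sum(y); n0 <- length(y) - n1
  stop_if(n1 == 0 || n0 == 0, "AUC needs both outcome classes.")
  r <- rank(score, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' DeLong 95% confidence interval for the AUC
#'
#' Thin wrapper over `pROC::ci.auc(..., method = "delong")` with the
#' direction fixed so higher scores mean higher risk.
#'
#' @inheritParams auc_mw
#' @return A one-row tibble: `auc`, `ci_lo`, `ci_hi`.
#' @export
auc_ci_delong <- function(y, score) {
  stop_if(!requireNamespace("pROC", quietly = TRUE),
          "DeLong intervals require the pROC package.")
  roc <- pROC::roc(response = y, predictor = score, levels = c(0, 1),
                   direction = "<", quiet = TRUE)
  ci <- as.numeric(pROC::ci.auc(roc, method = "delong"))
  tibble::tibble(auc = ci[2], ci_lo = ci[1], ci_hi = ci[3])
}

#' Seeded percentile bootstrap confidence interval
#'
#' Resamples rows (cases and controls together) with replacement, recomputes
#' the statistic on each resample, and returns the 2.5/97.5 percentiles. A
#' resample on which the statistic fails (error or NA) is redrawn, up to 10
#' retries per replicate, with a logged count.
#'
#' @param data A data frame (rows are resampled).
#' @param statistic Function `data -> single number`.
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return A one-row tibble: `ci_lo`, `ci_hi`, `n_boot`, `n_redraws`.
#' @export
bootstrap_ci <- function(data, statistic, n_boot = 1000L, seed = 1L,
                         conf = 0.95) {
  data <- as.data.frame(data)
  n <- nrow(data)
  withr::local_seed(split_seed(seed, 30L))
  stats_out <- numeric(n_boot)
  n_redraws <- 0L
  for (b in seq_len(n_boot)) {
    val <- NA_real_
    for (try in 0:10) {
      idx <- sample.int(n, n, replace = TRUE)
      val <- tryCatch(statistic(data[idx, , drop = FALSE]),
                      error = function(e) NA_real_)
      if (is.finite(val)) break
      n_redraws <- n_redraws + 1L
    }
    stop_if(!is.finite(val),
            "bootstrap statistic failed on 10 consecutive redraws (replicate %d).", b)
    stats_out[b] <- val
  }
  if (n_redraws > 0)
    rlang::inform(sprintf("bootstrap_ci: %d resample(s) redrawn.", n_redraws))
  a <- (1 - conf) / 2
  qs <- quantile(stats_out, c(a, 1 - a), names = FALSE, type = 7)
  tibble::tibble(ci_lo = qs[1], ci_hi = qs[2], n_boot = n_boot,
                 n_redraws = n_redraws)
}

#' Likelihood-ratio test between nested logistic fits
#'
#' @param fit_base,fit_full Fits from [fit_logistic()] on the same data, with
#'   `fit_full` nesting `fit_base` (`df_full > df_base`).
#' @return Two-sided chi-square p-value on `2 (ll_full - ll_base)` with
#'   `df_full - df_base` degrees of freedom; identical fits give p = 1.
#' @export
lr_test <- function(fit_base, fit_full) {
  stop_if(fit_full$df < fit_base$df,
          "`fit_full` must have at least as many parameters as `fit_base`.")
  stat <- 2 * (fit_full$loglik - fit_base$loglik)
  stop_if(stat < -1e-6, "ll_full < ll_base: models do not appear nested.")
  stat <- max(stat, 0)
  df <- fit_full$df - fit_base$df
  if (df == 0) return(1)
  pchisq(stat, df = df, lower.tail = FALSE)
}

#' Case prevalence by score decile
#'
#' Ranks samples by score (ties broken by stable input order), cuts them into
#' 10 near-equal bins (sizes differ by at most 1), and reports the case
#' fraction per bin. The size-weighted mean of the bin prevalences equals the
#' overall prevalence exactly.
#'
#' @param y Binary 0/1 outcome.
#' @param score Numeric score vector (`n >= 10`).
#' @return A tibble with `decile` (1 = lowest scores), `n`, `n_cases`,
#'   `prevalence`.
#' @export
decile_prevalence <- function(y, score) {
  n <- length(y)
  stop_if(n < 10, "decile prevalence needs n >= 10.")
  stop_if(length(score) != n, "`score` must match length(y).")
  r <- rank(score, ties.method = "first")
  bin <- ceiling(10 * r / n)
  tibble::tibble(decile = seq_len(10)) |>
    dplyr::left_join(
      tibble::tibble(decile = bin, y = y) |>
        dplyr::group_by(.data$decile) |>
        dplyr::summarise(n = dplyr::n(), n_cases = sum(.data$y),
                         prevalence = mean(.data$y), .groups = "drop"),
      by = "decile")
}

#' Association scan of many PGS against an outcome with FDR control
#'
#' Fits one logistic model per PGS column (standardized, with covariates),
#' collects per-PGS Wald statistics, and applies Benjamini-Hochberg at
#' `fdr_q` across all tested PGS. Constant columns are skipped with a log
#' entry and excluded from the BH denominator. A PGS whose fit hits
#' separation uses the ridge-stabilized fallback and is flagged, so one
#' degenerate column cannot halt a large scan.
#'
#' @param y Binary 0/1 outcome.
#' @param pgs_matrix Matrix/data frame of PGS columns.
#' @param covariates Optional covariates included in every model.
#' @param fdr_q Benjamini-Hochberg target FDR (default 0.05).
#' @return A tibble per PGS: `pgs_id`, `beta`, `se`, `p`, `q` (BH-adjusted),
#'   `discovery`, `status` (`"ok"`, `"skipped_constant"`, `"separation"`).
#' @export
pgs_scan <- function(y, pgs_matrix, covariates = NULL, fdr_q = 0.05) {
  X <- as_matrix_named(pgs_matrix, "PGS")
  Cm <- if (!is.null(covariates)) as_matrix_named(covariates, "covar")
  res <- purrr::map(seq_len(ncol(X)), function(k) {
    x <- X[, k]
    if (stats::sd(x) == 0)
      return(tibble::tibble(beta = NA_real_, se = NA_real_, p = NA_real_,
                            status = "skipped_constant"))
    z <- (x - mean(x)) / stats::sd(x)
    fit <- suppressWarnings(fit_logistic(y, cbind(score_std = z, Cm)))
    b <- fit$coefficients["score_std"]
    se <- sqrt(fit$vcov["score_std", "score_std"])
    tibble::tibble(beta = unname(b), se = unname(se),
                   p = unname(2 * pnorm(-abs(b / se))),
                   status = if (fit$separation) "separation" else "ok")
  }) |> dplyr::bind_rows()
  n_skip <- sum(res$status == "skipped_constant")
  if (n_skip > 0)
    rlang::inform(sprintf("pgs_scan: skipped %d constant PGS column(s).", n_skip))
  res <- dplyr::mutate(res, pgs_id = colnames(X), .before = 1)
  res$q <- NA_real_
  tested <- !is.na(res$p)
  res$q[tested] <- p.adjust(res$p[tested], method = "BH")
  res$discovery <- !is.na(res$q) & res$q <= fdr_q
  res
}

#' Evaluate a risk model on a cohort
#'
#' The full report for one score: odds ratio per SD with Wald CI, Nagelkerke
#' R2 with a percentile-bootstrap CI, AUC with a DeLong CI (bootstrap by
#' flag), decile prevalences, and a likelihood-ratio test against the
#' covariate-only base model. Passing `score = NULL` evaluates the base model
#' itself (no OR, LRT p = 1).
#'
#' @param y Binary 0/1 outcome.
#' @param score Numeric score vector, or `NULL` for the base model.
#' @param covariates Covariate matrix/data frame for the base model.
#' @param label Model label carried in the report.
#' @param n_boot Bootstrap replicates for the R2 interval (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @param auc_ci `"delong"` (default) or `"boot"`.
#' @return An object of class `multipgs_eval` with fields `model_label`,
#'   `or_per_sd`, `r2_nagelkerke`, `auc`, `decile_prevalence`, `n_cases`,
#'   `n_controls`, `lrt_p_vs_base`. Methods: `tidy()`, `glance()`,
#'   `autoplot()`, [write_eval_report()].
#' @export
evaluate_model <- function(y, score, covariates, label = "model",
                           n_boot = 1000L, seed = 1L,
                           auc_ci = c("delong", "boot")) {
  auc_ci <- match.arg(auc_ci)
  Cm <- if (!is.null(covariates)) as_matrix_named(covariates, "covar")
  fit_base <- fit_logistic(y, Cm)
  fit_null <- fit_logistic(y, NULL)
  if (is.null(score)) {
    fit_full <- fit_base
    or_tab <- tibble::tibble(or = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                             beta = NA_real_, se = NA_real_, p = NA_real_)
    lrt_p <- 1
    risk <- fit_base$fitted
  } else {
    z <- standardize_scores(score)$scores
    fit_full <- fit_logistic(y, cbind(score_std = z, Cm))
    or_tab <- or_per_sd(y, score, covariates)
    lrt_p <- lr_test(fit_base, fit_full)
    risk <- fit_full$fitted
  }
  r2 <- nagelkerke_r2(fit_null$loglik, fit_full$loglik, length(y))

  dat <- data.frame(y = y)
  if (!is.null(score)) dat$score <- score
  if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(Cm))
  r2_stat <- function(d) {
    yv <- d$y
    Cb <- as.matrix(d[setdiff(names(d), c("y", "score"))])
    if (ncol(Cb) == 0) Cb <- NULL
    Db <- if ("score" %in% names(d)) {
      cbind(score_std = standardize_scores(d$score)$scores, Cb)
    } else Cb
    f0 <- fit_logistic(yv, NULL)
    f1 <- suppressWarnings(fit_logistic(yv, Db))
    nagelkerke_r2(f0$loglik, f1$loglik, length(yv))
  }
  r2_ci <- bootstrap_ci(dat, r2_stat, n_boot = n_boot, seed = seed)

  auc_point <- auc_mw(y, risk)
  auc_tab <- if (auc_ci == "delong") {
    auc_ci_delong(y, risk)
  } else {
    ci <- bootstrap_ci(data.frame(y = y, risk = risk),
                       function(d) auc_mw(d$y, d$risk),
                       n_boot = n_boot, seed = seed + 1L)
    tibble::tibble(auc = auc_point, ci_lo = ci$ci_lo, ci_hi = ci$ci_hi)
  }
  structure(
    list(model_label = label,
         or_per_sd = or_tab,
         r2_nagelkerke = tibble::tibble(r2 = r2, ci_lo = r2_ci$ci_lo,
                                        ci_hi = r2_ci$ci_hi),
         auc = auc_tab,
         decile_prevalence = decile_prevalence(y, if (is.null(score)) risk else score),
         n_cases = sum(y), n_controls = sum(1 - y),
         lrt_p_vs_base = lrt_p),
    class = "multipgs_eval")
}

#' @export
print.multipgs_eval <- function(x, ...) {
  cat(sprintf("<multipgs_eval> %s  (%d cases / %d controls)\n",
              x$model_label, x$n_cases, x$n_controls))
  if (!is.na(x$or_per_sd$or))
    cat(sprintf("  OR per SD %.3f (%.3f-%.3f)\n", x$or_per_sd$or,
                x$or_per_sd$ci_lo, x$or_per_sd$ci_hi))
  cat(sprintf("  Nagelkerke R2 %.3f (%.3f-%.3f)\n", x$r2_nagelkerke$r2,
              x$r2_nagelkerke$ci_lo, x$r2_nagelkerke$ci_hi))
  cat(sprintf("  AUC %.3f (%.3f-%.3f)\n", x$auc$auc, x$auc$ci_lo, x$auc$ci_hi))
  cat(sprintf("  LRT vs base: p = %.3g\n", x$lrt_p_vs_base))
  invisible(x)
}

#' @rdname evaluate_model
#' @param x A `multipgs_eval` report.
#' @param ... Unused.
#' @export
tidy.multipgs_eval <- function(x, ...) {
  tibble::tibble(
    model_label = x$model_label,
    metric = c("or_per_sd", "r2_nagelkerke", "auc"),
    estimate = c(x$or_per_sd$or, x$r2_nagelkerke$r2, x$auc$auc),
    ci_lo = c(x$or_per_sd$ci_lo, x$r2_nagelkerke$ci_lo, x$auc$ci_lo),
    ci_hi = c(x$or_per_sd$ci_hi, x$r2_nagelkerke$ci_hi, x$auc$ci_hi))
}

#' @rdname evaluate_model
#' @export
glance.multipgs_eval <- function(x, ...) {
  tibble::tibble(model_label = x$model_label,
                 or_per_sd = x$or_per_sd$or,
                 r2_nagelkerke = x$r2_nagelkerke$r2,
                 auc = x$auc$auc,
                 lrt_p_vs_base = x$lrt_p_vs_base,
                 n_cases = x$n_cases, n_controls = x$n_controls)
}

#' @rdname evaluate_model
#' @param object A `multipgs_eval` report (for `autoplot`).
#' @export
autoplot.multipgs_eval <- function(object, ...) {
  ggplot2::ggplot(object$decile_prevalence,
                  ggplot2::aes(x = factor(.data$decile), y = .data$prevalence)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$n_cases /
                          (object$n_cases + object$n_controls),
                        linetype = 2) +
    ggplot2::labs(x = "Score decile (1 = lowest)", y = "Case prevalence",
                  title = object$model_label) +
    ggplot2::theme_minimal()
}

#' Write an evaluation report as JSON (plus a readable text table)
#'
#' @param report A `multipgs_eval` (or list of them).
#' @param path Output JSON path; a sibling `.txt` table is written alongside.
#' @return Invisibly, `path`.
#' @export
write_eval_report <- function(report, path) {
  reports <- if (inherits(report, "multipgs_eval")) list(report) else report
  obj <- purrr::map(reports, function(r) {
    list(model_label = r$model_label,
         or_per_sd = as.list(r$or_per_sd),
         r2_nagelkerke = as.list(r$r2_nagelkerke),
         auc = as.list(r$auc),
         decile_prevalence = r$decile_prevalence$prevalence,
         n_cases = r$n_cases, n_controls = r$n_controls,
         lrt_p_vs_base = r$lrt_p_vs_base)
  })
  names(obj) <- purrr::map_chr(reports, "model_label")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  txt <- purrr::map_chr(reports, function(r) {
    sprintf("%-22s OR %s  R2 %.3f (%.3f-%.3f)  AUC %.3f (%.3f-%.3f)",
            r$model_label,
            if (is.na(r$or_per_sd$or)) "   -  " else
              sprintf("%.2f (%.2f-%.2f)", r$or_per_sd$or, r$or_per_sd$ci_lo,
                      r$or_per_sd$ci_hi),
            r$r2_nagelkerke$r2, r$r2_nagelkerke$ci_lo, r$r2_nagelkerke$ci_hi,
            r$auc$auc, r$auc$ci_lo, r$auc$ci_hi)
  })
  writeLines(c("Model                  PGS OR (95% CI)   R2 (95% CI)        AUC (95% CI)",
               txt), sub("\\.json$", ".txt", path))
  invisible(path)
}
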