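#' Ordinary least squares as a `regression_fit`
#'
#' Gaussian identity-link fit by QR least squares, with t statistics and
#' two-sided p values on n - k degrees of freedom. Used as the fitting
#' engine for the log lower-limit model (and by the interaction pruner).
#'
#' @param X design matrix.
#' @param y response vector.
#' @return a `regression_fit` (family `gaussian`) with `sigma` (residual
#'   standard deviation), `residuals` and `fitted`.
#' @export
fit_ols <- function(X, y) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[seq.int(qx$rank + 1, ncol(X))]]
    stop_config("design matrix is rank deficient; aliased column(s): %s",
                paste(aliased, collapse = ", "))
  }
  n <- nrow(X); k <- ncol(X)
  est <- qr.coef(qx, y)
  fitted <- drop(X %*% est)
  res <- y - fitted
  df <- n - k
  sigma2 <- if (df > 0) sum(res^2) / df else NA_real_
  XtX_inv <- chol2inv(qr.R(qx))
  se <- sqrt(sigma2 * diag(XtX_inv))
  tval <- est / se
  p <- if (df > 0) 2 * stats::pt(-abs(tval), df = df)
       else rep(NA_real_, k)
  ll <- -0.5 * n * (log(2 * pi) + log(sum(res^2) / n) + 1)
  new_regression_fit("gaussian", "identity", colnames(X), est, se, tval, p,
                     loglik = ll, n = n,
                     extra = list(sigma = sqrt(sigma2), df_residual = df,
                                  residuals = res, fitted = fitted, X = X))
}

#' Fit the log-linear model for the lower limit of the Fucus zone
#'
#' Ordinary least squares with the natural-log lower limit (m) as response
#' and salinity, log exposure, Secchi depth and total nitrogen as main
#' effects plus their two-way interactions, backward-pruned at `alpha`
#' exactly as in the hurdle model. Total phosphorus is expected to have
#' been removed upstream by the collinearity screen. Both the response and
#' exposure use the natural log.
#'
#' @param dataset data.frame of retained transects with `lower_limit_m` > 0
#'   and covariate columns (`salinity`, `secchi`, `ntot`, and `exposure` or
#'   `log_exposure`).
#' @param main_effects main-effect terms.
#' @param alpha pruning significance level.
#' @param prune if `FALSE`, keep all two-way interactions.
#' @return list (`lowerlimit_fit`): `fit` (a `regression_fit`), `terms`,
#'   `dropped` ledger.
#' @export
fit_lower_limit <- function(dataset,
                            main_effects = c("salinity", "log_exposure",
                                             "secchi", "ntot"),
                            alpha = 0.05, prune = TRUE) {
  if (any(dataset$lower_limit_m <= 0))
    stop_config("lower limits must be strictly positive for the log model")
  y <- log(dataset$lower_limit_m)
  if (prune) {
    pr <- prune_interactions(fit_ols, dataset, y, main_effects,
                             alpha = alpha)
  } else {
    cmb <- utils::combn(main_effects, 2)
    terms <- c("intercept", main_effects,
               apply(cmb, 2, paste, collapse = ":"))
    fit <- fit_ols(design_matrix(dataset, terms), y)
    pr <- list(fit = fit, terms = terms,
               dropped = data.frame(term = character(0),
                                    p_value = numeric(0),
                                    step = integer(0)))
  }
  structure(pr, class = "lowerlimit_fit")
}

#' @export
print.lowerlimit_fit <- function(x, ...) {
  cat(sprintf("Log-linear model for the Fucus zone lower limit (n = %d)\n",
              x$fit$n))
  print(coef_table(x$fit), digits = 4)
  if (nrow(x$dropped))
    cat("Dropped interactions:", paste(x$dropped$term, collapse = ", "),
        "\n")
  invisible(x)
}

#' Predict lower limits on the metre scale
#'
#' `exp(linear predictor)`; by default no smearing correction is applied,
#' so the prediction is the conditional median rather than the mean on the
#' metre scale. `smearing = TRUE` multiplies by Duan's smearing factor
#' (mean of exponentiated residuals).
#'
#' @param object a `lowerlimit_fit`.
#' @param covariates new covariate data.frame.
#' @param smearing apply Duan's nonparametric retransformation factor.
#' @param ... unused.
#' @return predicted lower limits in metres.
#' @export
predict.lowerlimit_fit <- function(object, covariates, smearing = FALSE,
                                   ...) {
  eta <- drop(design_matrix(covariates, object$terms) %*%
                object$fit$estimates)
  f <- if (smearing) mean(exp(object$fit$residuals)) else 1
  f * exp(eta)
}

#' Residual diagnostics: normality and homoscedasticity
#'
#' Shapiro-Wilk on the residuals and a (Koenker studentized)
#' Breusch-Pagan test regressing squared residuals on the model design:
#' `LM = n * R^2`, chi-squared with k - 1 df. The tests only report; no
#' automatic refitting follows a failure. Degenerate residual vectors
#' (all equal) are flagged instead of tested.
#'
#' @param fit a `regression_fit` from [fit_ols()] (or a `lowerlimit_fit`).
#' @param alpha level for the pass/fail flags.
#' @return list (`diagnostics_report`): `shapiro` (statistic, p, pass),
#'   `breusch_pagan` (statistic, df, p, pass), `n`, `degenerate`.
#' @export
diagnostics <- function(fit, alpha = 0.05) {
  if (inherits(fit, "lowerlimit_fit")) fit <- fit$fit
  res <- fit$residuals
  n <- length(res)
  if (n < 3L) stop_config("diagnostics need at least 3 residuals")
  scale_ref <- max(abs(fit$fitted), 1)
  if (!is.finite(stats::sd(res)) || stats::sd(res) < 1e-10 * scale_ref) {
    return(structure(list(degenerate = TRUE, n = n, shapiro = NULL,
                          breusch_pagan = NULL),
                     class = "diagnostics_report"))
  }
  sw <- stats::shapiro.test(res)
  X <- fit$X
  aux <- fit_ols(X, res^2)
  r2 <- 1 - sum(aux$residuals^2) / sum((res^2 - mean(res^2))^2)
  df <- ncol(X) - 1
  bp_stat <- n * r2
  bp_p <- stats::pchisq(bp_stat, df = df, lower.tail = FALSE)
  structure(list(
    degenerate = FALSE, n = n,
    shapiro = list(statistic = unname(sw$statistic), p = sw$p.value,
                   pass = sw$p.value >= alpha),
    breusch_pagan = list(statistic = bp_stat, df = df, p = bp_p,
                         pass = bp_p >= alpha)),
    class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, ...) {
  if (x$degenerate) {
    cat("Residuals are degenerate (zero variance); diagnostics skipped\n")
    return(invisible(x))
  }
  cat(sprintf("Shapiro-Wilk normality: W = %.4f, p = %.4g (%s)\n",
              x$shapiro$statistic, x$shapiro$p,
              if (x$shapiro$pass) "pass" else "FAIL"))
  cat(sprintf("Breusch-Pagan homoscedasticity: LM = %.4f on %d df, p = %.4g (%s)\n",
              x$breusch_pagan$statistic, x$breusch_pagan$df,
              x$breusch_pagan$p,
              if (x$breusch_pagan$pass) "pass" else "FAIL"))
  invisible(x)
}

#' Calibrate the residual noise of the depth-limit simulation to a printed
#' standard error
#'
#' Given a design matrix and a target standard error for one coefficient,
#' returns the residual standard deviation sigma for which OLS would
#' report that standard error: `SE_j = sigma * sqrt((X'X)^-1_jj)`. Used to
#' set the generator's `sigma_loglimit` from a published coefficient table
#' instead of guessing.
#'
#' @param X design matrix of the simulated transect dataset.
#' @param term coefficient name.
#' @param se_target published standard error for that coefficient.
#' @return sigma (> 0).
#' @export
calibrate_sigma_loglimit <- function(X, term = "salinity",
                                     se_target = 0.21) {
  stopifnot(term %in% colnames(X))
  XtX_inv <- chol2inv(chol(crossprod(X)))
  j <- match(term, colnames(X))
  se_target / sqrt(XtX_inv[j, j])
}
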