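#' Build a regression design matrix from environmental covariates
#'
#' Terms are drawn from the main effects `intercept`, `salinity`,
#' `log_exposure`, `secchi`, `ntot`, `ptot` and their pairwise products
#' written `"a:b"`. The wave-exposure index always enters on the natural log
#' scale (`log_exposure`); all other covariates enter unstandardized, so
#' coefficient magnitudes are in raw units (PSU, metres, micrograms per
#' litre).
#'
#' @param covariates data.frame with columns `salinity`, `secchi`, `ntot`,
#'   `ptot` (as needed) and either `exposure` (> 0) or `log_exposure`.
#' @param terms character vector of term names; order is preserved.
#' @return numeric matrix with one column per term.
#' @export
design_matrix <- function(covariates, terms) {
  covariates <- as.data.frame(covariates)
  if (is.null(covariates$log_exposure) && !is.null(covariates$exposure)) {
    if (any(covariates$exposure <= 0, na.rm = TRUE))
      stop_config("exposure must be > 0 to enter on the log scale")
    covariates$log_exposure <- log(covariates$exposure)
  }
  n <- nrow(covariates)
  main_col <- function(nm) {
    if (nm == "intercept") return(rep(1, n))
    if (is.null(covariates[[nm]]))
      stop_config("covariate '%s' not found", nm)
    covariates[[nm]]
  }
  cols <- lapply(terms, function(tm) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    Reduce(`*`, lapply(parts, main_col))
  })
  X <- do.call(cbind, cols)
  colnames(X) <- terms
  X
}

# container for one fitted regression part
new_regression_fit <- function(family, link, terms, estimates, se, stat,
                               p, phi = NULL, loglik = NA_real_, n,
                               converged = TRUE, extra = list()) {
  stat_name <- if (family == "gaussian") "t" else "z"
  structure(
    c(list(family = family, link = link, terms = terms,
           estimates = setNames(estimates, terms),
           se = setNames(se, terms), statistic = setNames(stat, terms),
           p = setNames(p, terms), phi = phi, loglik = loglik, n = n,
           converged = converged, stat_name = stat_name), extra),
    class = "regression_fit"
  )
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit> family=%s link=%s n=%d%s converged=%s\n",
              x$family, x$link, x$n,
              if (!is.null(x$phi)) sprintf(" phi=%.3f", x$phi) else "",
              x$converged))
  print(coef_table(x), digits = 4)
  invisible(x)
}

#' Coefficient table of a fitted regression part
#'
#' @param fit a `regression_fit`.
#' @return data.frame with term, estimate, std error, z/t value, p value.
#' @export
coef_table <- function(fit) {
  data.frame(term = fit$terms, estimate = unname(fit$estimates),
             std_error = unname(fit$se), statistic = unname(fit$statistic),
             p_value = unname(fit$p), row.names = NULL)
}

#' Fit the binomial (presence/absence) part
#'
#' Logit-link binomial GLM fitted by maximum likelihood, with Wald standard
#' errors from the observed information. Complete separation is surfaced as
#' a non-convergence diagnostic instead of silently returning runaway
#' estimates.
#'
#' @param X design matrix from [design_matrix()].
#' @param presence 0/1 response vector.
#' @return a `regression_fit` (family `binomial`).
#' @export
fit_binomial <- function(X, presence) {
  stopifnot(is.matrix(X), nrow(X) == length(presence))
  if (!all(presence %in% c(0, 1))) stop_config("presence must be 0/1")
  if (qr(X)$rank < ncol(X)) stop_config("design matrix is rank deficient")
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(X, presence, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  est <- fit$coefficients
  # observed-information SEs: (X' W X)^-1 at the MLE
  mu <- fit$fitted.values
  W <- mu * (1 - mu)
  info <- crossprod(X, X * W)
  separated <- sep_warn && (all(presence == 1) || all(presence == 0) ||
                              max(abs(est)) > 1e2 || min(W) < 1e-12)
  cov_ok <- !separated && rcond(info) > 1e-14
  se <- if (cov_ok) sqrt(diag(solve(info))) else rep(NA_real_, ncol(X))
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  ll <- sum(stats::dbinom(presence, 1, pmin(pmax(mu, 1e-12), 1 - 1e-12),
                          log = TRUE))
  conv <- fit$converged && cov_ok
  out <- new_regression_fit("binomial", "logit", colnames(X), est, se, z, p,
                            loglik = ll, n = nrow(X), converged = conv)
  if (!conv)
    out$diagnostic <- if (separated)
      "apparent complete or quasi-complete separation" else
      "IRLS did not converge or information matrix is singular"
  out
}

# negative log-likelihood and analytic gradient of beta regression with
# logit mean link and constant precision phi = exp(theta[k+1])
beta_negll <- function(theta, X, y) {
  k <- ncol(X)
  eta <- drop(X %*% theta[seq_len(k)])
  mu <- stats::plogis(eta)
  phi <- exp(theta[k + 1])
  a <- mu * phi
  b <- (1 - mu) * phi
  -sum(lgamma(phi) - lgamma(a) - lgamma(b) +
         (a - 1) * log(y) + (b - 1) * log1p(-y))
}

beta_negll_grad <- function(theta, X, y) {
  k <- ncol(X)
  eta <- drop(X %*% theta[seq_len(k)])
  mu <- stats::plogis(eta)
  phi <- exp(theta[k + 1])
  ystar <- qlogis(y)
  mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
  dmu <- mu * (1 - mu)
  gbeta <- -phi * drop(crossprod(X, (ystar - mustar) * dmu))
  dphi <- sum(mu * (ystar - mustar) + log1p(-y) -
                digamma((1 - mu) * phi) + digamma(phi))
  c(gbeta, -phi * dphi)
}

#' Fit the truncated positive part by beta regression
#'
#' Maximum-likelihood beta regression in the mean-precision
#' parameterization: `y ~ Beta(mu * phi, (1 - mu) * phi)` with
#' `mu = plogis(X beta)` and a single precision `phi` shared by all
#' observations (internally log-transformed). Optimization is quasi-Newton
#' (BFGS) on `(beta, log phi)` with the analytic gradient; standard errors
#' come from the numerically differentiated Hessian at the optimum. Starting
#' values are least squares on the logit-transformed response and a
#' method-of-moments precision.
#'
#' Rates must lie strictly in (0, 1): zeros belong to the binomial hurdle
#' part, not here, and no automatic squeezing is applied.
#'
#' @param X design matrix.
#' @param rates response vector, all strictly inside (0, 1).
#' @return a `regression_fit` (family `beta`) with `phi` and `loglik`.
#' @export
fit_beta <- function(X, rates) {
  stopifnot(is.matrix(X), nrow(X) == length(rates))
  if (any(rates <= 0 | rates >= 1))
    stop_config(paste("rates must be strictly inside (0, 1);",
                      "fit zeros/ones with the hurdle split, not fit_beta"))
  if (qr(X)$rank < ncol(X)) stop_config("design matrix is rank deficient")
  k <- ncol(X)
  # internal column scaling: identical MLE, far better BFGS/Hessian
  # conditioning with raw-unit covariates and their products
  scl <- apply(abs(X), 2, max)
  scl[scl == 0] <- 1
  Xs <- sweep(X, 2, scl, "/")
  ystar <- qlogis(rates)
  beta0 <- stats::lm.fit(Xs, ystar)$coefficients
  mu0 <- stats::plogis(drop(Xs %*% beta0))
  # method-of-moments phi from the residual variance of the logit fit
  v <- stats::var(rates - mu0)
  phi0 <- max(mean(mu0 * (1 - mu0)) / max(v, 1e-8) - 1, 1)
  theta0 <- c(beta0, log(phi0))
  opt <- stats::optim(theta0, beta_negll, beta_negll_grad, X = Xs, y = rates,
                      method = "BFGS", hessian = TRUE,
                      control = list(maxit = 2000, reltol = 1e-13))
  est <- opt$par[seq_len(k)] / scl
  phi <- unname(exp(opt$par[k + 1]))
  H <- opt$hessian
  cov_ok <- all(is.finite(H)) && rcond(H) > 1e-14
  se <- rep(NA_real_, k)
  if (cov_ok) {
    d <- diag(solve(H))[seq_len(k)]
    if (any(d <= 0)) cov_ok <- FALSE else se <- sqrt(d) / scl
  }
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  grad_norm <- sqrt(sum(beta_negll_grad(opt$par, Xs, rates)^2))
  conv <- opt$convergence == 0 && cov_ok
  new_regression_fit("beta", "logit", colnames(X), est, se, z, p, phi = phi,
                     loglik = -opt$value, n = nrow(X), converged = conv,
                     extra = list(grad_norm = grad_norm))
}

#' Backward elimination of non-significant interaction terms
#'
#' Starting from all requested main effects plus all requested two-way
#' interactions, drops the interaction with the largest two-sided Wald p
#' value, refits, and repeats until every remaining interaction has
#' p < `alpha`. Main effects are never dropped. Each removal is recorded in
#' a ledger.
#'
#' @param fit_fun function `(X, y) -> regression_fit`.
#' @param covariates covariate data.frame (see [design_matrix()]).
#' @param response response vector passed to `fit_fun`.
#' @param main_effects character vector of main-effect terms (intercept
#'   added automatically).
#' @param interactions character vector of `"a:b"` interaction terms;
#'   defaults to all pairs of `main_effects`.
#' @param alpha Wald significance level for keeping an interaction.
#' @return list with `fit` (final `regression_fit`), `terms`, and `dropped`
#'   (data.frame ledger: term, p value, step).
#' @export
prune_interactions <- function(fit_fun, covariates, response,
                               main_effects, interactions = NULL,
                               alpha = 0.05) {
  if (is.null(interactions)) {
    cmb <- utils::combn(main_effects, 2)
    interactions <- apply(cmb, 2, paste, collapse = ":")
  }
  terms <- c("intercept", main_effects, interactions)
  ledger <- data.frame(term = character(0), p_value = numeric(0),
                       step = integer(0))
  step <- 0L
  repeat {
    X <- design_matrix(covariates, terms)
    fit <- fit_fun(X, response)
    if (!isTRUE(fit$converged))
      stop_config("fit failed to converge during pruning (%s); %d term(s) dropped so far",
                  fit$diagnostic %||% "no diagnostic", nrow(ledger))
    inter_now <- intersect(interactions, terms)
    if (!length(inter_now)) break
    pv <- fit$p[inter_now]
    pv[is.na(pv)] <- 1  # inestimable interaction: first to go
    worst <- inter_now[which.max(pv)]
    if (max(pv) < alpha) break
    step <- step + 1L
    ledger <- rbind(ledger, data.frame(term = worst, p_value = max(pv),
                                       step = step))
    terms <- setdiff(terms, worst)
  }
  list(fit = fit, terms = terms, dropped = ledger)
}

#' Fit the two-part hurdle model for zone occurrence rates
#'
#' The occurrence rate of a water body is zero-inflated: some zones have no
#' Fucus at all. The hurdle model therefore splits the data into (i) a
#' binomial presence/absence part over all zones and (ii) a truncated
#' positive part over zones with a nonzero rate, fitted by beta regression.
#' Interactions are pruned on the positive part first; the binomial part is
#' then fitted with the same main effects plus only those interactions that
#' survived in the positive part, which keeps the two parts comparable.
#'
#' Rates may be supplied in percent (0-100); values above 1 are divided by
#' 100 once at this boundary and all internal math is on (0, 1).
#'
#' @param covariates covariate data.frame, one row per zone.
#' @param rates occurrence rates, in \[0, 1) or percent \[0, 100).
#' @param main_effects main-effect terms (default the five environmental
#'   variables with exposure on the log scale).
#' @param alpha pruning significance level.
#' @param prune if `FALSE`, skip pruning and keep all interactions.
#' @return a `hurdle_fit`: list with `positive`, `binomial`
#'   (`regression_fit`s), `dropped_terms`, `terms_positive`,
#'   `terms_binomial`.
#' @export
fit_hurdle <- function(covariates, rates,
                       main_effects = c("salinity", "log_exposure", "secchi",
                                        "ntot", "ptot"),
                       alpha = 0.05, prune = TRUE) {
  stopifnot(nrow(covariates) == length(rates))
  if (any(rates < 0)) stop_config("rates must be non-negative")
  if (any(rates > 1)) rates <- rates / 100
  if (any(rates >= 1)) stop_config("rates must be below 1 (or 100%%)")
  pos <- rates > 0
  presence <- as.numeric(pos)
  if (sum(pos) < 10)
    stop_config("need at least 10 zones with positive rates, got %d", sum(pos))
  degenerate_binomial <- all(pos)
  if (prune) {
    pr <- prune_interactions(fit_beta, covariates[pos, , drop = FALSE],
                             rates[pos], main_effects, alpha = alpha)
    pos_fit <- pr$fit
    pos_terms <- pr$terms
    ledger <- pr$dropped
  } else {
    cmb <- utils::combn(main_effects, 2)
    pos_terms <- c("intercept", main_effects,
                   apply(cmb, 2, paste, collapse = ":"))
    pos_fit <- fit_beta(design_matrix(covariates[pos, , drop = FALSE],
                                      pos_terms), rates[pos])
    ledger <- data.frame(term = character(0), p_value = numeric(0),
                         step = integer(0))
  }
  bin_terms <- pos_terms
  bin_fit <- if (degenerate_binomial) {
    warning("no zero-rate zones: binomial part is degenerate", call. = FALSE)
    NULL
  } else {
    fit_binomial(design_matrix(covariates, bin_terms), presence)
  }
  structure(list(positive = pos_fit, binomial = bin_fit,
                 dropped_terms = ledger, terms_positive = pos_terms,
                 terms_binomial = bin_terms,
                 degenerate_binomial = degenerate_binomial),
            class = "hurdle_fit")
}

#' @export
print.hurdle_fit <- function(x, ...) {
  cat("Hurdle model for zone occurrence rates\n")
  cat(sprintf("Positive truncated beta part (n = %d):\n", x$positive$n))
  print(coef_table(x$positive), digits = 4)
  if (!is.null(x$binomial)) {
    cat(sprintf("Binomial presence/absence part (n = %d):\n", x$binomial$n))
    print(coef_table(x$binomial), digits = 4)
  } else cat("Binomial part degenerate (no zero zones)\n")
  if (nrow(x$dropped_terms))
    cat("Dropped interactions:",
        paste(x$dropped_terms$term, collapse = ", "), "\n")
  invisible(x)
}

#' Predict expected occurrence rates from a hurdle fit
#'
#' Merges the two parts by multiplication:
#' `E[rate] = P(presence) * E[rate | rate > 0]`, both on the response scale.
#'
#' @param fit a `hurdle_fit`.
#' @param covariates new covariate data.frame.
#' @return numeric vector of expected rates in (0, 1).
#' @export
predict_hurdle <- function(fit, covariates) {
  stopifnot(inherits(fit, "hurdle_fit"))
  mu <- stats::plogis(drop(design_matrix(covariates, fit$terms_positive) %*%
                             fit$positive$estimates))
  p_pres <- if (is.null(fit$binomial)) 1 else
    stats::plogis(drop(design_matrix(covariates, fit$terms_binomial) %*%
                         fit$binomial$estimates))
  p_pres * mu
}

#' Export a hurdle fit to JSON and CSV
#'
#' Writes the full fit (terms, estimates, standard errors, z, p, precision,
#' log-likelihoods, pruning ledger) to JSON, and optionally a combined
#' coefficient table in the two-part layout used for reporting.
#'
#' @param fit a `hurdle_fit`.
#' @param json_path,csv_path output paths (`NULL` to skip either).
#' @return invisibly, the list written to JSON.
#' @export
write_hurdle_fit <- function(fit, json_path = NULL, csv_path = NULL) {
  part <- function(f) if (is.null(f)) NULL else list(
    family = f$family, terms = f$terms, estimates = unname(f$estimates),
    se = unname(f$se), statistic = unname(f$statistic), p = unname(f$p),
    phi = f$phi, loglik = f$loglik, n = f$n, converged = f$converged)
  obj <- list(positive = part(fit$positive), binomial = part(fit$binomial),
              dropped_terms = fit$dropped_terms)
  if (!is.null(json_path))
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  if (!is.null(csv_path)) {
    tab <- coef_table(fit$positive)
    names(tab)[-1] <- paste0("positive_", names(tab)[-1])
    if (!is.null(fit$binomial)) {
      bt <- coef_table(fit$binomial)
      names(bt)[-1] <- paste0("binomial_", names(bt)[-1])
      tab <- merge(tab, bt, by = "term", sort = FALSE)
    }
    utils::write.csv(tab, csv_path, row.names = FALSE)
  }
  invisible(obj)
}
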