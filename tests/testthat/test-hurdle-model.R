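test_that("design_matrix builds intercept, log exposure and products", {
  tab <- data.frame(salinity = c(3, 4, 5, 6, 2), secchi = c(1, 2, 3, 4, 5),
                    exposure = c(1, 10, 100, 1e3, 1e4),
                    ntot = c(300, 310, 320, 330, 340))
  X <- design_matrix(tab, c("intercept"))
  expect_equal(unname(X[, 1]), rep(1, 5))
  X2 <- design_matrix(tab, c("intercept", "salinity", "secchi",
                             "salinity:secchi", "log_exposure"))
  expect_equal(X2[, "salinity:secchi"], X2[, "salinity"] * X2[, "secchi"])
  expect_equal(unname(X2[1, "log_exposure"]), 0)
  expect_equal(unname(X2[3, "log_exposure"]), log(100))
  expect_error(design_matrix(data.frame(exposure = c(1, -2)),
                             c("log_exposure")), "exposure")
  expect_error(design_matrix(tab, "ptot"), "not found")
})

test_that("fit_binomial: closed forms, separation, SEs", {
  # intercept-only with balanced response
  X <- matrix(1, 126, 1, dimnames = list(NULL, "intercept"))
  f0 <- fit_binomial(X[1:126, , drop = FALSE], rep(c(0, 1), 63))
  expect_equal(unname(f0$estimates), 0, tolerance = 1e-8)
  # intercept-only MLE is logit of the sample fraction (106 of 126)
  y <- c(rep(1, 106), rep(0, 20))
  f1 <- fit_binomial(X, y)
  expect_equal(unname(f1$estimates), qlogis(106 / 126), tolerance = 1e-8)
  expect_equal(unname(f1$se), sqrt(1 / (126 * (106 / 126) * (20 / 126))),
               tolerance = 1e-6)
  # complete separation is flagged, not silently returned
  Xs <- cbind(intercept = 1, x = c(-2, -1, 1, 2, 3, 4))
  fs <- fit_binomial(Xs, c(0, 0, 1, 1, 1, 1))
  expect_false(fs$converged)
  expect_match(fs$diagnostic, "separation")
  expect_error(fit_binomial(X, c(rep(2, 126))), "0/1")
})

test_that("binomial MLE matches exhaustive grid search on small problems", {
  set.seed(14)
  for (rep in 1:3) {
    n <- 30
    x <- rnorm(n)
    eta <- 0.4 + 0.9 * x
    y <- rbinom(n, 1, plogis(eta))
    X <- cbind(intercept = 1, x = x)
    fit <- fit_binomial(X, y)
    nll <- function(b0, b1) {
      p <- plogis(b0 + b1 * x)
      -sum(y * log(p) + (1 - y) * log(1 - p))
    }
    # exhaustive two-stage 2-D grid, independent of the IRLS path
    coarse <- expand.grid(b0 = seq(-3, 3, by = 0.05),
                          b1 = seq(-3, 4, by = 0.05))
    cb <- coarse[which.min(mapply(nll, coarse$b0, coarse$b1)), ]
    fine <- expand.grid(b0 = seq(cb$b0 - 0.1, cb$b0 + 0.1, by = 5e-4),
                        b1 = seq(cb$b1 - 0.1, cb$b1 + 0.1, by = 5e-4))
    fb <- fine[which.min(mapply(nll, fine$b0, fine$b1)), ]
    expect_lt(abs(unname(fit$estimates["intercept"]) - fb$b0), 1e-3)
    expect_lt(abs(unname(fit$estimates["x"]) - fb$b1), 1e-3)
  }
})

test_that("fit_beta: symmetry, grid-search oracle, likelihood ascent", {
  set.seed(15)
  # symmetric rates: intercept ~ 0
  r_sym <- c(runif(40, 0.2, 0.48), 1 - runif(40, 0.2, 0.48))
  X1 <- matrix(1, 80, 1, dimnames = list(NULL, "intercept"))
  fsym <- fit_beta(X1, r_sym)
  expect_equal(unname(fsym$estimates), 0, tolerance = 0.08)
  expect_true(fsym$converged)
  expect_lt(fsym$grad_norm, 1e-4)
  # dense 2-parameter grid search oracle (intercept + phi) on 25 obs
  y25 <- rbeta(25, 0.4 * 12, 0.6 * 12)
  X25 <- matrix(1, 25, 1, dimnames = list(NULL, "intercept"))
  fit25 <- fit_beta(X25, y25)
  ll <- function(b0, phi) {
    mu <- plogis(b0)
    sum(dbeta(y25, mu * phi, (1 - mu) * phi, log = TRUE))
  }
  grid <- expand.grid(b0 = seq(-2, 2, by = 5e-4),
                      phi = exp(seq(log(1), log(100), length.out = 800)))
  lls <- mapply(ll, grid$b0, grid$phi)
  best <- grid[which.max(lls), ]
  expect_lt(abs(unname(fit25$estimates) - best$b0), 1e-3)
  expect_equal(fit25$loglik, max(lls), tolerance = 1e-4)
  expect_gte(fit25$loglik, ll(qlogis(mean(y25)), 5))  # ascent vs naive start
  # zeros and ones are rejected with guidance toward the hurdle split
  expect_error(fit_beta(X1, c(r_sym[-1], 0)), "hurdle")
  expect_error(fit_beta(X1, c(r_sym[-1], 1)), "hurdle")
})

test_that("fit_beta recovers slope models and is shift-invariant", {
  set.seed(16)
  n <- 400
  x <- runif(n, 0, 4)
  mu <- plogis(-1 + 0.8 * x)
  y <- rbeta(n, mu * 30, (1 - mu) * 30)
  X <- cbind(intercept = 1, x = x)
  fit <- fit_beta(X, y)
  expect_equal(unname(fit$estimates), c(-1, 0.8), tolerance = 0.1)
  expect_equal(fit$phi, 30, tolerance = 0.25 * 30)
  # adding a constant to the covariate moves only the intercept
  X2 <- cbind(intercept = 1, x = x + 10)
  fit2 <- fit_beta(X2, y)
  expect_equal(unname(fit2$estimates["x"]), unname(fit$estimates["x"]),
               tolerance = 1e-4)
  expect_equal(unname(fit2$estimates["intercept"]),
               unname(fit$estimates["intercept"] - 10 * fit$estimates["x"]),
               tolerance = 1e-3)
})

test_that("prune_interactions drops only non-significant interactions", {
  set.seed(17)
  n <- 300
  tab <- data.frame(salinity = runif(n, 2, 6.5), secchi = runif(n, 1, 8),
                    exposure = exp(runif(n, log(1e3), log(1e6))))
  # strong salinity:secchi effect only
  eta <- -0.5 + 0.3 * tab$salinity + 0.2 * tab$secchi -
    0.15 * tab$salinity * tab$secchi
  y <- rbeta(n, plogis(eta) * 40, (1 - plogis(eta)) * 40)
  pr <- prune_interactions(fit_beta, tab, y,
                           c("salinity", "secchi", "log_exposure"))
  expect_true("salinity:secchi" %in% pr$terms)
  expect_false(any(c("salinity:log_exposure", "secchi:log_exposure")
                   %in% pr$terms))
  expect_equal(sort(pr$dropped$term),
               sort(c("salinity:log_exposure", "secchi:log_exposure")))
  # main effects are never dropped even when truly zero
  y0 <- rbeta(n, 0.4 * 40, 0.6 * 40)
  pr0 <- prune_interactions(fit_ols, tab, qlogis(y0),
                            c("salinity", "secchi", "log_exposure"))
  expect_true(all(c("salinity", "secchi", "log_exposure") %in% pr0$terms))
  expect_false(any(grepl(":", pr0$terms)))
})

test_that("fit_hurdle splits parts correctly and predicts by product", {
  cfg <- sim_config(seed = 20)
  zones <- generate_zones(cfg)
  oc <- simulate_zone_outcomes(zones, cfg$hurdle_positive,
                               cfg$hurdle_binomial, seed = 21)
  hf <- fit_hurdle(zones, oc$rate, prune = FALSE)
  expect_equal(hf$positive$n, sum(oc$rate > 0))
  expect_equal(hf$binomial$n, 126)
  # percent input gives the identical fit (units contract)
  # (r * 100) / 100 differs from r only in the last float bit
  hf_pct <- fit_hurdle(zones, oc$rate * 100, prune = FALSE)
  expect_equal(hf_pct$positive$estimates, hf$positive$estimates,
               tolerance = 1e-5)
  # merged prediction = P(presence) x beta mean, hand-computed on 3 rows
  nd <- zones[c(2, 60, 110), ]
  pred <- predict_hurdle(hf, nd)
  pbin <- plogis(drop(design_matrix(nd, hf$terms_binomial) %*%
                        hf$binomial$estimates))
  pbeta <- plogis(drop(design_matrix(nd, hf$terms_positive) %*%
                         hf$positive$estimates))
  expect_equal(pred, pbin * pbeta, tolerance = 1e-12)
  expect_true(all(pred > 0 & pred < 1))
  # zero-free data: binomial part degenerate, flagged
  rp <- pmin(pmax(oc$mu, 0.05), 0.95)
  expect_warning(hf0 <- fit_hurdle(zones, rp, prune = FALSE), "degenerate")
  expect_null(hf0$binomial)
  expect_equal(predict_hurdle(hf0, nd),
               plogis(drop(design_matrix(nd, hf0$terms_positive) %*%
                             hf0$positive$estimates)), tolerance = 1e-12)
})

test_that("hurdle fit exports to JSON and a two-part coefficient table", {
  cfg <- sim_config(seed = 23)
  zones <- generate_zones(cfg)
  oc <- simulate_zone_outcomes(zones, cfg$hurdle_positive,
                               cfg$hurdle_binomial, seed = 24)
  hf <- fit_hurdle(zones, oc$rate, prune = FALSE)
  jp <- withr::local_tempfile(fileext = ".json")
  cp <- withr::local_tempfile(fileext = ".csv")
  write_hurdle_fit(hf, jp, cp)
  back <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(back$positive$phi, hf$positive$phi, tolerance = 1e-10)
  expect_equal(back$binomial$n, 126)
  tab <- read.csv(cp)
  expect_true(all(c("positive_estimate", "binomial_estimate") %in% names(tab)))
  expect_equal(nrow(tab), length(hf$terms_positive))
})
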