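#' True regression parameters for simulation
#'
#' Ordered term names with their coefficient values, plus the beta precision
#' for the positive hurdle part. An `NA` intercept means "calibrate at
#' generation time" so that a stated marginal target is met (e.g. the
#' fraction of zones with any Fucus, or the mean log lower limit): the
#' calibration is a deterministic root-find given the simulated covariates,
#' not a tuning loop.
#'
#' @param terms character vector of term names (see [design_matrix()]).
#' @param values numeric coefficients, one per term.
#' @param phi beta precision > 0 (positive hurdle part only).
#' @param target marginal target used to calibrate an `NA` intercept:
#'   mean presence probability (binomial), mean of the beta mean `mu`
#'   (positive part), or mean log lower limit (depth-limit model).
#' @return a `true_params` list.
#' @export
true_params <- function(terms, values, phi = NULL, target = NULL) {
  if (length(terms) != length(values))
    stop_config("one value per term required")
  if (!is.null(phi) && phi <= 0) stop_config("phi must be > 0")
  structure(list(terms = terms, values = setNames(values, terms), phi = phi,
                 target = target), class = "true_params")
}

#' Default simulation truth
#'
#' The default coefficient sets used as ground truth by the generator: the
#' positive (truncated beta) and binomial parts of the occurrence-rate
#' hurdle model, and the log-linear model for the lower limit of the Fucus
#' zone. Intercepts are `NA` (calibrated to the stated marginal targets:
#' 106/126 zones with Fucus present, mean positive occurrence rate 0.30,
#' mean lower limit 3 m on the log scale).
#'
#' @name default_truth
#' @return a `true_params` object.
#' @export
default_hurdle_positive <- function() true_params(
  terms = c("intercept", "salinity", "log_exposure", "secchi", "ntot",
            "ptot", "salinity:secchi"),
  values = c(NA, 1.51, 0.04, 2.48, 0.002, -0.004, -0.45),
  phi = 10, target = 0.30)

#' @rdname default_truth
#' @export
default_hurdle_binomial <- function() true_params(
  terms = c("intercept", "salinity", "log_exposure", "secchi", "ntot",
            "ptot", "salinity:secchi"),
  values = c(NA, 1.37, 0.92, 3.81, -0.004, 0.02, -0.60),
  target = 106 / 126)

#' @rdname default_truth
#' @export
default_lowerlimit_params <- function() true_params(
  terms = c("intercept", "salinity", "log_exposure", "secchi", "ntot",
            "log_exposure:ntot", "salinity:secchi"),
  values = c(NA, 0.66, 0.27, 1.19, 0.005, -0.0005, -0.21),
  target = log(3))

#' Simulation configuration
#'
#' All knobs of the synthetic survey world, with defaults emulating the
#' Finnish coastal survey design: 126 water-body zones along a 2-6.5 PSU
#' salinity gradient, roughly 37 000 survey points, 328 dive transects with
#' embedded Fucus zones of which about 186 pass the substrate-continuation
#' filter. The five environmental grids are generated at their relative
#' resolutions (salinity 20 m, exposure 25 m, nutrients 100 m, Secchi
#' 300 m).
#'
#' @param n_zones number of water-body zones (>= 2).
#' @param n_points_per_zone survey points generated per zone.
#' @param n_transects dive transects generated (all carry a Fucus zone
#'   unless their true limit is shallower than the first sampling depth).
#' @param salinity_range,secchi_range,ntot_range,ptot_range covariate
#'   ranges (PSU, m, ug/L, ug/L).
#' @param exposure_range wave-exposure index range; sampled log-uniformly.
#' @param gradient_weight weight of the shared inshore-offshore axis in
#'   each covariate (0 = independent noise, 1 = perfectly collinear).
#' @param grid_noise cell noise amplitude as a fraction of each variable's
#'   range.
#' @param noise_smooth number of 3x3 mean-filter passes applied to the grid
#'   noise (0 = spatially uncorrelated).
#' @param zone_size zone rectangle edge length (m); must be a multiple of
#'   the coarsest cell size (300 m).
#' @param hard_fraction fraction of survey points that are
#'   hard-substrate-dominated.
#' @param depth_max maximum surveyed depth (m).
#' @param continuation_fraction fraction of transects where hard substrate
#'   continues below the Fucus zone (default 186/328).
#' @param hurdle_positive,hurdle_binomial,lowerlimit_params [true_params()]
#'   truth sets.
#' @param sigma_loglimit standard deviation of the Gaussian noise on the
#'   log lower limit.
#' @param photic_coefficient,light_fraction light-limit settings used when
#'   planting Fucus on potential sites.
#' @param seed root integer seed; all module substreams derive from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_zones = 126,
                       n_points_per_zone = 297,
                       n_transects = 328,
                       salinity_range = c(2, 6.5),
                       secchi_range = c(1, 8),
                       ntot_range = c(250, 550),
                       ptot_range = c(15, 40),
                       exposure_range = c(1e3, 1e6),
                       gradient_weight = 0.6,
                       grid_noise = 0.02,
                       noise_smooth = 0L,
                       zone_size = 600,
                       hard_fraction = 0.5,
                       depth_max = 12,
                       continuation_fraction = 186 / 328,
                       hurdle_positive = default_hurdle_positive(),
                       hurdle_binomial = default_hurdle_binomial(),
                       lowerlimit_params = default_lowerlimit_params(),
                       sigma_loglimit = 0.35,
                       photic_coefficient = 2.0,
                       light_fraction = 0.6,
                       seed = 1L) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_zones < 2) stop_config("n_zones must be >= 2")
  for (nm in c("salinity_range", "secchi_range", "ntot_range", "ptot_range",
               "exposure_range"))
    assert_range(cfg[[nm]], nm)
  if (cfg$exposure_range[1] <= 0) stop_config("exposure_range must be > 0")
  if (cfg$sigma_loglimit <= 0) stop_config("sigma_loglimit must be > 0")
  if (cfg$gradient_weight < 0 || cfg$gradient_weight > 1)
    stop_config("gradient_weight must be in [0, 1]")
  if (cfg$hard_fraction < 0 || cfg$hard_fraction > 1)
    stop_config("hard_fraction must be in [0, 1]")
  if (cfg$zone_size %% 300 != 0)
    stop_config("zone_size must be a multiple of 300 m (coarsest grid)")
  invisible(cfg)
}

#' Read or write a simulation configuration as JSON
#'
#' @param path JSON file path.
#' @param cfg a `sim_config`.
#' @return `read_sim_config` returns a `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("hurdle_positive", "hurdle_binomial", "lowerlimit_params"))
    if (!is.null(raw[[nm]]))
      raw[[nm]] <- true_params(raw[[nm]]$terms, unlist(raw[[nm]]$values),
                               phi = raw[[nm]]$phi,
                               target = raw[[nm]]$target)
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(cfg, path) {
  out <- unclass(cfg)
  for (nm in c("hurdle_positive", "hurdle_binomial", "lowerlimit_params"))
    out[[nm]] <- unclass(out[[nm]])
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

# mix a shared gradient axis with iid noise, mapped onto [lo, hi]
mix_axis <- function(u, noise, w, range) {
  range[1] + (range[2] - range[1]) * (w * u + (1 - w) * noise)
}

#' Generate water-body zones with covariate means
#'
#' Zones are axis-aligned rectangles tiling a planar, unitless coordinate
#' frame (no CRS: geodesy is irrelevant to the statistics). Covariate means
#' vary smoothly along an inshore-offshore axis (increasing x), with a
#' configurable weight of independent per-zone noise so that covariates are
#' realistically collinear: salinity, Secchi and exposure increase offshore,
#' nutrients decrease, and total phosphorus shares noise with total
#' nitrogen to mimic their strong observed correlation.
#'
#' @param config a [sim_config()].
#' @return data.frame: `zone_id`, rectangle bounds, axis position `u`, and
#'   the five covariate means (plus `log_exposure`).
#' @export
generate_zones <- function(config) {
  validate_sim_config(config)
  set.seed(seed_stream(config$seed, "zones"))
  n <- config$n_zones
  ncol_z <- ceiling(sqrt(n))
  nrow_z <- ceiling(n / ncol_z)
  i <- seq_len(n) - 1L
  col <- i %% ncol_z
  row <- i %/% ncol_z
  s <- config$zone_size
  # inshore-offshore axis: offshore distance grows with x (column)
  u <- if (ncol_z > 1) col / (ncol_z - 1) else rep(0.5, n)
  w <- config$gradient_weight
  e <- matrix(runif(5 * n), n, 5)
  rho_p <- 0.5  # shared noise fraction between the two nutrients
  e_ptot <- rho_p * e[, 3] + (1 - rho_p) * e[, 4]
  log_expo_range <- log(config$exposure_range)
  zones <- data.frame(
    zone_id = sprintf("Z%03d", seq_len(n)),
    xmin = col * s, xmax = (col + 1) * s,
    ymin = row * s, ymax = (row + 1) * s,
    u = u,
    salinity = mix_axis(u, e[, 1], w, config$salinity_range),
    secchi = mix_axis(u, e[, 2], w, config$secchi_range),
    ntot = mix_axis(1 - u, e[, 3], w, config$ntot_range),
    ptot = mix_axis(1 - u, e_ptot, w, config$ptot_range),
    log_exposure = mix_axis(u, e[, 5], w, log_expo_range)
  )
  zones$exposure <- exp(zones$log_exposure)
  zones
}

# cell sizes (m) of the five environmental grids
GRID_CELL_SIZES <- c(salinity = 20, exposure = 25, ntot = 100, ptot = 100,
                     secchi = 300)

smooth_once <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- m[c(1, 1:nr, nr), c(1, 1:nc, nc)]
  out <- matrix(0, nr, nc)
  for (di in 0:2) for (dj in 0:2)
    out <- out + pad[di + 1:nr, dj + 1:nc]
  out / 9
}

#' Generate the five environmental grids from zone means
#'
#' Each grid covers the zone tiling at its own resolution; a cell takes the
#' covariate mean of the zone containing its center plus uniform noise of
#' amplitude `grid_noise` x range (optionally smoothed into spatially
#' correlated noise). With zero noise the zonal mean over a zone equals the
#' zone mean exactly.
#'
#' @param zones output of [generate_zones()].
#' @param config a [sim_config()].
#' @return named list of [env_grid] objects
#'   (`salinity`, `exposure`, `ntot`, `ptot`, `secchi`).
#' @export
generate_grids <- function(zones, config) {
  set.seed(seed_stream(config$seed, "grids"))
  xmax <- max(zones$xmax); ymax <- max(zones$ymax)
  s <- config$zone_size
  ncol_z <- xmax / s; nrow_z <- ymax / s
  n <- nrow(zones)
  # zone lookup by (zone-row, zone-col); tiles beyond the last zone reuse it
  zone_of <- function(zc, zr) pmin(zr * ncol_z + zc + 1, n)
  ranges <- list(salinity = config$salinity_range,
                 exposure = config$exposure_range,
                 ntot = config$ntot_range, ptot = config$ptot_range,
                 secchi = config$secchi_range)
  grids <- list()
  for (v in names(GRID_CELL_SIZES)) {
    cs <- GRID_CELL_SIZES[[v]]
    nc <- ceiling(xmax / cs); nr <- ceiling(ymax / cs)
    xc <- ( seq_len(nc) - 0.5) * cs
    yc <- (nr - seq_len(nr) + 0.5) * cs  # top row first
    zc <- pmin(floor(outer(rep(1, nr), xc) / s), ncol_z - 1)
    zr <- pmin(floor(outer(yc, rep(1, nc)) / s), nrow_z - 1)
    vals <- matrix(zones[[v]][zone_of(zc, zr)], nr, nc)
    if (config$grid_noise > 0) {
      amp <- config$grid_noise * diff(ranges[[v]])
      noise <- matrix(runif(nr * nc, -amp, amp), nr, nc)
      if (config$noise_smooth > 0)
        for (k in seq_len(config$noise_smooth)) noise <- smooth_once(noise)
      vals <- vals + noise
      if (v == "exposure") vals <- pmax(vals, 1e-6)
    }
    grids[[v]] <- env_grid(vals, xll = 0, yll = 0, cell_size = cs,
                           variable = v)
  }
  grids
}

# allocate a total cover over classes by a Dirichlet draw (gamma ratios)
dirichlet_alloc <- function(n, k, alpha, total) {
  g <- matrix(rgamma(n * k, shape = alpha), n, k, byrow = TRUE)
  g / rowSums(g) * total
}

#' Generate survey points with substrate composition
#'
#' Uniform point locations within each zone; depths uniform on
#' `[0, depth_max]` so both lit and unlit seafloor occurs. Substrate covers
#' over the 11 field classes always sum to 100: a `hard_fraction` share of
#' points is hard-substrate-dominated (total hard cover 30-100%), the rest
#' carry under 10% hard cover, so the potential-site rule separates the two
#' groups exactly at the default threshold. Fucus is planted only on
#' potential sites, using the per-zone outcomes of
#' [simulate_zone_outcomes()]: within a zone with Fucus present, each
#' potential site is occupied independently with probability equal to the
#' zone's true occurrence rate.
#'
#' @param zones output of [generate_zones()].
#' @param grids output of [generate_grids()].
#' @param config a [sim_config()].
#' @param outcomes optional result of [simulate_zone_outcomes()]; generated
#'   from `config` if omitted.
#' @return data.frame of survey points (one row per point) with the 11
#'   substrate columns, `fucus_cover_pct`, and bookkeeping columns
#'   (`light_limit_m`, `potential_true`).
#' @export
generate_survey_points <- function(zones, grids, config, outcomes = NULL) {
  if (is.null(outcomes))
    outcomes <- simulate_zone_outcomes(zones, config$hurdle_positive,
                                       config$hurdle_binomial,
                                       seed = seed_stream(config$seed,
                                                          "outcomes"))
  set.seed(seed_stream(config$seed, "points"))
  npz <- config$n_points_per_zone
  n <- nrow(zones) * npz
  zi <- rep(seq_len(nrow(zones)), each = npz)
  pts <- data.frame(
    point_id = sprintf("P%06d", seq_len(n)),
    zone_id = zones$zone_id[zi],
    x = runif(n, zones$xmin[zi], zones$xmax[zi]),
    y = runif(n, zones$ymin[zi], zones$ymax[zi]),
    depth_m = runif(n, 0, config$depth_max),
    method = sample(c("video", "dive"), n, replace = TRUE,
                    prob = c(0.85, 0.15))
  )
  hard <- runif(n) < config$hard_fraction
  hard_total <- ifelse(hard, runif(n, 30, 100), runif(n, 0, 8))
  sub <- matrix(0, n, 11, dimnames = list(NULL, SUBSTRATE_CLASSES))
  sub[, HARD_CLASSES] <- dirichlet_alloc(n, 7, rep(1, 7), hard_total)
  soft <- setdiff(SUBSTRATE_CLASSES, HARD_CLASSES)
  sub[, soft] <- dirichlet_alloc(n, 4, rep(1, 4), 100 - hard_total)
  pts <- cbind(pts, as.data.frame(sub))
  secchi_at <- extract_at_points(grids$secchi, pts$x, pts$y)
  pts$light_limit_m <- light_limit_depth(
    photic_depth(secchi_at, config$photic_coefficient),
    config$light_fraction)
  pts$potential_true <- hard_cover(pts) >= 10 &
    pts$depth_m <= pts$light_limit_m
  rate <- outcomes$rate[match(pts$zone_id, outcomes$zone_id)]
  occupied <- pts$potential_true & runif(n) < rate
  pts$fucus_cover_pct <- ifelse(occupied, runif(n, 10, 90), 0)
  pts
}

# deterministic intercept calibration: find a such that
# mean(inv(a + offset)) == target, on the linear-predictor offsets
calibrate_intercept <- function(offset, target, inverse = stats::plogis) {
  f <- function(a) mean(inverse(a + offset)) - target
  stats::uniroot(f, interval = c(-50, 50), tol = 1e-10)$root
}

# linear predictor for a true_params set, calibrating an NA intercept
true_linear_predictor <- function(covariates, params,
                                  inverse = stats::plogis) {
  X <- design_matrix(covariates, params$terms)
  vals <- params$values
  if (is.na(vals["intercept"])) {
    if (is.null(params$target))
      stop_config("NA intercept requires a calibration target")
    offset <- drop(X[, params$terms != "intercept", drop = FALSE] %*%
                     vals[params$terms != "intercept"])
    vals["intercept"] <- calibrate_intercept(offset, params$target, inverse)
  }
  list(eta = drop(X %*% vals), values = vals)
}

#' Simulate per-zone Fucus presence and occurrence rates
#'
#' The generative inverse of the hurdle model: presence is Bernoulli with
#' probability `plogis(eta_binomial)`; zones with Fucus draw their
#' occurrence rate from `Beta(mu * phi, (1 - mu) * phi)` with
#' `mu = plogis(eta_positive)`; absent zones have rate 0. Draws that round
#' to exactly 0 or 1 in floating point are redrawn to keep the positive
#' support open. `NA` intercepts in either truth set are calibrated so the
#' stated marginal targets hold on this covariate draw.
#'
#' @param zones zone table with covariate means.
#' @param positive_params,binomial_params [true_params()] for the two
#'   parts; `positive_params$phi` must be > 0.
#' @param seed integer seed, or `NULL` to continue the current RNG stream
#'   (used by replicated experiments, which seed once).
#' @return data.frame: `zone_id`, `presence_prob`, `present`, `mu`, `rate`
#'   (0 for absent zones), plus the calibrated coefficient vectors as
#'   attributes `"positive_values"` and `"binomial_values"`.
#' @export
simulate_zone_outcomes <- function(zones, positive_params, binomial_params,
                                   seed = 1L) {
  if (is.null(positive_params$phi) || positive_params$phi <= 0)
    stop_config("positive part requires precision phi > 0")
  if (!is.null(seed)) set.seed(seed)
  bin <- true_linear_predictor(zones, binomial_params)
  pos <- true_linear_predictor(zones, positive_params)
  p_pres <- stats::plogis(bin$eta)
  mu <- stats::plogis(pos$eta)
  n <- nrow(zones)
  present <- rbinom(n, 1, p_pres) == 1
  phi <- positive_params$phi
  rate <- numeric(n)
  draw <- function(m) rbeta(length(m), m * phi, (1 - m) * phi)
  r <- draw(mu[present])
  while (any(bad <- r <= 0 | r >= 1)) r[bad] <- draw(mu[present][bad])
  rate[present] <- r
  structure(
    data.frame(zone_id = zones$zone_id, presence_prob = p_pres,
               present = present, mu = mu, rate = rate),
    positive_values = pos$values, binomial_values = bin$values)
}

#' Generate dive transects with embedded true lower limits
#'
#' Each transect runs from the shore outward with a monotone depth profile
#' sampled at 1 m depth intervals from 0 m down to `depth_max`. Its true
#' lower limit is `L = exp(eta + N(0, sigma_loglimit))` with `eta` the
#' linear predictor of the depth-limit truth at the transect's location
#' (covariates extracted from the grids). Points at depths `<= L` carry
#' Fucus cover of at least 10%; deeper points are below the belt. For a
#' `continuation_fraction` share of transects the substrate stays hard
#' below the limit (these pass the substrate-continuation filter); the rest
#' turn soft below the limit. Transects whose true limit exceeds
#' `depth_max` are flagged censored and excluded from the truth table.
#'
#' @param zones zone table (defines the domain extent).
#' @param grids environmental grids.
#' @param config a [sim_config()].
#' @return list with `points` (the transect table: `transect_id`,
#'   `distance_m`, `depth_m`, substrate columns, `fucus_cover_pct`) and
#'   `truth` (per-transect: head coordinates, covariates, `true_limit_m`,
#'   `continues`, `censored`).
#' @export
generate_transects <- function(zones, grids, config) {
  set.seed(seed_stream(config$seed, "transects"))
  nt <- config$n_transects
  xmax <- max(zones$xmax); ymax <- max(zones$ymax)
  head_x <- runif(nt, 0, xmax)
  head_y <- runif(nt, 0, ymax)
  cov <- data.frame(
    transect_id = sprintf("T%04d", seq_len(nt)),
    x = head_x, y = head_y,
    salinity = extract_at_points(grids$salinity, head_x, head_y),
    exposure = extract_at_points(grids$exposure, head_x, head_y),
    secchi = extract_at_points(grids$secchi, head_x, head_y),
    ntot = extract_at_points(grids$ntot, head_x, head_y),
    ptot = extract_at_points(grids$ptot, head_x, head_y)
  )
  lp <- true_linear_predictor(cov, config$lowerlimit_params,
                              inverse = identity)
  L <- exp(lp$eta + rnorm(nt, 0, config$sigma_loglimit))
  continues <- runif(nt) < config$continuation_fraction
  censored <- L > config$depth_max
  depths <- 0:config$depth_max
  npts <- length(depths)
  # depth increases monotonically with distance; 100 m transect
  dist <- seq(0, 100, length.out = npts)
  idx <- rep(seq_len(nt), each = npts)
  tp <- data.frame(
    transect_id = cov$transect_id[idx],
    x = head_x[idx], y = head_y[idx],
    distance_m = rep(dist, nt),
    depth_m = rep(depths, nt)
  )
  above <- tp$depth_m <= L[idx]
  n_all <- nrow(tp)
  cover <- ifelse(above, runif(n_all, 15, 80), runif(n_all, 0, 5))
  hard_here <- above | continues[idx]
  hard_total <- ifelse(hard_here, runif(n_all, 30, 100), runif(n_all, 0, 8))
  sub <- matrix(0, n_all, 11, dimnames = list(NULL, SUBSTRATE_CLASSES))
  sub[, HARD_CLASSES] <- dirichlet_alloc(n_all, 7, rep(1, 7), hard_total)
  soft <- setdiff(SUBSTRATE_CLASSES, HARD_CLASSES)
  sub[, soft] <- dirichlet_alloc(n_all, 4, rep(1, 4), 100 - hard_total)
  tp <- cbind(tp, as.data.frame(sub))
  tp$fucus_cover_pct <- cover
  truth <- cbind(cov, true_limit_m = L, continues = continues,
                 censored = censored)
  list(points = tp, truth = truth[!truth$censored, , drop = FALSE],
       truth_all = truth,
       lowerlimit_values = lp$values)
}

#' Run the full synthetic world once
#'
#' Convenience wrapper chaining zones, grids, zone outcomes, survey points
#' and transects under one root seed.
#'
#' @param config a [sim_config()].
#' @return list with `zones`, `grids`, `outcomes`, `points`, `transects`
#'   (the [generate_transects()] result), and `config`.
#' @export
simulate_survey <- function(config = sim_config()) {
  zones <- generate_zones(config)
  grids <- generate_grids(zones, config)
  outcomes <- simulate_zone_outcomes(zones, config$hurdle_positive,
                                     config$hurdle_binomial,
                                     seed = seed_stream(config$seed,
                                                        "outcomes"))
  points <- generate_survey_points(zones, grids, config, outcomes)
  transects <- generate_transects(zones, grids, config)
  list(zones = zones, grids = grids, outcomes = outcomes, points = points,
       transects = transects, config = config)
}
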