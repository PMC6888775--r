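test_that("generate_zones respects ranges, counts, and determinism", {
  cfg <- sim_config(seed = 11)
  zones <- generate_zones(cfg)
  expect_equal(nrow(zones), 126)
  expect_true(all(zones$salinity >= 2 & zones$salinity <= 6.5))
  expect_true(all(zones$secchi >= cfg$secchi_range[1] &
                    zones$secchi <= cfg$secchi_range[2]))
  expect_true(all(zones$exposure >= cfg$exposure_range[1] &
                    zones$exposure <= cfg$exposure_range[2]))
  # degenerate range pins the covariate
  z2 <- generate_zones(sim_config(n_zones = 2, salinity_range = c(3, 3)))
  expect_equal(z2$salinity, c(3, 3))
  # same seed twice: identical tables
  expect_identical(generate_zones(cfg), generate_zones(cfg))
  expect_error(sim_config(salinity_range = c(5, 2)), "min <= max")
  expect_error(sim_config(n_zones = 1), "n_zones")
})

test_that("grids honour resolutions, noise bounds, and zonal-mean recovery", {
  cfg <- small_config(grid_noise = 0)
  zones <- generate_zones(cfg)
  grids <- generate_grids(zones, cfg)
  # stated relative resolutions (salinity 20 m ... Secchi 300 m)
  expect_equal(grids$secchi$cell_size / grids$salinity$cell_size, 15)
  expect_equal(grids$secchi$cell_size / grids$exposure$cell_size, 12)
  expect_equal(grids$ntot$cell_size, 100)
  # zero noise: zonal mean equals the zone mean exactly
  for (i in c(1, 17, nrow(zones))) {
    expect_equal(zonal_mean(grids$salinity, zones[i, ]), zones$salinity[i])
    expect_equal(zonal_mean(grids$secchi, zones[i, ]), zones$secchi[i])
  }
  # with noise: values stay within range +- amplitude, zonal means close
  cfgn <- small_config(grid_noise = 0.02)
  gr <- generate_grids(zones, cfgn)
  amp <- 0.02 * diff(cfgn$secchi_range)
  expect_true(all(gr$secchi$values >= cfgn$secchi_range[1] - amp &
                    gr$secchi$values <= cfgn$secchi_range[2] + amp))
  expect_equal(zonal_mean(gr$secchi, zones[5, ]), zones$secchi[5],
               tolerance = amp)
})

test_that("survey points: simplex substrate, hard fraction, determinism", {
  cfg <- small_config()
  zones <- generate_zones(cfg)
  grids <- generate_grids(zones, cfg)
  pts <- generate_survey_points(zones, grids, cfg)
  expect_equal(nrow(pts), cfg$n_zones * cfg$n_points_per_zone)
  covers <- rowSums(as.matrix(pts[fucusstatus:::SUBSTRATE_CLASSES]))
  expect_true(all(abs(covers - 100) < 0.01))
  expect_true(all(pts$depth_m >= 0))
  expect_true(all(pts$method %in% c("dive", "video")))
  # hard_fraction = 0 -> no point reaches 10% hard substrate
  cfg0 <- small_config(hard_fraction = 0)
  pts0 <- generate_survey_points(zones, grids, cfg0)
  expect_equal(sum(rowSums(as.matrix(pts0[fucusstatus:::HARD_CLASSES])) >= 10), 0)
  # determinism
  pts_b <- generate_survey_points(zones, grids, cfg)
  expect_identical(pts, pts_b)
  # Fucus is planted only on potential sites (construction invariant)
  expect_true(all(pts$potential_true[pts$fucus_cover_pct > 0]))
})

test_that("zone outcomes follow the hurdle generative model", {
  cfg <- sim_config(seed = 5)
  zones <- generate_zones(cfg)
  # saturated-negative binomial intercept: everything absent
  bin_off <- true_params(c("intercept", "salinity"), c(-50, 0))
  pos <- cfg$hurdle_positive
  oc <- simulate_zone_outcomes(zones, pos, bin_off, seed = 1)
  expect_equal(sum(oc$present), 0)
  expect_equal(oc$rate, rep(0, 126))
  # symmetric positive part: mean rate across present zones ~ 0.5
  pos0 <- true_params(c("intercept", "salinity"), c(0, 0), phi = 50)
  bin_on <- true_params(c("intercept", "salinity"), c(50, 0))
  oc2 <- simulate_zone_outcomes(zones, pos0, bin_on, seed = 2)
  expect_equal(mean(oc2$rate[oc2$present]), 0.5, tolerance = 0.05)
  # phi -> infinity: rates equal the inverse-logit mean (noise-free)
  pos_inf <- cfg$hurdle_positive
  pos_inf$phi <- 1e9
  oc3 <- simulate_zone_outcomes(zones, pos_inf, bin_on, seed = 3)
  expect_equal(oc3$rate, oc3$mu, tolerance = 1e-3)
  # defaults: about 20 of 126 zones are Fucus-free (calibrated marginal)
  set.seed(44)
  zeros <- replicate(30, {
    oc <- simulate_zone_outcomes(zones, cfg$hurdle_positive,
                                 cfg$hurdle_binomial, seed = NULL)
    sum(!oc$present)
  })
  expect_equal(mean(zeros), 20, tolerance = 0.15)
  expect_error(
    simulate_zone_outcomes(zones, true_params("intercept", 0, phi = -1),
                           bin_on),
    "phi")
  expect_true(all(oc2$rate >= 0 & oc2$rate < 1))
})

test_that("transects embed their true lower limits and the retention funnel", {
  cfg <- sim_config(seed = 6)
  zones <- generate_zones(cfg)
  grids <- generate_grids(zones, cfg)
  tr <- generate_transects(zones, grids, cfg)
  expect_equal(length(unique(tr$points$transect_id)), 328)
  # fixed intercept, zero effects, no noise: every limit exactly 3 m
  cfg_fix <- cfg
  cfg_fix$lowerlimit_params <- true_params(
    c("intercept", "salinity"), c(log(3), 0), target = NULL)
  cfg_fix$sigma_loglimit <- 1e-9
  tr_fix <- generate_transects(zones, grids, cfg_fix)
  expect_equal(tr_fix$truth$true_limit_m, rep(3, 328), tolerance = 1e-6)
  # retained count: continuation fraction targets 186 of 328
  res <- assess_transects(tr$points)
  expect_equal(sum(res$retained), 186, tolerance = 0.12)
  # continuation fraction 1.0: every detected-and-uncensored zone retained
  cfg_all <- cfg
  cfg_all$continuation_fraction <- 1
  tr_all <- generate_transects(zones, grids, cfg_all)
  res_all <- assess_transects(tr_all$points)
  # censored transects end inside the belt and can never be retained
  uncensored <- res_all$transect_id %in% tr_all$truth$transect_id
  det <- res_all$zone_detected & uncensored
  expect_equal(res_all$retained[det], rep(TRUE, sum(det)))
})

test_that("sim_config round-trips through JSON", {
  cfg <- sim_config(n_zones = 12, seed = 99, grid_noise = 0.05)
  path <- withr::local_tempfile(fileext = ".json")
  write_sim_config(cfg, path)
  cfg2 <- read_sim_config(path)
  expect_equal(cfg2$n_zones, 12)
  expect_equal(cfg2$seed, 99)
  expect_equal(cfg2$hurdle_positive$values, cfg$hurdle_positive$values)
  expect_equal(cfg2$lowerlimit_params$target, log(3))
})
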