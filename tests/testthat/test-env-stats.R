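test_that("ESRI ASCII grids round-trip through disk", {
  set.seed(9)
  m <- matrix(round(runif(35, -5, 20), 4), 5, 7)
  m[2, 3] <- NA
  g <- env_grid(m, xll = 100, yll = 200, cell_size = 25, variable = "secchi")
  path <- withr::local_tempfile(fileext = ".asc")
  write_esri_ascii(g, path)
  g2 <- read_esri_ascii(path, variable = "secchi")
  expect_equal(g2$values, g$values)
  expect_equal(g2$cell_size, 25)
  expect_equal(g2$xll, 100)
  expect_equal(g2$yll, 200)
})

test_that("extract_at_points matches direct index lookup", {
  set.seed(21)
  m <- matrix(rnorm(12 * 9), 12, 9)
  g <- env_grid(m, xll = 50, yll = -30, cell_size = 10)
  # cell centers map to their own values
  expect_equal(extract_at_points(g, 50 + (3 - 0.5) * 10,
                                 -30 + (12 - 4 + 0.5) * 10),
               m[4, 3])
  # 20 random in-extent points vs hand-indexed lookup
  x <- runif(20, 50, 50 + 9 * 10)
  y <- runif(20, -30, -30 + 12 * 10)
  manual <- vapply(seq_len(20), function(i) {
    col <- floor((x[i] - 50) / 10) + 1
    row <- 12 - (floor((y[i] + 30) / 10) + 1) + 1
    m[row, col]
  }, numeric(1))
  expect_equal(extract_at_points(g, x, y), manual)
  # constant grid -> constant output
  gc <- env_grid(matrix(3.5, 4, 4), cell_size = 5)
  expect_equal(extract_at_points(gc, runif(5, 0, 20), runif(5, 0, 20)),
               rep(3.5, 5))
  expect_warning(v <- extract_at_points(g, 1e6, 0), "outside")
  expect_true(is.na(v))
})

test_that("zonal_mean matches exhaustive cell-center loop", {
  set.seed(4)
  m <- matrix(runif(100), 10, 10)
  g <- env_grid(m, xll = 0, yll = 0, cell_size = 1)
  zones <- list(
    list(xmin = 0, xmax = 10, ymin = 0, ymax = 10),
    list(xmin = 2.2, xmax = 7.9, ymin = 1.1, ymax = 4.5),
    list(xmin = 0, xmax = 1, ymin = 9, ymax = 10),
    list(xmin = 3, xmax = 5, ymin = 3, ymax = 4))
  for (z in zones) {
    vals <- c()
    for (r in 1:10) for (cc in 1:10) {
      xc <- cc - 0.5
      yc <- 10 - r + 0.5
      if (xc >= z$xmin && xc < z$xmax && yc >= z$ymin && yc < z$ymax)
        vals <- c(vals, m[r, cc])
    }
    expect_equal(zonal_mean(g, z), mean(vals))
  }
  # two specific cells valued 1 and 3
  g2 <- env_grid(matrix(c(1, 3, 5, 7), 2, 2), cell_size = 1)
  expect_equal(zonal_mean(g2, list(xmin = 0, xmax = 2, ymin = 1, ymax = 2)),
               mean(c(1, 5)))
  expect_warning(out <- zonal_mean(g2, list(xmin = 50, xmax = 51,
                                            ymin = 0, ymax = 1)),
                 "no cell centers")
  expect_true(is.na(out))
  # storage-order invariance: transposing the world symmetrically
  zc <- list(xmin = 0, xmax = 2, ymin = 0, ymax = 2)
  expect_equal(zonal_mean(g2, zc), mean(c(1, 3, 5, 7)))
})

test_that("correlation_matrix equals two-pass textbook formula", {
  set.seed(12)
  n <- 60
  tab <- data.frame(a = rnorm(n), b = rnorm(n))
  tab$c <- 0.7 * tab$a + rnorm(n, 0, 0.4)
  cm <- correlation_matrix(tab)
  twopass <- function(x, y) {
    mx <- mean(x); my <- mean(y)
    sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
  }
  for (i in 1:3) for (j in 1:3)
    expect_equal(cm$r[i, j], twopass(tab[[i]], tab[[j]]), tolerance = 1e-12)
  # p values match cor.test
  ct <- stats::cor.test(tab$a, tab$c)
  expect_equal(cm$p["a", "c"], ct$p.value, tolerance = 1e-10)
  expect_equal(diag(cm$r), c(a = 1, b = 1, c = 1))
  # perfect correlations
  d <- data.frame(x = 1:10, y = -(1:10))
  cm2 <- correlation_matrix(d)
  expect_equal(cm2$r["x", "y"], -1)
  expect_warning(correlation_matrix(data.frame(x = 1:5, z = rep(2, 5))),
                 "zero-variance")
  expect_error(correlation_matrix(data.frame(x = 1:2, y = 2:3)), "3 complete")
})

test_that("collinearity_screen drops configured victims only", {
  r <- diag(3)
  dimnames(r) <- list(c("ntot", "ptot", "secchi"), c("ntot", "ptot", "secchi"))
  r["ntot", "ptot"] <- r["ptot", "ntot"] <- 0.84
  expect_equal(as.character(collinearity_screen(r)), "ptot")
  r2 <- r; r2["ntot", "ptot"] <- r2["ptot", "ntot"] <- 0.5
  expect_length(collinearity_screen(r2), 0)
  expect_length(collinearity_screen(r, threshold = 1.01), 0)
  # unconfigured collinear pair: reported, nothing dropped
  r3 <- r
  r3["ntot", "secchi"] <- r3["secchi", "ntot"] <- -0.9
  expect_message(out <- collinearity_screen(r3), "no configured victim")
  expect_equal(as.character(out), "ptot")
  expect_setequal(attr(out, "pairs"), c("ntot|ptot", "ntot|secchi"))
})

test_that("synthetic transect covariates reproduce the nutrient correlation", {
  # stochastic structural check on the generator's collinearity design
  cfg <- sim_config(seed = 3)
  zones <- generate_zones(cfg)
  set.seed(8)
  cov <- fucusstatus:::sample_transect_covariates(zones, 400, cfg)
  cm <- correlation_matrix(cov[c("salinity", "secchi", "ntot", "ptot")])
  expect_gt(cm$r["ntot", "ptot"], 0.7)
  expect_lt(cm$r["ntot", "ptot"], 0.95)
  expect_gt(cm$r["salinity", "secchi"], 0.4)
  expect_lt(cm$r["salinity", "ntot"], -0.4)
})

test_that("zones round-trip through GeoJSON", {
  cfg <- sim_config(n_zones = 6, seed = 2)
  zones <- generate_zones(cfg)
  path <- withr::local_tempfile(fileext = ".geojson")
  write_zones_geojson(zones, path)
  back <- read_zones_geojson(path)
  expect_equal(back$zone_id, zones$zone_id)
  expect_equal(back$salinity, zones$salinity, tolerance = 1e-12)
  expect_equal(back$xmax, zones$xmax)
})
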