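#' Habitat-potential configuration
#'
#' Settings of the potential-site rule: a surveyed site is potential Fucus
#' habitat when it has at least `hard_substrate_threshold_pct` hard
#' substrate (rock, boulders, stones or gravel) and lies no deeper than the
#' local light limit, i.e. `light_fraction` (default 60%) of the photic
#' depth derived from Secchi depth. Water bodies with fewer than
#' `min_sites_per_zone` potential sites are excluded from occurrence-rate
#' reporting because their survey coverage is too thin.
#'
#' `photic_coefficients` converts Secchi depth to photic depth (1% of
#' surface PAR). The quartile conversion used operationally is not public,
#' so the default is a single documented coefficient of 2.0; a piecewise
#' table keyed by Secchi quartile breakpoints may be supplied instead as
#' `list(breaks = c(...), coefficients = c(...))` with
#' `length(coefficients) == length(breaks) + 1`.
#'
#' @param hard_substrate_threshold_pct percent hard cover required (0, 100].
#' @param photic_coefficients single multiplier or piecewise table.
#' @param light_fraction fraction of the photic depth lit enough for Fucus,
#'   in (0, 1].
#' @param min_sites_per_zone minimum potential sites for a zone to be kept.
#' @return a `potential_config` list.
#' @export
potential_config <- function(hard_substrate_threshold_pct = 10,
                             photic_coefficients = 2.0,
                             light_fraction = 0.6,
                             min_sites_per_zone = 10) {
  if (hard_substrate_threshold_pct <= 0 || hard_substrate_threshold_pct > 100)
    stop_config("hard_substrate_threshold_pct must be in (0, 100]")
  if (light_fraction <= 0 || light_fraction > 1)
    stop_config("light_fraction must be in (0, 1]")
  if (min_sites_per_zone < 1) stop_config("min_sites_per_zone must be >= 1")
  structure(list(hard_substrate_threshold_pct = hard_substrate_threshold_pct,
                 photic_coefficients = photic_coefficients,
                 light_fraction = light_fraction,
                 min_sites_per_zone = min_sites_per_zone),
            class = "potential_config")
}

#' Photic depth from Secchi depth
#'
#' Converts Secchi depth (m) to the depth of the photic zone (depth at
#' which 1% of surface PAR remains) by multiplying with a conversion
#' coefficient. With a piecewise table, the coefficient is looked up by the
#' Secchi value's position among the supplied breakpoints (clearer water
#' gets a larger multiplier).
#'
#' @param secchi_m Secchi depth(s) in metres, > 0.
#' @param photic_coefficients single coefficient or
#'   `list(breaks=, coefficients=)` (see [potential_config()]).
#' @return photic depth(s) in metres.
#' @export
photic_depth <- function(secchi_m, photic_coefficients = 2.0) {
  if (any(secchi_m <= 0, na.rm = TRUE))
    stop_config("Secchi depth must be > 0")
  if (is.list(photic_coefficients)) {
    br <- photic_coefficients$breaks
    cf <- photic_coefficients$coefficients
    if (length(cf) != length(br) + 1)
      stop_config("need one coefficient per Secchi interval (breaks + 1)")
    if (is.unsorted(br, strictly = TRUE))
      stop_config("breaks must be strictly increasing")
    k <- findInterval(secchi_m, br) + 1
    cf[k] * secchi_m
  } else {
    photic_coefficients * secchi_m
  }
}

#' Depth limit of adequate light for Fucus growth
#'
#' @param photic_m photic depth(s) in metres, >= 0.
#' @param light_fraction fraction of the photic depth, in (0, 1].
#' @return light-limit depth(s) in metres.
#' @export
light_limit_depth <- function(photic_m, light_fraction = 0.6) {
  if (light_fraction <= 0 || light_fraction > 1)
    stop_config("light_fraction must be in (0, 1]")
  if (any(photic_m < 0, na.rm = TRUE))
    stop_config("photic depth must be >= 0")
  light_fraction * photic_m
}

#' Flag potential Fucus sites
#'
#' A site is potential habitat iff its total hard-substrate cover (7 hard
#' classes) reaches the threshold and its depth does not exceed the local
#' light limit (inclusive comparison: a site exactly at the limit counts).
#' Missing substrate columns are treated as zero cover with a message.
#'
#' @param points survey-point data.frame with `depth_m` and substrate
#'   columns.
#' @param light_limit_m light-limit depth at each point (recycled if
#'   scalar), typically from the Secchi grid via [extract_at_points()],
#'   [photic_depth()] and [light_limit_depth()].
#' @param config a [potential_config()].
#' @return logical vector, one flag per point.
#' @export
is_potential_site <- function(points, light_limit_m,
                              config = potential_config()) {
  stopifnot(length(light_limit_m) %in% c(1L, nrow(points)))
  hard_cover(points) >= config$hard_substrate_threshold_pct &
    points$depth_m <= light_limit_m
}

#' Per-water-body Fucus occurrence rates
#'
#' For every zone: the number of potential sites, the number of potential
#' sites with any Fucus (`fucus_cover_pct > 0`), and the occurrence rate
#' `100 * occupied / potential`. Zones with fewer than
#' `min_sites_per_zone` potential sites are excluded (rate `NA`), since
#' sparse surveys cannot support a rate. A Fucus observation is any
#' positive cover; the 10% threshold belongs to the belt definition on
#' transects, not to occurrence counting. The numerator is restricted to
#' potential sites, so rates cannot exceed 100; observations outside the
#' potential layer surface only through [layer_validation()].
#'
#' @param points survey-point data.frame with `zone_id`,
#'   `fucus_cover_pct`, and a logical `potential` column (computed via
#'   [is_potential_site()] if absent and `light_limit_m` is a column).
#' @param config a [potential_config()].
#' @return data.frame (`zone_summary`): `zone_id`, `n_potential`,
#'   `n_with_fucus`, `occurrence_rate_pct`, `excluded`.
#' @export
zone_occurrence_rates <- function(points, config = potential_config()) {
  if (is.null(points$potential)) {
    if (is.null(points$light_limit_m))
      stop_config("points need a 'potential' or 'light_limit_m' column")
    points$potential <- is_potential_site(points, points$light_limit_m,
                                          config)
  }
  zones <- sort(unique(points$zone_id))
  pot <- points$potential
  occ <- pot & points$fucus_cover_pct > 0
  n_pot <- vapply(zones, function(z)
    sum(pot[points$zone_id == z]), numeric(1))
  n_occ <- vapply(zones, function(z)
    sum(occ[points$zone_id == z]), numeric(1))
  excluded <- n_pot < config$min_sites_per_zone
  rate <- ifelse(excluded, NA_real_, 100 * n_occ / n_pot)
  data.frame(zone_id = zones, n_potential = n_pot, n_with_fucus = n_occ,
             occurrence_rate_pct = rate, excluded = excluded,
             row.names = NULL)
}

#' Fraction of Fucus observations outside the potential layer
#'
#' Validation of the habitat-potential layer: among all points with any
#' Fucus, the percentage flagged non-potential. A small value indicates the
#' layer under- rather than over-estimates the habitat.
#'
#' @param points survey-point data.frame with `fucus_cover_pct` and a
#'   logical `potential` column.
#' @return percentage in \[0, 100\], or `NA` with a warning when there are
#'   no Fucus observations at all.
#' @export
layer_validation <- function(points) {
  if (is.null(points$potential))
    stop_config("points need a 'potential' column")
  obs <- points$fucus_cover_pct > 0
  if (!any(obs)) {
    warning("no Fucus observations; layer validation undefined",
            call. = FALSE)
    return(NA_real_)
  }
  100 * sum(obs & !points$potential) / sum(obs)
}
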