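# shared fixture builders; everything is generated in code at test time

# a small but statistically viable synthetic world configuration
small_config <- function(seed = 42, ...) {
  sim_config(n_zones = 60, n_points_per_zone = 60, n_transects = 80,
             seed = seed, ...)
}

# a transect data.frame from parallel cover/depth vectors; substrate split
# between bedrock and sand according to `hard_pct`
make_transect <- function(covers, depths = seq_along(covers),
                          distances = seq_along(covers),
                          hard_pct = rep(100, length(covers)),
                          id = "T1") {
  n <- length(covers)
  df <- data.frame(transect_id = rep_len(id, n),
                   distance_m = distances,
                   depth_m = depths, fucus_cover_pct = covers)
  sub <- matrix(0, n, 11, dimnames = list(NULL, fucusstatus:::SUBSTRATE_CLASSES))
  sub[, "bedrock"] <- hard_pct
  sub[, "sand"] <- 100 - hard_pct
  cbind(df, as.data.frame(sub))
}

# survey-point table with explicit hard cover and depths
make_points <- function(hard, depth, fucus = 0, zone = "Z1",
                        light_limit = Inf) {
  n <- max(length(hard), length(depth), length(fucus))
  hard <- rep_len(hard, n); depth <- rep_len(depth, n)
  fucus <- rep_len(fucus, n)
  sub <- matrix(0, n, 11, dimnames = list(NULL, fucusstatus:::SUBSTRATE_CLASSES))
  sub[, "bedrock"] <- hard
  sub[, "sand"] <- 100 - hard
  cbind(
    data.frame(point_id = sprintf("P%03d", seq_len(n)),
               zone_id = rep_len(zone, n), depth_m = depth,
               fucus_cover_pct = fucus,
               light_limit_m = rep_len(light_limit, n)),
    as.data.frame(sub))
}

# independent consecutive-pair oracle for zone detection
oracle_detect <- function(covers, threshold = 10) {
  if (length(covers) < 2) return(FALSE)
  for (i in seq_len(length(covers) - 1))
    if (covers[i] >= threshold && covers[i + 1] >= threshold) return(TRUE)
  FALSE
}

# literal-reading oracle for the lower limit
oracle_lower_limit <- function(covers, depths, threshold = 10) {
  if (!oracle_detect(covers, threshold)) return(NA_real_)
  max(depths[covers >= threshold])
}
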