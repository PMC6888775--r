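#' Detect a Fucus zone on a dive transect
#'
#' A Fucus zone (belt) is present when at least two consecutive study
#' points, in distance order along the transect, both have Fucus cover at
#' or above the threshold. "Consecutive" means consecutive recorded points
#' regardless of their spacing in metres. Transects with fewer than two
#' points cannot carry a zone.
#'
#' @param transect data.frame with `distance_m` and `fucus_cover_pct`.
#' @param cover_threshold percent cover defining the belt (default 10;
#'   comparisons are inclusive, so exactly 10% counts).
#' @return logical flag.
#' @export
detect_zone <- function(transect, cover_threshold = 10) {
  if (nrow(transect) < 2L) return(FALSE)
  cov <- transect$fucus_cover_pct[order(transect$distance_m)]
  hit <- cov >= cover_threshold
  any(hit[-length(hit)] & hit[-1])
}

#' Lower limit of the Fucus zone on a transect
#'
#' Given a detected zone, the lower limit is the depth of the deepest point
#' with cover at or above the threshold. By default this is taken literally
#' over the whole transect — an isolated deep patch beyond the contiguous
#' belt still sets the limit; `contiguous_only = TRUE` instead restricts to
#' the contiguous run(s) of at least two qualifying points. Depth ties are
#' resolved toward the larger distance (further offshore); this affects
#' only which point is reported, not the limit value.
#'
#' @param transect data.frame with `distance_m`, `depth_m`,
#'   `fucus_cover_pct`.
#' @param cover_threshold percent cover threshold.
#' @param contiguous_only restrict to points inside runs of >= 2
#'   consecutive qualifying points.
#' @return depth in metres, or `NA` when no zone is detected.
#' @export
lower_limit <- function(transect, cover_threshold = 10,
                        contiguous_only = FALSE) {
  if (!detect_zone(transect, cover_threshold)) return(NA_real_)
  o <- order(transect$distance_m)
  depth <- transect$depth_m[o]
  hit <- transect$fucus_cover_pct[o] >= cover_threshold
  if (contiguous_only) {
    r <- rle(hit)
    keep_run <- r$values & r$lengths >= 2
    hit <- rep(keep_run, r$lengths)
  }
  max(depth[hit])
}

#' Does hard substrate continue below the detected lower limit?
#'
#' The lower limit is only meaningful when it was set by factors other than
#' substrate: there must be at least one point strictly deeper than the
#' limit with hard-substrate cover at or above the threshold. A transect
#' that simply ends at the belt fails the check.
#'
#' @param transect data.frame with `depth_m` and substrate columns.
#' @param limit_m detected lower limit (m), not `NA`.
#' @param hard_threshold percent hard cover required below the limit.
#' @return logical flag.
#' @export
substrate_continues_below <- function(transect, limit_m,
                                      hard_threshold = 10) {
  stopifnot(!is.na(limit_m))
  below <- transect$depth_m > limit_m
  if (!any(below)) return(FALSE)
  any(hard_cover(transect[below, , drop = FALSE]) >= hard_threshold)
}

#' Assess all transects: zone detection, lower limit, continuation filter
#'
#' One row per transect. A transect is retained for lower-limit analysis
#' iff a zone was detected and hard substrate continues below its limit.
#' Transects with fewer than two usable rows are reported as zone-free with
#' a warning.
#'
#' @param transect_points data.frame of all transect points with
#'   `transect_id`, `distance_m`, `depth_m`, substrate columns and
#'   `fucus_cover_pct`.
#' @param cover_threshold Fucus cover threshold for the belt.
#' @param hard_threshold hard-substrate threshold for the continuation
#'   check.
#' @param contiguous_only see [lower_limit()].
#' @return data.frame (`fucus_zone_result`): `transect_id`,
#'   `zone_detected`, `lower_limit_m`, `substrate_continues`, `retained`.
#' @export
assess_transects <- function(transect_points, cover_threshold = 10,
                             hard_threshold = 10, contiguous_only = FALSE) {
  need <- c("transect_id", "distance_m", "depth_m", "fucus_cover_pct")
  miss <- setdiff(need, names(transect_points))
  if (length(miss))
    stop_config("transect table lacks column(s): %s",
                paste(miss, collapse = ", "))
  bad <- !stats::complete.cases(transect_points[need])
  if (any(bad)) {
    warning(sum(bad), " malformed transect row(s) skipped", call. = FALSE)
    transect_points <- transect_points[!bad, , drop = FALSE]
  }
  ids <- unique(transect_points$transect_id)
  rows <- lapply(ids, function(id) {
    tr <- transect_points[transect_points$transect_id == id, , drop = FALSE]
    det <- detect_zone(tr, cover_threshold)
    lim <- if (det) lower_limit(tr, cover_threshold, contiguous_only)
           else NA_real_
    cont <- if (det) substrate_continues_below(tr, lim, hard_threshold)
            else NA
    data.frame(transect_id = id, zone_detected = det, lower_limit_m = lim,
               substrate_continues = cont,
               retained = det && isTRUE(cont))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
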