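#' Gridded environmental variable
#'
#' A minimal single-band raster container: a numeric matrix in row-major
#' map order (row 1 = northernmost row) with an origin at the lower-left
#' corner and a square cell size, as in the ESRI ASCII grid format. Used for
#' the five environmental layers (surface salinity, wave-exposure index,
#' Secchi depth, total nitrogen, total phosphorus), each at its own
#' resolution.
#'
#' @param values numeric matrix (n_rows x n_cols), row 1 is the top row.
#' @param xll,yll coordinates of the lower-left corner of the grid.
#' @param cell_size cell edge length (m), > 0.
#' @param variable variable name.
#' @param nodata value marking missing cells (replaced by `NA` internally).
#' @return an object of class `env_grid`.
#' @export
env_grid <- function(values, xll = 0, yll = 0, cell_size = 1,
                     variable = "var", nodata = -9999) {
  values <- as.matrix(values)
  if (!is.numeric(cell_size) || cell_size <= 0)
    stop_config("cell_size must be > 0")
  values[values == nodata] <- NA_real_
  structure(
    list(variable = variable, values = values, xll = xll, yll = yll,
         cell_size = cell_size, n_rows = nrow(values), n_cols = ncol(values),
         nodata = nodata),
    class = "env_grid"
  )
}

#' @export
print.env_grid <- function(x, ...) {
  cat(sprintf("<env_grid '%s'> %d x %d cells, cell size %g, origin (%g, %g)\n",
              x$variable, x$n_rows, x$n_cols, x$cell_size, x$xll, x$yll))
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("  values in [%.4g, %.4g], %d NA cells\n",
              rng[1], rng[2], sum(is.na(x$values))))
  invisible(x)
}

#' Read and write ESRI ASCII grids
#'
#' Plain-text `.asc` raster IO (`ncols/nrows/xllcorner/yllcorner/cellsize/
#' NODATA_value` header followed by rows from north to south). No raster
#' package is required; the format is simple enough to parse directly.
#'
#' @param path file path.
#' @param variable variable name attached to the grid on read.
#' @return `read_esri_ascii` returns an [env_grid]; `write_esri_ascii`
#'   returns `path` invisibly.
#' @export
read_esri_ascii <- function(path, variable = sub("\\.asc$", "", basename(path))) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  env_grid(m, xll = hdr$xllcorner, yll = hdr$yllcorner,
           cell_size = hdr$cellsize, variable = variable,
           nodata = hdr$nodata_value %||% -9999)
}

#' @rdname read_esri_ascii
#' @param grid an [env_grid].
#' @export
write_esri_ascii <- function(grid, path) {
  stopifnot(inherits(grid, "env_grid"))
  v <- grid$values
  v[is.na(v)] <- grid$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", grid$n_cols),
    sprintf("nrows %d", grid$n_rows),
    sprintf("xllcorner %.10g", grid$xll),
    sprintf("yllcorner %.10g", grid$yll),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %.10g", grid$nodata)
  ), con)
  utils::write.table(format(v, trim = TRUE, digits = 10), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

# row/col (top-left indexed) of the cells containing planar coordinates;
# NA outside the grid extent.
grid_index <- function(grid, x, y) {
  col <- floor((x - grid$xll) / grid$cell_size) + 1
  row_from_bottom <- floor((y - grid$yll) / grid$cell_size) + 1
  row <- grid$n_rows - row_from_bottom + 1
  bad <- col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' Extract grid values at point locations
#'
#' Nearest-cell (point-in-cell) extraction, no interpolation: each point
#' receives the value of the cell containing it, matching the usual GIS
#' "extract values to points" semantics.
#'
#' @param grid an [env_grid].
#' @param x,y numeric coordinate vectors of equal length.
#' @return numeric vector of cell values; `NA` (with a warning) for points
#'   outside the grid extent or over nodata cells.
#' @export
extract_at_points <- function(grid, x, y) {
  stopifnot(inherits(grid, "env_grid"), length(x) == length(y))
  idx <- grid_index(grid, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(idx$row)
  if (any(!ok))
    warning(sum(!ok), " point(s) outside extent of grid '", grid$variable,
            "'; returned NA", call. = FALSE)
  out[ok] <- grid$values[cbind(idx$row[ok], idx$col[ok])]
  out
}

#' Zonal mean of a grid over a rectangular zone
#'
#' Arithmetic mean of the values of all cells whose centers fall inside the
#' zone rectangle; nodata cells are excluded, partially overlapped cells are
#' included or excluded purely by their center. This mirrors the default of
#' standard zonal-statistics tools and is exactly testable.
#'
#' @param grid an [env_grid].
#' @param zone a list or one-row data.frame with `xmin`, `xmax`, `ymin`,
#'   `ymax`.
#' @return the mean, or `NA` with a warning if no cell center falls inside.
#' @export
zonal_mean <- function(grid, zone) {
  stopifnot(inherits(grid, "env_grid"))
  cs <- grid$cell_size
  xc <- grid$xll + (seq_len(grid$n_cols) - 0.5) * cs
  yc_top_down <- grid$yll + (grid$n_rows - seq_len(grid$n_rows) + 0.5) * cs
  cols <- which(xc >= zone$xmin & xc < zone$xmax)
  rows <- which(yc_top_down >= zone$ymin & yc_top_down < zone$ymax)
  if (!length(cols) || !length(rows)) {
    warning("zone overlaps no cell centers of grid '", grid$variable, "'",
            call. = FALSE)
    return(NA_real_)
  }
  mean(grid$values[rows, cols, drop = FALSE], na.rm = TRUE)
}

#' Covariate table for water-body zones or transects
#'
#' Looks up the five environmental variables for each unit: by zonal mean
#' over the unit's rectangle (`zones`) or by point extraction (`points` with
#' `x`, `y`). Rows with any missing value are flagged.
#'
#' @param grids named list of [env_grid] objects (names =
#'   `salinity, exposure, secchi, ntot, ptot`, any subset).
#' @param zones data.frame with `zone_id`, `xmin`, `xmax`, `ymin`, `ymax`,
#'   or `NULL`.
#' @param points data.frame with an id column plus `x`, `y`, or `NULL`.
#' @param id name of the id column in `points`.
#' @return data.frame: id column, one column per grid, and `complete` flag.
#' @export
covariate_table <- function(grids, zones = NULL, points = NULL,
                            id = "transect_id") {
  stopifnot(xor(is.null(zones), is.null(points)))
  if (!is.null(zones)) {
    out <- data.frame(zone_id = zones$zone_id)
    for (v in names(grids))
      out[[v]] <- vapply(seq_len(nrow(zones)), function(i)
        zonal_mean(grids[[v]], zones[i, ]), numeric(1))
  } else {
    out <- data.frame(points[[id]])
    names(out) <- id
    for (v in names(grids))
      out[[v]] <- extract_at_points(grids[[v]], points$x, points$y)
  }
  out$complete <- stats::complete.cases(out)
  out
}

#' Pearson correlation matrix with two-sided p values
#'
#' Pairwise Pearson correlations between covariate columns, with p values
#' from the t distribution on n - 2 degrees of freedom. Zero-variance
#' columns yield `NA` correlations and are flagged with a warning.
#'
#' @param covariates data.frame or matrix of numeric columns (id columns and
#'   non-numerics are dropped).
#' @return list with `r` (correlation matrix), `p` (p-value matrix), `n`.
#' @export
correlation_matrix <- function(covariates) {
  x <- as.data.frame(covariates)
  x <- x[vapply(x, is.numeric, logical(1))]
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x)
  if (n < 3L) stop_config("need at least 3 complete rows, got %d", n)
  zv <- vapply(x, function(col) stats::var(col) == 0, logical(1))
  if (any(zv))
    warning("zero-variance column(s): ", paste(names(x)[zv], collapse = ", "),
            call. = FALSE)
  r <- suppressWarnings(stats::cor(x))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(p) <- 0
  list(r = r, p = p, n = n)
}

#' Collinearity screen
#'
#' Flags variable pairs whose absolute Pearson correlation reaches the
#' threshold and returns the configured victims to drop. The victim is
#' configured, not inferred: which member of a collinear pair to keep is a
#' scientific judgment (here, by default, total phosphorus is dropped when it
#' collides with total nitrogen).
#'
#' @param cormat result of [correlation_matrix()], or a plain correlation
#'   matrix.
#' @param threshold absolute correlation at or above which a pair is
#'   collinear (default 0.8).
#' @param victims named character vector mapping `"a|b"` pairs
#'   (alphabetical) to the variable to drop; pairs without an entry drop the
#'   second variable alphabetically, with a message.
#' @return character vector of variables to drop (possibly empty), with the
#'   offending pairs as the `"pairs"` attribute.
#' @export
collinearity_screen <- function(cormat, threshold = 0.8,
                                victims = c("ntot|ptot" = "ptot")) {
  r <- if (is.list(cormat)) cormat$r else cormat
  vars <- colnames(r)
  drop <- character(0)
  pairs <- character(0)
  for (i in seq_len(ncol(r) - 1)) for (j in seq.int(i + 1, ncol(r))) {
    if (!is.na(r[i, j]) && abs(r[i, j]) >= threshold) {
      key <- paste(sort(c(vars[i], vars[j])), collapse = "|")
      pairs <- c(pairs, key)
      if (!is.na(victims[key])) {
        drop <- c(drop, unname(victims[key]))
      } else {
        # which member to sacrifice is a scientific judgment; without a
        # configured victim the pair is only reported
        message("collinear pair ", key,
                " has no configured victim; nothing dropped")
      }
    }
  }
  structure(unique(drop), pairs = unique(pairs))
}

#' Write and read water-body zones as GeoJSON
#'
#' Zones are axis-aligned rectangles in a planar coordinate frame; they are
#' serialized as a GeoJSON FeatureCollection of Polygon features whose
#' properties carry the zone id and covariate means.
#'
#' @param zones data.frame with `zone_id`, `xmin`, `xmax`, `ymin`, `ymax`
#'   and optional covariate columns.
#' @param path output path.
#' @return `write_zones_geojson` returns `path` invisibly;
#'   `read_zones_geojson` returns the zones data.frame.
#' @export
write_zones_geojson <- function(zones, path) {
  feats <- lapply(seq_len(nrow(zones)), function(i) {
    z <- zones[i, ]
    ring <- list(
      c(z$xmin, z$ymin), c(z$xmax, z$ymin), c(z$xmax, z$ymax),
      c(z$xmin, z$ymax), c(z$xmin, z$ymin)
    )
    props <- as.list(z[setdiff(names(z), c("xmin", "xmax", "ymin", "ymax"))])
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = c(props, z[c("xmin", "xmax", "ymin", "ymax")]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_zones_geojson
#' @export
read_zones_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  rows <- lapply(gj$features, function(f) as.data.frame(f$properties))
  do.call(rbind, rows)
}
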