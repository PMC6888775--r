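#' Derive a reproducible sub-seed from a root seed and a stream name
#'
#' All randomness in the package flows from a single root seed; each module
#' draws from its own named substream so that adding draws in one stage does
#' not perturb another. The derived seed is kept strictly below 2^31.
#'
#' @param seed integer root seed.
#' @param stream character stream name.
#' @return an integer seed.
#' @export
seed_stream <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  # deterministic string hash (polynomial rolling, 31-bit)
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% 2147483629
  as.integer((abs(seed) %% 1000003) * 2029 + h) %% 2147483647L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

assert_range <- function(r, name) {
  if (!is.numeric(r) || length(r) != 2L || anyNA(r) || r[1] > r[2])
    stop_config("'%s' must be a numeric pair with min <= max", name)
  invisible(r)
}

# Sum of hard-substrate class covers for a data.frame of points; missing
# class columns are treated as zero cover (with a one-time message).
hard_cover <- function(points) {
  present <- intersect(HARD_CLASSES, names(points))
  missing <- setdiff(HARD_CLASSES, names(points))
  if (length(missing))
    message("substrate classes treated as 0 cover: ",
            paste(missing, collapse = ", "))
  if (!length(present)) return(rep(0, nrow(points)))
  rowSums(as.matrix(points[present]))
}
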