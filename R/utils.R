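#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, restoring the caller's
#' RNG state afterwards so library code never clobbers a user's stream.
#' With `seed = NULL` the code runs on the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Arc length of an open polyline
#' @param pts numeric matrix, one point per row (x, y).
#' @return total length in the units of `pts`.
#' @export
polyline_length <- function(pts) {
  if (is.null(dim(pts)) || nrow(pts) < 2L) return(0)
  sum(sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2))
}

# Resample an open polyline at (approximately) equal arc-length steps.
# Keeps both endpoints exactly.
resample_polyline <- function(pts, step) {
  if (nrow(pts) < 2L) return(pts)
  d <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  keep <- c(TRUE, d > 0)
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) < 2L) return(pts)
  cum <- c(0, cumsum(sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)))
  L <- cum[length(cum)]
  s <- seq(0, L, by = step)
  if (s[length(s)] < L) s <- c(s, L)
  cbind(stats::approx(cum, pts[, 1], xout = s)$y,
        stats::approx(cum, pts[, 2], xout = s)$y)
}

# Gaussian smoothing of an open polyline's coordinates (suppresses the
# pixel staircase of traced skeleton branches); endpoints are pinned.
smooth_polyline <- function(pts, sigma_px = 1.2) {
  n <- nrow(pts)
  if (sigma_px <= 0 || n < 5L) return(pts)
  half <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(seq(-half, half), sd = sigma_px)
  k <- k / sum(k)
  pad <- function(v) c(rep(v[1], half), v, rep(v[n], half))
  sm <- function(v) stats::filter(pad(v), k, sides = 2)[(half + 1):(half + n)]
  out <- cbind(as.numeric(sm(pts[, 1])), as.numeric(sm(pts[, 2])))
  out[1, ] <- pts[1, ]
  out[n, ] <- pts[n, ]
  out
}
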