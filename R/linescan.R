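# Line-scan intensity profiling and transverse-profile classification.

# Bilinear interpolation of image intensities at physical coordinates (um).
# Coordinates are clamped to the pixel-centre lattice at the edges.
bilinear_sample <- function(img, x_um, y_um, px) {
  H <- nrow(img)
  W <- ncol(img)
  cf <- pmin(pmax(x_um / px + 0.5, 1), W)
  rf <- pmin(pmax(y_um / px + 0.5, 1), H)
  c0 <- pmin(floor(cf), W - 1L)
  r0 <- pmin(floor(rf), H - 1L)
  tc <- cf - c0
  tr <- rf - r0
  i00 <- (c0 - 1) * H + r0
  img[i00] * (1 - tr) * (1 - tc) + img[i00 + 1] * tr * (1 - tc) +
    img[i00 + H] * (1 - tr) * tc + img[i00 + H + 1] * tr * tc
}

#' Intensity profile along a scan line
#'
#' Samples one or more channels along the segment from `p_start` to `p_end`
#' at sub-pixel steps (bilinear interpolation), averaging perpendicular to
#' the line over a breadth of `width_um`.
#'
#' @param image a `synthetic_image` (or list with `channels`,
#'   `pixel_size_um`).
#' @param channel channel name(s); default all channels.
#' @param p_start,p_end numeric length-2, segment endpoints in um (x, y).
#' @param width_um averaging breadth perpendicular to the line (0 = none).
#' @param step_um sampling step along the line (default half a pixel).
#' @return object of class `line_scan`: list with `positions_um` (strictly
#'   increasing), `intensity` (named list of vectors) and `width_um`.
#' @export
line_scan <- function(image, channel = NULL, p_start, p_end, width_um = 0,
                      step_um = NULL) {
  px <- image$pixel_size_um
  chans <- channel %||% names(image$channels)
  missing <- setdiff(chans, names(image$channels))
  if (length(missing)) stop("no channel(s): ", paste(missing, collapse = ", "))
  H <- nrow(image$channels[[1]])
  W <- ncol(image$channels[[1]])
  for (p in list(p_start, p_end))
    if (p[1] < 0 || p[1] > W * px || p[2] < 0 || p[2] > H * px)
      stop("scan endpoints must lie inside the image")
  L <- sqrt(sum((p_end - p_start)^2))
  if (L <= 0) stop("zero-length scan line")
  step <- step_um %||% (px / 2)
  pos <- seq(0, L, by = step)
  if (pos[length(pos)] < L) pos <- c(pos, L)
  u <- (p_end - p_start) / L
  nrm <- c(-u[2], u[1])
  offs <- if (width_um > 0) seq(-width_um / 2, width_um / 2, by = px / 2) else 0
  xs <- outer(pos, rep(1, length(offs))) * u[1] + p_start[1] +
    outer(rep(1, length(pos)), offs) * nrm[1]
  ys <- outer(pos, rep(1, length(offs))) * u[2] + p_start[2] +
    outer(rep(1, length(pos)), offs) * nrm[2]
  intensity <- lapply(image$channels[chans], function(img) {
    v <- bilinear_sample(img, as.vector(xs), as.vector(ys), px)
    rowMeans(matrix(v, nrow = length(pos)))
  })
  structure(list(positions_um = pos, intensity = intensity,
                 width_um = width_um),
            class = "line_scan")
}

# Peak prominence in the scipy sense: height above the higher of the two
# minima reached before a higher point (or the series end) on either side.
peak_prominences <- function(y, peaks) {
  vapply(peaks, function(i) {
    left <- if (i > 1) {
      seg <- y[seq_len(i - 1)]
      hi <- which(seg > y[i])
      lo <- if (length(hi)) max(hi) + 1L else 1L
      min(y[lo:i])
    } else y[i]
    n <- length(y)
    right <- if (i < n) {
      seg <- y[(i + 1):n]
      hi <- which(seg > y[i])
      lo <- if (length(hi)) i + min(hi) - 1L else n
      min(y[i:lo])
    } else y[i]
    y[i] - max(left, right)
  }, numeric(1))
}

# Indices of strict local maxima (plateaus collapse to their centre).
find_local_maxima <- function(y) {
  rl <- rle(y)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  k <- length(rl$values)
  if (k < 3L) return(integer(0))
  isp <- vapply(2:(k - 1), function(i)
    rl$values[i] > rl$values[i - 1] && rl$values[i] > rl$values[i + 1],
    logical(1))
  idx <- which(isp) + 1L
  as.integer(round((starts[idx] + ends[idx]) / 2))
}

#' Classify a transverse intensity profile
#'
#' Counts local maxima whose prominence is at least `min_prominence` times
#' the profile range: 0 peaks is `"none"`, 1 is `"single_peak"`, 2 or more
#' is `"double_peak"`.  A scan drawn across a junction distinguishes
#' continuous junctional decoration (one peak) from the two-row punctate
#' phenotype (two peaks straddling the junction line).
#'
#' @param profile a `line_scan` or a bare numeric vector.
#' @param min_prominence prominence threshold, relative to the range.
#' @param channel channel to classify when `profile` is a `line_scan`
#'   (default: its first channel).
#' @return `"none"`, `"single_peak"` or `"double_peak"`; attribute
#'   `"n_peaks"` carries the count.
#' @export
classify_transverse_profile <- function(profile, min_prominence = 0.2,
                                        channel = NULL) {
  y <- if (inherits(profile, "line_scan")) {
    ch <- channel %||% names(profile$intensity)[1]
    profile$intensity[[ch]]
  } else as.numeric(profile)
  rng <- diff(range(y))
  if (rng == 0) return(structure("none", n_peaks = 0L))
  pk <- find_local_maxima(y)
  if (length(pk)) {
    prom <- peak_prominences(y, pk)
    pk <- pk[prom >= min_prominence * rng]
  }
  n <- length(pk)
  structure(if (n == 0L) "none" else if (n == 1L) "single_peak"
            else "double_peak", n_peaks = n)
}
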