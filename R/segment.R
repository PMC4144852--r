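# Junction-ridge segmentation: background subtraction, global threshold,
# small-object removal.  Stands in for manual tracing of the junction marker.

#' Otsu's threshold
#'
#' Maximizes between-class variance over a fixed-bin histogram.
#' @param x numeric vector (or matrix) of intensities.
#' @param nbins histogram bins.
#' @return threshold value (a bin edge).
#' @export
otsu_threshold <- function(x, nbins = 256L) {
  x <- as.numeric(x)
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-(nbins + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  sb <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- 0
  br[which.max(sb) + 1L]
}

# 8-connected component labelling of a logical matrix, via an igraph over
# the foreground pixel adjacency.  Returns an integer label matrix (0 = bg).
label_components <- function(mask) {
  H <- nrow(mask)
  W <- ncol(mask)
  lab <- matrix(0L, H, W)
  idx <- which(mask)
  n <- length(idx)
  if (n == 0L) return(lab)
  rank <- integer(H * W)
  rank[idx] <- seq_len(n)
  r <- ((idx - 1L) %% H) + 1L
  cc <- ((idx - 1L) %/% H) + 1L
  el <- vector("list", 4L)
  shifts <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  for (si in seq_along(shifts)) {
    dr <- shifts[[si]][1]
    dc <- shifts[[si]][2]
    r2 <- r + dr
    c2 <- cc + dc
    ok <- r2 >= 1L & r2 <= H & c2 >= 1L & c2 <= W
    j <- (c2[ok] - 1L) * H + r2[ok]
    ok2 <- mask[j]
    el[[si]] <- cbind(rank[idx[ok][ok2]], rank[j[ok2]])
  }
  el <- do.call(rbind, el)
  g <- igraph::make_graph(if (nrow(el)) as.vector(t(el)) else integer(0), n = n,
                          directed = FALSE)
  lab[idx] <- igraph::components(g)$membership
  lab
}

remove_small_objects <- function(mask, min_px) {
  if (min_px <= 1L || !any(mask)) return(mask)
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_px)
  lab > 0L & lab %in% keep
}

#' Segment junction ridges in a fluorescence channel
#'
#' Background subtraction (constant median, rolling mean, or none), a global
#' threshold (Otsu by default, or a fixed value), and removal of connected
#' components smaller than `min_object_px`.
#'
#' @param image a `synthetic_image` (or any list with `channels` and
#'   `pixel_size_um`).
#' @param channel channel name, default `"junction"`.
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param threshold fixed threshold value (required for `"fixed"`).
#' @param background `"constant"` (subtract the median), `"rolling"`
#'   (subtract a local box mean) or `"none"`.
#' @param background_radius_um rolling-mean radius.
#' @param min_object_px connected components below this size are dropped.
#' @return logical mask matrix; attribute `"threshold"` records the value used.
#' @export
segment_junctions <- function(image, channel = "junction",
                              threshold_method = c("otsu", "fixed"),
                              threshold = NULL,
                              background = c("constant", "rolling", "none"),
                              background_radius_um = 3,
                              min_object_px = 20L) {
  threshold_method <- match.arg(threshold_method)
  background <- match.arg(background)
  if (is.null(image$channels[[channel]]))
    stop("image has no channel '", channel, "'")
  img <- image$channels[[channel]]
  px <- image$pixel_size_um
  if (is.null(px) || is.na(px)) stop("image has no pixel size")
  img2 <- switch(background,
    none = img,
    constant = img - stats::median(img),
    rolling = {
      r <- max(1L, round(background_radius_um / px))
      img - box_blur(img, r)
    })
  thr <- if (threshold_method == "fixed") {
    if (is.null(threshold)) stop("threshold_method = 'fixed' needs `threshold`")
    threshold
  } else otsu_threshold(img2)
  mask <- img2 > thr
  mask <- remove_small_objects(mask, min_object_px)
  if (!any(mask))
    stop(sprintf("empty foreground (method = %s, threshold = %.6g)",
                 threshold_method, thr))
  attr(mask, "threshold") <- thr
  mask
}

# FFT box mean over a (2r+1)^2 neighbourhood, circular boundary.
box_blur <- function(img, r) {
  H <- nrow(img)
  W <- ncol(img)
  k1 <- function(n) {
    v <- numeric(n)
    ix <- c(1:(r + 1), (n - r + 1):n)
    v[unique(pmin(pmax(ix, 1), n))] <- 1
    v / sum(v)
  }
  K <- outer(k1(H), k1(W))
  Re(stats::fft(stats::fft(img) * stats::fft(K), inverse = TRUE)) / (H * W)
}
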