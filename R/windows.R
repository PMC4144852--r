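#' Randomly sample fixed-area analysis windows from a network
#'
#' Places `n_windows` axis-aligned square windows (side `sqrt(window_area_um2)`)
#' uniformly at random, fully contained in the field.  A side belongs to a
#' window iff both of its vertices lie inside the window; border-flagged
#' sides are never eligible.  Windows containing no eligible side are
#' re-drawn up to `max_retry` times.
#'
#' @param network a [junction_network()].
#' @param window_area_um2 window area; the default 840 um^2 is the
#'   field-standard analysis area for this assay.
#' @param n_windows number of windows per sample (default 5).
#' @param seed RNG seed for window placement.
#' @param max_retry redraw cap per window.
#' @return list of windows, each a list with `side_ids`, `x0_um`, `y0_um`,
#'   `size_um`.
#' @export
sample_windows <- function(network, window_area_um2 = 840, n_windows = 5,
                           seed = NULL, max_retry = 100L) {
  s <- sqrt(window_area_um2)
  Wf <- network$field_um[1]
  Hf <- network$field_um[2]
  if (is.na(Wf) || is.na(Hf)) stop("network has no field extent")
  if (s > Wf || s > Hf)
    stop("window side ", signif(s, 4), " um exceeds the field")
  elig <- vapply(network$sides, function(x)
    !isTRUE(x$border) && x$v1 != x$v2, logical(1))
  if (!any(elig)) stop("network has no eligible (non-border) sides")
  vx <- stats::setNames(network$vertices$x_um, network$vertices$id)
  vy <- stats::setNames(network$vertices$y_um, network$vertices$id)
  sid <- vapply(network$sides, function(x) as.character(x$id), character(1))
  v1 <- vapply(network$sides, function(x) as.character(x$v1), character(1))
  v2 <- vapply(network$sides, function(x) as.character(x$v2), character(1))
  x1 <- vx[v1]; y1 <- vy[v1]; x2 <- vx[v2]; y2 <- vy[v2]
  with_seed(seed, {
    lapply(seq_len(n_windows), function(i) {
      for (try in seq_len(max_retry)) {
        x0 <- stats::runif(1, 0, Wf - s)
        y0 <- stats::runif(1, 0, Hf - s)
        inside <- elig &
          x1 >= x0 & x1 <= x0 + s & y1 >= y0 & y1 <= y0 + s &
          x2 >= x0 & x2 <= x0 + s & y2 >= y0 & y2 <= y0 + s
        if (any(inside))
          return(list(side_ids = sid[inside], x0_um = x0, y0_um = y0,
                      size_um = s))
      }
      stop("could not place a non-empty window after ", max_retry, " tries")
    })
  })
}

#' Window zigzag indices for a measured network
#'
#' @param network a [junction_network()].
#' @param morphometry optional precomputed [measure_network()] table.
#' @inheritParams sample_windows
#' @return list with `windows` (from [sample_windows()]), `indices`
#'   (numeric vector of per-window zigzag indices) and `n_sides_total`
#'   (sides pooled over all windows, with multiplicity).
#' @export
window_zigzag <- function(network, window_area_um2 = 840, n_windows = 5,
                          seed = NULL, morphometry = NULL) {
  m <- morphometry %||% measure_network(network)
  w <- sample_windows(network, window_area_um2, n_windows, seed)
  idx <- vapply(w, function(win)
    compute_zigzag_index(win$side_ids, m, window = win)$value, numeric(1))
  list(windows = w, indices = idx,
       n_sides_total = sum(vapply(w, function(win) length(win$side_ids),
                                  integer(1))))
}

#' Clone-level zigzag summary
#'
#' Aggregation hierarchy: each sample's value is the mean of its window
#' indices; the clone is summarized as mean +/- standard error across
#' samples (SE reported as NA for a single sample).
#'
#' @param per_sample_window_indices list of numeric vectors, one vector of
#'   window indices per sample.
#' @return list with `sample_means`, `mean`, `se`, `n`.
#' @examples
#' clone_zigzag_summary(list(1.2, 1.3, 1.4))$se  # 0.1/sqrt(3)
#' @export
clone_zigzag_summary <- function(per_sample_window_indices) {
  stopifnot(length(per_sample_window_indices) >= 1L)
  sm <- vapply(per_sample_window_indices, function(v) {
    stopifnot(length(v) >= 1L)
    mean(v)
  }, numeric(1))
  n <- length(sm)
  list(sample_means = sm, mean = mean(sm),
       se = if (n > 1L) stats::sd(sm) / sqrt(n) else NA_real_, n = n)
}
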