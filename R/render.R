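# Rasterization and optics for the synthetic-image forward model.
# Images are numeric matrices indexed [row, col] with pixel centres at
# ((col - 0.5) * px, (row - 0.5) * px) in um; origin top-left, y downward.

# Distance-based anti-aliased rasterization of polylines at a fixed width.
# Polylines are sampled densely; every pixel near a sample gets the exact
# distance to the nearest sample and a linear edge-coverage intensity.
rasterize_polylines <- function(polylines, dim_hw, px, width_um, level) {
  H <- dim_hw[1]
  W <- dim_hw[2]
  img <- matrix(0, H, W)
  step <- px / 2
  pts <- do.call(rbind, lapply(polylines, resample_polyline, step = step))
  if (is.null(pts) || nrow(pts) == 0L) return(img)
  r_px <- width_um / 2 / px + 1.5
  rr <- ceiling(r_px)
  off <- expand.grid(dr = -rr:rr, dc = -rr:rr)
  off <- off[off$dr^2 + off$dc^2 <= (r_px + 0.8)^2, , drop = FALSE]
  prow <- floor(pts[, 2] / px) + 1
  pcol <- floor(pts[, 1] / px) + 1
  n <- nrow(pts)
  m <- nrow(off)
  rows <- rep(prow, m) + rep(off$dr, each = n)
  cols <- rep(pcol, m) + rep(off$dc, each = n)
  sx <- rep(pts[, 1], m)
  sy <- rep(pts[, 2], m)
  ok <- rows >= 1 & rows <= H & cols >= 1 & cols <= W
  rows <- rows[ok]; cols <- cols[ok]
  d <- sqrt(((cols - 0.5) * px - sx[ok])^2 + ((rows - 0.5) * px - sy[ok])^2)
  idx <- (cols - 1L) * H + rows
  o <- order(idx, d)
  idx <- idx[o]; d <- d[o]
  first <- !duplicated(idx)
  dmin <- d[first]
  cov <- pmin(1, pmax(0, (width_um / 2 + 0.5 * px - dmin) / px))
  img[idx[first]] <- level * cov
  img
}

# Sum-accumulated Gaussian puncta (centres in um, one amplitude).
rasterize_puncta <- function(centers, dim_hw, px, sigma_um, level) {
  H <- dim_hw[1]
  W <- dim_hw[2]
  img <- matrix(0, H, W)
  if (is.null(centers) || nrow(centers) == 0L) return(img)
  rr <- ceiling(3 * sigma_um / px + 1)
  off <- expand.grid(dr = -rr:rr, dc = -rr:rr)
  prow <- floor(centers[, 2] / px) + 1
  pcol <- floor(centers[, 1] / px) + 1
  n <- nrow(centers)
  m <- nrow(off)
  rows <- rep(prow, m) + rep(off$dr, each = n)
  cols <- rep(pcol, m) + rep(off$dc, each = n)
  sx <- rep(centers[, 1], m)
  sy <- rep(centers[, 2], m)
  ok <- rows >= 1 & rows <= H & cols >= 1 & cols <= W
  rows <- rows[ok]; cols <- cols[ok]
  d2 <- ((cols - 0.5) * px - sx[ok])^2 + ((rows - 0.5) * px - sy[ok])^2
  val <- level * exp(-d2 / (2 * sigma_um^2))
  idx <- (cols - 1L) * H + rows
  acc <- rowsum(val, idx)
  img[as.integer(rownames(acc))] <- acc[, 1]
  img
}

# FFT Gaussian blur (circular boundary; junction density is roughly
# homogeneous so wrap-around bias is negligible at psf scales << field).
gaussian_blur <- function(img, sigma_px) {
  if (sigma_px <= 0.2) return(img)
  H <- nrow(img)
  W <- ncol(img)
  gk <- function(n) {
    x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    k <- exp(-x^2 / (2 * sigma_px^2))
    k / sum(k)
  }
  K <- outer(gk(H), gk(W))
  Re(stats::fft(stats::fft(img) * stats::fft(K), inverse = TRUE)) / (H * W)
}

# Puncta centres for the two_row myosin mode: points every spacing um along
# each side, offset +/- offset_um along the local normal.
two_row_centers <- function(polylines, spacing_um, offset_um) {
  out <- lapply(polylines, function(p) {
    L <- polyline_length(p)
    if (L < spacing_um) return(NULL)
    rp <- resample_polyline(p, spacing_um / 4)
    cum <- c(0, cumsum(sqrt(diff(rp[, 1])^2 + diff(rp[, 2])^2)))
    s <- seq(spacing_um / 2, L, by = spacing_um)
    ix <- vapply(s, function(si) which.min(abs(cum - si)), integer(1))
    ix <- pmin(pmax(ix, 2L), nrow(rp) - 1L)
    tx <- rp[ix + 1L, 1] - rp[ix - 1L, 1]
    ty <- rp[ix + 1L, 2] - rp[ix - 1L, 2]
    tl <- sqrt(tx^2 + ty^2)
    nx <- -ty / tl
    ny <- tx / tl
    rbind(cbind(rp[ix, 1] + offset_um * nx, rp[ix, 2] + offset_um * ny),
          cbind(rp[ix, 1] - offset_um * nx, rp[ix, 2] - offset_um * ny))
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Render a synthetic monolayer image from its specification
#'
#' Forward model: build the ground-truth network
#' ([build_junction_network()]), rasterize the junction polylines at
#' `junction_level` and `junction_width_um`, blur with the Gaussian PSF, add
#' the background plateau and additive Gaussian noise (optionally Poisson
#' shot noise first).  The myosin channel, when requested, is rendered from
#' the same polylines, either continuously or as two rows of Gaussian puncta
#' flanking the junction.
#'
#' @param spec a [monolayer_spec()].
#' @param render logical; `FALSE` skips rasterization and returns only the
#'   ground truth (channels empty), useful for geometry-only studies.
#' @return object of class `synthetic_image`: list with `channels` (named
#'   list of matrices), `pixel_size_um`, `spec`, `truth` (the ground-truth
#'   network) and `warnings`.
#' @examples
#' sp <- monolayer_spec(field_width_um = 30, field_height_um = 30,
#'                      n_cells = 12, noise_sd = 0, seed = 7)
#' img <- generate_monolayer(sp)
#' dim(img$channels$junction)  # 300 x 300
#' @export
generate_monolayer <- function(spec, render = TRUE) {
  stopifnot(inherits(spec, "monolayer_spec"))
  with_seed(spec$seed, {
    net <- build_network_impl(spec)
    channels <- list()
    if (render) {
      px <- spec$pixel_size_um
      H <- round(spec$field_height_um / px)
      W <- round(spec$field_width_um / px)
      polys <- lapply(net$sides, `[[`, "polyline")
      base <- rasterize_polylines(polys, c(H, W), px,
                                  spec$junction_width_um, spec$junction_level)
      channels$junction <- finish_channel(base, spec)
      if (spec$myosin_mode == "continuous") {
        channels$myosin <- finish_channel(base, spec)
      } else if (spec$myosin_mode == "two_row") {
        ctr <- two_row_centers(polys, spec$puncta_spacing_um,
                               spec$two_row_offset_um)
        my <- rasterize_puncta(ctr, c(H, W), px, spec$puncta_sigma_um,
                               spec$junction_level)
        channels$myosin <- finish_channel(my, spec)
      }
    }
    structure(list(channels = channels, pixel_size_um = spec$pixel_size_um,
                   spec = spec, truth = net,
                   warnings = attr(net, "warnings")),
              class = "synthetic_image")
  })
}

finish_channel <- function(base, spec) {
  img <- gaussian_blur(base, spec$psf_sigma_um / spec$pixel_size_um) +
    spec$background_level
  if (spec$shot_noise)
    img <- matrix(stats::rpois(length(img), pmax(img, 0)),
                  nrow(img), ncol(img))
  if (spec$noise_sd > 0)
    img <- img + matrix(stats::rnorm(length(img), sd = spec$noise_sd),
                        nrow(img), ncol(img))
  pmax(img, 0)
}

#' @export
print.synthetic_image <- function(x, ...) {
  cat(sprintf("synthetic_image: channels [%s], %s px, %.3g um/px\n",
              paste(names(x$channels), collapse = ", "),
              if (length(x$channels)) paste(dim(x$channels[[1]]), collapse = " x ")
              else "un-rendered", x$pixel_size_um))
  print(x$truth)
  invisible(x)
}
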