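#' Specification of a synthetic epithelial monolayer image
#'
#' The stated world for the forward model: physical field size, target cell
#' count, rendering resolution, sinusoidal junction tortuosity (perpendicular
#' displacement amplitude and along-edge wavelength), optical parameters and
#' the myosin-channel decoration mode.  Defaults emulate a confluent MDCK II
#' monolayer imaged on a confocal at high zoom: ~65 um^2 cells, 0.1 um
#' pixels, ~0.25 um junction linewidth and a mild wild-type tortuosity.
#'
#' @param field_width_um,field_height_um physical field extent (um).
#' @param n_cells target number of Voronoi seed cells (>= 4).
#' @param pixel_size_um um per pixel (must not exceed `junction_width_um`).
#' @param tortuosity_amplitude_um perpendicular zigzag amplitude (um, >= 0;
#'   0 renders straight junctions, truth index exactly 1).
#' @param tortuosity_wavelength_um along-edge period of the zigzag (um).
#' @param junction_width_um rendered junction line width (um).
#' @param psf_sigma_um Gaussian point-spread blur (um).
#' @param background_level,junction_level mean intensities (arbitrary units).
#' @param noise_sd additive Gaussian noise SD (AU).
#' @param shot_noise logical; add Poisson shot noise before the Gaussian term.
#' @param myosin_mode `"none"`, `"continuous"` (myosin along the junction) or
#'   `"two_row"` (puncta flanking the junction, the knockout phenotype).
#' @param two_row_offset_um perpendicular offset of the two puncta rows (um).
#' @param puncta_spacing_um,puncta_sigma_um punctum spacing and Gaussian
#'   radius along the junction (um).
#' @param min_edge_um interior Voronoi edges with a shorter chord are
#'   contracted to one vertex before decoration (sub-resolution junctions).
#' @param seed integer RNG seed; one seed drives every stochastic draw.
#' @return validated list of class `monolayer_spec`.
#' @export
monolayer_spec <- function(field_width_um = 120, field_height_um = 120,
                           n_cells = 220, pixel_size_um = 0.1,
                           tortuosity_amplitude_um = 0.35,
                           tortuosity_wavelength_um = 3,
                           junction_width_um = 0.25, psf_sigma_um = 0.12,
                           background_level = 10, junction_level = 100,
                           noise_sd = 2, shot_noise = FALSE,
                           myosin_mode = c("none", "continuous", "two_row"),
                           two_row_offset_um = 0.5, puncta_spacing_um = 0.5,
                           puncta_sigma_um = 0.15, min_edge_um = 0.8,
                           seed = 1L) {
  myosin_mode <- match.arg(myosin_mode)
  spec <- list(field_width_um = field_width_um, field_height_um = field_height_um,
               n_cells = as.integer(n_cells), pixel_size_um = pixel_size_um,
               tortuosity_amplitude_um = tortuosity_amplitude_um,
               tortuosity_wavelength_um = tortuosity_wavelength_um,
               junction_width_um = junction_width_um, psf_sigma_um = psf_sigma_um,
               background_level = background_level, junction_level = junction_level,
               noise_sd = noise_sd, shot_noise = isTRUE(shot_noise),
               myosin_mode = myosin_mode, two_row_offset_um = two_row_offset_um,
               puncta_spacing_um = puncta_spacing_um,
               puncta_sigma_um = puncta_sigma_um, min_edge_um = min_edge_um,
               seed = as.integer(seed))
  for (f in c("field_width_um", "field_height_um", "pixel_size_um",
              "tortuosity_wavelength_um", "junction_width_um"))
    if (!is.numeric(spec[[f]]) || spec[[f]] <= 0)
      stop("monolayer_spec: ", f, " must be > 0")
  if (spec$tortuosity_amplitude_um < 0)
    stop("monolayer_spec: tortuosity_amplitude_um must be >= 0")
  if (spec$n_cells < 4L) stop("monolayer_spec: n_cells must be >= 4")
  if (spec$pixel_size_um > spec$junction_width_um)
    stop("monolayer_spec: pixel_size_um must not exceed junction_width_um")
  if (spec$psf_sigma_um < 0 || spec$noise_sd < 0 ||
      spec$background_level < 0 || spec$junction_level <= 0)
    stop("monolayer_spec: invalid intensity/optics parameters")
  structure(spec, class = "monolayer_spec")
}

# Sinusoidal perpendicular displacement of a straight chord; an integer
# number of periods pins both endpoints at the vertices.
decorate_sinusoid <- function(p1, p2, amplitude, wavelength) {
  chord <- sqrt(sum((p2 - p1)^2))
  if (amplitude <= 0 || chord <= 0) return(rbind(p1, p2))
  k <- max(1, round(chord / wavelength))
  lam_eff <- chord / k
  step <- min(lam_eff / 24, chord / 8)
  tt <- seq(0, 1, length.out = max(9L, ceiling(chord / step) + 1L))
  u <- (p2 - p1) / chord
  nrm <- c(-u[2], u[1])
  disp <- amplitude * sin(2 * pi * k * tt)
  cbind(p1[1] + tt * (p2[1] - p1[1]) + disp * nrm[1],
        p1[2] + tt * (p2[2] - p1[2]) + disp * nrm[2])
}

#' Build the ground-truth junction network of a synthetic monolayer
#'
#' Seeds cells by Poisson-disc sampling, tessellates the field into Voronoi
#' cells, contracts sub-resolution edges, and replaces every non-frame edge
#' by a sinusoidal polyline with the spec's amplitude and wavelength
#' (endpoints fixed at the vertices).  Sides touching the field border are
#' flagged `border = TRUE` and are excluded from index pooling downstream.
#'
#' @param spec a [monolayer_spec()].
#' @return a [junction_network()]; attribute `"warnings"` records sides whose
#'   amplitude reaches half their chord.
#' @export
build_junction_network <- function(spec) {
  stopifnot(inherits(spec, "monolayer_spec"))
  with_seed(spec$seed, build_network_impl(spec))
}

build_network_impl <- function(spec) {
  W <- spec$field_width_um
  H <- spec$field_height_um
  min_dist <- 0.7 * sqrt(W * H / spec$n_cells)
  seeds <- poisson_disc_sample(spec$n_cells, W, H, min_dist)
  cells <- voronoi_cells(seeds, W, H)
  interior <- vapply(cells, function(p) {
    !is.null(p) && nrow(p) >= 3L &&
      all(p[, 1] > 1e-6 & p[, 2] > 1e-6 &
            p[, 1] < W - 1e-6 & p[, 2] < H - 1e-6)
  }, logical(1))
  if (sum(interior) < 4L)
    stop("degenerate tessellation: fewer than 4 interior cells (got ",
         sum(interior), ")")
  g <- mosaic_graph(cells, W, H)
  g <- collapse_short_edges(g, spec$min_edge_um)
  v <- g$vertices
  e <- g$edges
  warns <- character(0)
  sides <- vector("list", nrow(e))
  for (i in seq_len(nrow(e))) {
    p1 <- c(v$x[match(e$v1[i], v$id)], v$y[match(e$v1[i], v$id)])
    p2 <- c(v$x[match(e$v2[i], v$id)], v$y[match(e$v2[i], v$id)])
    chord <- sqrt(sum((p2 - p1)^2))
    amp <- spec$tortuosity_amplitude_um
    if (amp > 0 && amp >= chord / 2)
      warns <- c(warns, sprintf(
        "side %d: amplitude %.3g um >= half chord %.3g um", i, amp, chord / 2))
    poly <- if (e$frame[i]) rbind(p1, p2)
      else decorate_sinusoid(p1, p2, amp, spec$tortuosity_wavelength_um)
    sides[[i]] <- list(id = i, v1 = e$v1[i], v2 = e$v2[i],
                       polyline = poly, border = e$border[i])
  }
  net <- junction_network(
    data.frame(id = v$id, x_um = v$x, y_um = v$y),
    sides, pixel_size_um = spec$pixel_size_um, field_um = c(W, H))
  attr(net, "warnings") <- warns
  net
}
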