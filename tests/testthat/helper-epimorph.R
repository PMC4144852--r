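# Shared fixtures, memoized so expensive renders are built once per run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# Small mosaic spec used throughout the unit tests (~25 cells, 40 x 40 um).
tiny_spec <- function(...) {
  args <- list(field_width_um = 40, field_height_um = 40, n_cells = 25,
               noise_sd = 0, seed = 5)
  do.call(monolayer_spec, utils::modifyList(args, list(...)))
}

# Medium mosaic (55 cells, 60 x 60 um) rendered noiselessly; full
# segment -> skeleton -> network products, shared across test files.
render_fixture <- function(amplitude, seed = 11) {
  key <- sprintf("render_%g_%d", amplitude, seed)
  cached(key, {
    sp <- monolayer_spec(field_width_um = 60, field_height_um = 60,
                         n_cells = 55, tortuosity_amplitude_um = amplitude,
                         noise_sd = 0, seed = seed)
    img <- generate_monolayer(sp)
    mask <- segment_junctions(img)
    net <- suppressMessages(extract_network(mask, img$pixel_size_um))
    list(spec = sp, img = img, mask = mask, net = net)
  })
}

# Rasterized 1-px truth polyline pixels (linear indices) of a render.
truth_pixel_indices <- function(img) {
  px <- img$pixel_size_um
  H <- nrow(img$channels$junction)
  W <- ncol(img$channels$junction)
  idx <- unique(unlist(lapply(img$truth$sides, function(s) {
    p <- resample_polyline(s$polyline, px / 2)
    r <- pmin(pmax(floor(p[, 2] / px) + 1, 1), H)
    cc <- pmin(pmax(floor(p[, 1] / px) + 1, 1), W)
    (cc - 1) * H + r
  })))
  idx
}

# Transverse line scans over myosin renders: returns classification labels
# for up to `per_image` junction crossings per seed.
myosin_scan_labels <- function(mode, seeds, per_image = 13L) {
  labels <- character(0)
  for (sd in seeds) {
    sp <- tiny_spec(tortuosity_amplitude_um = 0, myosin_mode = mode,
                    n_cells = 22, seed = sd)
    img <- generate_monolayer(sp)
    m <- measure_network(img$truth)
    ok <- which(!m$border & m$L_St_um > 3)
    Wf <- img$truth$field_um[1]
    taken <- 0L
    for (i in ok) {
      if (taken >= per_image) break
      s <- img$truth$sides[[match(m$side_id[i], vapply(img$truth$sides,
        function(x) as.character(x$id), character(1)))]]
      p <- s$polyline
      mid <- p[ceiling(nrow(p) / 2), ]
      u <- p[nrow(p), ] - p[1, ]
      u <- u / sqrt(sum(u^2))
      nrm <- c(-u[2], u[1])
      a <- mid + 1.5 * nrm
      b <- mid - 1.5 * nrm
      if (any(c(a, b) < 0.5) || any(c(a, b) > Wf - 0.5)) next
      sc <- line_scan(img, "myosin", a, b, width_um = 1)
      labels <- c(labels, classify_transverse_profile(sc))
      taken <- taken + 1L
    }
  }
  labels
}
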