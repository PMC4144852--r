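# Voronoi mosaic of the imaging field by perpendicular-bisector clipping.
# For each seed the cell polygon starts as the field rectangle and is cut by
# the half-plane nearer the seed than each neighbour; shared polygon edges
# give the exact junction topology (tricellular vertices emerge as the
# points where three clipped cells meet).

# Dart-throwing Poisson-disc sampling; returns <= n points.
poisson_disc_sample <- function(n, width, height, min_dist, max_tries = 300L * n) {
  xs <- numeric(0)
  ys <- numeric(0)
  tries <- 0L
  while (length(xs) < n && tries < max_tries) {
    x <- stats::runif(1, 0, width)
    y <- stats::runif(1, 0, height)
    if (length(xs) == 0L || min((xs - x)^2 + (ys - y)^2) >= min_dist^2) {
      xs <- c(xs, x)
      ys <- c(ys, y)
    }
    tries <- tries + 1L
  }
  cbind(xs, ys)
}

# Sutherland-Hodgman clip of a convex polygon by half-plane a*x + b*y <= c.
clip_halfplane <- function(poly, a, b, cc) {
  n <- nrow(poly)
  if (n == 0L) return(poly)
  f <- a * poly[, 1] + b * poly[, 2] - cc
  inside <- f <= 0
  out <- matrix(numeric(0), 0, 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (inside[i]) out <- rbind(out, poly[i, ])
    if (inside[i] != inside[j]) {
      t <- f[i] / (f[i] - f[j])
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  # drop numerically duplicated consecutive points
  if (nrow(out) > 1L) {
    d <- sqrt(rowSums((out - out[c(2:nrow(out), 1), ])^2))
    out <- out[d > 1e-9, , drop = FALSE]
  }
  out
}

# Voronoi cell polygons clipped to [0,width] x [0,height].
voronoi_cells <- function(seeds, width, height) {
  n <- nrow(seeds)
  rect <- rbind(c(0, 0), c(width, 0), c(width, height), c(0, height))
  cells <- vector("list", n)
  for (i in seq_len(n)) {
    poly <- rect
    d2 <- (seeds[, 1] - seeds[i, 1])^2 + (seeds[, 2] - seeds[i, 2])^2
    ord <- order(d2)
    for (j in ord) {
      if (j == i) next
      # all remaining seeds are farther than twice the cell radius: done
      maxr2 <- max((poly[, 1] - seeds[i, 1])^2 + (poly[, 2] - seeds[i, 2])^2)
      if (d2[j] > 4 * maxr2) break
      a <- 2 * (seeds[j, 1] - seeds[i, 1])
      b <- 2 * (seeds[j, 2] - seeds[i, 2])
      cc <- sum(seeds[j, ]^2) - sum(seeds[i, ]^2)
      poly <- clip_halfplane(poly, a, b, cc)
      if (nrow(poly) < 3L) break
    }
    cells[[i]] <- poly
  }
  cells
}

# Assemble the undirected edge/vertex structure of a clipped Voronoi mosaic.
# Returns vertices (id, x, y, border) and edges (v1, v2, border, frame);
# `frame` marks fragments lying along the field rectangle itself.
mosaic_graph <- function(cells, width, height, tol = 1e-6) {
  key <- function(x, y) sprintf("%.5f_%.5f", x, y)
  vx <- new.env(parent = emptyenv())
  vid <- 0L
  getv <- function(x, y) {
    k <- key(x, y)
    v <- vx[[k]]
    if (is.null(v)) {
      vid <<- vid + 1L
      v <- list(id = vid, x = x, y = y)
      vx[[k]] <- v
    }
    v$id
  }
  e1 <- integer(0)
  e2 <- integer(0)
  for (poly in cells) {
    m <- nrow(poly)
    if (is.null(m) || m < 3L) next
    ids <- vapply(seq_len(m), function(i) getv(poly[i, 1], poly[i, 2]), integer(1))
    jj <- c(2:m, 1L)
    e1 <- c(e1, ids)
    e2 <- c(e2, ids[jj])
  }
  vs <- as.list(vx)
  vdf <- data.frame(id = vapply(vs, function(v) v$id, integer(1)),
                    x = vapply(vs, function(v) v$x, numeric(1)),
                    y = vapply(vs, function(v) v$y, numeric(1)))
  vdf <- vdf[order(vdf$id), , drop = FALSE]
  on_border <- function(x, y)
    x < tol | y < tol | x > width - tol | y > height - tol
  vdf$border <- on_border(vdf$x, vdf$y)
  ekey <- paste(pmin(e1, e2), pmax(e1, e2))
  cnt <- table(ekey)
  first <- !duplicated(ekey)
  edf <- data.frame(v1 = pmin(e1, e2)[first], v2 = pmax(e1, e2)[first])
  edf$count <- as.integer(cnt[paste(edf$v1, edf$v2)])
  bx <- vdf$border[match(edf$v1, vdf$id)] | vdf$border[match(edf$v2, vdf$id)]
  edf$border <- edf$count == 1L | bx
  # frame fragments: both endpoints on the same rectangle side
  x1 <- vdf$x[match(edf$v1, vdf$id)]; y1 <- vdf$y[match(edf$v1, vdf$id)]
  x2 <- vdf$x[match(edf$v2, vdf$id)]; y2 <- vdf$y[match(edf$v2, vdf$id)]
  edf$frame <- (x1 < tol & x2 < tol) | (y1 < tol & y2 < tol) |
    (x1 > width - tol & x2 > width - tol) | (y1 > height - tol & y2 > height - tol)
  list(vertices = vdf, edges = edf)
}

# Contract interior edges shorter than min_len (merge endpoints at the
# midpoint); keeps the truth network commensurate with imaging resolution.
collapse_short_edges <- function(g, min_len) {
  v <- g$vertices
  e <- g$edges
  repeat {
    x1 <- v$x[match(e$v1, v$id)]; y1 <- v$y[match(e$v1, v$id)]
    x2 <- v$x[match(e$v2, v$id)]; y2 <- v$y[match(e$v2, v$id)]
    len <- sqrt((x1 - x2)^2 + (y1 - y2)^2)
    b1 <- v$border[match(e$v1, v$id)]
    b2 <- v$border[match(e$v2, v$id)]
    short <- which(len < min_len & !b1 & !b2)
    if (length(short) == 0L) break
    i <- short[1]
    keep <- e$v1[i]
    drop <- e$v2[i]
    k <- match(keep, v$id)
    d <- match(drop, v$id)
    v$x[k] <- (v$x[k] + v$x[d]) / 2
    v$y[k] <- (v$y[k] + v$y[d]) / 2
    v <- v[-d, , drop = FALSE]
    e$v1[e$v1 == drop] <- keep
    e$v2[e$v2 == drop] <- keep
    e <- e[e$v1 != e$v2, , drop = FALSE]
    nv1 <- pmin(e$v1, e$v2); nv2 <- pmax(e$v1, e$v2)
    e$v1 <- nv1; e$v2 <- nv2
    e <- e[!duplicated(paste(e$v1, e$v2)), , drop = FALSE]
  }
  list(vertices = v, edges = e)
}
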