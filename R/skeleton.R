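# Zhang-Suen thinning and skeleton-graph tracing.

#' Thin a binary mask to 1-pixel centerlines
#'
#' Zhang-Suen iterative thinning (two sub-iterations per pass until stable).
#' @param mask logical matrix.
#' @return logical matrix of the same shape.
#' @export
skeletonize <- function(mask) {
  M <- mask
  H <- nrow(M)
  W <- ncol(M)
  nbr <- function(pad, dr, dc) pad[(2 + dr):(H + 1 + dr), (2 + dc):(W + 1 + dc)]
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      pad <- matrix(FALSE, H + 2, W + 2)
      pad[2:(H + 1), 2:(W + 1)] <- M
      p2 <- nbr(pad, -1, 0); p3 <- nbr(pad, -1, 1); p4 <- nbr(pad, 0, 1)
      p5 <- nbr(pad, 1, 1); p6 <- nbr(pad, 1, 0); p7 <- nbr(pad, 1, -1)
      p8 <- nbr(pad, 0, -1); p9 <- nbr(pad, -1, -1)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
        (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      cond <- if (pass == 1)
        M & B >= 2 & B <= 6 & A == 1 & !(p2 & p4 & p6) & !(p4 & p6 & p8)
      else
        M & B >= 2 & B <= 6 & A == 1 & !(p2 & p4 & p8) & !(p2 & p6 & p8)
      if (any(cond)) {
        M[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  M
}

# 8-neighbour count of every pixel of a logical matrix.
neighbor_count <- function(M) {
  H <- nrow(M)
  W <- ncol(M)
  pad <- matrix(0L, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- M
  s <- matrix(0L, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    s <- s + pad[(2 + dr):(H + 1 + dr), (2 + dc):(W + 1 + dc)]
  }
  s
}

# Crossing number: 0->1 transitions in the circular 8-neighbourhood.
# Curve pixels score 2 whatever their raw neighbour count; true branch
# points score >= 3, line ends score 1.
transition_count <- function(M) {
  H <- nrow(M)
  W <- ncol(M)
  pad <- matrix(FALSE, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- M
  nbr <- function(dr, dc) pad[(2 + dr):(H + 1 + dr), (2 + dc):(W + 1 + dc)]
  p2 <- nbr(-1, 0); p3 <- nbr(-1, 1); p4 <- nbr(0, 1); p5 <- nbr(1, 1)
  p6 <- nbr(1, 0); p7 <- nbr(1, -1); p8 <- nbr(0, -1); p9 <- nbr(-1, -1)
  (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
    (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
}

# Order the pixels of one skeleton branch component into a simple path.
# L: sorted linear indices of the component.  Uses the shortest pixel-graph
# path between the two most distant endpoints (double-BFS when the
# staircase is doubled and no degree-1 pixel exists), which also straightens
# redundant staircase pixels.  Returns list(path = positional indices,
# had_endpoint = logical); a closed component without endpoints comes back
# with had_endpoint = FALSE so the caller can decide ring vs arc.
order_branch_path <- function(L, H) {
  s <- length(L)
  if (s == 1L) return(list(path = 1L, had_endpoint = TRUE))
  r <- (L - 1L) %% H + 1L
  cc <- (L - 1L) %/% H + 1L
  offs <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  nb <- matrix(NA_integer_, s, 8L)
  for (k in 1:8) {
    dr <- offs[k, 1]
    dc <- offs[k, 2]
    j <- match(L + dr + dc * H, L)
    j[r + dr < 1L | r + dr > H] <- NA_integer_
    nb[, k] <- j
  }
  ii <- rep(seq_len(s), 8L)
  jj <- as.vector(nb)
  keep <- !is.na(jj) & ii < jj
  g <- igraph::make_graph(rbind(ii[keep], jj[keep]), n = s, directed = FALSE)
  deg <- rowSums(!is.na(nb))
  ends <- which(deg <= 1L)
  had_endpoint <- length(ends) > 0L
  if (length(ends) >= 2L) {
    d2 <- outer(r[ends], r[ends], "-")^2 + outer(cc[ends], cc[ends], "-")^2
    pick <- arrayInd(which.max(d2), dim(d2))
    u <- ends[pick[1]]
    v <- ends[pick[2]]
  } else {
    du <- igraph::distances(g, v = 1)[1, ]
    du[!is.finite(du)] <- -1
    u <- which.max(du)
    dv <- igraph::distances(g, v = u)[1, ]
    dv[!is.finite(dv)] <- -1
    v <- which.max(dv)
  }
  if (u == v) return(list(path = u, had_endpoint = had_endpoint))
  path <- as.integer(igraph::shortest_paths(g, from = u, to = v,
                                            output = "vpath")$vpath[[1]])
  list(path = path, had_endpoint = had_endpoint)
}

# Junction pixels by cell adjacency.  Cell interiors (background components
# of the segmentation mask, small noise holes excluded) are propagated
# across the foreground ridge so that label fronts meet at the centerline;
# a skeleton pixel with >= 3 distinct cell labels in a tight neighbourhood
# is a tricellular (or higher-order) node.  Robust to thinning staircase
# artifacts that defeat the crossing-number criterion.
junction_node_pixels <- function(sk, mask, radius_px = 2L, min_cell_px = 30L,
                                 max_fill_iter = 50L) {
  H <- nrow(sk)
  W <- ncol(sk)
  cl <- label_components(!mask)
  if (max(cl) < 3L) return(sk & FALSE)
  sizes <- tabulate(cl[cl > 0L])
  tiny <- cl > 0L
  tiny[tiny] <- sizes[cl[tiny]] < min_cell_px
  cl[tiny] <- 0L
  if (length(unique(cl[cl > 0L])) < 3L) return(sk & FALSE)
  # grow each cell across the ridge until fronts meet (deterministic fill)
  for (it in seq_len(max_fill_iter)) {
    empty <- cl == 0L
    if (!any(empty)) break
    pad <- matrix(0L, H + 2L, W + 2L)
    pad[2:(H + 1), 2:(W + 1)] <- cl
    filled <- FALSE
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      nb <- pad[(2 + dr):(H + 1 + dr), (2 + dc):(W + 1 + dc)]
      take <- empty & cl == 0L & nb > 0L
      if (any(take)) {
        cl[take] <- nb[take]
        filled <- TRUE
      }
    }
    if (!filled) break
  }
  idx <- which(sk)
  r <- (idx - 1L) %% H + 1L
  cc <- (idx - 1L) %/% H + 1L
  off <- expand.grid(dr = -radius_px:radius_px, dc = -radius_px:radius_px)
  labs <- matrix(0L, length(idx), nrow(off))
  for (k in seq_len(nrow(off))) {
    r1 <- r + off$dr[k]
    c1 <- cc + off$dc[k]
    ok <- r1 >= 1L & r1 <= H & c1 >= 1L & c1 <= W
    v <- integer(length(idx))
    v[ok] <- cl[(c1[ok] - 1L) * H + r1[ok]]
    labs[, k] <- v
  }
  ndist <- apply(labs, 1, function(x) length(unique(x[x > 0L])))
  node <- sk & FALSE
  node[idx[ndist >= 3L]] <- TRUE
  node
}

#' Extract a junction network from a segmented mask
#'
#' Skeletonizes the mask, places graph nodes at skeleton pixels with three
#' or more neighbours (merging node clusters within `merge_radius_px`) and
#' at free line terminations, traces every branch into an ordered polyline,
#' prunes short terminal spurs, contracts sub-resolution node-to-node
#' stubs, and lightly smooths the traced polylines to suppress the pixel
#' staircase before lengths are measured.  Closed rings that meet no node
#' are dropped (their count is kept in attribute `"dropped_rings"`).
#'
#' @param mask logical matrix from [segment_junctions()].
#' @param pixel_size_um um per pixel.
#' @param prune_spur_um terminal branches shorter than this are deleted.
#' @param node_radius_px a skeleton pixel is a junction node iff at least 3
#'   distinct cells (background components of the mask) lie within this
#'   radius; robust to thinning staircase artifacts.
#' @param merge_radius_px node pixels within this radius fuse to one vertex.
#' @param min_side_um node-to-node sides with a shorter chord are contracted.
#' @param smooth_sigma_px Gaussian sigma for polyline coordinate smoothing.
#' @param border_margin_px sides passing within this margin of the image
#'   edge are flagged `border`.
#' @return a [junction_network()].
#' @export
extract_network <- function(mask, pixel_size_um, prune_spur_um = 1,
                            node_radius_px = 2, merge_radius_px = 3,
                            min_side_um = 0.6, smooth_sigma_px = 0.6,
                            border_margin_px = 3) {
  if (!any(mask)) stop("mask is empty")
  px <- pixel_size_um
  H <- nrow(mask)
  W <- ncol(mask)
  sk <- skeletonize(mask)
  if (!any(sk)) stop("skeleton is empty")
  node <- junction_node_pixels(sk, mask, node_radius_px)
  # fall back to the crossing-number criterion for masks with no resolvable
  # cell interiors (thin synthetic test patterns)
  if (!any(node)) node <- sk & transition_count(sk) >= 3L

  # --- fuse node pixels into vertex clusters -------------------------------
  nidx <- which(node)
  clmap <- integer(H * W)
  centroids <- matrix(numeric(0), 0, 2)
  n_cl <- 0L
  if (length(nidx) > 0L) {
    r <- (nidx - 1L) %% H + 1L
    cc <- (nidx - 1L) %/% H + 1L
    mr2 <- merge_radius_px^2
    el <- list()
    k <- 0L
    for (dr in 0:merge_radius_px) for (dc in -merge_radius_px:merge_radius_px) {
      if (dr == 0L && dc <= 0L) next
      if (dr^2 + dc^2 > mr2) next
      j <- match(nidx + dr + dc * H, nidx)
      ok <- !is.na(j) & r + dr >= 1L & r + dr <= H
      if (any(ok)) {
        k <- k + 1L
        el[[k]] <- cbind(seq_along(nidx)[ok], j[ok])
      }
    }
    el <- if (k) do.call(rbind, el) else matrix(integer(0), 0, 2)
    g <- igraph::make_graph(if (nrow(el)) as.vector(t(el)) else integer(0),
                            n = length(nidx), directed = FALSE)
    mem <- igraph::components(g)$membership
    n_cl <- max(mem)
    clmap[nidx] <- mem
    cx <- as.numeric(tapply((cc - 0.5) * px, mem, mean))
    cy <- as.numeric(tapply((r - 0.5) * px, mem, mean))
    centroids <- cbind(cx, cy)
  }

  # --- trace branches ------------------------------------------------------
  # cut out each node pixel plus its 1-ring: arm pixels flanking a junction
  # are mutually 8-adjacent, so removing the node alone does not split them
  node_dil <- node
  if (any(node)) {
    pad <- matrix(FALSE, H + 2, W + 2)
    pad[2:(H + 1), 2:(W + 1)] <- node
    for (dr in -1:1) for (dc in -1:1)
      node_dil <- node_dil | pad[(2 + dr):(H + 1 + dr), (2 + dc):(W + 1 + dc)]
  }
  branch <- sk & !node_dil
  lab <- label_components(branch)
  comp_idx <- split(which(branch), lab[branch])
  verts <- list()
  for (i in seq_len(n_cl))
    verts[[i]] <- list(x = centroids[i, 1], y = centroids[i, 2],
                       terminal = FALSE)
  sides <- list()
  dropped_rings <- 0L

  adj_clusters <- function(lin) {
    r0 <- (lin - 1L) %% H + 1L
    c0 <- (lin - 1L) %/% H + 1L
    out <- integer(0)
    for (dr in -2:2) for (dc in -2:2) {
      if (dr == 0L && dc == 0L) next
      r1 <- r0 + dr
      c1 <- c0 + dc
      if (r1 < 1L || r1 > H || c1 < 1L || c1 > W) next
      j <- (c1 - 1L) * H + r1
      if (clmap[j] > 0L) out <- c(out, clmap[j])
    }
    unique(out)
  }
  new_terminal <- function(x, y) {
    verts[[length(verts) + 1L]] <<- list(x = x, y = y, terminal = TRUE)
    length(verts)
  }
  pick_cluster <- function(cls, x, y) {
    if (length(cls) == 1L) return(cls)
    d2 <- (centroids[cls, 1] - x)^2 + (centroids[cls, 2] - y)^2
    cls[which.min(d2)]
  }

  for (comp in comp_idx) {
    L <- sort(comp)
    ord <- order_branch_path(L, H)
    if (!ord$had_endpoint) {
      # no free end: isolated ring unless the component touches a cluster
      touches <- any(vapply(L, function(l) length(adj_clusters(l)) > 0L,
                            logical(1)))
      if (!touches) {
        dropped_rings <- dropped_rings + 1L
        next
      }
    }
    lin <- L[ord$path]
    xs <- ((lin - 1L) %/% H + 0.5) * px
    ys <- ((lin - 1L) %% H + 0.5) * px
    a1 <- adj_clusters(lin[1])
    a2 <- adj_clusters(lin[length(lin)])
    if (length(lin) == 1L && length(a1) >= 2L) {
      # single pixel bridging two clusters
      v1 <- a1[1]
      v2 <- a1[2]
    } else {
      v1 <- if (length(a1)) pick_cluster(a1, xs[1], ys[1]) else
        new_terminal(xs[1], ys[1])
      v2 <- if (length(a2)) pick_cluster(a2, xs[length(lin)], ys[length(lin)]) else
        new_terminal(xs[length(lin)], ys[length(lin)])
    }
    poly <- cbind(xs, ys)
    if (!verts[[v1]]$terminal) poly <- rbind(c(verts[[v1]]$x, verts[[v1]]$y), poly)
    if (!verts[[v2]]$terminal) poly <- rbind(poly, c(verts[[v2]]$x, verts[[v2]]$y))
    sides[[length(sides) + 1L]] <- list(v1 = v1, v2 = v2, polyline = poly)
  }
  # isolated clusters with no branch (all-node blobs) simply keep degree 0
  if (length(sides) == 0L) stop("no junction sides could be traced")

  # --- prune terminal spurs ------------------------------------------------
  if (prune_spur_um > 0) {
    deg <- integer(length(verts))
    for (s in sides) {
      deg[s$v1] <- deg[s$v1] + 1L
      deg[s$v2] <- deg[s$v2] + 1L
    }
    keep <- vapply(sides, function(s) {
      free1 <- verts[[s$v1]]$terminal && deg[s$v1] == 1L
      free2 <- verts[[s$v2]]$terminal && deg[s$v2] == 1L
      !((free1 || free2) && polyline_length(s$polyline) < prune_spur_um)
    }, logical(1))
    sides <- sides[keep]
    if (length(sides) == 0L) stop("no junction sides left after spur pruning")
  }

  # --- contract sub-resolution node-to-node stubs --------------------------
  repeat {
    done <- TRUE
    for (i in seq_along(sides)) {
      s <- sides[[i]]
      if (s$v1 == s$v2) next
      if (verts[[s$v1]]$terminal || verts[[s$v2]]$terminal) next
      chord <- sqrt((verts[[s$v1]]$x - verts[[s$v2]]$x)^2 +
                      (verts[[s$v1]]$y - verts[[s$v2]]$y)^2)
      if (chord >= min_side_um) next
      vkeep <- s$v1
      vdrop <- s$v2
      verts[[vkeep]]$x <- (verts[[vkeep]]$x + verts[[vdrop]]$x) / 2
      verts[[vkeep]]$y <- (verts[[vkeep]]$y + verts[[vdrop]]$y) / 2
      sides <- sides[-i]
      for (j in seq_along(sides)) {
        if (sides[[j]]$v1 == vdrop) sides[[j]]$v1 <- vkeep
        if (sides[[j]]$v2 == vdrop) sides[[j]]$v2 <- vkeep
      }
      done <- FALSE
      break
    }
    if (done) break
  }

  # --- finalize: smooth, pin endpoints, flag border ------------------------
  used <- sort(unique(unlist(lapply(sides, function(s) c(s$v1, s$v2)))))
  remap <- integer(length(verts))
  remap[used] <- seq_along(used)
  vx <- vapply(verts[used], `[[`, numeric(1), "x")
  vy <- vapply(verts[used], `[[`, numeric(1), "y")
  margin <- border_margin_px * px
  out_sides <- vector("list", length(sides))
  for (i in seq_along(sides)) {
    s <- sides[[i]]
    v1 <- remap[s$v1]
    v2 <- remap[s$v2]
    poly <- smooth_polyline(s$polyline, smooth_sigma_px)
    poly[1, ] <- c(vx[v1], vy[v1])
    poly[nrow(poly), ] <- c(vx[v2], vy[v2])
    border <- any(poly[, 1] < margin | poly[, 1] > W * px - margin |
                    poly[, 2] < margin | poly[, 2] > H * px - margin)
    out_sides[[i]] <- list(id = i, v1 = v1, v2 = v2, polyline = poly,
                           border = border)
  }
  net <- junction_network(
    data.frame(id = seq_along(used), x_um = vx, y_um = vy),
    out_sides, pixel_size_um = px, field_um = c(W * px, H * px))
  attr(net, "dropped_rings") <- dropped_rings
  if (dropped_rings > 0L)
    message(dropped_rings, " isolated skeleton ring(s) dropped")
  net
}
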