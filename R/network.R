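#' Construct a junction network
#'
#' The morphometric substrate: a planar graph of tricellular vertices joined
#' by polyline junction sides, in micrometres with the image convention
#' (origin top-left, x rightward, y downward).
#'
#' @param vertices data.frame with columns `id`, `x_um`, `y_um`.
#' @param sides list; each element a list with `id`, `v1`, `v2`,
#'   `polyline` (n x 2 matrix of x/y in um, first/last rows at the vertex
#'   coordinates) and `border` (logical: touches the field border).
#' @param pixel_size_um provenance: um per pixel of the source image (NA if
#'   the network is analytic ground truth).
#' @param field_um length-2 numeric, physical field extent (width, height).
#' @return object of class `junction_network`.
#' @export
junction_network <- function(vertices, sides, pixel_size_um = NA_real_,
                             field_um = c(NA_real_, NA_real_)) {
  stopifnot(is.data.frame(vertices),
            all(c("id", "x_um", "y_um") %in% names(vertices)),
            is.list(sides))
  vmap <- stats::setNames(seq_len(nrow(vertices)), vertices$id)
  for (s in sides) {
    stopifnot(!is.null(s$polyline), nrow(s$polyline) >= 2L)
    for (v in c(s$v1, s$v2))
      if (is.na(vmap[as.character(v)]))
        stop("side ", s$id, " references unknown vertex ", v)
    p1 <- s$polyline[1, ]
    p2 <- s$polyline[nrow(s$polyline), ]
    i1 <- vmap[as.character(s$v1)]
    i2 <- vmap[as.character(s$v2)]
    if (max(abs(p1 - c(vertices$x_um[i1], vertices$y_um[i1]))) > 1e-6 ||
        max(abs(p2 - c(vertices$x_um[i2], vertices$y_um[i2]))) > 1e-6)
      stop("side ", s$id, ": polyline endpoints do not coincide with its vertices")
  }
  structure(list(vertices = vertices, sides = sides,
                 pixel_size_um = pixel_size_um, field_um = field_um),
            class = "junction_network")
}

#' @export
print.junction_network <- function(x, ...) {
  nb <- sum(vapply(x$sides, function(s) isTRUE(s$border), logical(1)))
  cat(sprintf("junction_network: %d vertices, %d sides (%d border), field %.4g x %.4g um\n",
              nrow(x$vertices), length(x$sides), nb,
              x$field_um[1], x$field_um[2]))
  invisible(x)
}

#' Measure one junction side
#'
#' `L_TJ` is the traced path length (sum of consecutive polyline point
#' distances); `L_St` is the straight vertex-to-vertex chord.  Their pooled
#' ratio is the zigzag index.
#'
#' @param side one element of `junction_network$sides`.
#' @return list with `side_id`, `L_TJ_um`, `L_St_um`, `border`, or `NULL`
#'   (with a message) for degenerate sides whose vertices coincide.
#' @examples
#' s <- list(id = 1, v1 = 1, v2 = 2, border = FALSE,
#'           polyline = rbind(c(0, 0), c(1, 1), c(2, 0)))
#' measure_edge(s)$L_TJ_um  # 2*sqrt(2)
#' @export
measure_edge <- function(side) {
  p <- side$polyline
  L_tj <- polyline_length(p)
  L_st <- sqrt(sum((p[nrow(p), ] - p[1, ])^2))
  if (L_st <= 0) {
    message("side ", side$id, " excluded: coincident vertices (L_St = 0)")
    return(NULL)
  }
  list(side_id = side$id, L_TJ_um = L_tj, L_St_um = L_st,
       border = isTRUE(side$border))
}

#' Per-side morphometry table for a whole network
#'
#' @param network a [junction_network()].
#' @return data.frame with one row per non-degenerate side: `side_id`,
#'   `L_TJ_um`, `L_St_um`, `border`.
#' @export
measure_network <- function(network) {
  rows <- lapply(network$sides, measure_edge)
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    return(data.frame(side_id = character(0), L_TJ_um = numeric(0),
                      L_St_um = numeric(0), border = logical(0)))
  data.frame(side_id = vapply(rows, function(r) as.character(r$side_id), character(1)),
             L_TJ_um = vapply(rows, function(r) r$L_TJ_um, numeric(1)),
             L_St_um = vapply(rows, function(r) r$L_St_um, numeric(1)),
             border = vapply(rows, function(r) r$border, logical(1)),
             stringsAsFactors = FALSE)
}

#' Zigzag index of a set of sides
#'
#' Ratio of sums, `sum(L_TJ) / sum(L_St)` -- not the mean of per-side
#' ratios -- over the sides of one sampled window.
#'
#' @param side_ids character/numeric ids selecting rows of `morphometry`.
#' @param morphometry data.frame from [measure_network()].
#' @param window optional window geometry to carry along.
#' @return object of class `zigzag_index`: list with `value`, `n_sides`,
#'   `window`.
#' @examples
#' m <- data.frame(side_id = c("a", "b"), L_TJ_um = c(3, 5),
#'                 L_St_um = c(2, 4), border = FALSE)
#' compute_zigzag_index(c("a", "b"), m)$value  # 8/6
#' @export
compute_zigzag_index <- function(side_ids, morphometry, window = NULL) {
  if (length(side_ids) == 0L) stop("empty side set: zigzag index undefined")
  i <- match(as.character(side_ids), morphometry$side_id)
  if (anyNA(i)) stop("unknown side id(s): ",
                     paste(side_ids[is.na(i)], collapse = ", "))
  structure(list(value = sum(morphometry$L_TJ_um[i]) / sum(morphometry$L_St_um[i]),
                 n_sides = length(i), window = window),
            class = "zigzag_index")
}

#' Pooled ground-truth zigzag index of a network
#'
#' Convenience wrapper: ratio of sums over all non-border sides.
#' @param network a [junction_network()].
#' @return numeric scalar >= 1.
#' @export
pooled_zigzag_index <- function(network) {
  m <- measure_network(network)
  m <- m[!m$border, , drop = FALSE]
  if (nrow(m) == 0L) stop("network has no non-border sides")
  sum(m$L_TJ_um) / sum(m$L_St_um)
}
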