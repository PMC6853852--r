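#' Normalized vertical gradient of a B-scan
#'
#' Retinal layer boundaries show up as axial intensity transitions: dark to
#' bright (e.g. vitreous into NFL, ONL into the IS-OS complex) or bright to
#' dark (e.g. RPE into the choroid). The raw vertical first difference
#' `D(r, c) = I(r, c) - I(r - 1, c)` is positive where intensity increases
#' with depth; it is min-max rescaled to `[0, 1]` over the whole image. The
#' bright-to-dark map is the pointwise inverse `1 - map` of the
#' dark-to-bright map, so each polarity highlights one transition sign.
#' Row 1 (which has no row above) replicates row 2's difference so no
#' artificial transition appears at the image top.
#'
#' @param image An `oct_bscan` or numeric matrix with at least 2 rows.
#' @param polarity `"dark_to_bright"` or `"bright_to_dark"`.
#' @return An `oct_gradient`: list with `values` (matrix in `[0, 1]`, same
#'   shape as the image) and `polarity`.
#' @examples
#' g <- vertical_gradient(matrix(c(0, 100, 50, 0, 100, 50), 3, 2))
#' g$values
#' @export
vertical_gradient <- function(image,
                              polarity = c("dark_to_bright", "bright_to_dark")) {
  polarity <- match.arg(polarity)
  px <- as_bscan(image)$pixels
  d <- px[-1L, , drop = FALSE] - px[-nrow(px), , drop = FALSE]
  d <- rbind(d[1L, , drop = FALSE], d)
  lo <- min(d)
  hi <- max(d)
  if (hi <= lo) {
    warning("constant image: vertical gradient is degenerate, returning 0.5")
    v <- matrix(0.5, nrow(px), ncol(px))
  } else {
    v <- (d - lo) / (hi - lo)
  }
  if (polarity == "bright_to_dark") v <- 1 - v
  structure(list(values = v, polarity = polarity), class = "oct_gradient")
}

#' Build the weighted pixel adjacency graph from a gradient map
#'
#' Every pixel is a node; neighboring pixels (8- or 4-connectivity) are
#' joined by an undirected edge with weight
#' `w_ab = 2 - g_a - g_b + w_min`,
#' where `g_a`, `g_b` are the normalized gradient values at the two nodes
#' and `w_min` is a small positive stabilization constant. Edges lying along
#' a strong transition of the map's polarity thus get weights near `w_min`,
#' and edges in homogeneous tissue weights near `2 + w_min`, so the minimum
#' weighted lateral path traces the strongest boundary.
#'
#' @param grad An `oct_gradient` from [vertical_gradient()].
#' @param w_min Positive stabilization constant added to every weight.
#' @param connectivity 8 (diagonal moves allowed, the default: sloped
#'   boundaries need diagonal steps) or 4.
#' @return A `pixel_graph`: node indices are column-major over the `H x W`
#'   image grid; edges stored as vectors `from`, `to`, `w`.
#' @export
build_pixel_graph <- function(grad, w_min = 1e-5, connectivity = 8) {
  if (!inherits(grad, "oct_gradient"))
    stop("`grad` must come from vertical_gradient()")
  if (!is.numeric(w_min) || length(w_min) != 1L || w_min <= 0)
    stop("`w_min` must be a single positive number (Dijkstra needs positive weights)")
  if (!connectivity %in% c(4, 8)) stop("`connectivity` must be 4 or 8")
  g <- grad$values
  H <- nrow(g)
  W <- ncol(g)
  idx <- matrix(seq_len(H * W), H, W)
  offsets <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offsets <- c(offsets, list(c(1L, 1L), c(1L, -1L)))
  from <- to <- integer(0)
  for (off in offsets) {
    dr <- off[1L]; dc <- off[2L]
    rs <- seq_len(H - dr)
    cs <- if (dc >= 0L) seq_len(W - dc) else seq.int(1L - dc, W)
    from <- c(from, as.integer(idx[rs, cs, drop = FALSE]))
    to <- c(to, as.integer(idx[rs + dr, cs + dc, drop = FALSE]))
  }
  gv <- as.vector(g)
  structure(
    list(H = H, W = W, from = from, to = to,
         w = 2 - gv[from] - gv[to] + w_min,
         w_min = w_min, polarity = grad$polarity,
         connectivity = connectivity,
         fuzzified = FALSE, augmented = FALSE),
    class = "pixel_graph"
  )
}

#' @export
print.pixel_graph <- function(x, ...) {
  cat(sprintf(
    "<pixel_graph> %d x %d image%s, %s, %d edges, w in [%.6g, %.6g]%s\n",
    x$H, x$W, if (x$augmented) " + 2 virtual columns" else "",
    x$polarity, length(x$w), min(x$w), max(x$w),
    if (x$fuzzified) ", fuzzified" else ""
  ))
  invisible(x)
}

#' Fuzzify graph edge weights
#'
#' Re-assigns the adjacency weights through the same fuzzy hyperbolization
#' idea used for pixel intensities, with a constant fuzzifier for speed:
#' weights are min-max normalized over all edges of the graph,
#' `w' = (w - min) / (max - min)`, raised to the power `beta_w`,
#' `w'' = (w')^beta_w`, and floored by adding `w_min` back so every weight
#' stays strictly positive. The map is monotone, so the relative order of
#' edge weights is preserved; cheap boundary edges are pushed towards the
#' floor and expensive homogeneous-tissue edges stay near `1 + w_min`,
#' which re-emphasizes both continuity and discontinuity and steers the
#' shortest path away from "wrong short-cuts".
#'
#' @param graph A `pixel_graph` from [build_pixel_graph()].
#' @param beta_w Positive constant fuzzifier exponent.
#' @return The graph with re-assigned weights in `[w_min, 1 + w_min]`.
#' @export
fuzzify_weights <- function(graph, beta_w = 2) {
  if (!inherits(graph, "pixel_graph")) stop("`graph` must be a pixel_graph")
  if (graph$augmented)
    stop("fuzzify before adding endpoint columns: virtual edges keep weight w_min")
  if (!is.numeric(beta_w) || length(beta_w) != 1L || beta_w <= 0)
    stop("`beta_w` must be a single positive number")
  lo <- min(graph$w)
  hi <- max(graph$w)
  if (hi <= lo) stop("degenerate graph: all edge weights equal")
  graph$w <- ((graph$w - lo) / (hi - lo))^beta_w + graph$w_min
  graph$fuzzified <- TRUE
  graph$beta_w <- beta_w
  graph
}

#' Append virtual endpoint columns to a pixel graph
#'
#' Retinal boundaries extend across the full image width, so the search is
#' initialized by appending one virtual column on each lateral side whose
#' edges (vertical within the column and horizontal into the image) all
#' carry the minimum weight `w_min`. A path can then enter or leave the
#' image at any row at negligible cost; the source is the top of the left
#' virtual column and the sink the top of the right one.
#'
#' @param graph A `pixel_graph` (typically after [fuzzify_weights()]).
#' @return The graph re-indexed over the `H x (W + 2)` augmented grid, with
#'   `source` and `sink` node indices set.
#' @export
add_endpoint_columns <- function(graph) {
  if (!inherits(graph, "pixel_graph")) stop("`graph` must be a pixel_graph")
  if (graph$augmented) stop("endpoint columns already added")
  H <- graph$H
  Wa <- graph$W + 2L
  # image columns shift right by one: node index gains H
  from <- graph$from + H
  to <- graph$to + H
  w <- graph$w
  left <- seq_len(H)
  right <- (Wa - 1L) * H + seq_len(H)
  vert_from <- c(left[-H], right[-H])
  vert_to <- c(left[-1L], right[-1L])
  horiz_from <- c(left, right)
  horiz_to <- c(left + H, right - H)
  n_virtual <- length(vert_from) + length(horiz_from)
  graph$from <- c(from, vert_from, horiz_from)
  graph$to <- c(to, vert_to, horiz_to)
  graph$w <- c(w, rep(graph$w_min, n_virtual))
  graph$Wa <- Wa
  graph$augmented <- TRUE
  graph$source <- 1L
  graph$sink <- (Wa - 1L) * H + 1L
  graph
}
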