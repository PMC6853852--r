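#' Restrict the shortest-path search to a band between two boundaries
#'
#' Sequential segmentation uses previously found boundaries as benchmarks:
#' each new search runs strictly between an upper and a lower reference,
#' with a safety margin excluded next to each reference so a delimiting
#' boundary cannot be re-found. `NULL` references mean the image top or
#' bottom (no margin applied there).
#'
#' @param upper Upper reference: an `oct_boundary`, a numeric vector of
#'   per-column rows, or `NULL` for the image top.
#' @param lower Lower reference, or `NULL` for the image bottom.
#' @param height,width Dimensions of the (cropped) image.
#' @param margin Rows excluded adjacent to each delimiting boundary.
#' @return An `oct_region` with per-column allowed row ranges `lo..hi`
#'   (inclusive, 1-based).
#' @examples
#' r <- limit_region(upper = rep(11, 5), lower = rep(101, 5),
#'                   height = 120, width = 5, margin = 2)
#' r$lo[1] # 14
#' r$hi[1] # 98
#' @export
limit_region <- function(upper = NULL, lower = NULL, height, width, margin = 1) {
  as_rows <- function(b) {
    if (is.null(b)) return(NULL)
    if (inherits(b, "oct_boundary")) b <- b$rows
    if (length(b) != width) stop("reference boundary length must equal image width")
    b
  }
  up <- as_rows(upper)
  lo_ref <- as_rows(lower)
  lo <- if (is.null(up)) rep(1L, width) else round(up) + margin + 1
  hi <- if (is.null(lo_ref)) rep(height, width) else round(lo_ref) - margin - 1
  if (!is.null(up) && !is.null(lo_ref) && any(lo_ref < up))
    stop("ordering error: lower reference crosses above upper reference")
  lo <- pmax(lo, 1)
  hi <- pmin(hi, height)
  if (any(lo > hi))
    stop(sprintf("region empty in %d column(s): references too close for margin %g",
                 sum(lo > hi), margin))
  structure(list(lo = lo, hi = hi, margin = margin,
                 height = height, width = width),
            class = "oct_region")
}

#' Trace one layer boundary as a minimum-weight graph path
#'
#' Runs Dijkstra's algorithm from the top of the left virtual column to the
#' top of the right virtual column, optionally restricted to an
#' [limit_region()] band (nodes outside the band are removed). The node path
#' is converted to a per-column boundary: virtual-column nodes are dropped
#' and, where 8-connectivity lets the path visit several rows of one image
#' column, the last visited row is kept so the boundary is single-valued.
#'
#' @param graph An augmented `pixel_graph` (after [add_endpoint_columns()]).
#' @param region An `oct_region`, or `NULL` for the whole image.
#' @param label Optional boundary label to attach.
#' @return An `oct_boundary`: per-column `rows` (length = image width),
#'   `label`, `mean_row` and total path `cost`.
#' @export
trace_boundary <- function(graph, region = NULL, label = NA_character_) {
  if (!inherits(graph, "pixel_graph") || !graph$augmented)
    stop("`graph` must be a pixel_graph with endpoint columns added")
  H <- graph$H
  W <- graph$W
  Wa <- graph$Wa
  n <- H * Wa
  keep <- rep(TRUE, n)
  if (!is.null(region)) {
    if (!inherits(region, "oct_region")) stop("`region` must come from limit_region()")
    if (region$height != H || region$width != W)
      stop("region dimensions do not match the graph")
    rowv <- rep(seq_len(H), times = W)
    lo <- rep(region$lo, each = H)
    hi <- rep(region$hi, each = H)
    keep[H + seq_len(H * W)] <- rowv >= lo & rowv <= hi
  }
  esel <- keep[graph$from] & keep[graph$to]
  newid <- cumsum(keep)
  g <- igraph::make_graph(
    rbind(newid[graph$from[esel]], newid[graph$to[esel]]),
    n = sum(keep), directed = FALSE
  )
  wts <- graph$w[esel]
  sp <- igraph::shortest_paths(
    g, from = newid[graph$source], to = newid[graph$sink],
    weights = wts, output = "both", algorithm = "dijkstra"
  )
  vp <- sp$vpath[[1L]]
  if (length(vp) == 0L)
    stop("no path from source to sink: search region is disconnected")
  cost <- sum(wts[as.integer(sp$epath[[1L]])])
  orig <- which(keep)[as.integer(vp)]
  node_row <- ((orig - 1L) %% H) + 1L
  node_col <- ((orig - 1L) %/% H) + 1L
  inside <- node_col >= 2L & node_col <= Wa - 1L
  rows <- rep(NA_integer_, W)
  # last visited row per column, in path order
  rows[node_col[inside] - 1L] <- node_row[inside]
  if (anyNA(rows))
    stop("path skipped image columns; boundary undefined")
  new_boundary(rows, label = label, cost = cost)
}

new_boundary <- function(rows, label = NA_character_, cost = NA_real_) {
  structure(list(rows = as.numeric(rows), label = label,
                 mean_row = mean(rows), cost = cost),
            class = "oct_boundary")
}

#' @export
print.oct_boundary <- function(x, ...) {
  cat(sprintf("<oct_boundary> %s: %d columns, mean row %.2f, rows %g..%g\n",
              if (is.na(x$label)) "(unlabeled)" else x$label,
              length(x$rows), x$mean_row, min(x$rows), max(x$rows)))
  invisible(x)
}

#' Order two candidate boundaries anatomically by mean row
#'
#' The ILM lies above the IS-OS junction, so when the same dark-to-bright
#' search is run twice (full image, then below the first path) the two
#' candidates are told apart by the mean of their vertical positions: the
#' path with the smaller mean row is the anatomically upper boundary.
#' Order-invariant in its inputs; an exact tie keeps the input order with a
#' warning.
#'
#' @param a,b Two `oct_boundary` candidates.
#' @return A list with elements `upper` and `lower`.
#' @export
order_by_mean_row <- function(a, b) {
  if (a$mean_row < b$mean_row) return(list(upper = a, lower = b))
  if (b$mean_row < a$mean_row) return(list(upper = b, lower = a))
  warning("mean-row tie between candidate paths; keeping input order")
  list(upper = a, lower = b)
}

#' The 8 boundary labels, vitreous to choroid
#' @return Character vector of the 8 interface names in anatomical order.
#' @export
boundary_labels <- function() {
  c("ILM", "NFL-GCL", "IPL-INL", "INL-OPL",
    "OPL-ONL", "IS-OS", "OS-RPE", "RPE-Choroid")
}

#' The 7 layer labels, vitreous to choroid
#' @return Character vector of the 7 layer names between consecutive boundaries.
#' @export
layer_labels <- function() {
  c("NFL", "GCL+IPL", "INL", "OPL", "ONL+IS", "OS", "RPE")
}

#' Segment all 8 retinal boundaries of an enhanced B-scan
#'
#' Runs the full sequential graph-cut scheme on an (already enhanced and
#' cropped) B-scan. Both polarity graphs are built once; each boundary is
#' then extracted as a minimum-weight path in the order
#' ILM, IS-OS, RPE-Choroid, NFL-GCL, OS-RPE, INL-OPL, IPL-INL, OPL-ONL,
#' with previously found boundaries limiting each search region:
#' \enumerate{
#'   \item ILM: strongest dark-to-bright transition, whole image;
#'   \item IS-OS: next dark-to-bright transition below the first path; the
#'     two candidates are ordered by [order_by_mean_row()];
#'   \item RPE-Choroid: strongest bright-to-dark transition (whole image by
#'     default; set `rpe_below_isos` to restrict below IS-OS on noisy data);
#'   \item NFL-GCL: bright-to-dark between ILM and IS-OS;
#'   \item OS-RPE: dark-to-bright between IS-OS and RPE-Choroid;
#'   \item INL-OPL: dark-to-bright between NFL-GCL and IS-OS;
#'   \item IPL-INL: bright-to-dark between NFL-GCL and INL-OPL;
#'   \item OPL-ONL: bright-to-dark between INL-OPL and IS-OS.
#' }
#' A failed stage aborts with the stage name. The returned boundaries are
#' checked for the top-to-bottom weak ordering invariant; a violation is
#' flagged in the result (`ordering_ok = FALSE`, with a warning), never
#' silently repaired.
#'
#' @param image An enhanced `oct_bscan` (see [fhh_enhance()]).
#' @param w_min Stabilization constant for edge weights.
#' @param beta_w Weight-fuzzifier exponent, see [fuzzify_weights()].
#' @param connectivity 8 or 4, see [build_pixel_graph()].
#' @param margin Rows excluded next to each delimiting boundary.
#' @param rpe_below_isos Restrict the RPE-Choroid search below IS-OS.
#' @return An `oct_segmentation`: named list `boundaries` in anatomical
#'   order, extraction order, per-stage path costs, `ordering_ok` flag, and
#'   the image geometry (`H`, `W`, `crop_offset`).
#' @seealso [oct_pipeline()] for the crop + enhance + segment composition.
#' @export
segment_layers <- function(image, w_min = 1e-5, beta_w = 2, connectivity = 8,
                           margin = 1, rpe_below_isos = FALSE) {
  image <- as_bscan(image)
  H <- nrow(image$pixels)
  W <- ncol(image$pixels)
  prep <- function(polarity) {
    add_endpoint_columns(fuzzify_weights(
      build_pixel_graph(vertical_gradient(image, polarity),
                        w_min = w_min, connectivity = connectivity),
      beta_w = beta_w
    ))
  }
  g_db <- prep("dark_to_bright")
  g_bd <- prep("bright_to_dark")
  stage <- function(name, graph, upper = NULL, lower = NULL) {
    tryCatch(
      trace_boundary(graph,
                     if (is.null(upper) && is.null(lower)) NULL
                     else limit_region(upper, lower, height = H, width = W,
                                       margin = margin),
                     label = name),
      error = function(e) stop(sprintf("stage %s: %s", name, conditionMessage(e)),
                               call. = FALSE)
    )
  }

  p1 <- stage("ILM", g_db)
  p2 <- stage("IS-OS", g_db, upper = p1)
  ord <- order_by_mean_row(p1, p2)
  ilm <- ord$upper; ilm$label <- "ILM"
  isos <- ord$lower; isos$label <- "IS-OS"
  rpech <- stage("RPE-Choroid", g_bd,
                 upper = if (rpe_below_isos) isos else NULL)
  nflgcl <- stage("NFL-GCL", g_bd, upper = ilm, lower = isos)
  osrpe <- stage("OS-RPE", g_db, upper = isos, lower = rpech)
  inlopl <- stage("INL-OPL", g_db, upper = nflgcl, lower = isos)
  iplinl <- stage("IPL-INL", g_bd, upper = nflgcl, lower = inlopl)
  oplonl <- stage("OPL-ONL", g_bd, upper = inlopl, lower = isos)

  boundaries <- list(ilm, nflgcl, iplinl, inlopl, oplonl, isos, osrpe, rpech)
  names(boundaries) <- boundary_labels()
  rows <- vapply(boundaries, function(b) b$rows, numeric(W))
  ordering_ok <- all(apply(rows, 1L, function(r) all(diff(r) >= 0)))
  if (!ordering_ok)
    warning("boundary ordering invariant violated; flagged, not repaired")
  structure(
    list(boundaries = boundaries,
         order_of_extraction = c("ILM", "IS-OS", "RPE-Choroid", "NFL-GCL",
                                 "OS-RPE", "INL-OPL", "IPL-INL", "OPL-ONL"),
         costs = vapply(boundaries, function(b) b$cost, numeric(1)),
         ordering_ok = ordering_ok,
         H = H, W = W, crop_offset = image$crop_offset),
    class = "oct_segmentation"
  )
}

#' @export
print.oct_segmentation <- function(x, ...) {
  cat(sprintf("<oct_segmentation> %d x %d (crop_offset %d), ordering %s\n",
              x$H, x$W, x$crop_offset,
              if (x$ordering_ok) "ok" else "VIOLATED"))
  for (b in x$boundaries)
    cat(sprintf("  %-12s mean row %7.2f  cost %.4g\n",
                b$label, b$mean_row, b$cost))
  invisible(x)
}

#' Extract per-column boundary rows as a matrix
#'
#' @param x An `oct_segmentation` or a list of `oct_boundary`.
#' @param original_coords Add `crop_offset` so rows refer to the uncropped
#'   image.
#' @return Numeric `W x 8` matrix, columns named by [boundary_labels()].
#' @export
boundary_matrix <- function(x, original_coords = TRUE) {
  bl <- if (inherits(x, "oct_segmentation")) x$boundaries else x
  m <- vapply(bl, function(b) b$rows, numeric(length(bl[[1L]]$rows)))
  colnames(m) <- vapply(bl, function(b) b$label, character(1))
  if (original_coords && inherits(x, "oct_segmentation"))
    m <- m + x$crop_offset
  m
}

#' Binary masks of the 7 retinal layers
#'
#' Layer k occupies, per column, the half-open row band from its upper
#' boundary (inclusive) to its lower boundary (exclusive), so the 7 masks
#' partition the band between ILM and RPE-Choroid.
#'
#' @param x An `oct_segmentation`, or a `W x 8` matrix of boundary rows.
#' @param height Image height (taken from the segmentation if present).
#' @return Named list of 7 logical `height x W` matrices.
#' @export
layer_masks <- function(x, height = NULL) {
  if (inherits(x, "oct_segmentation")) {
    m <- boundary_matrix(x, original_coords = FALSE)
    if (is.null(height)) height <- x$H
  } else {
    m <- x
    if (is.null(height)) stop("`height` required when passing a boundary matrix")
  }
  W <- nrow(m)
  rowmat <- matrix(seq_len(height), height, W)
  masks <- vector("list", 7L)
  for (k in seq_len(7L)) {
    up <- matrix(round(m[, k]), height, W, byrow = TRUE)
    lo <- matrix(round(m[, k + 1L]), height, W, byrow = TRUE)
    masks[[k]] <- rowmat >= up & rowmat < lo
  }
  names(masks) <- layer_labels()
  masks
}
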