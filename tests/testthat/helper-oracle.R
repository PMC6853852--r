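# Independent shortest-path oracle: Bellman-Ford relaxation over the edge
# list of an (augmented) pixel_graph, optionally restricted to a node mask.
# Deliberately shares no code with trace_boundary()'s Dijkstra route.
bf_shortest_cost <- function(graph, keep = NULL) {
  f <- graph$from
  t <- graph$to
  w <- graph$w
  n <- graph$H * graph$Wa
  if (!is.null(keep)) {
    sel <- keep[f] & keep[t]
    f <- f[sel]; t <- t[sel]; w <- w[sel]
  }
  ff <- c(f, t)
  tt <- c(t, f)
  ww <- c(w, w)
  dist <- rep(Inf, n)
  dist[graph$source] <- 0
  repeat {
    m <- tapply(dist[ff] + ww, tt, min)
    idx <- as.integer(names(m))
    new <- dist
    new[idx] <- pmin(new[idx], m)
    if (max(dist - new, na.rm = TRUE) < 1e-12) break
    dist <- new
  }
  dist[graph$sink]
}

# node mask for an oct_region over an augmented graph (virtual columns free)
region_keep <- function(graph, region) {
  keep <- rep(TRUE, graph$H * graph$Wa)
  rowv <- rep(seq_len(graph$H), times = graph$W)
  lo <- rep(region$lo, each = graph$H)
  hi <- rep(region$hi, each = graph$H)
  keep[graph$H + seq_len(graph$H * graph$W)] <- rowv >= lo & rowv <= hi
  keep
}

# random small augmented graph from a random gradient map
random_small_graph <- function(H, W, w_min = 1e-3, connectivity = 8,
                               fuzzify = TRUE) {
  g <- structure(list(values = matrix(runif(H * W), H, W),
                      polarity = "dark_to_bright"),
                 class = "oct_gradient")
  pg <- build_pixel_graph(g, w_min = w_min, connectivity = connectivity)
  if (fuzzify) pg <- fuzzify_weights(pg, beta_w = 2)
  add_endpoint_columns(pg)
}

# a gradient map object with given values (bypasses vertical_gradient)
as_gradient <- function(values, polarity = "dark_to_bright") {
  structure(list(values = as.matrix(values), polarity = polarity),
            class = "oct_gradient")
}
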