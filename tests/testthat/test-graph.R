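test_that("vertical gradient normalizes transitions and inverts by polarity", {
  # single dark->bright step: the transition row normalizes to 1
  img <- matrix(c(0, 0, 100, 100, 0, 0, 100, 100), 4, 2)
  g <- vertical_gradient(img, "dark_to_bright")
  expect_equal(g$values[3, 1], 1)
  inv <- vertical_gradient(img, "bright_to_dark")
  expect_equal(inv$values, 1 - g$values)
  # hand-computed min-max on a 3-row column {0, 100, 50}
  col3 <- matrix(c(0, 100, 50, 0, 100, 50), 3, 2)
  v <- vertical_gradient(col3, "dark_to_bright")$values
  expect_equal(v[2, 1], 1)
  expect_equal(v[3, 1], 0)
  expect_equal(v[1, 1], v[2, 1])  # top row replicates, no fake transition
  expect_warning(vertical_gradient(matrix(5, 3, 3)), "degenerate")
  suppressWarnings(vd <- vertical_gradient(matrix(5, 3, 3))$values)
  expect_true(all(vd == 0.5))
})

test_that("adjacency weights follow 2 - g_a - g_b + w_min and its bounds", {
  w_min <- 1e-5
  g <- as_gradient(matrix(c(1, 1, 0, 0, 0.6, 0.3), 1, 6))
  pg <- build_pixel_graph(g, w_min = w_min)
  # 1x6 grid: 5 horizontal edges in column order
  expect_equal(pg$w[1], w_min)               # g_a = g_b = 1
  expect_equal(pg$w[3], 2 + w_min)           # g_a = g_b = 0
  expect_equal(pg$w[5], 2 - 0.6 - 0.3 + w_min)  # = 1.10001
  expect_equal(pg$w[5], 1.10001)
  set.seed(3)
  rg <- random_small_graph(6, 6, fuzzify = FALSE)
  expect_true(all(rg$w >= rg$w_min - 1e-12))
  img_edges <- rg$w[rg$w > rg$w_min]  # virtual edges sit exactly at w_min
  expect_true(all(img_edges <= 2 + rg$w_min + 1e-12))
  expect_error(build_pixel_graph(g, w_min = 0), "positive")
})

test_that("both polarity graphs share topology, differing only in weights", {
  img <- bscan(matrix(sample(0:255, 48, replace = TRUE), 8, 6))
  a <- build_pixel_graph(vertical_gradient(img, "dark_to_bright"))
  b <- build_pixel_graph(vertical_gradient(img, "bright_to_dark"))
  expect_identical(a$from, b$from)
  expect_identical(a$to, b$to)
  expect_false(isTRUE(all.equal(a$w, b$w)))
})

test_that("weight fuzzification maps extremes to {0,1} pre-floor and keeps rank", {
  set.seed(5)
  g <- as_gradient(matrix(runif(36), 6, 6))
  pg <- build_pixel_graph(g, w_min = 1e-5)
  fz <- fuzzify_weights(pg, beta_w = 2)
  pre_floor <- fz$w - fz$w_min
  expect_equal(min(pre_floor), 0)
  expect_equal(max(pre_floor), 1)
  expect_true(all(fz$w > 0))
  # mid-normalized weight 0.5 -> 0.25 under beta_w = 2 (edge with g_a + g_b = 1)
  g2 <- as_gradient(matrix(c(1, 1, 0, 0, 0.75, 0.75), 1, 6))
  f2 <- fuzzify_weights(build_pixel_graph(g2, w_min = 1e-5), beta_w = 2)
  expect_equal(f2$w[2] - f2$w_min, 0.25)
  # monotone: order of edge weights unchanged
  expect_identical(order(pg$w), order(fz$w))
  # degenerate all-equal weights
  flat <- build_pixel_graph(as_gradient(matrix(0.4, 3, 3)))
  expect_error(fuzzify_weights(flat), "equal")
})

test_that("endpoint columns add free-moving virtual nodes on both sides", {
  set.seed(9)
  H <- 7; W <- 5
  pg <- random_small_graph(H, W, fuzzify = TRUE)
  expect_equal(pg$H * pg$Wa, H * (W + 2))
  expect_equal(max(c(pg$from, pg$to)), H * (W + 2))
  # every edge incident to a virtual node has weight exactly w_min
  virt <- c(seq_len(H), (pg$Wa - 1) * H + seq_len(H))
  touches <- pg$from %in% virt | pg$to %in% virt
  expect_true(all(pg$w[touches] == pg$w_min))
  # traversing a whole virtual column is negligible
  expect_equal((H - 1) * pg$w_min, 6e-3, tolerance = 1e-9)
  expect_error(add_endpoint_columns(pg), "already")
})

test_that("on a two-band image the cheapest dark->bright path is the interface", {
  img <- bscan(matrix(rep(c(rep(20, 6), rep(200, 6)), 8), 12, 8))
  gr <- vertical_gradient(img, "dark_to_bright")
  pg <- add_endpoint_columns(fuzzify_weights(build_pixel_graph(gr)))
  b <- trace_boundary(pg)
  expect_equal(b$rows, rep(7, 8))  # first bright row
})

test_that("uniform-weight 4-connected grid yields a horizontal line", {
  g <- as_gradient(matrix(0.5, 4, 4))
  pg <- add_endpoint_columns(build_pixel_graph(g, connectivity = 4))
  b <- trace_boundary(pg)
  expect_true(all(diff(b$rows) == 0))
  expect_equal(b$cost, bf_shortest_cost(pg), tolerance = 1e-10)
})
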