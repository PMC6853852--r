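test_that("noise-free phantom renders homogeneous horizontal bands", {
  spec <- phantom_spec(height = 64, width = 96,
                       base_rows = c(12, 18, 26, 32, 37, 46, 51, 56),
                       tilt = 0, bow = 0, vessels = list())
  ph <- generate_phantom(spec)
  px <- ph$image$pixels
  refl <- spec$reflectivities
  # flat profiles: each band is constant at its layer reflectivity
  expect_true(all(px[1:11, ] == refl["background"]))
  expect_true(all(px[12:17, ] == refl["NFL"]))
  expect_true(all(px[46:50, ] == refl["OS"]))
  expect_true(all(px[56:64, ] == refl["choroid"]))
  # ground truth satisfies the boundary ordering invariant by construction
  expect_true(all(apply(ph$boundaries, 1, function(r) all(diff(r) >= 2))))
})

test_that("simulation is bit-identical for the same seed", {
  a <- simulate_bscan(small_spec(seed = 5,
                                 vessels = list(list(center = 40, width = 8,
                                                     attenuation = 0.6))))
  b <- simulate_bscan(small_spec(seed = 5,
                                 vessels = list(list(center = 40, width = 8,
                                                     attenuation = 0.6))))
  expect_identical(a$image$pixels, b$image$pixels)
  c <- simulate_bscan(small_spec(seed = 6))
  expect_false(identical(a$image$pixels, c$image$pixels))
})

test_that("speckle is multiplicative with unit mean and vanishes as looks grow", {
  flat <- bscan(matrix(100, 500, 500))
  noisy <- add_speckle(flat, looks = 4, seed = 1)
  field <- noisy$pixels / 100
  # unit-mean: smoothing preserves the gamma field's expectation
  se <- sd(field) / sqrt(length(field))   # conservative (field is correlated)
  expect_lt(abs(mean(field) - 1), 6 * se + 1e-3)
  # neighborhood correlation is present
  expect_gt(cor(as.vector(field[-1, ]), as.vector(field[-500, ])), 0.3)
  calm <- add_speckle(flat, looks = 1e8, seed = 1)
  expect_equal(calm$pixels, flat$pixels, tolerance = 1e-3)
})

test_that("speckled bands keep the mean ordering of their reflectivities", {
  spec <- small_spec(seed = 3)
  sim <- simulate_bscan(small_spec(seed = 3))
  masks <- layer_masks(spec$boundaries, height = spec$height)
  means <- vapply(masks, function(m) mean(sim$image$pixels[m]), numeric(1))
  refl <- spec$reflectivities[layer_labels()]
  expect_identical(order(means), order(refl))
})

test_that("vessel shadows attenuate their column band and nothing else", {
  img <- bscan(matrix(100, 80, 120))
  same <- add_vessel_shadows(img, list(list(center = 60, width = 10,
                                            attenuation = 1)))
  expect_equal(same$pixels, img$pixels)
  sh <- add_vessel_shadows(img, list(list(center = 60, width = 10,
                                          attenuation = 0.5,
                                          start_row = 20)))
  expect_equal(mean(sh$pixels[20:80, 60]) / mean(sh$pixels[20:80, 5]), 0.5,
               tolerance = 1e-6)
  expect_equal(sh$pixels[1:19, ], img$pixels[1:19, ])  # above start untouched
  far <- sh$pixels[, c(1:10, 110:120)]
  expect_equal(mean(far), 100, tolerance = 0.1)        # smooth falloff dies out
})

test_that("phantom specs reject invalid geometry and reflectivities", {
  expect_error(phantom_spec(base_rows = c(60, 62, 63, 130, 148, 185, 200, 215)),
               "separation")
  expect_error(small_spec(reflectivities = c(8, 300, 75, 40, 85, 30, 145,
                                             175, 25)),
               "\\[0, L - 1\\]")
  expect_error(small_spec(vessels = list(list(center = 9999, width = 5,
                                              attenuation = 0.5))),
               "outside")
  expect_error(small_spec(speckle_looks = 0.2), "looks")
})
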