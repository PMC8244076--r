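test_that("concentric-sphere thickness is the wall gap", {
  sh <- shell(10, 11, level = 3)
  sh <- surface_thickness(sh, internal_tags_1 = 2L, external_tags = 1L)
  tau <- sh$point_data$thickness
  expect_equal(mean(tau), 1, tolerance = 0.02)
  expect_true(all(tau > 0))
})

test_that("two-cavity composition gives the septum and outer-wall thicknesses", {
  tc <- two_cavity_shell(10, 3, 4, level = 3)
  tc <- surface_thickness(tc, internal_tags_1 = 2L, external_tags = 1L,
                          internal_tags_2 = 3L)
  q <- tc$points
  i_sept <- which.min(rowSums(sweep(q, 2, c(-1, 0, 0), `-`)^2))
  i_out <- which.min(rowSums(sweep(q, 2, c(10, 0, 0), `-`)^2))
  expect_equal(tc$point_data$thickness[i_sept], 2, tolerance = 0.05)
  expect_equal(tc$point_data$thickness[i_out], 3, tolerance = 0.05)
  expect_true(all(tc$point_data$thickness > 0))
})

test_that("the two-wall composition reduces to the single-wall one without a second cavity", {
  sh <- shell(10, 11, level = 2)
  a <- surface_thickness(sh, 2L, 1L)
  # passing the same wall as both internal sets must not change the result
  b <- surface_thickness(sh, 2L, 1L, internal_tags_2 = integer(0))
  expect_identical(a$point_data$thickness, b$point_data$thickness)
  expect_error(surface_thickness(sh, 5L, 1L), "no cells")
})

test_that("thickening a thin shell recovers the target thickness", {
  sh <- shell(9.75, 10.25, level = 3)
  sh <- surface_thickness(sh, 2L, 1L)
  expect_equal(mean(sh$point_data$thickness), 0.5, tolerance = 0.02)
  th <- surface_thicken(sh, sigma = 1)
  th <- surface_thickness(th, 2L, 1L)
  expect_equal(mean(th$point_data$thickness), 1, tolerance = 0.03)
  r_out <- sqrt(rowSums(subset_cells(th, which(th$cell_tags == 1L))$points^2))
  r_in <- sqrt(rowSums(subset_cells(th, which(th$cell_tags == 2L))$points^2))
  expect_equal(mean(r_out), 10.5, tolerance = 0.01)
  expect_equal(mean(r_in), 9.5, tolerance = 0.01)
})

test_that("thickening is the identity where tau >= sigma", {
  sh <- shell(9, 11, level = 2)
  sh <- surface_thickness(sh, 2L, 1L)      # tau ~ 2 everywhere
  out <- surface_thicken(sh, sigma = 1)
  expect_identical(out$points, sh$points)
})

test_that("excluding the outer wall with alpha = 2 moves only the inner wall", {
  sh <- shell(9.75, 10.25, level = 3)
  sh <- surface_thickness(sh, 2L, 1L)
  out <- surface_thicken(sh, sigma = 1, alpha = 2, excluded_tags = 1L)
  # outer wall fixed
  outer_pts <- unique(as.vector(sh$triangles[sh$cell_tags == 1L, ]))
  expect_identical(out$points[outer_pts, ], sh$points[outer_pts, ])
  # recomputed thickness reaches sigma
  out <- surface_thickness(out, 2L, 1L)
  expect_equal(mean(out$point_data$thickness), 1, tolerance = 0.03)
})

test_that("mesh-size arithmetic follows the clamped power law", {
  s <- mean_curvature(icosphere(4, radius = 4))
  s <- mesh_size(s, list(field = "curvature", alpha = 0.3, beta = -0.5,
                         gamma = 0, m = 0.3, M = 2))
  expect_equal(mean(s$point_data$meshsize), 0.6, tolerance = 0.03)
  # constant rule
  s <- mesh_size(s, list(gamma = 1.25), name = "hc")
  expect_identical(s$point_data$hc, rep(1.25, nrow(s$points)))
  # clamping
  s$point_data$one <- rep(1, nrow(s$points))
  s <- mesh_size(s, list(field = "one", alpha = 10, m = 0.1, M = 2), name = "hM")
  expect_identical(s$point_data$hM, rep(2, nrow(s$points)))
  expect_error(mesh_size(s, list(field = "one", m = 3, M = 2)), "m <= M")
  s$point_data$neg <- rep(-1, nrow(s$points))
  expect_error(mesh_size(s, list(field = "neg", beta = -0.5)), "undefined")
})

test_that("multi-rule combination takes the pointwise minimum", {
  s <- icosphere(2)
  s$point_data$f1 <- rep(1, nrow(s$points))
  s$point_data$f2 <- rep(2, nrow(s$points))
  s <- mesh_size(s, list(list(field = "f1"), list(field = "f2")))
  expect_identical(s$point_data$meshsize, rep(1, nrow(s$points)))
  # monotone in gamma and in M
  s <- mesh_size(s, list(field = "f1", gamma = 0.5), name = "hg")
  expect_true(all(s$point_data$hg >= s$point_data$meshsize))
  # adding a rule can only decrease h
  s <- mesh_size(s, list(list(field = "f1"), list(field = "f2"),
                         list(gamma = 0.2)), name = "h3")
  expect_true(all(s$point_data$h3 <= s$point_data$meshsize))
})

test_that("tag-restricted mesh-size updates only the targeted points", {
  s <- icosphere(2)
  s$point_data$zz <- abs(s$points[, 3]) + 0.5
  s$cell_tags[s$points[s$triangles[, 1], 3] > 0] <- 8L
  s <- mesh_size(s, list(gamma = 1), smooth_iterations = 0L)
  h0 <- s$point_data$meshsize
  s <- mesh_size(s, list(field = "zz"), target_tags = 8L, smooth_iterations = 0L)
  pts8 <- unique(as.vector(s$triangles[s$cell_tags == 8L, ]))
  other <- setdiff(seq_len(nrow(s$points)), pts8)
  expect_identical(s$point_data$meshsize[other], h0[other])
  expect_identical(s$point_data$meshsize[pts8], s$point_data$zz[pts8])
})

test_that("field smoothing is a convex averaging", {
  s <- square_patch(6)
  s$point_data$c0 <- rep(2, nrow(s$points))
  s <- smooth_field(s, "c0", iterations = 5)
  expect_equal(s$point_data$c0, rep(2, nrow(s$points)), tolerance = 1e-12)
  # single spike decays monotonically
  s$point_data$sp <- rep(0, nrow(s$points)); s$point_data$sp[25] <- 1
  prev <- 1
  for (k in 1:4) {
    s <- smooth_field(s, "sp", iterations = 1, relaxation = 0.6)
    expect_lt(max(s$point_data$sp), prev)
    expect_gte(min(s$point_data$sp), 0)
    prev <- max(s$point_data$sp)
  }
  # smoothed mesh-size range stays inside the raw range
  s2 <- icosphere(2)
  s2$point_data$h <- 1 + s2$points[, 3]
  s2 <- smooth_field(s2, "h", iterations = 10, output = "hs")
  expect_gte(min(s2$point_data$hs), min(s2$point_data$h))
  expect_lte(max(s2$point_data$hs), max(s2$point_data$h))
})

test_that("discrete mean curvature matches spheres and cylinders", {
  expect_equal(mean(mean_curvature(icosphere(3))$point_data$curvature), 1,
               tolerance = 0.05)
  expect_equal(mean(mean_curvature(icosphere(3, radius = 4))$point_data$curvature),
               0.25, tolerance = 0.05)
  tb <- mean_curvature(tube(radius = 2, length = 6, n_theta = 48, n_z = 25))
  away <- tb$points[, 3] > 1 & tb$points[, 3] < 5
  expect_equal(mean(tb$point_data$curvature[away]), 1 / 4, tolerance = 0.05)
})
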