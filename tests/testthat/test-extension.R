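tagged_tube <- function(n_theta = 24, n_z = 17) {
  tb <- tube(radius = 1, length = 2, n_theta = n_theta, n_z = n_z)
  z <- tb$points[, 3]
  zb <- (z[tb$triangles[, 1]] + z[tb$triangles[, 2]] + z[tb$triangles[, 3]]) / 3
  tb$cell_tags[zb < 0.25] <- 1L
  tb$point_data$f <- ifelse(z <= 0.25, 5, 0)
  tb
}

test_that("constant source with natural free rings extends to the constant", {
  tb <- tagged_tube()
  tb$point_data$f <- ifelse(tb$points[, 3] <= 0.25, 3.3, 0)
  out <- harmonic_extension(tb, "f", source_tags = 1L)
  expect_equal(out$point_data$f, rep(3.3, nrow(tb$points)), tolerance = 1e-10)
})

test_that("rim Dirichlet value produces the linear axial profile", {
  tb <- tagged_tube()
  out <- harmonic_extension(tb, "f", source_tags = 1L, ring_values = c(1))
  z <- tb$points[, 3]
  pred <- ifelse(z <= 0.25, 5, 5 + (1 - 5) * (z - 0.25) / (2 - 0.25))
  expect_lt(max(abs(out$point_data$f - pred)), 1e-2)
  # identity on the source region, continuous across the interface
  src_pts <- unique(as.vector(tb$triangles[tb$cell_tags == 1L, ]))
  expect_identical(out$point_data$f[src_pts], tb$point_data$f[src_pts])
})

test_that("vector fields obey the componentwise maximum principle", {
  tb <- tagged_tube()
  set.seed(4)
  v <- cbind(stats::runif(nrow(tb$points), -1, 2), 0.5, sin(tb$points[, 1]))
  tb$point_data$fib <- v
  out <- harmonic_extension(tb, "fib", source_tags = 1L)
  src_pts <- unique(as.vector(tb$triangles[tb$cell_tags == 1L, ]))
  for (k in 1:3) {
    expect_gte(min(out$point_data$fib[, k]), min(v[src_pts, k]) - 1e-9)
    expect_lte(max(out$point_data$fib[, k]), max(v[src_pts, k]) + 1e-9)
  }
})

test_that("zero tags force zero and normalization restores unit length", {
  tb <- tube(radius = 1, length = 3, n_theta = 16, n_z = 13)
  z <- tb$points[, 3]
  zb <- (z[tb$triangles[, 1]] + z[tb$triangles[, 2]] + z[tb$triangles[, 3]]) / 3
  tb$cell_tags[zb < 0.5] <- 1L
  tb$cell_tags[zb > 2.5] <- 9L
  th <- atan2(tb$points[, 2], tb$points[, 1])
  tb$point_data$fib <- cbind(-sin(th), cos(th), 0)    # unit circumferential field
  out <- harmonic_extension(tb, "fib", source_tags = 1L, zero_tags = 9L)
  zero_pts <- unique(as.vector(tb$triangles[tb$cell_tags == 9L, ]))
  expect_true(all(abs(out$point_data$fib[zero_pts, ]) == 0))
  # un-normalized extension loses unit length in the interior
  mid <- which(z > 1 & z < 2)
  expect_lt(max(sqrt(rowSums(out$point_data$fib[mid, ]^2))), 1)
  out2 <- harmonic_extension(tb, "fib", source_tags = 1L, normalize = TRUE)
  expect_equal(sqrt(rowSums(out2$point_data$fib^2)), rep(1, nrow(tb$points)),
               tolerance = 1e-9)
})

test_that("degenerate configurations error clearly", {
  tb <- tagged_tube()
  expect_error(harmonic_extension(tb, "f", source_tags = 42L), "no cells")
  all1 <- tb; all1$cell_tags[] <- 1L
  expect_error(harmonic_extension(all1, "f", source_tags = 1L), "empty")
  expect_error(harmonic_extension(tb, "missing", source_tags = 1L), "not found")
})
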