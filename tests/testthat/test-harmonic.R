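cyl_solution <- function(n_theta, n_z) {
  tb <- tube(radius = 1, length = 2, n_theta = n_theta, n_z = n_z)
  z <- tb$points[, 3]
  bot <- which(abs(z) < 1e-12); top <- which(abs(z - 2) < 1e-12)
  sol <- solve_harmonic(tb, c(bot, top), c(rep(0, length(bot)), rep(1, length(top))))
  list(sol = sol, exact = z / 2, tb = tb)
}

test_that("constant Dirichlet data reproduces the constant exactly", {
  s <- icosphere(2)
  s2 <- square_patch(3)
  ring <- extract_boundary_rings(s2)[[1]]
  sol <- solve_harmonic(s2, as.integer(ring), rep(4.2, length(ring)))
  expect_equal(sol, rep(4.2, nrow(s2$points)), tolerance = 1e-12)
})

test_that("cylinder axial profile is linear", {
  r <- cyl_solution(24, 17)
  expect_lt(max(abs(r$sol - r$exact)), 1e-3)
})

test_that("flat annulus reproduces the log-radial closed form", {
  an <- annular_patch(1, 2, n_theta = 48, n_r = 13)
  rr <- sqrt(rowSums(an$points[, 1:2]^2))
  inner <- which(abs(rr - 1) < 1e-9); outer <- which(abs(rr - 2) < 1e-9)
  sol <- solve_harmonic(an, c(inner, outer),
                        c(rep(1, length(inner)), rep(0, length(outer))))
  expect_lt(max(abs(sol - log(2 / rr) / log(2))), 1e-2)
})

test_that("discrete maximum principle holds on a non-obtuse mesh", {
  sq <- square_patch(6)
  ring <- as.integer(extract_boundary_rings(sq)[[1]])
  set.seed(5)
  vals <- stats::runif(length(ring), -3, 7)
  sol <- solve_harmonic(sq, ring, vals)
  expect_gte(min(sol), min(vals) - 1e-12)
  expect_lte(max(sol), max(vals) + 1e-12)
})

test_that("the solve is linear in the boundary data", {
  sq <- square_patch(4)
  ring <- as.integer(extract_boundary_rings(sq)[[1]])
  set.seed(9)
  v1 <- stats::runif(length(ring)); v2 <- stats::runif(length(ring))
  s1 <- solve_harmonic(sq, ring, v1)
  s2 <- solve_harmonic(sq, ring, v2)
  s12 <- solve_harmonic(sq, ring, v1 + v2)
  expect_equal(s12, s1 + s2, tolerance = 1e-10)
})

test_that("vector problems are solved componentwise and match constraints", {
  sq <- square_patch(3)
  ring <- as.integer(extract_boundary_rings(sq)[[1]])
  vals <- cbind(sq$points[ring, 1], 2 * sq$points[ring, 2], -1)
  sol <- solve_harmonic(sq, ring, vals)
  expect_equal(sol[ring, ], vals, tolerance = 1e-12)
  # coordinate functions are harmonic on a flat patch: interior reproduced
  expect_equal(sol[, 1], sq$points[, 1], tolerance = 1e-10)
  expect_equal(sol[, 2], 2 * sq$points[, 2], tolerance = 1e-10)
})

test_that("error decreases under uniform refinement (annulus closed form)", {
  errs <- vapply(1:3, function(lev) {
    an <- annular_patch(1, 2, n_theta = 12 * 2^lev, n_r = 2^lev + 1)
    rr <- sqrt(rowSums(an$points[, 1:2]^2))
    inner <- which(abs(rr - 1) < 1e-9); outer <- which(abs(rr - 2) < 1e-9)
    sol <- solve_harmonic(an, c(inner, outer),
                          c(rep(1, length(inner)), rep(0, length(outer))))
    max(abs(sol - log(2 / rr) / log(2)))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("degenerate problems are rejected", {
  expect_error(solve_harmonic(square_patch(2), integer(0), numeric(0)), "Dirichlet")
  expect_error(solve_harmonic(square_patch(2), 999L, 1), "out of range")
})
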