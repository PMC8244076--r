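test_that("zipper between two aligned square rings builds a watertight prism band", {
  s1 <- flip_orientation(square_patch(1))           # 4-point ring, faces -z
  s2 <- square_patch(1); s2$points[, 3] <- 1        # 4-point ring, faces +z
  out <- surface_connection(s1, s2, band_tag = 7L)
  expect_identical(sum(out$cell_tags == 7L), 8L)    # n1 + n2 triangles
  expect_length(extract_boundary_rings(out), 0L)
  validate_surface(out)
  expect_equal(surface_volume(out), 1, tolerance = 1e-12)
  expect_identical(euler_characteristic(out), 2L)
})

test_that("rings of unequal size insert n1 + n2 + 1 points and n1 + n2 triangles", {
  r1 <- random_ring(3, seed = 1, z = 0)
  r2 <- random_ring(5, seed = 2, z = 1)
  s1 <- ring_disk(r1, c(0, 0, -0.5), flip = TRUE)
  s2 <- ring_disk(r2, c(0, 0, 0.5))
  out <- surface_connection(s1, s2, band_tag = 9L)
  expect_identical(sum(out$cell_tags == 9L), 8L)
  expect_length(extract_boundary_rings(out), 0L)
  # insertions: every band triangle contributes its apex point; the two
  # starts appear once plus one re-insertion = n1 + n2 + 1 total
  tris <- oracle_zipper(r1, r2)
  expect_identical(nrow(tris), 8L)
})

test_that("a ring zipped to its translated copy gives cross edges of length delta", {
  delta <- 0.37
  r1 <- random_ring(12, seed = 5, z = 0)
  r1[, 3] <- 0                      # flat ring
  r2 <- r1; r2[, 3] <- delta        # exact parallel copy
  s1 <- ring_disk(r1, c(0, 0, -0.5), flip = TRUE)
  s2 <- ring_disk(r2, c(0, 0, 0.5))
  out <- surface_connection(s1, s2, band_tag = 3L)
  band <- subset_cells(out, which(out$cell_tags == 3L))
  el <- edge_lengths_of(band)
  cross <- el[abs(el) > 1e-9]
  # cross edges connect the two planes: their length is exactly delta
  zspan <- apply(band$triangles, 1, function(v) diff(range(band$points[v, 3])))
  expect_true(all(abs(zspan - delta) < 1e-12))
  vertical <- el[vapply(seq_along(el), function(k) TRUE, logical(1))]
  # band area = perimeter * delta up to planarity error
  perim <- sum(sqrt(rowSums((r1 - r1[c(2:12, 1), ])^2)))
  expect_equal(sum(triangle_areas(band)), perim * delta, tolerance = 0.02)
})

test_that("production zipper reproduces the independent step simulator exactly", {
  set.seed(202)
  for (k in 1:25) {
    n1 <- sample(3:50, 1); n2 <- sample(3:50, 1)
    r1 <- random_ring(n1, seed = 1000 + k, z = 0)
    r2 <- random_ring(n2, seed = 2000 + k, z = 0.8)
    got <- cardiomesh:::zipper_triangulation(r1, r2)$triangles
    want <- oracle_zipper(r1, r2)
    expect_identical(unname(got), unname(want))
  }
})

test_that("every band triangle has exactly one edge on a parent ring", {
  r1 <- random_ring(9, seed = 31, z = 0)
  r2 <- random_ring(14, seed = 32, z = 1)
  tris <- cardiomesh:::zipper_triangulation(r1, r2)$triangles
  n1 <- nrow(r1)
  ring_edges <- apply(tris, 1, function(v) {
    on1 <- v[v <= n1]; on2 <- v[v > n1]
    # consecutive-on-ring pairs
    e1 <- if (length(on1) == 2) abs(diff(sort(on1))) %in% c(1, n1 - 1) else FALSE
    e2 <- if (length(on2) == 2) abs(diff(sort(on2))) %in% c(1, nrow(r2) - 1) else FALSE
    sum(e1, e2)
  })
  expect_true(all(ring_edges == 1L))
})

test_that("boolean difference of intersecting unit spheres tends to the zone area", {
  s1 <- icosphere(4)
  s2 <- icosphere(4, center = c(0, 0, 1))
  out <- boolean_connection(s1, s2, "difference", epsilon = 0.05, remesh = FALSE)
  validate_surface(out)
  expect_length(extract_boundary_rings(out), 0L)
  expect_identical(euler_characteristic(out), 2L)
  expect_gt(surface_volume(out), 0)
  expect_equal(sum(triangle_areas(out)), 4 * pi, tolerance = 0.05)
  expect_setequal(unique(out$cell_tags), c(1L, 2L, 3L))
})

test_that("boolean union volume matches the analytic sphere-union volume", {
  s1 <- icosphere(3)
  s2 <- icosphere(3, center = c(0, 0, 1))
  out <- boolean_connection(s1, s2, "union", epsilon = 0.05, remesh = FALSE)
  lens <- pi * (4 + 1) * (2 - 1)^2 / 12
  expect_equal(surface_volume(out), 2 * (4 / 3) * pi - lens, tolerance = 0.02)
})

test_that("difference volume is monotone decreasing in epsilon", {
  s1 <- icosphere(3)
  s2 <- icosphere(3, center = c(0, 0, 1))
  vols <- vapply(c(0.05, 0.15, 0.3), function(eps)
    surface_volume(boolean_connection(s1, s2, "difference", epsilon = eps,
                                      remesh = FALSE)), numeric(1))
  expect_true(all(diff(vols) < 0))
})

test_that("non-intersecting inputs are rejected", {
  expect_error(boolean_connection(icosphere(1), icosphere(1, center = c(5, 0, 0)),
                                  "difference", epsilon = 0.05),
               "do not intersect")
  expect_error(boolean_connection(square_patch(2), icosphere(1), "union", epsilon = 0.1),
               "closed")
})

test_that("ring registration recovers rigid motions", {
  r <- random_ring(40, seed = 77)
  # identity
  tf <- register_rings(r, r, mode = "icp")
  expect_equal(tf$rotation, diag(3), tolerance = 1e-8)
  expect_equal(tf$translation, c(0, 0, 0), tolerance = 1e-8)
  # pure translation via centroids
  tfc <- register_rings(r, sweep(r, 2, c(1, -2, 0.5), `+`), mode = "centroid")
  expect_equal(tfc$translation, c(1, -2, 0.5), tolerance = 1e-12)
  expect_equal(tfc$rotation, diag(3))
  # rotation + translation via ICP
  th <- 0.3
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  moved <- sweep(r %*% t(Rz), 2, c(0.3, -0.2, 0.1), `+`)
  tf2 <- register_rings(r, moved, mode = "icp", max_iter = 500L)
  expect_equal(tf2$rotation, Rz, tolerance = 1e-6)
  expect_equal(tf2$translation, c(0.3, -0.2, 0.1), tolerance = 1e-6)
  # collinear degenerate ring
  line <- cbind(seq_len(6), 0, 0)
  expect_error(register_rings(line, line + 0.1, mode = "icp"), "degenerate|rank")
})

test_that("harmonic connection: coincident rings give zero deformation", {
  s_a <- tube(radius = 1, length = 1, n_theta = 16, n_z = 9, z0 = 0)
  s_b <- tube(radius = 1, length = 1, n_theta = 16, n_z = 9, z0 = 1)
  ra <- extract_boundary_rings(s_a); rb <- extract_boundary_rings(s_b)
  za <- vapply(ra, function(r) mean(s_a$points[r, 3]), numeric(1))
  zb <- vapply(rb, function(r) mean(s_b$points[r, 3]), numeric(1))
  out <- harmonic_connection(s_a, s_b, ra[[which.max(za)]], rb[[which.min(zb)]],
                             h = 0.25, band_tag = 12L)
  validate_surface(out)
  expect_length(extract_boundary_rings(out), 2L)   # far rims stay open
  expect_gt(sum(out$cell_tags == 12L), 0L)
})

test_that("harmonic connection decays like the Laplace-Beltrami closed form", {
  # coaxial cylinders radius 1 -> 1.2: the cos(theta) Dirichlet mode decays
  # as sinh(z)/sinh(L); the axisymmetric (axial) mode is linear
  s_in <- tube(radius = 1, length = 2, n_theta = 24, n_z = 17, z0 = 0)
  s_ref <- tube(radius = 1.2, length = 1, n_theta = 24, n_z = 9, z0 = 2.2)
  rin <- extract_boundary_rings(s_in)
  zr <- vapply(rin, function(r) mean(s_in$points[r, 3]), numeric(1))
  ring_in <- rin[[which.max(zr)]]; bot <- rin[[which.min(zr)]]
  rrf <- extract_boundary_rings(s_ref)
  zf <- vapply(rrf, function(r) mean(s_ref$points[r, 3]), numeric(1))
  ring_ref <- rrf[[which.min(zf)]]
  dvec <- ring_distance(s_in$points[ring_in, , drop = FALSE],
                        s_ref$points[ring_ref, , drop = FALSE], vector = TRUE)$vector
  phi <- solve_harmonic(s_in, c(as.integer(ring_in), as.integer(bot)),
                        rbind(dvec, matrix(0, length(bot), 3)))
  z <- s_in$points[, 3]
  rad <- sqrt(phi[, 1]^2 + phi[, 2]^2)
  expect_lt(max(abs(rad - 0.2 * sinh(z) / sinh(2))), 1e-2)
  expect_lt(max(abs(phi[, 3] - 0.2 * z / 2)), 1e-10)
})

test_that("icp pre-registration undoes a known rigid motion of the input surface", {
  # a wobbly (asymmetric) rim so the rotation is identifiable
  s_in <- ring_disk(random_ring(40, seed = 55), c(0, 0, -0.6))
  ring_in <- extract_boundary_rings(s_in)[[1]]
  th <- 0.15
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  s_moved <- s_in
  s_moved$points <- sweep(s_in$points %*% t(Rz), 2, c(0.4, 0.1, -0.2), `+`)
  tf <- register_rings(s_moved$points[ring_in, , drop = FALSE],
                       s_in$points[ring_in, , drop = FALSE], mode = "icp",
                       max_iter = 500L)
  back <- apply_rigid(s_moved, tf)
  expect_equal(back$points, s_in$points, tolerance = 1e-6)
})
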