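z_sphere <- function(level = 3) {
  s <- icosphere(level)
  s$point_data$z <- s$points[, 3]
  s
}

test_that("simple-array tagging selects cells by barycenter value", {
  s <- z_sphere()
  t1 <- tag_simple(s, "z", 0, new_tag = 5L)
  expect_equal(sum(triangle_areas(t1)[t1$cell_tags == 5L]), 2 * pi, tolerance = 0.05)
  # sigma below the minimum: nothing tagged
  t0 <- tag_simple(s, "z", -2, new_tag = 5L)
  expect_identical(sum(t0$cell_tags == 5L), 0L)
  # invert flips the tagged set exactly (sigma off any barycenter value)
  ta <- tag_simple(s, "z", 0.05, new_tag = 5L)
  tb <- tag_simple(s, "z", 0.05, new_tag = 6L, invert = TRUE)
  expect_true(all(xor(ta$cell_tags == 5L, tb$cell_tags == 6L)))
  expect_error(tag_simple(s, "nope", 0, 1L), "not found")
})

test_that("clip-array splits exactly at the level set", {
  s <- z_sphere()
  t2 <- tag_clip(s, "z", 0, new_tag = 5L)
  ring <- inter_tag_points(t2, 5L)
  expect_gt(length(ring), 0)
  expect_lt(max(abs(t2$points[ring, 3])), 1e-9 * diff(range(s$points[, 3])))
  validate_surface(t2)
  expect_length(extract_boundary_rings(t2), 0L)
  # area of the tagged side approaches the exact hemisphere
  expect_equal(sum(triangle_areas(t2)[t2$cell_tags == 5L]),
               sum(triangle_areas(t2)) / 2, tolerance = 1e-9)
})

test_that("clip on a tube splits the lateral area in the exact axial ratio", {
  tb <- tube(radius = 1, length = 2, n_theta = 24, n_z = 9)
  tb$point_data$z <- tb$points[, 3]
  sigma <- 0.6180339887
  out <- tag_clip(tb, "z", sigma, new_tag = 4L)
  a_low <- sum(triangle_areas(out)[out$cell_tags == 4L])
  expect_equal(a_low / sum(triangle_areas(out)), sigma / 2, tolerance = 1e-6)
})

test_that("tagged area of the sublevel set is monotone in sigma", {
  s <- z_sphere(2)
  areas <- vapply(c(-0.5, 0, 0.4, 0.8), function(sg) {
    t1 <- tag_clip(s, "z", sg, new_tag = 5L)
    sum(triangle_areas(t1)[t1$cell_tags == 5L])
  }, numeric(1))
  expect_true(all(diff(areas) > 0))
})

test_that("sigma outside the field range warns and reduces to simple tagging", {
  s <- z_sphere(1)
  expect_warning(out <- tag_clip(s, "z", 5, new_tag = 3L), "tag_simple")
  expect_identical(nrow(out$triangles), nrow(s$triangles))
  expect_true(all(out$cell_tags == 3L))
})

test_that("harmonic-array tagging moves the zig-zag ring onto the level set without remeshing", {
  s <- z_sphere(3)
  out <- tag_harmonic(s, "z", 0, new_tag = 5L, rho = 0.5, distance_like = FALSE,
                      recompute = function(su) su$points[, 3])
  expect_identical(nrow(out$triangles), nrow(s$triangles))
  expect_identical(nrow(out$points), nrow(s$points))
  ring <- inter_tag_points(out, 5L)
  expect_lt(max(abs(out$points[ring, 3])), 1e-3)
  expect_gte(min(triangle_quality(out)), 0.5 * min(triangle_quality(s)))
  validate_surface(out)
})

test_that("zig-zag already on the level set leaves the surface unmoved", {
  tb <- tube(radius = 1, length = 2, n_theta = 16, n_z = 9)
  tb$point_data$z <- tb$points[, 3]
  # sigma on an existing vertex row: barycenter split puts Gamma_zig on it
  out <- tag_harmonic(tb, "z", 0.25 + 1e-13, new_tag = 4L, rho = 0.6,
                      distance_like = FALSE, recompute = function(su) su$points[, 3])
  expect_equal(out$points, tb$points, tolerance = 1e-9)
  simple <- tag_simple(tb, "z", 0.25 + 1e-13, new_tag = 4L)
  expect_identical(out$cell_tags, simple$cell_tags)
})

test_that("no output triangle collapses when consecutive zig-zag points share a cell", {
  s <- z_sphere(3)
  out <- tag_harmonic(s, "z", 0.1, new_tag = 5L, rho = 0.5, distance_like = FALSE,
                      recompute = function(su) su$points[, 3])
  expect_gt(min(triangle_areas(out)), 1e-8)
})

test_that("connectivity tagging assigns one fresh tag per component", {
  tc <- two_cavity_shell(10, 3, 4, level = 1)
  tc$cell_tags[] <- 0L
  out <- tag_connectivity(tc)
  expect_identical(length(unique(out$cell_tags)), 3L)
  expect_identical(length(unique(out$cell_tags)), oracle_component_count(tc))
  # fully connected tag: unchanged except renumbering
  s <- icosphere(1); s$cell_tags[] <- 7L
  out2 <- tag_connectivity(s)
  expect_identical(length(unique(out2$cell_tags)), 1L)
})

test_that("explicit cell tagging and geodesic patches behave", {
  s <- icosphere(2)
  expect_identical(tag_cells(s, 4L, cell_ids = integer(0))$cell_tags, s$cell_tags)
  allc <- tag_cells(s, 4L, cell_ids = seq_len(nrow(s$triangles)))
  expect_true(all(allc$cell_tags == 4L))
  expect_error(tag_cells(s, 4L, cell_ids = 10^6), "out of range")
  # seed + radius: spherical-cap area
  s4 <- icosphere(4)
  t5 <- tag_cells(s4, 9L, seed = 1L, radius = 0.5)
  capA <- sum(triangle_areas(t5)[t5$cell_tags == 9L])
  expect_equal(capA, 2 * pi * (1 - cos(0.5)), tolerance = 0.05)
})

test_that("taggers are idempotent and excluded tags are untouched", {
  s <- z_sphere(2)
  a <- tag_simple(s, "z", 0.05, new_tag = 5L)
  expect_identical(tag_simple(a, "z", 0.05, new_tag = 5L), a)
  b <- tag_clip(s, "z", 0.05, new_tag = 5L)
  b2 <- tag_clip(b, "z", 0.05, new_tag = 5L)
  expect_identical(nrow(b2$triangles), nrow(b$triangles))
  # excluded tags keep geometry and tag
  s$cell_tags[1:100] <- 9L
  e <- tag_simple(s, "z", 0.5, new_tag = 5L, excluded_tags = 9L)
  expect_true(all(e$cell_tags[1:100] == 9L))
  ec <- tag_clip(s, "z", 0.5, new_tag = 5L, excluded_tags = 9L)
  expect_identical(cell_fingerprint(ec, which(ec$cell_tags == 9L)),
                   cell_fingerprint(s, 1:100))
})

test_that("clip and harmonic taggers place the inter-tag ring at the same location", {
  s <- z_sphere(3)
  hc <- tag_harmonic(s, "z", 0.2, new_tag = 5L, rho = 0.5, distance_like = FALSE,
                     recompute = function(su) su$points[, 3])
  cl <- tag_clip(s, "z", 0.2, new_tag = 5L)
  rh <- hc$points[inter_tag_points(hc, 5L), , drop = FALSE]
  rc <- cl$points[inter_tag_points(cl, 5L), , drop = FALSE]
  # Hausdorff distance between the two rings below the mesh resolution
  h <- cardiomesh:::mean_edge_length(s)
  d1 <- max(ring_distance(rh, rc))
  expect_lt(d1, h)
})
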