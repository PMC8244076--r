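test_that("boundary ring extraction matches surface topology", {
  expect_length(extract_boundary_rings(icosphere(2)), 0L)

  tb <- tube(n_theta = 16, n_z = 5)
  rings <- extract_boundary_rings(tb)
  expect_length(rings, 2L)
  expect_true(all(lengths(rings) == 16L))

  for (k in c(2, 4, 7)) {
    sq <- square_patch(k)
    rings <- extract_boundary_rings(sq)
    expect_length(rings, 1L)
    expect_length(rings[[1]], 4L * k)
  }
})

test_that("rings are closed loops of boundary edges, winding-consistent", {
  sq <- square_patch(3)
  r <- extract_boundary_rings(sq)[[1]]
  expect_false(anyDuplicated(as.integer(r)) > 0)
  # every consecutive pair is a boundary edge (exactly one incident cell)
  tr <- sq$triangles
  i <- c(tr[, 1], tr[, 2], tr[, 3]); j <- c(tr[, 2], tr[, 3], tr[, 1])
  key <- paste(pmin(i, j), pmax(i, j))
  cnt <- table(key)
  n <- length(r)
  rk <- paste(pmin(r, r[c(2:n, 1)]), pmax(r, r[c(2:n, 1)]))
  expect_true(all(cnt[rk] == 1L))
})

test_that("non-manifold edges are rejected with the edge named", {
  # three triangles sharing one edge
  p <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1))
  s <- tri_surface(p, rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5)))
  expect_error(validate_surface(s), "non-manifold edge")
  expect_error(extract_boundary_rings(s), "non-manifold")
})

test_that("connected components partition the surface", {
  expect_length(connected_components(icosphere(1)), 1L)
  two <- merge_surfaces(list(icosphere(1), icosphere(1, center = c(5, 0, 0))), tol = 0)
  comps <- connected_components(two)
  expect_length(comps, 2L)
  # union of components reproduces the input up to reindexing
  expect_identical(cell_fingerprint(merge_surfaces(comps, tol = 0)),
                   cell_fingerprint(two))
})

test_that("biventricular analog splits into three components once valve tags removed", {
  tc <- two_cavity_shell(10, 3, 4, level = 1)
  expect_length(connected_components(tc), 3L)
})

test_that("merge_surfaces unifies duplicate points and preserves manifoldness", {
  # two half-spheres sharing their equator ring -> closed sphere
  s <- icosphere(2)
  s$point_data$z <- s$points[, 3]
  top <- clip_at_level(s, "z", 0, keep = "above")
  bottom <- clip_at_level(s, "z", 0, keep = "below")
  glued <- merge_surfaces(list(top, bottom))
  expect_length(extract_boundary_rings(glued), 0L)
  expect_identical(euler_characteristic(glued), 2L)

  # disjoint parts with tol = 0: plain concatenation
  cat2 <- merge_surfaces(list(icosphere(1), icosphere(1, center = c(9, 0, 0))), tol = 0)
  expect_identical(nrow(cat2$points), 2L * nrow(icosphere(1)$points))
})

test_that("warp translates points and preserves everything else", {
  s <- icosphere(2)
  s$cell_tags[3:7] <- 4L
  expect_equal(warp_surface(s, matrix(0, nrow(s$points), 3)), s)
  moved <- warp_surface(s, matrix(rep(c(1, 0, 0), each = nrow(s$points)), ncol = 3))
  expect_equal(moved$points[, 1], s$points[, 1] + 1)
  expect_identical(moved$triangles, s$triangles)
  expect_identical(moved$cell_tags, s$cell_tags)
  expect_equal(edge_lengths_of(moved), edge_lengths_of(s))
  # radial field on the unit sphere scales the radius
  radial <- warp_surface(s, s$points * 0.1)
  expect_equal(sqrt(rowSums(radial$points^2)), rep(1.1, nrow(s$points)), tolerance = 1e-12)
  expect_error(warp_surface(s, matrix(0, 5, 3)), "every point")
})

test_that("closed genus-0 surfaces satisfy Euler characteristic 2 and positive volume", {
  for (s in list(icosphere(1), icosphere(3), ellipsoid_chamber(n_theta = 16, n_phi = 8))) {
    expect_identical(euler_characteristic(s), 2L)
    expect_gt(surface_volume(s), 0)
    validate_surface(s)
  }
})
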