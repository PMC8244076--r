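test_that("star-shaped tetrahedralization cones the boundary exactly", {
  cube_surf <- boundary_surface(cube_tet(1))
  cube_surf$cell_tags[] <- 0L
  m <- tetrahedralize(cube_surf)
  expect_identical(nrow(m$tets), nrow(cube_surf$triangles))
  expect_equal(sum(tet_volumes(m)), 1, tolerance = 1e-14)
  validate_tet_mesh(m)
  # boundary triangulation preserved (vertices and faces)
  expect_identical(cell_fingerprint(boundary_surface(m)), cell_fingerprint(cube_surf))

  ms <- tetrahedralize(icosphere(3))
  expect_equal(sum(tet_volumes(ms)), 4 / 3 * pi, tolerance = 0.02)
})

test_that("non-star-shaped regions are refused by the fallback backend", {
  torus <- local({
    R <- 2; r0 <- 0.7; nu <- 24; nv <- 12
    u <- seq(0, 2 * pi, length.out = nu + 1)[-(nu + 1)]
    v <- seq(0, 2 * pi, length.out = nv + 1)[-(nv + 1)]
    pts <- do.call(rbind, lapply(v, function(vv)
      cbind((R + r0 * cos(vv)) * cos(u), (R + r0 * cos(vv)) * sin(u), r0 * sin(vv))))
    idx <- function(iv, iu) ((iv - 1) %% nv) * nu + ((iu - 1) %% nu) + 1
    tr <- list()
    for (iv in 1:nv) for (iu in 1:nu) {
      a <- idx(iv, iu); b <- idx(iv, iu + 1); c <- idx(iv + 1, iu); d <- idx(iv + 1, iu + 1)
      tr[[length(tr) + 1]] <- rbind(c(a, b, d), c(a, d, c))
    }
    s <- tri_surface(pts, do.call(rbind, tr))
    if (surface_volume(s) < 0) s <- flip_orientation(s)
    s
  })
  expect_error(tetrahedralize(torus), "star-shaped")
  expect_error(tetrahedralize(square_patch(2)), "closed")
})

test_that("mesh connection across a gap conserves volume and tags", {
  m1 <- cube_tet(2)
  m2 <- cube_tet(2, origin = c(1.2, 0, 0))
  out <- mesh_connection(m1, m2, tags1 = 2L, tags2 = 1L, h = NULL)
  expect_equal(sum(tet_volumes(out)), 2.2, tolerance = 0.01)
  expect_setequal(unique(out$cell_tags), c(1L, 2L, 3L))
  expect_identical(sum(unique(out$boundary_tags) >= 100L), 1L)  # one wall tag
  validate_tet_mesh(out)
  # volumes add exactly: vol(connection) = total - inputs
  expect_equal(sum(tet_volumes(out)[out$cell_tags == 3L]), 0.2, tolerance = 1e-9)
})

test_that("shrinking the gap shrinks the connecting volume toward zero", {
  m1 <- cube_tet(1)
  vols <- vapply(c(0.4, 0.2, 0.05), function(gap) {
    m2 <- cube_tet(1, origin = c(1 + gap, 0, 0))
    out <- mesh_connection(m1, m2, tags1 = 2L, tags2 = 1L, h = NULL)
    sum(tet_volumes(out)[out$cell_tags == 3L])
  }, numeric(1))
  expect_true(all(diff(vols) < 0))
  expect_lt(vols[3], 0.06)
})

test_that("patches with two rings each produce one wall tag per ring pair", {
  # each input is a pair of disjoint cubes, so the tagged facing region has
  # two boundary rings; the connection must build two walls and two tags
  pair_of_cubes <- function(origin_z, x0) {
    merge_tet_meshes(list(cube_tet(1, origin = c(x0, 0, 0)),
                          cube_tet(1, origin = c(x0, 0, 2))), tol = 0)
  }
  m1 <- pair_of_cubes(0, 0)
  m2 <- pair_of_cubes(0, 1.3)
  out <- mesh_connection(m1, m2, tags1 = 2L, tags2 = 1L, h = NULL)
  wall_tags <- unique(out$boundary_tags[out$boundary_tags >= 100L])
  expect_identical(length(wall_tags), 2L)
  expect_equal(sum(tet_volumes(out)), 2 + 2 + 2 * 0.3, tolerance = 0.01)
  validate_tet_mesh(out)
})

test_that("refinement meets the sizing criterion with exact volume and tag projection", {
  m <- cube_tet(2)
  # two volume tags across z = 0.5
  zb <- vapply(seq_len(nrow(m$tets)), function(t1) mean(m$points[m$tets[t1, ], 3]), numeric(1))
  m$cell_tags[zb > 0.5] <- 2L
  m$point_data$f <- abs(m$points[, 3] - 0.5)
  out <- refine_mesh(m, "f", alpha = 0.2, beta = 1, m = 0.1)
  expect_gte(nrow(out$tets), nrow(m$tets))
  expect_equal(sum(tet_volumes(out)), 1, tolerance = 1e-10)
  validate_tet_mesh(out)
  # criterion: longest edge <= 1.5 h(barycenter) everywhere
  ed <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  lmax <- vapply(seq_len(nrow(out$tets)), function(t1) {
    v <- out$tets[t1, ]
    max(apply(ed, 1, function(e) sqrt(sum((out$points[v[e[1]], ] - out$points[v[e[2]], ])^2))))
  }, numeric(1))
  fb <- rowMeans(matrix(out$point_data$f[out$tets], ncol = 4))
  expect_true(all(lmax <= 1.5 * pmax(0.1, 0.2 * fb) + 1e-12))
  # tag projection: every output tet carries the tag of the input tet
  # containing its barycenter (point-in-tet oracle on a subsample)
  set.seed(8)
  pick <- sample(nrow(out$tets), 40)
  bary <- t(vapply(pick, function(t1) colMeans(out$points[out$tets[t1, ], ]), numeric(3)))
  host <- locate_tets(m, bary)
  expect_false(anyNA(host))
  expect_identical(out$cell_tags[pick], m$cell_tags[host])
})

test_that("refinement is the identity when the mesh already satisfies the sizing", {
  m <- cube_tet(1)
  m$point_data$f <- rep(100, nrow(m$points))
  out <- refine_mesh(m, "f", alpha = 1, beta = 1, m = 0.5)
  expect_identical(nrow(out$tets), nrow(m$tets))
  expect_error(refine_mesh(m, "f", m = 0), "m must be > 0")
})

test_that("tet-to-hex conversion has the exact combinatorics and conserves volume", {
  one <- tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)), matrix(1:4, 1))
  hx <- tet_to_hex(one)
  expect_identical(nrow(hx$hexes), 4L)
  expect_identical(nrow(hx$points), 15L)
  expect_identical(nrow(hx$boundary_quads), 12L)   # 3 per boundary triangle
  expect_equal(sum(hex_volumes(hx)), 1 / 6, tolerance = 1e-12)
  expect_true(all(hex_corner_jacobians(hx) > 0))

  hx1 <- tet_to_hex(one, n_rbs = 1)
  expect_identical(nrow(hx1$hexes), 32L)
  expect_identical(nrow(hx1$boundary_quads), 48L)
  expect_equal(sum(hex_volumes(hx1)), 1 / 6, tolerance = 1e-12)

  m <- cube_tet(2)
  m$cell_tags[1:10] <- 3L
  hq <- tet_to_hex(m, n_rbs = 1)
  expect_identical(nrow(hq$hexes), 4L * nrow(m$tets) * 8L)
  expect_identical(nrow(hq$boundary_quads), 3L * nrow(m$boundary_faces) * 4L)
  expect_equal(sum(hex_volumes(hq)), sum(tet_volumes(m)), tolerance = 1e-10)
  expect_true(all(hex_corner_jacobians(hq) > 0))
  # tags inherited per parent cell
  expect_identical(hq$cell_tags, rep(rep(m$cell_tags, each = 4L), each = 8L))
})
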