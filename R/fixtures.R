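#' Deterministic synthetic cardiac-like geometries
#'
#' Generators of the idealized shapes used throughout the package in place
#' of commercial anatomical data: closed smooth shells (epicardium /
#' endocardium analogs), nested two-cavity shells (biventricular analog),
#' open tubes with boundary rings (atrium / aorta analogs), thin-wall
#' shells, flat patches, and simple tetrahedral meshes.  All generators are
#' fully deterministic: the same parameters always produce bit-identical
#' output.
#'
#' @name fixtures
NULL

#' Icosphere
#'
#' Subdivided icosahedron with `20 * 4^level` triangles projected onto a
#' sphere; closed, outward-oriented.
#'
#' @param level Subdivision level (0 = icosahedron).
#' @param radius Sphere radius (mm).
#' @param center Length-3 center.
#' @return A [tri_surface()].
#' @export
icosphere <- function(level = 3, radius = 1, center = c(0, 0, 0)) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(1 + t^2)
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (l in seq_len(level)) {
    mid_cache <- new.env(hash = TRUE)
    np <- nrow(v)
    newv <- list()
    midpoint <- function(a, b) {
      key <- edge_key(a, b)
      got <- mid_cache[[key]]
      if (!is.null(got)) return(got)
      m <- (v[a, ] + v[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      newv[[length(newv) + 1L]] <<- m
      idx <- np + length(newv)
      mid_cache[[key]] <- idx
      idx
    }
    f2 <- matrix(0L, nrow(f) * 4L, 3L)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; c <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      f2[(k - 1L) * 4L + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(c, ca, bc), c(ab, bc, ca))
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- f2
  }
  pts <- sweep(v * radius, 2, center, `+`)
  tri_surface(pts, f)
}

#' Spherical wall shell
#'
#' Two concentric icospheres forming the closed boundary of a spherical
#' wall: the outer sphere keeps outward normals, the inner (cavity) sphere
#' is flipped so its normals point into the cavity, i.e. out of the solid
#' wall.  Tags: outer = `outer_tag`, inner = `inner_tag`.
#'
#' @param r_inner,r_outer Radii (mm), `r_inner < r_outer`.
#' @param level Icosphere subdivision level.
#' @param center Common center.
#' @param inner_tag,outer_tag Integer cell tags.
#' @return A [tri_surface()] with two connected components.
#' @export
shell <- function(r_inner, r_outer, level = 3, center = c(0, 0, 0),
                  inner_tag = 2L, outer_tag = 1L) {
  stopifnot(r_inner > 0, r_inner < r_outer)
  outer <- icosphere(level, r_outer, center)
  inner <- flip_orientation(icosphere(level, r_inner, center))
  outer$cell_tags[] <- outer_tag
  inner$cell_tags[] <- inner_tag
  merge_surfaces(list(outer, inner), tol = 0)
}

#' Two-cavity shell (biventricular analog)
#'
#' One outer sphere with two disjoint internal cavity spheres, all closed;
#' cavity orientations are flipped so all normals point out of the solid
#' wall.  Tags: outer = 1, first cavity = 2, second cavity = 3.
#'
#' @param r_outer Outer radius.
#' @param r_cavity Cavity radius.
#' @param offset Cavity centers sit at `(+/- offset, 0, 0)`.
#' @param level Icosphere subdivision level.
#' @return A [tri_surface()] with three connected components.
#' @export
two_cavity_shell <- function(r_outer = 10, r_cavity = 3, offset = 4, level = 3) {
  if (r_cavity + offset >= r_outer) stop("cavities intersect the outer wall", call. = FALSE)
  if (offset <= r_cavity) stop("cavities intersect each other", call. = FALSE)
  outer <- icosphere(level, r_outer)
  c1 <- flip_orientation(icosphere(level, r_cavity, c(offset, 0, 0)))
  c2 <- flip_orientation(icosphere(level, r_cavity, c(-offset, 0, 0)))
  outer$cell_tags[] <- 1L; c1$cell_tags[] <- 2L; c2$cell_tags[] <- 3L
  merge_surfaces(list(outer, c1, c2), tol = 0)
}

#' Open cylindrical tube
#'
#' Lateral surface of a cylinder along z with two boundary rim rings;
#' outward-oriented (normals point radially out).
#'
#' @param radius Radius (mm).
#' @param length Axial length; the tube spans `z in [z0, z0 + length]`.
#' @param n_theta Points around the circumference.
#' @param n_z Rings of points along the axis (>= 2).
#' @param z0 Axial start.
#' @return A [tri_surface()] with two boundary rings.
#' @export
tube <- function(radius = 1, length = 2, n_theta = 32, n_z = 17, z0 = 0) {
  th <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  zz <- seq(z0, z0 + length, length.out = n_z)
  pts <- cbind(radius * cos(rep(th, n_z)), radius * sin(rep(th, n_z)),
               rep(zz, each = n_theta))
  idx <- function(iz, it) (iz - 1L) * n_theta + ((it - 1L) %% n_theta) + 1L
  tr <- list()
  for (iz in seq_len(n_z - 1L)) for (it in seq_len(n_theta)) {
    a <- idx(iz, it); b <- idx(iz, it + 1L)
    c2 <- idx(iz + 1L, it); d <- idx(iz + 1L, it + 1L)
    # outward winding: CCW seen from outside the cylinder
    tr[[length(tr) + 1L]] <- rbind(c(a, b, d), c(a, d, c2))
  }
  tri_surface(pts, do.call(rbind, tr))
}

#' Flat annular patch
#'
#' A planar annulus in the z = 0 plane triangulated on a polar grid;
#' boundary rings at the inner and outer radii.  Winding gives +z normals.
#'
#' @param r_inner,r_outer Radii.
#' @param n_theta Angular resolution.
#' @param n_r Radial point rows (>= 2).
#' @return A [tri_surface()].
#' @export
annular_patch <- function(r_inner = 1, r_outer = 2, n_theta = 48, n_r = 9) {
  stopifnot(r_inner > 0, r_inner < r_outer)
  th <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  rr <- seq(r_inner, r_outer, length.out = n_r)
  pts <- cbind(rep(rr, each = n_theta) * cos(rep(th, n_r)),
               rep(rr, each = n_theta) * sin(rep(th, n_r)), 0)
  idx <- function(ir, it) (ir - 1L) * n_theta + ((it - 1L) %% n_theta) + 1L
  tr <- list()
  for (ir in seq_len(n_r - 1L)) for (it in seq_len(n_theta)) {
    a <- idx(ir, it); b <- idx(ir, it + 1L)
    c2 <- idx(ir + 1L, it); d <- idx(ir + 1L, it + 1L)
    tr[[length(tr) + 1L]] <- rbind(c(a, b, d), c(a, d, c2))
  }
  tri_surface(pts, do.call(rbind, tr))
}

#' Flat square patch on a k x k grid
#'
#' Unit-square style patch in the z = 0 plane, `k x k` quads split into
#' triangles; one boundary ring of `4k` points.  Winding gives +z normals.
#'
#' @param k Quads per side.
#' @param size Side length.
#' @return A [tri_surface()].
#' @export
square_patch <- function(k = 4, size = 1) {
  xs <- seq(0, size, length.out = k + 1L)
  pts <- cbind(rep(xs, k + 1L), rep(xs, each = k + 1L), 0)
  idx <- function(ix, iy) (iy - 1L) * (k + 1L) + ix
  tr <- list()
  for (iy in seq_len(k)) for (ix in seq_len(k)) {
    a <- idx(ix, iy); b <- idx(ix + 1L, iy)
    c2 <- idx(ix, iy + 1L); d <- idx(ix + 1L, iy + 1L)
    tr[[length(tr) + 1L]] <- rbind(c(a, b, d), c(a, d, c2))
  }
  tri_surface(pts, do.call(rbind, tr))
}

#' Truncated prolate ellipsoid chamber (idealized left ventricle)
#'
#' A prolate ellipsoid (semi-axes `a, a, c`), truncated at the base plane
#' `z = z_base`.  With `wall = FALSE` (default) the cavity is capped flat at
#' the base, producing a closed, star-shaped "blood pool" surface (cap tag
#' 3, chamber tag 2).  With `wall = TRUE` an outer ellipsoid (semi-axes
#' grown by `thickness`) is added and the two base rims are joined by a flat
#' annular cap: a closed myocardial wall with tags epicardium = 1,
#' endocardium = 2, base = 3.
#'
#' @param a,c_ax Equatorial and long semi-axes (mm).
#' @param z_base Truncation plane (apex at `z = -c_ax`).
#' @param thickness Wall thickness for `wall = TRUE`.
#' @param n_theta,n_phi Angular resolutions.
#' @param wall Build a hollow wall instead of a capped pool.
#' @return A [tri_surface()].
#' @export
ellipsoid_chamber <- function(a = 25, c_ax = 45, z_base = 15, thickness = 8,
                              n_theta = 40, n_phi = 24, wall = FALSE) {
  open_shell <- function(a1, c1, zb, flip = FALSE) {
    # phi from apex (-c1) up to the base plane
    phi_base <- acos(pmin(1, pmax(-1, zb / c1)))
    phis <- seq(pi, phi_base, length.out = n_phi + 1L)  # pi = apex
    th <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
    # apex point + rings
    pts <- rbind(c(0, 0, -c1))
    for (ph in phis[-1]) {
      pts <- rbind(pts, cbind(a1 * sin(ph) * cos(th), a1 * sin(ph) * sin(th),
                              c1 * cos(ph)))
    }
    tr <- list()
    # apex fan (wound like the quad strip above it)
    for (it in seq_len(n_theta)) {
      b <- 1L + it; c2 <- 1L + (it %% n_theta) + 1L
      tr[[length(tr) + 1L]] <- c(1L, b, c2)
    }
    idx <- function(ir, it) 1L + (ir - 1L) * n_theta + ((it - 1L) %% n_theta) + 1L
    for (ir in seq_len(n_phi - 1L)) for (it in seq_len(n_theta)) {
      p1 <- idx(ir, it); p2 <- idx(ir, it + 1L)
      p3 <- idx(ir + 1L, it); p4 <- idx(ir + 1L, it + 1L)
      tr[[length(tr) + 1L]] <- c(p1, p4, p2)
      tr[[length(tr) + 1L]] <- c(p1, p3, p4)
    }
    s <- tri_surface(pts, do.call(rbind, tr))
    if (surface_volume(merge_surfaces(list(s, cap_of(s)), tol = 0)) < 0)
      s <- flip_orientation(s)
    if (flip) s <- flip_orientation(s)
    s
  }
  cap_of <- function(s) {
    ring <- extract_boundary_rings(s)[[1]]
    ctr <- colMeans(s$points[ring, , drop = FALSE])
    n <- length(ring)
    pts <- rbind(s$points[ring, , drop = FALSE], ctr)
    tr <- cbind(seq_len(n), c(seq_len(n)[-1], 1L), n + 1L)
    tri_surface(pts, tr[, c(2, 1, 3)])
  }
  endo <- open_shell(a, c_ax, z_base)
  endo$cell_tags[] <- 2L
  if (!wall) {
    cap <- cap_of(endo)
    cap$cell_tags[] <- 3L
    out <- merge_surfaces(list(endo, cap))
    if (surface_volume(out) < 0) out <- flip_orientation(out)
    return(out)
  }
  epi <- open_shell(a + thickness, c_ax + thickness, z_base)
  epi$cell_tags[] <- 1L
  endo_w <- flip_orientation(endo)      # cavity wall of the solid
  ring_epi <- extract_boundary_rings(epi)[[1]]
  ring_endo <- extract_boundary_rings(endo_w)[[1]]
  # annular base cap joining the two rims, built with the zipper so its
  # winding is consistent with both shells
  base <- zipper_band(epi, ring_epi, endo_w, ring_endo, band_tag = 3L)
  out <- merge_surfaces(list(epi, endo_w, base))
  validate_surface(out)
  if (surface_volume(out) < 0) out <- flip_orientation(out)
  out
}

#' Tetrahedral mesh of a cube
#'
#' Unit-style cube split into `n^3` subcubes, each into 6 Kuhn tetrahedra
#' (so `6 n^3` tets); conforming, with all tet volumes positive.  Boundary
#' faces are tagged 1..6 by side (`-x, +x, -y, +y, -z, +z`).
#'
#' @param n Subdivisions per side.
#' @param size Edge length.
#' @param origin Lower corner.
#' @param volume_tag Tag for all tets.
#' @return A [tet_mesh()].
#' @export
cube_tet <- function(n = 2, size = 1, origin = c(0, 0, 0), volume_tag = 1L) {
  xs <- seq(0, size, length.out = n + 1L)
  np <- n + 1L
  pts <- as.matrix(expand.grid(x = xs, y = xs, z = xs))[, 1:3]
  pts <- sweep(unname(pts), 2, origin, `+`)
  idx <- function(i, j, k) (k - 1L) * np * np + (j - 1L) * np + i
  # Kuhn subdivision: 6 tets per cube around the main diagonal
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  tets <- list()
  for (k in seq_len(n)) for (j in seq_len(n)) for (i in seq_len(n)) {
    corner <- c(i, j, k)
    for (pp in seq_len(6)) {
      path <- rbind(c(0, 0, 0),
                    diag(3)[perms[pp, 1], ],
                    diag(3)[perms[pp, 1], ] + diag(3)[perms[pp, 2], ],
                    c(1, 1, 1))
      vv <- apply(path, 1, function(d) idx(corner[1] + d[1], corner[2] + d[2], corner[3] + d[3]))
      tets[[length(tets) + 1L]] <- vv
    }
  }
  tets <- do.call(rbind, tets)
  # fix orientation: positive volume
  vol <- tet_volumes_raw(pts, tets)
  neg <- vol < 0
  tets[neg, c(3, 4)] <- tets[neg, c(4, 3)]
  m <- tet_mesh(pts, tets, cell_tags = rep(as.integer(volume_tag), nrow(tets)))
  # tag boundary faces by cube side
  bf <- m$boundary_faces
  ctr <- (pts[bf[, 1], , drop = FALSE] + pts[bf[, 2], , drop = FALSE] + pts[bf[, 3], , drop = FALSE]) / 3
  eps <- 1e-9 * size
  tag <- integer(nrow(bf))
  tag[abs(ctr[, 1] - origin[1]) < eps] <- 1L
  tag[abs(ctr[, 1] - (origin[1] + size)) < eps] <- 2L
  tag[abs(ctr[, 2] - origin[2]) < eps] <- 3L
  tag[abs(ctr[, 2] - (origin[2] + size)) < eps] <- 4L
  tag[abs(ctr[, 3] - origin[3]) < eps] <- 5L
  tag[abs(ctr[, 3] - (origin[3] + size)) < eps] <- 6L
  m$boundary_tags <- tag
  m
}

#' Tetrahedral slab
#'
#' Rectangular slab `nx x ny x nz` subcubes of edge `h`, via [cube_tet()]
#' style Kuhn subdivision.
#'
#' @param nx,ny,nz Subdivisions.
#' @param h Subcube edge length.
#' @param origin Lower corner.
#' @return A [tet_mesh()].
#' @export
slab_tet <- function(nx = 4, ny = 4, nz = 1, h = 0.25, origin = c(0, 0, 0)) {
  xs <- seq(0, nx * h, by = h); ys <- seq(0, ny * h, by = h); zs <- seq(0, nz * h, by = h)
  npx <- nx + 1L; npy <- ny + 1L
  pts <- as.matrix(expand.grid(x = xs, y = ys, z = zs))[, 1:3]
  pts <- sweep(unname(pts), 2, origin, `+`)
  idx <- function(i, j, k) (k - 1L) * npx * npy + (j - 1L) * npx + i
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  tets <- list()
  for (k in seq_len(nz)) for (j in seq_len(ny)) for (i in seq_len(nx)) {
    for (pp in seq_len(6)) {
      path <- rbind(c(0, 0, 0),
                    diag(3)[perms[pp, 1], ],
                    diag(3)[perms[pp, 1], ] + diag(3)[perms[pp, 2], ],
                    c(1, 1, 1))
      vv <- apply(path, 1, function(d) idx(i + d[1], j + d[2], k + d[3]))
      tets[[length(tets) + 1L]] <- vv
    }
  }
  tets <- do.call(rbind, tets)
  vol <- tet_volumes_raw(pts, tets)
  neg <- vol < 0
  tets[neg, c(3, 4)] <- tets[neg, c(4, 3)]
  tet_mesh(pts, tets)
}

#' Build a fixture from a declarative description
#'
#' Single entry point used by the command-line interface; dispatches on
#' `kind` to the individual generators.
#'
#' @param kind One of `"icosphere"`, `"shell"`, `"two_cavity_shell"`,
#'   `"tube"`, `"annular_patch"`, `"square_patch"`, `"cube_tet"`,
#'   `"slab_tet"`, `"ellipsoid_chamber"`.
#' @param ... Parameters forwarded to the generator.
#' @return A [tri_surface()] or [tet_mesh()].
#' @export
make_fixture <- function(kind, ...) {
  switch(kind,
         icosphere = icosphere(...),
         shell = shell(...),
         two_cavity_shell = two_cavity_shell(...),
         tube = tube(...),
         annular_patch = annular_patch(...),
         square_patch = square_patch(...),
         cube_tet = cube_tet(...),
         slab_tet = slab_tet(...),
         ellipsoid_chamber = ellipsoid_chamber(...),
         stop(sprintf("unknown fixture kind '%s'", kind), call. = FALSE))
}
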