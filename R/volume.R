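#' Tetrahedral volume meshes
#'
#' A `tet_mesh` stores a conforming tetrahedral mesh with an integer tag per
#' tet and tagged boundary faces.  The node-ordering convention is fixed so
#' that every signed tet volume is positive:
#' `det[p2 - p1, p3 - p1, p4 - p1] > 0`.  Boundary faces are the triangles
#' belonging to exactly one tet, wound with outward normals.
#'
#' @param points n x 3 coordinate matrix (mm).
#' @param tets m x 4 integer matrix of point indices.
#' @param cell_tags Integer tag per tet (default 0).
#' @param point_data,cell_data Named field lists as in [tri_surface()].
#' @param boundary_faces Optional k x 3 matrix; recomputed when `NULL`.
#' @param boundary_tags Integer tag per boundary face.
#' @return An object of class `tet_mesh`.
#' @export
tet_mesh <- function(points, tets, cell_tags = NULL, point_data = list(),
                     cell_data = list(), boundary_faces = NULL,
                     boundary_tags = NULL) {
  points <- as_point_matrix(points)
  tets <- as.matrix(tets); storage.mode(tets) <- "integer"; dimnames(tets) <- NULL
  if (ncol(tets) != 4L) stop("tets must be an m x 4 matrix", call. = FALSE)
  if (is.null(cell_tags)) cell_tags <- integer(nrow(tets))
  m <- structure(list(points = points, tets = tets,
                      cell_tags = as.integer(cell_tags),
                      point_data = point_data, cell_data = cell_data),
                 class = "tet_mesh")
  if (is.null(boundary_faces)) {
    bf <- compute_boundary_faces(tets)
    m$boundary_faces <- bf
    m$boundary_tags <- integer(nrow(bf))
  } else {
    storage.mode(boundary_faces) <- "integer"
    m$boundary_faces <- boundary_faces
    m$boundary_tags <- as.integer(boundary_tags %||% integer(nrow(boundary_faces)))
  }
  m
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("tet_mesh: %d points, %d tets (vol %.6g), %d boundary faces, volume tags {%s}\n",
              nrow(x$points), nrow(x$tets), sum(tet_volumes(x)),
              nrow(x$boundary_faces),
              paste(sort(unique(x$cell_tags)), collapse = ",")))
  invisible(x)
}

tet_volumes_raw <- function(p, tets) {
  a <- p[tets[, 1], , drop = FALSE]
  u <- p[tets[, 2], , drop = FALSE] - a
  v <- p[tets[, 3], , drop = FALSE] - a
  w <- p[tets[, 4], , drop = FALSE] - a
  rowSums(row_cross(u, v) * w) / 6
}

#' Signed tet volumes
#' @param m A [tet_mesh()].
#' @return Numeric vector; positive under the package convention.
#' @export
tet_volumes <- function(m) tet_volumes_raw(m$points, m$tets)

# Faces of tets in outward-wound order for face (opposite each vertex).
tet_faces_all <- function(tets) {
  # for positively oriented (1,2,3,4): outward faces are
  # (1,3,2), (1,2,4), (2,3,4), (1,4,3)
  rbind(tets[, c(1, 3, 2), drop = FALSE],
        tets[, c(1, 2, 4), drop = FALSE],
        tets[, c(2, 3, 4), drop = FALSE],
        tets[, c(1, 4, 3), drop = FALSE])
}

compute_boundary_faces <- function(tets) {
  f <- tet_faces_all(tets)
  key <- apply(f, 1, function(v) paste(sort(v), collapse = "-"))
  cnt <- table(key)
  f[key %in% names(cnt)[cnt == 1L], , drop = FALSE]
}

#' Validate a tetrahedral mesh
#'
#' Checks positive volumes, index ranges and that the stored boundary faces
#' are exactly the once-used faces.
#' @param m A [tet_mesh()].
#' @return Invisibly `TRUE`.
#' @export
validate_tet_mesh <- function(m) {
  stopifnot(inherits(m, "tet_mesh"))
  if (min(m$tets) < 1L || max(m$tets) > nrow(m$points))
    stop("tet indices out of range", call. = FALSE)
  v <- tet_volumes(m)
  if (any(v <= 0)) stop(sprintf("non-positive tet volume at cell %d", which(v <= 0)[1]), call. = FALSE)
  bf <- compute_boundary_faces(m$tets)
  k1 <- sort(apply(bf, 1, function(x) paste(sort(x), collapse = "-")))
  k2 <- sort(apply(m$boundary_faces, 1, function(x) paste(sort(x), collapse = "-")))
  if (!identical(k1, k2)) stop("stored boundary faces out of date", call. = FALSE)
  invisible(TRUE)
}

#' Boundary surface of a tet mesh
#'
#' @param m A [tet_mesh()].
#' @param tags Optional subset of boundary-face tags to keep.
#' @return A [tri_surface()] whose `cell_tags` are the boundary-face tags
#'   and whose `point_data$parent_index` maps back to mesh point indices.
#' @export
boundary_surface <- function(m, tags = NULL) {
  bf <- m$boundary_faces; bt <- m$boundary_tags
  if (!is.null(tags)) { keep <- bt %in% tags; bf <- bf[keep, , drop = FALSE]; bt <- bt[keep] }
  used <- sort(unique(as.vector(bf)))
  remap <- integer(nrow(m$points)); remap[used] <- seq_along(used)
  tri_surface(m$points[used, , drop = FALSE], matrix(remap[bf], ncol = 3),
              cell_tags = bt,
              point_data = c(lapply(m$point_data, function(f)
                if (is.matrix(f)) f[used, , drop = FALSE] else f[used]),
                list(parent_index = used)))
}

#' Tetrahedralize a closed surface (star-shaped backend)
#'
#' Fills a closed, outward-oriented surface with tetrahedra by coning every
#' boundary triangle to the centroid of the enclosed volume.  This built-in
#' backend is valid only for star-shaped regions (every boundary triangle
#' visible from the centroid); non-star-shaped input raises an error.  The
#' boundary triangulation is preserved exactly, so any external constrained
#' Delaunay mesher honouring the same contract can be substituted via
#' `backend`.
#'
#' @param boundary A closed [tri_surface()].
#' @param backend A function `(boundary) -> tet_mesh`, or `"star"`.
#' @param volume_tag Integer tag for the generated tets.
#' @return A [tet_mesh()] whose boundary faces inherit the surface cell
#'   tags.
#' @export
tetrahedralize <- function(boundary, backend = "star", volume_tag = 1L) {
  if (is.function(backend)) return(backend(boundary))
  if (!is_closed(boundary)) stop("boundary surface must be closed", call. = FALSE)
  comps <- connected_components(boundary)
  if (length(comps) > 1L) {
    # disjoint closed regions are coned independently; a cavity component
    # (negative volume) cannot be filled and fails the star-shape test
    parts <- lapply(comps, tetrahedralize, backend = backend, volume_tag = volume_tag)
    return(merge_tet_meshes(parts, tol = 0))
  }
  p <- boundary$points; tr <- boundary$triangles
  # volume centroid via divergence theorem
  a <- p[tr[, 1], , drop = FALSE]; b <- p[tr[, 2], , drop = FALSE]; c <- p[tr[, 3], , drop = FALSE]
  w <- rowSums(a * row_cross(b, c)) / 6
  ctr <- colSums((a + b + c) / 4 * w) / sum(w)
  apex <- nrow(p) + 1L
  tets <- cbind(tr[, 1], tr[, 3], tr[, 2], apex)
  vols <- tet_volumes_raw(rbind(p, ctr), tets)
  if (any(vols <= 1e-14 * max(abs(vols))))
    stop("region not star-shaped; external backend required", call. = FALSE)
  m <- tet_mesh(rbind(p, ctr), tets,
                cell_tags = rep(as.integer(volume_tag), nrow(tets)),
                boundary_faces = tr, boundary_tags = boundary$cell_tags)
  m
}

#' Connect two tetrahedral meshes through a generated wall volume
#'
#' Builds a connecting volume between two disjoint tet meshes: the selected
#' boundary patches (by boundary-face tag) are joined ring-by-ring with
#' zipper walls, the walls are optionally remeshed at mesh-size `h` with
#' the patch triangulations frozen (so the interfaces stay conforming), the
#' closed connection surface is tetrahedralized, and the three meshes are
#' merged with duplicate interface points unified.
#'
#' @param m1,m2 [tet_mesh()] objects, disjoint.
#' @param tags1,tags2 Boundary-face tags selecting the patches to connect;
#'   the two patches must have the same number of boundary rings.
#' @param h Wall mesh-size; `NULL` skips the wall remesh.
#' @param volume_tags Length-3 integer: tags for m1, m2 and the new volume.
#' @param wall_tag_start First integer used for the new wall face tags (one
#'   per ring pair).
#' @return A [tet_mesh()] with three volume tags and one new boundary tag
#'   per wall.
#' @export
mesh_connection <- function(m1, m2, tags1, tags2, h = NULL,
                            volume_tags = c(1L, 2L, 3L), wall_tag_start = 100L,
                            backend = "star") {
  p1 <- boundary_surface(m1, tags1)
  p2 <- boundary_surface(m2, tags2)
  if (n_cells(p1) == 0L || n_cells(p2) == 0L)
    stop("selected boundary tags are empty", call. = FALSE)
  r1 <- extract_boundary_rings(p1)
  r2 <- extract_boundary_rings(p2)
  if (length(r1) != length(r2))
    stop(sprintf("ring-count mismatch: %d vs %d", length(r1), length(r2)), call. = FALSE)
  # flip patches so the closed connection surface is outward-oriented
  # (patch normals currently point out of their parent volumes, i.e. into
  # the gap)
  f1 <- flip_orientation(p1); f2 <- flip_orientation(p2)
  rr1 <- extract_boundary_rings(f1); rr2 <- extract_boundary_rings(f2)
  # pair rings by minimum average distance
  n <- length(rr1)
  ravg <- function(ra, sa, rb, sb) {
    pa <- sa$points[ra, , drop = FALSE]; pb <- sb$points[rb, , drop = FALSE]
    mean(vapply(seq_len(nrow(pa)), function(i)
      sqrt(min(rowSums(sweep(pb, 2, pa[i, ], `-`)^2))), numeric(1)))
  }
  pairing <- integer(n); usedb <- logical(n)
  for (i in seq_len(n)) {
    d <- vapply(seq_len(n), function(j)
      if (usedb[j]) Inf else ravg(rr1[[i]], f1, rr2[[j]], f2), numeric(1))
    pairing[i] <- which.min(d); usedb[pairing[i]] <- TRUE
  }
  parts <- list(f1, f2)
  wall_tags <- integer(0)
  # build each wall as a standalone band surface between the paired rings
  for (j in seq_len(n)) {
    tagw <- as.integer(wall_tag_start + j - 1L)
    band <- zipper_band(f1, rr1[[j]], f2, rr2[[pairing[j]]], band_tag = tagw)
    if (!is.null(h)) {
      band2 <- tryCatch(
        isotropic_remesh(band, h = h, target_tags = tagw,
                         preserve_boundary = TRUE),
        error = function(e) band)
      band <- band2
    }
    parts[[length(parts) + 1L]] <- band
    wall_tags <- c(wall_tags, tagw)
  }
  sigma3 <- merge_surfaces(parts)
  if (!is_closed(sigma3)) stop("connection surface failed to close", call. = FALSE)
  if (surface_volume(sigma3) < 0) sigma3 <- flip_orientation(sigma3)
  m3 <- tetrahedralize(sigma3, backend = backend, volume_tag = volume_tags[3])
  merge_tet_meshes(list(retag_volume(m1, volume_tags[1]),
                        retag_volume(m2, volume_tags[2]),
                        m3))
}

retag_volume <- function(m, tag) { m$cell_tags[] <- as.integer(tag); m }

# Build just the zipper band (no parents) between rings of two surfaces.
zipper_band <- function(s1, ring1, s2, ring2, band_tag = 1L) {
  res <- zipper_triangulation(s1$points[ring1, , drop = FALSE],
                              s2$points[ring2, , drop = FALSE])
  pts <- rbind(s1$points[ring1, , drop = FALSE], s2$points[ring2, , drop = FALSE])
  tri_surface(pts, res$triangles, cell_tags = rep(as.integer(band_tag), nrow(res$triangles)))
}

#' Merge tetrahedral meshes, unifying duplicated interface points
#'
#' @param parts List of [tet_mesh()] objects with conforming interfaces.
#' @param tol Point-merge tolerance; default 1e-9 of the joint bounding-box
#'   diagonal.
#' @return A single conforming [tet_mesh()]; duplicated boundary faces at
#'   interfaces become interior and are removed.
#' @export
merge_tet_meshes <- function(parts, tol = NULL) {
  pts <- do.call(rbind, lapply(parts, function(m) m$points))
  offs <- cumsum(c(0L, vapply(parts, function(m) nrow(m$points), integer(1))))
  tets <- do.call(rbind, Map(function(m, o) m$tets + o, parts, offs[seq_along(parts)]))
  tags <- unlist(lapply(parts, function(m) m$cell_tags), use.names = FALSE)
  bf <- do.call(rbind, Map(function(m, o) m$boundary_faces + o, parts, offs[seq_along(parts)]))
  bt <- unlist(lapply(parts, function(m) m$boundary_tags), use.names = FALSE)
  if (is.null(tol)) {
    rng <- apply(pts, 2, range)
    tol <- 1e-9 * sqrt(sum((rng[2, ] - rng[1, ])^2))
  }
  key <- if (tol > 0)
    paste(round(pts[, 1] / tol), round(pts[, 2] / tol), round(pts[, 3] / tol))
  else paste(pts[, 1], pts[, 2], pts[, 3])
  first <- !duplicated(key)
  newidx <- match(key, key[first])
  keep <- which(first)
  tets2 <- matrix(newidx[tets], ncol = 4)
  bf2 <- matrix(newidx[bf], ncol = 3)
  # interface faces now appear twice -> drop both copies
  fkey <- apply(bf2, 1, function(x) paste(sort(x), collapse = "-"))
  dup <- fkey %in% fkey[duplicated(fkey)]
  tet_mesh(pts[keep, , drop = FALSE], tets2, cell_tags = tags,
           boundary_faces = bf2[!dup, , drop = FALSE], boundary_tags = bt[!dup])
}

#' Sizing-driven conforming refinement of a tet mesh
#'
#' Refines by conforming longest-edge bisection until every tet's longest
#' edge is at most `1.5 * h(barycenter)`, where the target size is
#' `h(x) = max(m, alpha * f(x)^beta)` for a per-point field `f`.  Bisecting
#' an edge splits every tet sharing it, so the mesh stays conforming and
#' the total volume is exactly preserved.  Volume and boundary tags are
#' inherited by the children (equivalently: each output cell carries the tag
#' of the input cell containing its barycenter).
#'
#' @param mesh A [tet_mesh()].
#' @param field Name of a per-point scalar field of `mesh`.
#' @param alpha,beta Sizing parameters (`h = max(m, alpha * f^beta)`).
#' @param m Minimum mesh-size; must be positive (refinement is unbounded
#'   otherwise).
#' @param max_pass Safety cap on bisection sweeps.
#' @return The refined [tet_mesh()].
#' @export
refine_mesh <- function(mesh, field, alpha = 1, beta = 1, m, max_pass = 60L) {
  if (missing(m) || m <= 0) stop("minimum mesh-size m must be > 0", call. = FALSE)
  f <- mesh$point_data[[field]]
  if (is.null(f)) stop(sprintf("field '%s' not found", field), call. = FALSE)
  pts <- mesh$points
  tets <- mesh$tets
  tags <- mesh$cell_tags
  fval <- as.numeric(f)
  ed <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  target_h <- function(idx4) {
    fb <- rowMeans(matrix(fval[idx4], ncol = 4))
    pmax(m, alpha * ifelse(fb < 0 & (beta %% 1 != 0), NA, sign(fb)^0 * abs(fb)^beta * ifelse(fb < 0 & beta %% 2 == 1, -1, 1)))
  }
  for (pass in seq_len(max_pass)) {
    # longest edge per tet
    el <- matrix(0, nrow(tets), 6)
    for (e in 1:6) {
      d <- pts[tets[, ed[e, 1]], , drop = FALSE] - pts[tets[, ed[e, 2]], , drop = FALSE]
      el[, e] <- sqrt(rowSums(d * d))
    }
    lmax <- apply(el, 1, max)
    larg <- apply(el, 1, which.max)
    fb <- rowMeans(matrix(fval[as.vector(tets)], nrow(tets), 4))
    h <- pmax(m, alpha * abs(fb)^beta * ifelse(fb < 0, ifelse(beta %% 2 == 1, -1, 1), 1))
    h[fb < 0 & beta %% 1 != 0] <- m   # negative base with fractional power: clamp
    h <- pmax(m, h)
    bad <- which(lmax > 1.5 * h)
    if (length(bad) == 0L) break
    # collect longest edges of violating tets (unique, longest first)
    ekeys <- vapply(bad, function(t1) {
      v <- tets[t1, ed[larg[t1], ]]
      paste(sort(v), collapse = "-")
    }, character(1))
    o <- order(lmax[bad], decreasing = TRUE)
    ekeys <- ekeys[o][!duplicated(ekeys[o])]
    split_edges <- do.call(rbind, lapply(strsplit(ekeys, "-", fixed = TRUE), as.integer))
    # split edges one sweep at a time; each split is conforming by itself
    for (r in seq_len(nrow(split_edges))) {
      a <- split_edges[r, 1]; b <- split_edges[r, 2]
      hit <- which(rowSums(tets == a) > 0 & rowSums(tets == b) > 0)
      if (length(hit) == 0L) next
      mid <- (pts[a, ] + pts[b, ]) / 2
      pts <- rbind(pts, mid)
      fval <- c(fval, (fval[a] + fval[b]) / 2)
      midx <- nrow(pts)
      child <- tets[hit, , drop = FALSE]
      childA <- child; childA[childA == b] <- midx
      childB <- child; childB[childB == a] <- midx
      tets <- rbind(tets[-hit, , drop = FALSE], childA, childB)
      tags <- c(tags[-hit], tags[hit], tags[hit])
    }
  }
  # rebuild boundary faces and project their tags from the input mesh
  out <- tet_mesh(pts, tets, cell_tags = tags,
                  point_data = list(), cell_data = list())
  out$point_data[[field]] <- fval
  out$boundary_tags <- project_face_tags(mesh, out$boundary_faces, pts)
  out
}

# Assign to each face the tag of the nearest input boundary face barycenter.
project_face_tags <- function(mesh, faces, pts) {
  if (nrow(faces) == 0L) return(integer(0))
  inb <- mesh$boundary_faces
  bi <- (mesh$points[inb[, 1], , drop = FALSE] + mesh$points[inb[, 2], , drop = FALSE] +
           mesh$points[inb[, 3], , drop = FALSE]) / 3
  bo <- (pts[faces[, 1], , drop = FALSE] + pts[faces[, 2], , drop = FALSE] +
           pts[faces[, 3], , drop = FALSE]) / 3
  idx <- vapply(seq_len(nrow(bo)), function(i)
    which.min(rowSums(sweep(bi, 2, bo[i, ], `-`)^2)), integer(1))
  mesh$boundary_tags[idx]
}

#' Locate the tet containing each query point
#'
#' Barycentric point-in-tet search; used as the tag-projection oracle.
#' @param mesh A [tet_mesh()].
#' @param q k x 3 matrix of query points.
#' @param tol Barycentric slack.
#' @return Integer vector of tet indices (NA when outside).
#' @export
locate_tets <- function(mesh, q, tol = 1e-10) {
  q <- as_point_matrix(q)
  p <- mesh$points; tets <- mesh$tets
  vol <- tet_volumes(mesh)
  out <- rep(NA_integer_, nrow(q))
  for (i in seq_len(nrow(q))) {
    x <- q[i, ]
    for (t1 in seq_len(nrow(tets))) {
      v <- tets[t1, ]
      b <- numeric(4)
      ok <- TRUE
      for (k in 1:4) {
        vv <- v; vv[k] <- 0L
        a <- p[v[(k %% 4) + 1], ]
        # barycentric coordinate via sub-tet volume replacing vertex k by x
        pm <- p[v, , drop = FALSE]; pm[k, ] <- x
        b[k] <- tet_volumes_raw(rbind(pm), matrix(1:4, 1)) / vol[t1]
        if (b[k] < -tol) { ok <- FALSE; break }
      }
      if (ok && abs(sum(b) - 1) < 1e-6) { out[i] <- t1; break }
    }
  }
  out
}

#' Convert a tetrahedral mesh to a hexahedral mesh
#'
#' Each tetrahedron is divided into four hexahedra using its edge midpoints,
#' face barycenters and cell barycenter; each boundary triangle becomes
#' three quads.  Optional refine-by-splitting (RBS) iterations split every
#' hex into eight (and every quad into four), halving the mesh-size.  Tags
#' are inherited from parent cells and the total volume is conserved
#' exactly.
#'
#' @param mesh A [tet_mesh()].
#' @param n_rbs Number of RBS iterations (>= 0).
#' @return A [hex_mesh()].
#' @export
tet_to_hex <- function(mesh, n_rbs = 0L) {
  if (any(tet_volumes(mesh) <= 0)) stop("inverted tet in input", call. = FALSE)
  p <- mesh$points
  tets <- mesh$tets
  reg <- point_registry(p)
  hexes <- matrix(0L, 4L * nrow(tets), 8L)
  htags <- rep(mesh$cell_tags, each = 4L)
  for (t1 in seq_len(nrow(tets))) {
    v <- tets[t1, ]
    mid <- function(a, b) reg$get((reg$p(a) + reg$p(b)) / 2)
    fc <- function(a, b, c) reg$get((reg$p(a) + reg$p(b) + reg$p(c)) / 3)
    cc <- reg$get((reg$p(v[1]) + reg$p(v[2]) + reg$p(v[3]) + reg$p(v[4])) / 4)
    m12 <- mid(v[1], v[2]); m13 <- mid(v[1], v[3]); m14 <- mid(v[1], v[4])
    m23 <- mid(v[2], v[3]); m24 <- mid(v[2], v[4]); m34 <- mid(v[3], v[4])
    f123 <- fc(v[1], v[2], v[3]); f124 <- fc(v[1], v[2], v[4])
    f134 <- fc(v[1], v[3], v[4]); f234 <- fc(v[2], v[3], v[4])
    # corner hex at vertex vi: vi, three edge midpoints, three face centers,
    # cell center; ordered bottom quad + matching top quad
    hexes[(t1 - 1L) * 4L + 1L, ] <- c(v[1], m12, f123, m13, m14, f124, cc, f134)
    hexes[(t1 - 1L) * 4L + 2L, ] <- c(v[2], m23, f123, m12, m24, f234, cc, f124)
    hexes[(t1 - 1L) * 4L + 3L, ] <- c(v[3], m13, f123, m23, m34, f134, cc, f234)
    hexes[(t1 - 1L) * 4L + 4L, ] <- c(v[4], m14, f124, m24, m34, f134, cc, f234)
  }
  # boundary quads: 3 per boundary triangle
  bf <- mesh$boundary_faces
  quads <- matrix(0L, 3L * nrow(bf), 4L)
  qtags <- rep(mesh$boundary_tags, each = 3L)
  if (nrow(bf) > 0) for (k in seq_len(nrow(bf))) {
    v <- bf[k, ]
    mid <- function(a, b) reg$get((reg$p(a) + reg$p(b)) / 2)
    fc <- reg$get((reg$p(v[1]) + reg$p(v[2]) + reg$p(v[3])) / 3)
    m12 <- mid(v[1], v[2]); m23 <- mid(v[2], v[3]); m31 <- mid(v[3], v[1])
    quads[(k - 1L) * 3L + 1L, ] <- c(v[1], m12, fc, m31)
    quads[(k - 1L) * 3L + 2L, ] <- c(v[2], m23, fc, m12)
    quads[(k - 1L) * 3L + 3L, ] <- c(v[3], m31, fc, m23)
  }
  hm <- hex_mesh(reg$points(), hexes, cell_tags = htags,
                 boundary_quads = quads, boundary_tags = qtags)
  hm <- orient_hexes(hm)
  n_rbs <- as.integer(n_rbs)
  while (n_rbs > 0L) { hm <- rbs_refine(hm); n_rbs <- n_rbs - 1L }
  hm
}

# incremental point registry with exact-coordinate dedup
point_registry <- function(p0) {
  env <- new.env(hash = TRUE)
  pts <- p0
  for (i in seq_len(nrow(p0))) env[[paste(p0[i, ], collapse = "|")]] <- i
  list(
    p = function(i) pts[i, ],
    get = function(x) {
      key <- paste(x, collapse = "|")
      got <- env[[key]]
      if (!is.null(got)) return(got)
      pts <<- rbind(pts, x)
      env[[key]] <- nrow(pts)
      nrow(pts)
    },
    points = function() { rownames(pts) <- NULL; pts }
  )
}

#' Hexahedral meshes
#'
#' Nodes of each hex follow the usual convention: bottom quad
#' counter-clockwise seen from below (outside the cell), then the matching
#' top quad.
#'
#' @param points n x 3 coordinate matrix.
#' @param hexes m x 8 integer matrix.
#' @param cell_tags Integer per hex.
#' @param boundary_quads k x 4 integer matrix.
#' @param boundary_tags Integer per quad.
#' @return An object of class `hex_mesh`.
#' @export
hex_mesh <- function(points, hexes, cell_tags = NULL, boundary_quads = NULL,
                     boundary_tags = NULL) {
  points <- as_point_matrix(points)
  hexes <- as.matrix(hexes); storage.mode(hexes) <- "integer"; dimnames(hexes) <- NULL
  structure(list(points = points, hexes = hexes,
                 cell_tags = as.integer(cell_tags %||% integer(nrow(hexes))),
                 boundary_quads = if (is.null(boundary_quads)) matrix(0L, 0, 4) else {
                   storage.mode(boundary_quads) <- "integer"; boundary_quads },
                 boundary_tags = as.integer(boundary_tags %||% integer(NROW(boundary_quads)))),
            class = "hex_mesh")
}

#' @export
print.hex_mesh <- function(x, ...) {
  cat(sprintf("hex_mesh: %d points, %d hexes (vol %.6g), %d boundary quads\n",
              nrow(x$points), nrow(x$hexes), sum(hex_volumes(x)),
              nrow(x$boundary_quads)))
  invisible(x)
}

#' Hex volumes (exact, via tet decomposition around the cell centroid)
#' @param m A [hex_mesh()].
#' @return Numeric vector of volumes.
#' @export
hex_volumes <- function(m) {
  p <- m$points; hx <- m$hexes
  # decompose each hex into 24 tets: face-triangle + hex centroid, over the
  # 6 quad faces split at their own centroids -> exact for bilinear faces
  faces <- hex_face_corners()
  ctr <- (p[hx[, 1], , drop = FALSE] + p[hx[, 2], , drop = FALSE] + p[hx[, 3], , drop = FALSE] +
            p[hx[, 4], , drop = FALSE] + p[hx[, 5], , drop = FALSE] + p[hx[, 6], , drop = FALSE] +
            p[hx[, 7], , drop = FALSE] + p[hx[, 8], , drop = FALSE]) / 8
  vol <- numeric(nrow(hx))
  for (f in seq_len(6)) {
    q <- faces[f, ]
    a <- p[hx[, q[1]], , drop = FALSE]; b <- p[hx[, q[2]], , drop = FALSE]
    c <- p[hx[, q[3]], , drop = FALSE]; d <- p[hx[, q[4]], , drop = FALSE]
    fctr <- (a + b + c + d) / 4
    for (e in list(list(a, b), list(b, c), list(c, d), list(d, a))) {
      u <- e[[1]] - ctr; v <- e[[2]] - ctr; w <- fctr - ctr
      vol <- vol + rowSums(row_cross(u, v) * w) / 6
    }
  }
  vol
}

# outward-wound quad faces of the reference hex (1-4 bottom, 5-8 top)
hex_face_corners <- function() {
  rbind(c(1, 4, 3, 2),  # bottom (outward = down)
        c(5, 6, 7, 8),  # top
        c(1, 2, 6, 5),
        c(2, 3, 7, 6),
        c(3, 4, 8, 7),
        c(4, 1, 5, 8))
}

#' Corner Jacobians of every hex
#'
#' Determinant of the three edge vectors leaving each of the 8 corners,
#' signed with the corner parity; all positive for a valid hex.
#' @param m A [hex_mesh()].
#' @return m x 8 matrix of corner Jacobians.
#' @export
hex_corner_jacobians <- function(m) {
  p <- m$points; hx <- m$hexes
  # adjacent corners ordered as a right-handed triple at every corner
  nb <- rbind(c(2, 4, 5), c(3, 1, 6), c(4, 2, 7), c(1, 3, 8),
              c(8, 6, 1), c(5, 7, 2), c(6, 8, 3), c(7, 5, 4))
  out <- matrix(0, nrow(hx), 8)
  for (k in 1:8) {
    a <- p[hx[, nb[k, 1]], , drop = FALSE] - p[hx[, k], , drop = FALSE]
    b <- p[hx[, nb[k, 2]], , drop = FALSE] - p[hx[, k], , drop = FALSE]
    c <- p[hx[, nb[k, 3]], , drop = FALSE] - p[hx[, k], , drop = FALSE]
    out[, k] <- rowSums(row_cross(a, b) * c)
  }
  out
}

orient_hexes <- function(m) {
  bad <- hex_volumes(m) < 0
  if (any(bad)) m$hexes[bad, ] <- m$hexes[bad, c(5:8, 1:4), drop = FALSE]
  m
}

# one refine-by-splitting sweep: hex -> 8 hexes, quad -> 4 quads
rbs_refine <- function(m) {
  reg <- point_registry(m$points)
  hx <- m$hexes
  out <- matrix(0L, nrow(hx) * 8L, 8L)
  tags <- rep(m$cell_tags, each = 8L)
  for (t1 in seq_len(nrow(hx))) {
    v <- hx[t1, ]
    g <- function(...) {
      ii <- c(...)
      reg$get(colMeans(do.call(rbind, lapply(ii, reg$p))))
    }
    # lattice of 27 points indexed by (i,j,k) in {0,1,2}
    corner <- array(0L, c(3, 3, 3))
    cidx <- rbind(c(1, 1, 1), c(3, 1, 1), c(3, 3, 1), c(1, 3, 1),
                  c(1, 1, 3), c(3, 1, 3), c(3, 3, 3), c(1, 3, 3))
    for (k in 1:8) corner[cidx[k, 1], cidx[k, 2], cidx[k, 3]] <- v[k]
    # fill midpoints by averaging the bilinear/trilinear corner set
    for (i in 1:3) for (j in 1:3) for (k in 1:3) {
      if (corner[i, j, k] != 0L) next
      lo <- function(x) if (x == 2) c(1, 3) else x
      ii <- lo(i); jj <- lo(j); kk <- lo(k)
      combo <- expand.grid(ii, jj, kk)
      ids <- apply(combo, 1, function(r) corner[r[1], r[2], r[3]])
      corner[i, j, k] <- g(ids)
    }
    sub <- 0L
    for (k in 1:2) for (j in 1:2) for (i in 1:2) {
      sub <- sub + 1L
      out[(t1 - 1L) * 8L + sub, ] <- c(corner[i, j, k], corner[i + 1, j, k],
                                       corner[i + 1, j + 1, k], corner[i, j + 1, k],
                                       corner[i, j, k + 1], corner[i + 1, j, k + 1],
                                       corner[i + 1, j + 1, k + 1], corner[i, j + 1, k + 1])
    }
  }
  qd <- m$boundary_quads
  qout <- matrix(0L, nrow(qd) * 4L, 4L)
  qtags <- rep(m$boundary_tags, each = 4L)
  if (nrow(qd) > 0) for (t1 in seq_len(nrow(qd))) {
    v <- qd[t1, ]
    g2 <- function(...) { ii <- c(...); reg$get(colMeans(do.call(rbind, lapply(ii, reg$p)))) }
    m12 <- g2(v[1], v[2]); m23 <- g2(v[2], v[3]); m34 <- g2(v[3], v[4]); m41 <- g2(v[4], v[1])
    cc <- g2(v[1], v[2], v[3], v[4])
    qout[(t1 - 1L) * 4L + 1L, ] <- c(v[1], m12, cc, m41)
    qout[(t1 - 1L) * 4L + 2L, ] <- c(v[2], m23, cc, m12)
    qout[(t1 - 1L) * 4L + 3L, ] <- c(v[3], m34, cc, m23)
    qout[(t1 - 1L) * 4L + 4L, ] <- c(v[4], m41, cc, m34)
  }
  hm <- hex_mesh(reg$points(), out, cell_tags = tags,
                 boundary_quads = qout, boundary_tags = qtags)
  orient_hexes(hm)
}
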