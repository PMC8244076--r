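#' Distance from points to a triangulated surface
#'
#' Exact euclidean distance from each query point to the reference
#' triangulation (faces, edges and vertices, not vertices only).  When
#' `signed = TRUE` the sign is resolved with the angle-weighted
#' pseudonormal at the closest feature: negative inside the closed
#' reference, positive outside.  Signed queries require a closed reference
#' with outward normals -- the sign is not robustly defined for open
#' surfaces.
#'
#' @param query k x 3 matrix of query points (or a [tri_surface()], whose
#'   points are used).
#' @param reference A [tri_surface()].
#' @param signed Return signed distance.
#' @param vector Also return the displacement toward the closest point.
#' @return Numeric vector of distances, or (if `vector`) a list with
#'   `distance` and the k x 3 `vector` of closest-point displacements.
#' @export
surface_distance <- function(query, reference, signed = FALSE, vector = FALSE) {
  if (inherits(query, "tri_surface")) query <- query$points
  query <- as_point_matrix(query)
  if (signed && !is_closed(reference))
    stop("signed distance requires a closed reference surface", call. = FALSE)
  res <- cpp_closest_point(query, reference$points, reference$triangles)
  d <- res$distance
  if (signed) {
    pn <- feature_pseudonormals(reference, res$triangle, res$bary)
    disp <- query - res$closest
    s <- sign(rowSums(disp * pn))
    s[s == 0] <- 1
    d <- d * s
  }
  if (vector) list(distance = d, vector = res$closest - query) else d
}

# Angle-weighted pseudonormal at the closest feature of each query result:
# face normal inside a face, sum of the two face normals on an edge, and
# the angle-weighted vertex normal at a vertex.
feature_pseudonormals <- function(s, tri_idx, bary, tol = 1e-9) {
  fn <- triangle_normals(s)
  vn_needed <- NULL
  out <- matrix(0, length(tri_idx), 3)
  on_vertex <- rowSums(bary > tol) == 1L
  on_edge <- rowSums(bary > tol) == 2L
  on_face <- !on_vertex & !on_edge
  out[on_face, ] <- fn[tri_idx[on_face], , drop = FALSE]
  if (any(on_edge)) {
    ek <- surface_edges(s)
    # map undirected edge key -> sum of incident face normals
    fsum <- rowsum(fn[ek$cell, , drop = FALSE], ek$key)
    for (i in which(on_edge)) {
      v <- s$triangles[tri_idx[i], ]
      pair <- v[bary[i, ] > tol]
      out[i, ] <- fsum[edge_key(pair[1], pair[2]), ]
    }
  }
  if (any(on_vertex)) {
    vn <- point_normals(s)
    for (i in which(on_vertex)) {
      v <- s$triangles[tri_idx[i], ]
      out[i, ] <- vn[v[which.max(bary[i, ])], ]
    }
  }
  out
}

#' Distance from points to a boundary ring
#'
#' Distance to the closed polyline through the ring points (segments, not
#' samples).  The vector form returns the displacement to the closest point
#' on the polyline, which is the Dirichlet datum of the harmonic connection.
#'
#' @param query k x 3 matrix of query points.
#' @param ring A `ring` (indices into `ring_surface`) or a k0 x 3 matrix of
#'   ordered ring coordinates.
#' @param ring_surface Parent surface of `ring` (when `ring` is indices).
#' @param vector Return closest-point displacement vectors as well.
#' @return Numeric distances, or a list with `distance` and `vector`.
#' @export
ring_distance <- function(query, ring, ring_surface = NULL, vector = FALSE) {
  query <- as_point_matrix(query)
  rp <- if (is.matrix(ring)) ring else {
    if (is.null(ring_surface)) stop("ring_surface required with index rings", call. = FALSE)
    ring_surface$points[as.integer(ring), , drop = FALSE]
  }
  n <- nrow(rp)
  if (n < 1L) stop("empty ring", call. = FALSE)
  a <- rp
  b <- rp[c(2:n, 1L), , drop = FALSE]
  ab <- b - a
  len2 <- rowSums(ab * ab)
  len2[len2 == 0] <- 1
  best_d <- rep(Inf, nrow(query))
  best_cp <- matrix(0, nrow(query), 3)
  for (sgm in seq_len(n)) {
    ap <- sweep(query, 2, a[sgm, ], `-`)
    t1 <- pmin(1, pmax(0, (ap %*% ab[sgm, ]) / len2[sgm]))
    cp <- matrix(a[sgm, ], nrow(query), 3, byrow = TRUE) + as.vector(t1) %o% ab[sgm, ]
    d <- row_norms(query - cp)
    hit <- d < best_d
    best_d[hit] <- d[hit]
    best_cp[hit, ] <- cp[hit, , drop = FALSE]
  }
  if (vector) list(distance = best_d, vector = best_cp - query) else best_d
}

#' Attach a distance field to a surface
#'
#' Convenience wrapper computing [surface_distance()] (or [ring_distance()])
#' at the points of `s` and storing it as a named point field.
#'
#' @param s A [tri_surface()].
#' @param reference A [tri_surface()] or ring coordinate matrix.
#' @param name Point-field name.
#' @param signed Signed distance (surface references only).
#' @return `s` with the new point field.
#' @export
add_distance_field <- function(s, reference, name = "distance", signed = FALSE) {
  d <- if (inherits(reference, "tri_surface"))
    surface_distance(s$points, reference, signed = signed)
  else ring_distance(s$points, reference)
  s$point_data[[name]] <- d
  s
}
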