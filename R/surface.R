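#' Triangulated surface meshes
#'
#' A `tri_surface` is the central container of the package: a triangulated
#' 2-manifold with an integer tag per triangle and arbitrary named scalar or
#' vector fields attached to points or cells.  Closed surfaces are stored
#' with counter-clockwise winding seen from outside, so right-hand-rule
#' normals point outward.
#'
#' @param points n x 3 numeric matrix of vertex coordinates (mm).
#' @param triangles m x 3 integer matrix of 1-based vertex indices.
#' @param cell_tags integer vector of length m (default all 0).
#' @param point_data named list of per-point fields (length-n vectors or
#'   n x k matrices).
#' @param cell_data named list of per-cell fields.
#' @param tag_names optional named character vector mapping tag integers to
#'   human-readable labels.
#' @return An object of class `tri_surface`.
#' @export
tri_surface <- function(points, triangles, cell_tags = NULL,
                        point_data = list(), cell_data = list(),
                        tag_names = NULL) {
  points <- as_point_matrix(points)
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  dimnames(triangles) <- NULL
  if (ncol(triangles) != 3L) stop("triangles must be an m x 3 matrix", call. = FALSE)
  m <- nrow(triangles)
  if (is.null(cell_tags)) cell_tags <- integer(m)
  cell_tags <- as.integer(cell_tags)
  if (length(cell_tags) != m) stop("cell_tags length must match triangle count", call. = FALSE)
  s <- structure(list(points = points, triangles = triangles,
                      cell_tags = cell_tags, point_data = point_data,
                      cell_data = cell_data, tag_names = tag_names),
                 class = "tri_surface")
  s
}

#' @export
print.tri_surface <- function(x, ...) {
  nb <- tryCatch(length(boundary_ring_list(x)), error = function(e) NA_integer_)
  cat(sprintf("tri_surface: %d points, %d triangles, tags {%s}, %s boundary ring(s)\n",
              nrow(x$points), nrow(x$triangles),
              paste(sort(unique(x$cell_tags)), collapse = ","),
              ifelse(is.na(nb), "?", nb)))
  if (length(x$point_data)) cat("  point fields:", paste(names(x$point_data), collapse = ", "), "\n")
  if (length(x$cell_data)) cat("  cell fields:", paste(names(x$cell_data), collapse = ", "), "\n")
  invisible(x)
}

n_points <- function(s) nrow(s$points)
n_cells <- function(s) nrow(s$triangles)

#' Validate a triangulated surface
#'
#' Checks index ranges, triangle areas, and edge-manifoldness (every edge
#' shared by at most two triangles).  For closed surfaces it additionally
#' checks that the total signed volume is positive, i.e. that the winding
#' convention gives outward normals.
#'
#' @param s A [tri_surface()].
#' @param check_orientation Also require consistent neighbour winding.
#' @return Invisibly `TRUE`; errors describe the first violation found.
#' @export
validate_surface <- function(s, check_orientation = TRUE) {
  stopifnot(inherits(s, "tri_surface"))
  tr <- s$triangles
  if (nrow(tr) == 0L) return(invisible(TRUE))
  if (min(tr) < 1L || max(tr) > n_points(s))
    stop("triangle indices out of range", call. = FALSE)
  a <- triangle_areas(s)
  if (any(a <= 0)) stop(sprintf("degenerate triangle (zero area): cell %d",
                                which(a <= 0)[1]), call. = FALSE)
  ek <- surface_edges(s)
  cnt <- table(ek$key)
  if (any(cnt > 2L)) {
    bad <- names(cnt)[cnt > 2L][1]
    stop(sprintf("non-manifold edge %s shared by %d triangles", bad, max(cnt)), call. = FALSE)
  }
  if (check_orientation) {
    # each undirected edge of an interior pair must appear once per direction
    dk <- paste(ek$i, ek$j, sep = ">")
    if (anyDuplicated(dk))
      stop("inconsistent triangle winding (directed edge repeated)", call. = FALSE)
  }
  invisible(TRUE)
}

# All directed edges (i -> j) of the triangulation with undirected keys.
surface_edges <- function(s) {
  tr <- s$triangles
  i <- c(tr[, 1], tr[, 2], tr[, 3])
  j <- c(tr[, 2], tr[, 3], tr[, 1])
  list(i = i, j = j, key = edge_key(i, j),
       cell = rep.int(seq_len(nrow(tr)), 3L))
}

#' Per-triangle areas
#' @param s A [tri_surface()].
#' @return Numeric vector of areas (mm^2).
#' @export
triangle_areas <- function(s) {
  p <- s$points; tr <- s$triangles
  0.5 * row_norms(row_cross(p[tr[, 2], , drop = FALSE] - p[tr[, 1], , drop = FALSE],
                            p[tr[, 3], , drop = FALSE] - p[tr[, 1], , drop = FALSE]))
}

#' Per-triangle unit normals
#' @param s A [tri_surface()].
#' @return m x 3 matrix of unit normals following the winding convention.
#' @export
triangle_normals <- function(s) {
  p <- s$points; tr <- s$triangles
  normalize_rows(row_cross(p[tr[, 2], , drop = FALSE] - p[tr[, 1], , drop = FALSE],
                           p[tr[, 3], , drop = FALSE] - p[tr[, 1], , drop = FALSE]))
}

#' Angle-weighted outward point normals
#'
#' Vertex normals computed as the sum of incident face normals weighted by
#' the face angle at the vertex; this is the standard pseudonormal used both
#' for signed distances and for thickening deformations.
#'
#' @param s A [tri_surface()].
#' @return n x 3 matrix of unit vertex normals.
#' @export
point_normals <- function(s) {
  p <- s$points; tr <- s$triangles
  fn <- triangle_normals(s)
  out <- matrix(0, n_points(s), 3)
  for (k in 1:3) {
    a <- tr[, k]; b <- tr[, k %% 3L + 1L]; c <- tr[, (k + 1L) %% 3L + 1L]
    u <- normalize_rows(p[b, , drop = FALSE] - p[a, , drop = FALSE])
    v <- normalize_rows(p[c, , drop = FALSE] - p[a, , drop = FALSE])
    ang <- acos(pmin(1, pmax(-1, rowSums(u * v))))
    w <- fn * ang
    for (d in 1:3) out[, d] <- out[, d] + unname(tapply(w[, d], factor(a, levels = seq_len(n_points(s))), sum, default = 0))
  }
  out[is.na(out)] <- 0
  normalize_rows(out)
}

#' Signed enclosed volume of a closed surface
#'
#' Divergence-theorem volume; positive for a closed surface with outward
#' normals.
#' @param s A [tri_surface()].
#' @return Scalar volume (mm^3).
#' @export
surface_volume <- function(s) {
  p <- s$points; tr <- s$triangles
  a <- p[tr[, 1], , drop = FALSE]; b <- p[tr[, 2], , drop = FALSE]; c <- p[tr[, 3], , drop = FALSE]
  sum(rowSums(a * row_cross(b, c))) / 6
}

#' Euler characteristic V - E + F
#' @param s A [tri_surface()].
#' @return Integer Euler characteristic.
#' @export
euler_characteristic <- function(s) {
  ek <- surface_edges(s)
  n_points_used <- length(unique(as.vector(s$triangles)))
  n_points_used - length(unique(ek$key)) + n_cells(s)
}

# Boundary edges: undirected edges with exactly one incident triangle.
boundary_edge_table <- function(s) {
  ek <- surface_edges(s)
  cnt <- table(ek$key)
  single <- names(cnt)[cnt == 1L]
  keep <- ek$key %in% single
  data.frame(i = ek$i[keep], j = ek$j[keep], cell = ek$cell[keep])
}

#' Boundary rings of an open surface
#'
#' Extracts every closed loop of boundary edges (edges with exactly one
#' incident triangle).  Each ring is ordered in the direction induced by the
#' triangle winding, i.e. walking the ring keeps the surface on the left,
#' and starts at its lowest point index for determinism.
#'
#' @param s A [tri_surface()].
#' @return A list of `ring` objects (integer index vectors); empty for
#'   closed surfaces.
#' @export
extract_boundary_rings <- function(s) {
  validate_surface(s, check_orientation = FALSE)
  be <- boundary_edge_table(s)
  if (nrow(be) == 0L) return(list())
  # boundary edges are directed as they appear in their unique triangle;
  # following successor pointers i -> j yields winding-consistent loops.
  nxt <- integer(0)
  if (anyDuplicated(be$i)) stop("non-manifold boundary vertex", call. = FALSE)
  nxt <- structure(be$j, names = as.character(be$i))
  visited <- structure(logical(nrow(be)), names = as.character(be$i))
  rings <- list()
  for (start in sort(be$i)) {
    key <- as.character(start)
    if (visited[[key]]) next
    loop <- integer(0)
    cur <- start
    repeat {
      ck <- as.character(cur)
      if (is.na(nxt[ck])) stop("open boundary chain: surface is not manifold", call. = FALSE)
      visited[[ck]] <- TRUE
      loop <- c(loop, cur)
      cur <- unname(nxt[[ck]])
      if (cur == start) break
      if (length(loop) > nrow(be)) stop("boundary walk failed to close", call. = FALSE)
    }
    # rotate so the lowest index comes first
    k <- which.min(loop)
    if (k > 1L) loop <- c(loop[k:length(loop)], loop[seq_len(k - 1L)])
    rings[[length(rings) + 1L]] <- new_ring(loop)
  }
  rings
}

# internal alias used by print
boundary_ring_list <- extract_boundary_rings

new_ring <- function(idx) structure(as.integer(idx), class = "ring")

#' @export
print.ring <- function(x, ...) {
  cat(sprintf("ring: %d points (%s...)\n", length(x),
              paste(utils::head(unclass(x), 5), collapse = ",")))
  invisible(x)
}

#' Edge-connected components of a surface
#'
#' @param s A [tri_surface()].
#' @param indices If `TRUE` return, for each component, the cell indices
#'   instead of sub-surfaces.
#' @return List of [tri_surface()] objects (or integer cell-index vectors),
#'   ordered by their lowest contained cell index.
#' @export
connected_components <- function(s, indices = FALSE) {
  m <- n_cells(s)
  if (m == 0L) return(list())
  ek <- surface_edges(s)
  sp <- split(ek$cell, ek$key)
  pairs <- sp[lengths(sp) == 2L]
  comp <- seq_len(m)
  # union-find with path compression
  find <- function(x) { while (comp[x] != x) { comp[x] <<- comp[comp[x]]; x <- comp[x] }; x }
  for (pr in pairs) {
    a <- find(pr[1]); b <- find(pr[2])
    if (a != b) comp[max(a, b)] <- min(a, b)
  }
  roots <- vapply(seq_len(m), find, integer(1))
  groups <- split(seq_len(m), roots)
  groups <- groups[order(vapply(groups, min, integer(1)))]
  names(groups) <- NULL
  if (indices) return(groups)
  lapply(groups, function(cells) subset_cells(s, cells))
}

#' Extract a sub-surface by cell indices
#'
#' Points are re-indexed compactly; point and cell fields and tags follow.
#' @param s A [tri_surface()].
#' @param cells Integer cell indices to keep.
#' @return A [tri_surface()].
#' @export
subset_cells <- function(s, cells) {
  cells <- as.integer(cells)
  tr <- s$triangles[cells, , drop = FALSE]
  used <- sort(unique(as.vector(tr)))
  remap <- integer(n_points(s)); remap[used] <- seq_along(used)
  tri_surface(s$points[used, , drop = FALSE],
              matrix(remap[tr], ncol = 3),
              cell_tags = s$cell_tags[cells],
              point_data = lapply(s$point_data, function(f)
                if (is.matrix(f)) f[used, , drop = FALSE] else f[used]),
              cell_data = lapply(s$cell_data, function(f)
                if (is.matrix(f)) f[cells, , drop = FALSE] else f[cells]),
              tag_names = s$tag_names)
}

#' Merge surfaces, unifying duplicate points
#'
#' Concatenates the parts and merges points closer than `tol`; tags and
#' fields are preserved.  The default tolerance is 1e-9 times the joint
#' bounding-box diagonal.
#'
#' @param parts List of [tri_surface()] objects.
#' @param tol Length below which two points are considered identical (mm).
#' @return A single [tri_surface()].
#' @export
merge_surfaces <- function(parts, tol = NULL) {
  stopifnot(length(parts) >= 1L)
  pts <- do.call(rbind, lapply(parts, function(p) p$points))
  offs <- cumsum(c(0L, vapply(parts, n_points, integer(1))))
  tr <- do.call(rbind, Map(function(p, o) p$triangles + o, parts, offs[seq_along(parts)]))
  tags <- unlist(lapply(parts, function(p) p$cell_tags), use.names = FALSE)
  pd_names <- unique(unlist(lapply(parts, function(p) names(p$point_data))))
  point_data <- list()
  for (nm in pd_names) {
    cols <- lapply(parts, function(p) {
      f <- p$point_data[[nm]]
      if (is.null(f)) {
        k <- if (is.matrix(parts[[which(!vapply(parts, function(q) is.null(q$point_data[[nm]]), logical(1)))[1]]]$point_data[[nm]]))
          ncol(parts[[which(!vapply(parts, function(q) is.null(q$point_data[[nm]]), logical(1)))[1]]]$point_data[[nm]]) else 1L
        f <- matrix(0, n_points(p), k)
      }
      if (!is.matrix(f)) f <- matrix(f, ncol = 1)
      f
    })
    f <- do.call(rbind, cols)
    if (ncol(f) == 1L) f <- drop(f)
    point_data[[nm]] <- f
  }
  cd_names <- unique(unlist(lapply(parts, function(p) names(p$cell_data))))
  cell_data <- list()
  for (nm in cd_names) {
    cell_data[[nm]] <- unlist(lapply(parts, function(p)
      p$cell_data[[nm]] %||% rep(0, n_cells(p))), use.names = FALSE)
  }
  if (is.null(tol)) {
    rng <- apply(pts, 2, range)
    tol <- 1e-9 * sqrt(sum((rng[2, ] - rng[1, ])^2))
  }
  s <- tri_surface(pts, tr, tags, point_data, cell_data,
                   tag_names = do.call(c, lapply(parts, function(p) p$tag_names)))
  if (tol > 0) s <- dedupe_points(s, tol) else s
}

# Unify points closer than tol (grid hashing), drop unreferenced points.
dedupe_points <- function(s, tol) {
  p <- s$points
  if (tol <= 0) return(s)
  key <- paste(round(p[, 1] / tol), round(p[, 2] / tol), round(p[, 3] / tol))
  first <- !duplicated(key)
  # key[first] is ordered like the kept points, so the match position IS
  # the compact new index
  newidx <- match(key, key[first])
  keep <- which(first)
  tr <- matrix(newidx[s$triangles], ncol = 3)
  degen <- tr[, 1] == tr[, 2] | tr[, 2] == tr[, 3] | tr[, 1] == tr[, 3]
  tri_surface(p[keep, , drop = FALSE], tr[!degen, , drop = FALSE],
              cell_tags = s$cell_tags[!degen],
              point_data = lapply(s$point_data, function(f)
                if (is.matrix(f)) f[keep, , drop = FALSE] else f[keep]),
              cell_data = lapply(s$cell_data, function(f)
                if (is.matrix(f)) f[!degen, , drop = FALSE] else f[!degen]),
              tag_names = s$tag_names)
}

#' Warp a surface by a per-point displacement field
#'
#' @param s A [tri_surface()].
#' @param displacement n x 3 matrix, or the name of a vector point field.
#' @return The displaced [tri_surface()]; connectivity, tags and fields are
#'   unchanged.
#' @export
warp_surface <- function(s, displacement) {
  if (is.character(displacement)) {
    displacement <- s$point_data[[displacement]]
    if (is.null(displacement)) stop("displacement field not found", call. = FALSE)
  }
  displacement <- as.matrix(displacement)
  if (nrow(displacement) != n_points(s) || ncol(displacement) != 3L)
    stop("displacement must be defined at every point (n x 3)", call. = FALSE)
  s$points <- s$points + displacement
  s
}

#' Flip the orientation of a surface
#' @param s A [tri_surface()].
#' @return Surface with all triangle windings reversed.
#' @export
flip_orientation <- function(s) {
  s$triangles <- s$triangles[, c(1L, 3L, 2L), drop = FALSE]
  s
}

#' Is the surface closed (no boundary edges)?
#' @param s A [tri_surface()].
#' @return Logical.
#' @export
is_closed <- function(s) nrow(boundary_edge_table(s)) == 0L

# One-ring vertex adjacency as a list of integer vectors.
vertex_adjacency <- function(s) {
  ek <- surface_edges(s)
  und_first <- !duplicated(ek$key)
  i <- ek$i[und_first]; j <- ek$j[und_first]
  adj <- split(c(j, i), c(i, j))
  out <- vector("list", n_points(s))
  out[as.integer(names(adj))] <- lapply(adj, unique)
  out
}

#' Split a surface along a level set of a point field
#'
#' Cuts every triangle crossed by the iso-contour `f == sigma` by linear
#' interpolation along its edges, fan-triangulating the resulting polygons.
#' Both sides are kept; cells inherit tags, new points interpolate the point
#' fields linearly.  Used by the clip-array tagger and the boolean
#' connection.
#'
#' @param s A [tri_surface()].
#' @param f Numeric per-point field (or a point-field name).
#' @param sigma Level at which to cut.
#' @return A [tri_surface()] whose `cell_data$side` is -1 for cells with
#'   `f <= sigma` and +1 otherwise; the field `f` (named `"clip_field"` in
#'   `point_data` if `f` was given as values) is carried along.
#' @export
split_at_level <- function(s, f, sigma) {
  fname <- NULL
  if (is.character(f)) { fname <- f; f <- s$point_data[[f]]
    if (is.null(f)) stop("field not found", call. = FALSE) }
  f <- as.numeric(f)
  stopifnot(length(f) == n_points(s))
  p <- s$points; tr <- s$triangles
  frange <- max(f) - min(f)
  tol <- 1e-12 * max(frange, abs(sigma), 1e-300)
  on_level <- abs(f - sigma) <= tol
  strictly_below <- f < sigma - tol
  strictly_above <- f > sigma + tol
  pd <- s$point_data
  if (!is.null(fname)) pd[[fname]] <- f else pd[["clip_field"]] <- f

  # new point per edge with a strict sign change
  ek_i <- c(tr[, 1], tr[, 2], tr[, 3]); ek_j <- c(tr[, 2], tr[, 3], tr[, 1])
  crossed <- (strictly_below[ek_i] & strictly_above[ek_j]) |
    (strictly_above[ek_i] & strictly_below[ek_j])
  keys <- edge_key(ek_i, ek_j)[crossed]
  uk <- unique(keys)
  es <- if (length(uk)) do.call(rbind, strsplit(uk, "-", fixed = TRUE)) else matrix(0L, 0, 2)
  ei <- as.integer(es[, 1]); ej <- as.integer(es[, 2])
  t_par <- (sigma - f[ei]) / (f[ej] - f[ei])
  t_par <- pmin(1, pmax(0, t_par))
  newp <- p[ei, , drop = FALSE] + (p[ej, , drop = FALSE] - p[ei, , drop = FALSE]) * t_par
  new_idx <- n_points(s) + seq_along(uk)
  names(new_idx) <- uk

  interp_field <- function(fld) {
    if (is.matrix(fld)) {
      rbind(fld, fld[ei, , drop = FALSE] + (fld[ej, , drop = FALSE] - fld[ei, , drop = FALSE]) * t_par)
    } else c(fld, fld[ei] + (fld[ej] - fld[ei]) * t_par)
  }
  pd2 <- lapply(pd, interp_field)
  # force the clip field to be exactly sigma at new points
  cf <- if (!is.null(fname)) fname else "clip_field"
  if (length(new_idx)) pd2[[cf]][new_idx] <- sigma
  allp <- rbind(p, newp)

  out_tr <- vector("list", nrow(tr)); out_tag <- vector("list", nrow(tr))
  out_side <- vector("list", nrow(tr))
  cd_keep <- vector("list", nrow(tr))
  for (c1 in seq_len(nrow(tr))) {
    v <- tr[c1, ]
    ks <- edge_key(v, v[c(2, 3, 1)])
    cut <- !is.na(match(ks, uk))
    if (!any(cut)) {
      out_tr[[c1]] <- matrix(v, ncol = 3)
      side <- if (any(strictly_above[v])) 1 else -1
      out_side[[c1]] <- side
      out_tag[[c1]] <- s$cell_tags[c1]
      cd_keep[[c1]] <- c1
      next
    }
    # walk the triangle boundary inserting crossing points -> two polygons;
    # vertices lying on the level set belong to both sides
    polyA <- integer(0); polyB <- integer(0)  # A: below side, B: above
    for (k in 1:3) {
      a <- v[k]
      if (on_level[a]) { polyA <- c(polyA, a); polyB <- c(polyB, a) }
      else if (strictly_below[a]) polyA <- c(polyA, a)
      else polyB <- c(polyB, a)
      if (cut[k]) {
        np <- new_idx[[ks[k]]]
        polyA <- c(polyA, np); polyB <- c(polyB, np)
      }
    }
    fan <- function(poly) {
      if (length(poly) < 3L) return(NULL)
      cbind(poly[1], poly[2:(length(poly) - 1L)], poly[3:length(poly)])
    }
    ta <- fan(polyA); tb <- fan(polyB)
    out_tr[[c1]] <- rbind(ta, tb)
    out_side[[c1]] <- c(rep(-1, NROW(ta)), rep(1, NROW(tb)))
    out_tag[[c1]] <- rep(s$cell_tags[c1], NROW(ta) + NROW(tb))
    cd_keep[[c1]] <- rep(c1, NROW(ta) + NROW(tb))
  }
  tr2 <- do.call(rbind, out_tr)
  keep_map <- unlist(cd_keep)
  res <- tri_surface(allp, tr2,
                     cell_tags = unlist(out_tag),
                     point_data = pd2,
                     cell_data = c(lapply(s$cell_data, function(fld)
                       if (is.matrix(fld)) fld[keep_map, , drop = FALSE] else fld[keep_map]),
                       list(side = unlist(out_side))),
                     tag_names = s$tag_names)
  drop_unused_points(res)
}

drop_unused_points <- function(s) {
  used <- sort(unique(as.vector(s$triangles)))
  if (length(used) == n_points(s)) return(s)
  remap <- integer(n_points(s)); remap[used] <- seq_along(used)
  s$points <- s$points[used, , drop = FALSE]
  s$point_data <- lapply(s$point_data, function(f)
    if (is.matrix(f)) f[used, , drop = FALSE] else f[used])
  s$triangles <- matrix(remap[s$triangles], ncol = 3)
  s
}

#' Keep one side of a level-set split
#'
#' Convenience wrapper around [split_at_level()] that returns only the cells
#' on the requested side of the `f == sigma` contour.
#'
#' @inheritParams split_at_level
#' @param keep `"below"` (`f <= sigma`) or `"above"`.
#' @return A [tri_surface()].
#' @export
clip_at_level <- function(s, f, sigma, keep = c("below", "above")) {
  keep <- match.arg(keep)
  sp <- split_at_level(s, f, sigma)
  side <- sp$cell_data$side
  sp$cell_data$side <- NULL
  subset_cells(sp, which(if (keep == "below") side < 0 else side > 0))
}
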