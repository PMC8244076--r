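#' Array-driven surface tagging
#'
#' Assigns a new integer tag to the cells of a surface using a scalar
#' point field `f` and a cut-off `sigma`, with three flavours:
#'
#' * `tag_simple()` keeps the triangulation and tags cells whose barycenter
#'   value satisfies `f <= sigma` (the inter-tag ring zig-zags through the
#'   existing edges);
#' * `tag_clip()` splits the triangles exactly at the `f == sigma` level
#'   set, producing precise tags but distorted triangles;
#' * `tag_harmonic()` moves the zig-zag ring points onto the exact level
#'   set and blends the movement harmonically inside a buffer of radius
#'   `rho`, preserving the connectivity.
#'
#' Cells whose current tag is in `excluded_tags` are never modified.
#'
#' @param s A [tri_surface()].
#' @param field Name of a scalar point field of `s`.
#' @param sigma Cut-off value.
#' @param new_tag Integer tag for the `f <= sigma` side.
#' @param invert Tag the `f >= sigma` side instead.
#' @param excluded_tags Integer tags to leave untouched.
#' @return The tagged [tri_surface()].
#' @export
tag_simple <- function(s, field, sigma, new_tag, invert = FALSE,
                       excluded_tags = integer(0)) {
  f <- s$point_data[[field]]
  if (is.null(f)) stop(sprintf("point field '%s' not found", field), call. = FALSE)
  fb <- cell_barycenter_values(s, as.numeric(f))
  sel <- if (invert) fb >= sigma else fb <= sigma
  sel <- sel & !(s$cell_tags %in% excluded_tags)
  s$cell_tags[sel] <- as.integer(new_tag)
  s
}

#' @rdname tag_simple
#' @export
tag_clip <- function(s, field, sigma, new_tag, invert = FALSE,
                     excluded_tags = integer(0)) {
  f <- s$point_data[[field]]
  if (is.null(f)) stop(sprintf("point field '%s' not found", field), call. = FALSE)
  f <- as.numeric(f)
  if (sigma < min(f) || sigma > max(f)) {
    warning("sigma outside field range; reduces to tag_simple", call. = FALSE)
    return(tag_simple(s, field, sigma, new_tag, invert, excluded_tags))
  }
  if (length(excluded_tags)) {
    keep <- which(s$cell_tags %in% excluded_tags)
    work <- which(!(s$cell_tags %in% excluded_tags))
    sub <- subset_cells(s, work)
    sub <- tag_clip(sub, field, sigma, new_tag, invert)
    frozen <- subset_cells(s, keep)
    return(merge_surfaces(list(frozen, sub)))
  }
  sp <- split_at_level(s, field, sigma)
  side <- sp$cell_data$side
  sp$cell_data$side <- NULL
  sel <- if (invert) side > 0 else side < 0
  sp$cell_tags[sel] <- as.integer(new_tag)
  sp
}

#' @param rho Buffer radius (mm) of the harmonic blend; default 5 times the
#'   mean edge length.
#' @param distance_like Treat `field` as an unsigned distance and update it
#'   after the warp as `f + |phi|`; otherwise supply `recompute`.
#' @param recompute Function `(surface) -> numeric` recomputing the field
#'   on the warped surface; required for non-distance fields.
#' @rdname tag_simple
#' @export
tag_harmonic <- function(s, field, sigma, new_tag, rho = NULL, invert = FALSE,
                         excluded_tags = integer(0), distance_like = TRUE,
                         recompute = NULL) {
  f0 <- s$point_data[[field]]
  if (is.null(f0)) stop(sprintf("point field '%s' not found", field), call. = FALSE)
  f0 <- as.numeric(f0)
  if (is.null(rho)) rho <- 5 * mean_edge_length(s)
  # 1-2. clip oracle ring and zig-zag ring of the simple tagger
  gamma_clip <- level_ring_points(s, f0, sigma)
  fb <- cell_barycenter_values(s, f0)
  below_cell <- fb <= sigma
  zig <- zigzag_rings(s, below_cell)
  if (length(zig) == 0L) {
    # level set misses the surface: nothing to move
    return(tag_simple(s, field, sigma, new_tag, invert, excluded_tags))
  }
  phi <- matrix(0, n_points(s), 3)
  moved <- logical(n_points(s))
  dir_idx <- integer(0); dir_val <- NULL
  for (ring in zig) {
    pruned <- prune_zigzag(s, ring)
    dv <- ring_distance(s$points[pruned, , drop = FALSE], gamma_clip, vector = TRUE)$vector
    dir_idx <- c(dir_idx, pruned)
    dir_val <- rbind(dir_val, dv)
    moved[pruned] <- TRUE
  }
  # buffer: points with distance from the (pruned) zig-zag ring <= rho
  zz_pts <- s$points[dir_idx, , drop = FALSE]
  d0 <- ring_distance(s$points, zz_pts)
  outside <- which(d0 > rho & !moved)
  dir_idx2 <- c(dir_idx, outside)
  dir_val2 <- rbind(dir_val, matrix(0, length(outside), 3))
  phi <- solve_harmonic(s, dir_idx2, dir_val2)
  out <- warp_surface(s, phi)
  if (any(triangle_areas(out) <= 1e-14 * max(triangle_areas(s))))
    stop("triangle inverted/collapsed by the harmonic warp; increase rho", call. = FALSE)
  amag <- row_norms(phi)
  if (!is.null(recompute)) {
    out$point_data[[field]] <- recompute(out)
  } else if (distance_like) {
    # unsigned-distance shortcut: the moved points travelled |phi|
    out$point_data[[field]] <- f0 + amag
  } else {
    stop("field is not distance-like and no recompute hook was given", call. = FALSE)
  }
  tag_simple(out, field, sigma, new_tag, invert, excluded_tags)
}

mean_edge_length <- function(s) {
  ek <- surface_edges(s)
  first <- !duplicated(ek$key)
  mean(row_norms(s$points[ek$i[first], , drop = FALSE] - s$points[ek$j[first], , drop = FALSE]))
}

# ordered coordinates of the f == sigma level ring (clip oracle)
level_ring_points <- function(s, f, sigma) {
  s2 <- s; s2$point_data$..lvl <- f
  cut <- split_at_level(s2, "..lvl", sigma)
  side <- cut$cell_data$side
  below <- subset_cells(cut, which(side < 0))
  rings <- extract_boundary_rings(below)
  # keep only rings on the level set (boundary rings of the original
  # surface also appear); level-ring points satisfy f == sigma
  fcut <- below$point_data$..lvl
  lvl <- Filter(function(r) all(abs(fcut[r] - sigma) <= 1e-9 * (max(f) - min(f) + 1e-300)), rings)
  if (length(lvl) == 0L) stop("level set does not intersect the surface", call. = FALSE)
  do.call(rbind, lapply(lvl, function(r) below$points[r, , drop = FALSE]))
}

# boundary rings between below/above cell regions of the simple tagger,
# as ordered point-index loops on the original surface
zigzag_rings <- function(s, below_cell) {
  if (!any(below_cell) || all(below_cell)) return(list())
  sub <- which(below_cell)
  tr <- s$triangles[sub, , drop = FALSE]
  # boundary edges of the below region that are interior edges of s
  ek_i <- c(tr[, 1], tr[, 2], tr[, 3]); ek_j <- c(tr[, 2], tr[, 3], tr[, 1])
  keys <- edge_key(ek_i, ek_j)
  cnt <- table(keys)
  single <- keys %in% names(cnt)[cnt == 1L]
  # drop edges that are boundary of the full surface
  be <- boundary_edge_table(s)
  bkeys <- edge_key(be$i, be$j)
  keep <- single & !(keys %in% bkeys)
  i <- ek_i[keep]; j <- ek_j[keep]
  if (length(i) == 0L) return(list())
  nxt <- structure(j, names = as.character(i))
  rings <- list(); visited <- character(0)
  for (start in sort(unique(i))) {
    if (as.character(start) %in% visited) next
    loop <- integer(0); cur <- start; ok <- TRUE
    repeat {
      ck <- as.character(cur)
      if (is.na(nxt[ck])) { ok <- FALSE; break }
      visited <- c(visited, ck)
      loop <- c(loop, cur)
      cur <- unname(nxt[[ck]])
      if (cur == start) break
      if (length(loop) > length(i)) { ok <- FALSE; break }
    }
    if (ok && length(loop) >= 3L) {
      k <- which.min(loop)
      if (k > 1L) loop <- c(loop[k:length(loop)], loop[seq_len(k - 1L)])
      rings[[length(rings) + 1L]] <- loop
    }
  }
  rings
}

# Delete zig-zag points so that no three consecutive ring points share a
# triangle (which would make that triangle collapse onto a line once the
# ring is warped onto the level set).  Single ordered scan: for a triple
# (x_i, x_{i+1}, x_{i+2}) sharing a triangle, delete x_i if x_{i-1} is
# still present, otherwise delete x_{i+1}.
prune_zigzag <- function(s, ring) {
  tr <- s$triangles
  tri_of <- split(rep(seq_len(nrow(tr)), 3L), as.vector(tr))
  n <- length(ring)
  if (n < 4L) return(ring)
  deleted <- logical(n)
  get_tris <- function(p) tri_of[[as.character(p)]] %||% integer(0)
  for (ii in seq_len(n)) {
    i1 <- ii; i2 <- ii %% n + 1L; i3 <- (ii + 1L) %% n + 1L
    if (deleted[i1] || deleted[i2] || deleted[i3]) next
    common <- intersect(intersect(get_tris(ring[i1]), get_tris(ring[i2])), get_tris(ring[i3]))
    if (length(common)) {
      if (sum(!deleted) <= 3L) break
      prev <- (i1 - 2L) %% n + 1L
      if (!deleted[prev]) deleted[i1] <- TRUE else deleted[i2] <- TRUE
    }
  }
  ring[!deleted]
}

#' Tag connected components within existing tags
#'
#' Within each tag of `base_tags`, every edge-connected component receives
#' a fresh unique tag, numbered deterministically by the lowest contained
#' cell index.
#'
#' @param s A [tri_surface()].
#' @param base_tags Tags to split (default: all tags present).
#' @param start_tag First new tag value (defaults to `max(tag) + 1`).
#' @return The re-tagged [tri_surface()].
#' @export
tag_connectivity <- function(s, base_tags = NULL, start_tag = NULL) {
  if (is.null(base_tags)) base_tags <- sort(unique(s$cell_tags))
  nxt <- as.integer(start_tag %||% (max(s$cell_tags) + 1L))
  for (tg in sort(unique(base_tags))) {
    cells <- which(s$cell_tags == tg)
    if (length(cells) == 0L) next
    sub_groups <- connected_components(subset_cells(s, cells), indices = TRUE)
    if (length(sub_groups) <= 1L) next
    sub_groups <- sub_groups[order(vapply(sub_groups, function(g) min(cells[g]), integer(1)))]
    for (g in sub_groups) {
      s$cell_tags[cells[g]] <- nxt
      nxt <- nxt + 1L
    }
  }
  s
}

#' Tag an explicit list of cells, or a geodesic patch around a seed
#'
#' Non-interactive replacement for hand-drawing tags: either the listed
#' `cell_ids`, or all cells whose barycenter lies within a surface
#' (edge-graph) distance `radius` of the `seed` cell, receive `new_tag`.
#'
#' @param s A [tri_surface()].
#' @param new_tag Integer tag.
#' @param cell_ids Explicit cell indices.
#' @param seed Seed cell index (with `radius`).
#' @param radius Geodesic radius (mm) around the seed barycenter.
#' @return The tagged [tri_surface()].
#' @export
tag_cells <- function(s, new_tag, cell_ids = NULL, seed = NULL, radius = NULL) {
  if (!is.null(cell_ids)) {
    cell_ids <- as.integer(cell_ids)
    if (length(cell_ids) && (min(cell_ids) < 1L || max(cell_ids) > n_cells(s)))
      stop("cell id out of range", call. = FALSE)
    s$cell_tags[cell_ids] <- as.integer(new_tag)
    return(s)
  }
  stopifnot(!is.null(seed), !is.null(radius))
  bary0 <- colMeans(s$points[s$triangles[seed, ], , drop = FALSE])
  # seed the solver with exact euclidean distances in a small neighbourhood
  # (locally flat), then propagate geodesically
  dc <- row_norms(sweep(s$points, 2, bary0, `-`))
  src <- which(dc <= max(3 * mean_edge_length(s), min(dc) + 1e-12))
  dist <- geodesic_field(s, src, dc[src])
  db <- cell_barycenter_values(s, dist)
  s$cell_tags[db <= radius] <- as.integer(new_tag)
  s
}

#' Geodesic distance field on a triangulated surface
#'
#' First-arrival distance from a set of source points, computed with the
#' triangle-based Eikonal update (planar two-point wavefront solution per
#' triangle corner) iterated with Jacobi sweeps until convergence; edge
#' (Dijkstra) updates serve as the fallback and the upper bound.
#'
#' @param s A [tri_surface()].
#' @param src Integer indices of source points.
#' @param src_val Initial distances at the sources (default 0).
#' @param tol Convergence threshold on the sup change per sweep.
#' @param max_sweep Sweep cap.
#' @return Numeric distance per point.
#' @export
geodesic_field <- function(s, src, src_val = 0, tol = 1e-12, max_sweep = 1000L) {
  p <- s$points; tr <- s$triangles
  n <- n_points(s)
  d <- rep(Inf, n)
  d[src] <- src_val
  # precompute per-corner geometry: for corner C with neighbours A, B
  corners <- list()
  for (k in 1:3) {
    ci <- tr[, k]; ai <- tr[, k %% 3L + 1L]; bi <- tr[, (k + 1L) %% 3L + 1L]
    b0 <- row_norms(p[ci, , drop = FALSE] - p[ai, , drop = FALSE])  # |CA|
    a0 <- row_norms(p[ci, , drop = FALSE] - p[bi, , drop = FALSE])  # |CB|
    u <- p[ai, , drop = FALSE] - p[ci, , drop = FALSE]
    v <- p[bi, , drop = FALSE] - p[ci, , drop = FALSE]
    costh <- rowSums(u * v) / (b0 * a0)
    corners[[k]] <- list(c = ci, a = ai, b = bi, b0 = b0, a0 = a0, costh = costh)
  }
  for (sweep in seq_len(max_sweep)) {
    dold <- d
    for (k in 1:3) {
      cr <- corners[[k]]
      da <- d[cr$a]; db2 <- d[cr$b]
      # one-point (edge) updates
      cand <- pmin(da + cr$b0, db2 + cr$a0)
      # two-point planar wavefront update; u = d(B) - d(A) must be >= 0,
      # so apply it with the two known distances in both orders
      two_point <- function(da, db, b0, a0, ct) {
        u <- db - da
        st2 <- pmax(0, 1 - ct^2)
        A <- a0^2 + b0^2 - 2 * a0 * b0 * ct
        B <- 2 * b0 * u * (a0 * ct - b0)
        C <- b0^2 * (u^2 - a0^2 * st2)
        disc <- B^2 - 4 * A * C
        t1 <- (-B + sqrt(pmax(disc, 0))) / (2 * A)
        w <- b0 * (t1 - u) / t1
        ok <- is.finite(u) & u >= 0 & disc >= 0 & t1 > u &
          w > a0 * ct & w < a0 / pmax(ct, 1e-300) & ct > 0
        ok[is.na(ok)] <- FALSE
        ifelse(ok, da + t1, Inf)
      }
      cand <- pmin(cand,
                   two_point(da, db2, cr$b0, cr$a0, cr$costh),
                   two_point(db2, da, cr$a0, cr$b0, cr$costh))
      # aggregate minimum per target vertex
      o <- order(cr$c, cand)
      firsts <- !duplicated(cr$c[o])
      tgt <- cr$c[o][firsts]; val <- cand[o][firsts]
      d[tgt] <- pmin(d[tgt], val)
    }
    d[src] <- src_val
    changed <- (is.finite(d) & !is.finite(dold)) |
      (is.finite(d) & is.finite(dold) & abs(d - dold) > tol)
    if (!any(changed)) break
  }
  d
}
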