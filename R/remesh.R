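#' Tag-preserving isotropic surface remeshing
#'
#' Incremental remeshing driven by a target edge length: long edges
#' (> 4/3 of the local target) are split at their midpoint, short edges
#' (< 4/5) collapsed, interior edges flipped toward valence 6, and
#' vertices tangentially relaxed and projected back onto the input
#' surface.  The operation can be localized to a subset of cell tags:
#' cells outside `target_tags` are left untouched, and the polylines
#' separating different tags (and the surface boundary) are treated as
#' constraints -- their vertices only slide along the constraint, so tag
#' boundaries keep their geometry.
#'
#' @param s A manifold [tri_surface()].
#' @param h Constant target edge length (mm); ignored if `size_field`
#'   given.
#' @param size_field Name of a per-point sizing field of `s`.
#' @param target_tags Cell tags to remesh (default: all).
#' @param iterations Remeshing sweeps (default 10).
#' @param preserve_boundary Keep surface-boundary vertices and edges
#'   exactly fixed (needed when the boundary must stay conforming with
#'   another mesh); if `FALSE` boundary vertices slide along the boundary
#'   polyline.
#' @param project Project relaxed vertices back onto the input surface.
#' @return The remeshed [tri_surface()].
#' @export
isotropic_remesh <- function(s, h = NULL, size_field = NULL, target_tags = NULL,
                             iterations = 10L, preserve_boundary = TRUE,
                             project = TRUE) {
  validate_surface(s, check_orientation = FALSE)
  if (is.null(h) && is.null(size_field)) stop("give h or size_field", call. = FALSE)
  if (!is.null(size_field)) {
    hv <- as.numeric(s$point_data[[size_field]])
    if (is.null(hv) || length(hv) != n_points(s)) stop("bad size field", call. = FALSE)
  } else hv <- rep(h, n_points(s))
  if (any(hv <= 0)) stop("mesh-size must be positive on the target region", call. = FALSE)
  st <- list(pts = s$points, tris = s$triangles, tags = s$cell_tags, h = hv)
  st$target <- if (is.null(target_tags)) rep(TRUE, nrow(st$tris)) else st$tags %in% target_tags
  if (!any(st$target)) return(s)   # nothing to do
  reference <- s
  for (it in seq_len(iterations)) {
    st <- remesh_split_pass(st, preserve_boundary)
    st <- remesh_collapse_pass(st, preserve_boundary)
    st <- remesh_flip_pass(st)
    st <- remesh_relax_pass(st, reference, preserve_boundary, project)
  }
  out <- tri_surface(st$pts, st$tris, cell_tags = st$tags, tag_names = s$tag_names)
  out <- drop_unused_points(out)
  validate_surface(out, check_orientation = FALSE)
  out
}

# --- shared helpers ------------------------------------------------------

remesh_edge_info <- function(st, preserve_boundary) {
  tr <- st$tris
  i <- c(tr[, 1], tr[, 2], tr[, 3]); j <- c(tr[, 2], tr[, 3], tr[, 1])
  cell <- rep.int(seq_len(nrow(tr)), 3L)
  key <- edge_key(i, j)
  first <- !duplicated(key)
  # per-edge incident cells
  cells_by_edge <- split(cell, key)
  tags_by_edge <- lapply(cells_by_edge, function(cc) unique(st$tags[cc]))
  target_by_edge <- vapply(cells_by_edge, function(cc) all(st$target[cc]), logical(1))
  nincident <- lengths(cells_by_edge)
  ukey <- names(cells_by_edge)
  is_boundary <- nincident == 1L
  is_interface <- lengths(tags_by_edge) > 1L
  list(i = i[first], j = j[first], key = key[first],
       cells = cells_by_edge[key[first]],
       boundary = is_boundary[match(key[first], ukey)],
       interface = is_interface[match(key[first], ukey)],
       in_target = target_by_edge[match(key[first], ukey)])
}

# vertex constraint classes: 0 free, 1 on constraint polyline, 2 fixed
remesh_vertex_class <- function(st, ei, preserve_boundary) {
  cls <- integer(nrow(st$pts))
  onb <- unique(c(ei$i[ei$boundary], ei$j[ei$boundary]))
  oni <- unique(c(ei$i[ei$interface], ei$j[ei$interface]))
  cls[oni] <- 1L
  cls[onb] <- if (preserve_boundary) 2L else 1L
  # vertices touching any non-target cell are fixed
  nt <- which(!st$target)
  if (length(nt)) cls[unique(as.vector(st$tris[nt, , drop = FALSE]))] <- 2L
  # junctions of >2 constraint edges are corners: fixed
  cedge <- ei$interface | ei$boundary
  cidx <- c(ei$i[cedge], ei$j[cedge])
  cnt <- table(cidx)
  cls[as.integer(names(cnt)[cnt > 2L])] <- 2L
  # sharp bends of a constraint polyline are feature corners: fixed
  two <- as.integer(names(cnt)[cnt == 2L])
  if (length(two)) {
    ci <- ei$i[cedge]; cj <- ei$j[cedge]
    for (v in two) {
      nb <- c(cj[ci == v], ci[cj == v])
      u1 <- st$pts[nb[1], ] - st$pts[v, ]
      u2 <- st$pts[nb[2], ] - st$pts[v, ]
      ca <- sum(u1 * u2) / sqrt(sum(u1^2) * sum(u2^2))
      if (ca > -0.866) cls[v] <- 2L      # bend sharper than 30 degrees
    }
  }
  cls
}

edge_target_h <- function(st, a, b) (st$h[a] + st$h[b]) / 2

# --- split ---------------------------------------------------------------

remesh_split_pass <- function(st, preserve_boundary) {
  ei <- remesh_edge_info(st, preserve_boundary)
  len <- row_norms(st$pts[ei$i, , drop = FALSE] - st$pts[ei$j, , drop = FALSE])
  he <- edge_target_h(st, ei$i, ei$j)
  splittable <- ei$in_target & len > (4 / 3) * he
  if (preserve_boundary) splittable <- splittable & !ei$boundary
  if (!any(splittable)) return(st)
  sk <- ei$key[splittable]
  mids <- (st$pts[ei$i[splittable], , drop = FALSE] + st$pts[ei$j[splittable], , drop = FALSE]) / 2
  hmid <- he[splittable]
  mid_idx <- nrow(st$pts) + seq_len(sum(splittable))
  names(mid_idx) <- sk
  st$pts <- rbind(st$pts, mids)
  st$h <- c(st$h, hmid)
  newt <- vector("list", nrow(st$tris))
  newtag <- vector("list", nrow(st$tris))
  newtar <- vector("list", nrow(st$tris))
  for (c1 in seq_len(nrow(st$tris))) {
    v <- st$tris[c1, ]
    ks <- edge_key(v, v[c(2, 3, 1)])
    m <- mid_idx[ks]          # NA where not split
    nsplit <- sum(!is.na(m))
    if (nsplit == 0L) { newt[[c1]] <- matrix(v, 1); newtag[[c1]] <- st$tags[c1]; newtar[[c1]] <- st$target[c1]; next }
    # rotate so that edge 1 (v1-v2) is split
    while (is.na(m[1])) { v <- v[c(2, 3, 1)]; m <- m[c(2, 3, 1)] }
    a <- v[1]; b <- v[2]; c2 <- v[3]
    mab <- m[1]; mbc <- m[2]; mca <- m[3]
    tt <- if (nsplit == 3L) {
      rbind(c(a, mab, mca), c(mab, b, mbc), c(mca, mbc, c2), c(mab, mbc, mca))
    } else if (nsplit == 1L) {
      rbind(c(a, mab, c2), c(mab, b, c2))
    } else if (!is.na(mbc)) {      # split ab and bc
      rbind(c(mab, b, mbc), c(a, mab, mbc), c(a, mbc, c2))
    } else {                       # split ab and ca
      rbind(c(a, mab, mca), c(mab, b, c2), c(mab, c2, mca))
    }
    newt[[c1]] <- tt
    newtag[[c1]] <- rep(st$tags[c1], nrow(tt))
    newtar[[c1]] <- rep(st$target[c1], nrow(tt))
  }
  st$tris <- do.call(rbind, newt)
  st$tags <- unlist(newtag)
  st$target <- unlist(newtar)
  st
}

# --- collapse ------------------------------------------------------------

remesh_collapse_pass <- function(st, preserve_boundary) {
  ei <- remesh_edge_info(st, preserve_boundary)
  cls <- remesh_vertex_class(st, ei, preserve_boundary)
  len <- row_norms(st$pts[ei$i, , drop = FALSE] - st$pts[ei$j, , drop = FALSE])
  he <- edge_target_h(st, ei$i, ei$j)
  cand <- which(ei$in_target & len < (4 / 5) * he)
  if (length(cand) == 0L) return(st)
  cand <- cand[order(len[cand])]
  # adjacency for link condition
  nbrs <- vertex_adjacency(tri_surface(st$pts, st$tris))
  touched <- logical(nrow(st$pts))
  vmap <- seq_len(nrow(st$pts))
  newpos <- st$pts
  newh <- st$h
  for (e in cand) {
    a <- ei$i[e]; b <- ei$j[e]
    if (touched[a] || touched[b]) next
    ca <- cls[a]; cb <- cls[b]
    if (ca == 2L && cb == 2L) next
    # constraint-compatible target position
    if (ca >= 1L && cb >= 1L) {
      # both on constraints: only along a shared constraint edge
      if (!(ei$boundary[e] || ei$interface[e])) next
      if (ca == 2L || cb == 2L) {
        keep_pos <- if (ca == 2L) st$pts[a, ] else st$pts[b, ]
      } else keep_pos <- (st$pts[a, ] + st$pts[b, ]) / 2
    } else if (ca >= 1L) keep_pos <- st$pts[a, ]
    else if (cb >= 1L) keep_pos <- st$pts[b, ]
    else keep_pos <- (st$pts[a, ] + st$pts[b, ]) / 2
    if (ca == 2L && !ei$boundary[e] && !ei$interface[e]) next
    if (cb == 2L && !ei$boundary[e] && !ei$interface[e]) next
    # link condition
    shared <- intersect(nbrs[[a]], nbrs[[b]])
    want <- if (ei$boundary[e]) 1L else 2L
    if (length(shared) != want) next
    # no over-long new edges
    ring <- setdiff(union(nbrs[[a]], nbrs[[b]]), c(a, b))
    dmax <- max(row_norms(sweep(newpos[ring, , drop = FALSE], 2, keep_pos, `-`)))
    if (dmax > (4 / 3) * max(st$h[c(a, b)])) next
    vmap[b] <- a
    newpos[a, ] <- keep_pos
    newh[a] <- mean(st$h[c(a, b)])
    touched[c(a, b, ring)] <- TRUE
  }
  if (all(vmap == seq_along(vmap))) return(st)
  tr2 <- matrix(vmap[st$tris], ncol = 3)
  degen <- tr2[, 1] == tr2[, 2] | tr2[, 2] == tr2[, 3] | tr2[, 1] == tr2[, 3]
  st2 <- st
  st2$pts <- newpos; st2$h <- newh
  st2$tris <- tr2[!degen, , drop = FALSE]
  st2$tags <- st$tags[!degen]
  st2$target <- st$target[!degen]
  # roll back if the pass broke manifoldness or created duplicates
  ok <- tryCatch({
    validate_surface(tri_surface(st2$pts, st2$tris), check_orientation = TRUE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) return(st)
  st2
}

# --- flip ----------------------------------------------------------------

remesh_flip_pass <- function(st) {
  tr <- st$tris
  i <- c(tr[, 1], tr[, 2], tr[, 3]); j <- c(tr[, 2], tr[, 3], tr[, 1])
  cell <- rep.int(seq_len(nrow(tr)), 3L)
  key <- edge_key(i, j)
  sp <- split(seq_along(key), key)
  interior <- sp[lengths(sp) == 2L]
  deg <- tabulate(c(i[!duplicated(key)], j[!duplicated(key)]), nrow(st$pts))
  ei0 <- remesh_edge_info(st, TRUE)
  bnd_v <- unique(c(ei0$i[ei0$boundary], ei0$j[ei0$boundary]))
  tgt_val <- rep(6L, nrow(st$pts)); tgt_val[bnd_v] <- 4L
  all_keys <- new.env(hash = TRUE)
  for (k in unique(key)) all_keys[[k]] <- TRUE
  touched_cell <- logical(nrow(tr))
  for (ent in interior) {
    e1 <- ent[1]; e2 <- ent[2]
    c1 <- cell[e1]; c2 <- cell[e2]
    if (touched_cell[c1] || touched_cell[c2]) next
    if (!st$target[c1] || !st$target[c2]) next
    if (st$tags[c1] != st$tags[c2]) next           # tag interface: constrained
    a <- i[e1]; b <- j[e1]
    # opposite vertices
    o1 <- setdiff(tr[c1, ], c(a, b)); o2 <- setdiff(tr[c2, ], c(a, b))
    if (length(o1) != 1L || length(o2) != 1L) next
    nk <- edge_key(o1, o2)
    if (!is.null(all_keys[[nk]])) next             # edge already exists
    dev_before <- abs(deg[a] - tgt_val[a]) + abs(deg[b] - tgt_val[b]) +
      abs(deg[o1] - tgt_val[o1]) + abs(deg[o2] - tgt_val[o2])
    dev_after <- abs(deg[a] - 1L - tgt_val[a]) + abs(deg[b] - 1L - tgt_val[b]) +
      abs(deg[o1] + 1L - tgt_val[o1]) + abs(deg[o2] + 1L - tgt_val[o2])
    if (dev_after >= dev_before) next
    # geometric sanity: new triangles non-degenerate, normals coherent
    p <- st$pts
    n_old <- row_cross(rbind(p[b, ] - p[a, ]), rbind(p[o1, ] - p[a, ]))
    t1 <- c(a, o2, o1); t2 <- c(b, o1, o2)
    n1 <- row_cross(rbind(p[t1[2], ] - p[t1[1], ]), rbind(p[t1[3], ] - p[t1[1], ]))
    n2 <- row_cross(rbind(p[t2[2], ] - p[t2[1], ]), rbind(p[t2[3], ] - p[t2[1], ]))
    if (sqrt(sum(n1^2)) < 1e-14 || sqrt(sum(n2^2)) < 1e-14) next
    nr <- sum(n_old * n1) / sqrt(sum(n_old^2)) / sqrt(sum(n1^2))
    nr2 <- sum(n_old * n2) / sqrt(sum(n_old^2)) / sqrt(sum(n2^2))
    if (nr < 0.2 || nr2 < 0.2) next
    # orient the two new triangles consistently with the old pair
    # old c1 = (a, b, o1) cyclic; new pair around edge o1-o2
    st$tris[c1, ] <- c(a, o2, o1)
    st$tris[c2, ] <- c(o2, b, o1)
    # fix orientation: ensure edge a-b no longer present and windings match
    deg[a] <- deg[a] - 1L; deg[b] <- deg[b] - 1L
    deg[o1] <- deg[o1] + 1L; deg[o2] <- deg[o2] + 1L
    rm(list = edge_key(a, b), envir = all_keys)
    all_keys[[nk]] <- TRUE
    touched_cell[c(c1, c2)] <- TRUE
  }
  # validate; roll back wholesale on failure
  ok <- tryCatch({
    validate_surface(tri_surface(st$pts, st$tris), check_orientation = TRUE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) { st$tris <- tr; return(st) }
  st
}

# --- relax ---------------------------------------------------------------

remesh_relax_pass <- function(st, reference, preserve_boundary, project,
                              lambda = 0.6) {
  ei <- remesh_edge_info(st, preserve_boundary)
  cls <- remesh_vertex_class(st, ei, preserve_boundary)
  surf <- tri_surface(st$pts, st$tris)
  adj <- vertex_adjacency(surf)
  vn <- point_normals(surf)
  target_pts <- unique(as.vector(st$tris[st$target, , drop = FALSE]))
  free <- target_pts[cls[target_pts] == 0L]
  newp <- st$pts
  if (length(free)) {
    for (v in free) {
      nb <- adj[[v]]
      if (is.null(nb) || length(nb) < 2L) next
      cent <- colMeans(st$pts[nb, , drop = FALSE])
      d <- cent - st$pts[v, ]
      d <- d - vn[v, ] * sum(d * vn[v, ])     # tangential component
      newp[v, ] <- st$pts[v, ] + lambda * d
    }
    if (project) {
      res <- cpp_closest_point(newp[free, , drop = FALSE],
                               reference$points, reference$triangles)
      newp[free, ] <- res$closest
    }
  }
  # constraint vertices slide along their constraint polyline
  sliders <- target_pts[cls[target_pts] == 1L]
  if (length(sliders)) {
    cedge <- ei$boundary | ei$interface
    cseg_i <- ei$i[cedge]; cseg_j <- ei$j[cedge]
    for (v in sliders) {
      nb_on <- unique(c(cseg_j[cseg_i == v], cseg_i[cseg_j == v]))
      if (length(nb_on) != 2L) next
      cent <- colMeans(st$pts[nb_on, , drop = FALSE])
      cand <- st$pts[v, ] + lambda * (cent - st$pts[v, ])
      # project onto the two incident constraint segments
      best <- st$pts[v, ]; bd <- Inf
      for (w in nb_on) {
        a <- st$pts[v, ]; b <- st$pts[w, ]
        ab <- b - a; t1 <- sum((cand - a) * ab) / max(sum(ab * ab), 1e-300)
        t1 <- min(1, max(0, t1))
        pp <- a + t1 * ab
        dd <- sum((cand - pp)^2)
        if (dd < bd) { bd <- dd; best <- pp }
      }
      newp[v, ] <- best
    }
  }
  # reject relaxations that invert triangles
  areas_ok <- tryCatch({
    tmp <- tri_surface(newp, st$tris)
    all(triangle_areas(tmp) > 0)
  }, error = function(e) FALSE)
  if (areas_ok) st$pts <- newp
  st
}
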