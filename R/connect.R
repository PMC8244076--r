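# Core greedy zipper between two ordered rings of 3D points.
#
# ring1 is traversed in its stored (winding-consistent) order starting at
# its first point; the traversal direction on ring2 is fixed by the
# neighbour of the closest starting point that is nearest to the first
# ring1 candidate.  Each step appends the triangle (P1, P2, P*) where P* is
# the candidate with the shorter connecting edge (ties advance on ring1);
# a final triangle closes the band.  Indices in the result refer to the
# concatenation (ring1 points, then ring2 points).
zipper_triangulation <- function(q1, q2, start1 = 1L, dir2 = NULL) {
  n1 <- nrow(q1); n2 <- nrow(q2)
  if (n1 < 3L || n2 < 3L) stop("rings need at least 3 points", call. = FALSE)
  i2 <- function(k) n1 + k
  # start pair
  s1 <- start1
  d <- rowSums(sweep(q2, 2, q1[s1, ], `-`)^2)
  s2 <- which.min(d)
  nxt1 <- function(k) k %% n1 + 1L
  # candidate after the start on ring1 (fixed forward direction)
  c1 <- nxt1(s1)
  # ring2 direction: neighbour of s2 closest to q1[c1,] unless forced
  fwd <- s2 %% n2 + 1L
  bwd <- (s2 - 2L) %% n2 + 1L
  dirf <- sum((q2[fwd, ] - q1[c1, ])^2)
  dirb <- sum((q2[bwd, ] - q1[c1, ])^2)
  step2 <- if (!is.null(dir2)) as.integer(dir2)
  else if (dirf <= dirb) +1L else -1L
  nxt2 <- function(k) (k - 1L + step2) %% n2 + 1L
  c2 <- nxt2(s2)

  p1 <- s1; p2 <- s2
  used1 <- 1L; used2 <- 1L   # counts of inserted points per ring
  tris <- matrix(0L, n1 + n2, 3L)
  tcount <- 0L
  i <- 2L
  while (i <= n1 + n2) {
    d1 <- sum((q1[c1, ] - q2[p2, ])^2)
    d2 <- sum((q2[c2, ] - q1[p1, ])^2)
    adv1 <- d1 <= d2     # tie-break: advance on ring1
    # a ring that has wrapped back to its start cannot advance again
    if (used1 > n1) adv1 <- FALSE
    if (used2 > n2) adv1 <- TRUE
    if (adv1) {
      tcount <- tcount + 1L
      tris[tcount, ] <- c(p1, i2(p2), c1)
      p1 <- c1
      used1 <- used1 + 1L
      c1 <- if (used1 < n1) nxt1(p1) else s1      # wrap to the start point
    } else {
      tcount <- tcount + 1L
      tris[tcount, ] <- c(p1, i2(p2), i2(c2))
      p2 <- c2
      used2 <- used2 + 1L
      c2 <- if (used2 < n2) nxt2(p2) else s2
    }
    i <- i + 1L
  }
  # closing triangle: exactly one ring has wrapped back to its start;
  # close with the start point of the other ring
  tcount <- tcount + 1L
  if (used1 > n1) {
    tris[tcount, ] <- c(p1, i2(p2), i2(s2))
  } else {
    tris[tcount, ] <- c(p1, i2(p2), s1)
  }
  list(triangles = tris[seq_len(tcount), , drop = FALSE], start2 = s2)
}

#' Connect two open surfaces with a zipper band
#'
#' Greedy triangulation between a boundary ring of each surface: starting
#' from the lowest-index point of `ring1` and its closest point on
#' `ring2`, triangles are appended one at a time, always choosing the
#' shorter of the two candidate connecting edges, and a closing triangle
#' finishes the band.  The band carries `band_tag` and is watertight
#' against both parents; the result is the merged surface
#' `s1` + band + `s2`.
#'
#' @param s1,s2 Disjoint open [tri_surface()]s.
#' @param ring1,ring2 Boundary rings of `s1` / `s2` (from
#'   [extract_boundary_rings()]); defaults to the only ring when a surface
#'   has exactly one.
#' @param band_tag Integer tag for the band triangles.
#' @return A single [tri_surface()].
#' @export
surface_connection <- function(s1, s2, ring1 = NULL, ring2 = NULL, band_tag = 1L) {
  pick_ring <- function(s, r, who) {
    if (!is.null(r)) return(r)
    rings <- extract_boundary_rings(s)
    if (length(rings) != 1L)
      stop(sprintf("%s has %d boundary rings; specify one", who, length(rings)), call. = FALSE)
    rings[[1]]
  }
  ring1 <- pick_ring(s1, ring1, "s1"); ring2 <- pick_ring(s2, ring2, "s2")
  check_ring_of(s1, ring1); check_ring_of(s2, ring2)
  if (surfaces_share_points(s1, s2))
    stop("input surfaces share points; they must be disjoint", call. = FALSE)
  q1 <- s1$points[ring1, , drop = FALSE]
  q2 <- s2$points[ring2, , drop = FALSE]
  # the start point and the traversal direction of the second ring are free
  # choices of the greedy construction; a poor pick on wobbly rings can
  # self-overlap the band, so validated variants are tried in a fixed order
  n1 <- nrow(q1)
  attempts <- list()
  for (off in unique(c(0L, (1:4) * max(1L, n1 %/% 5L))))
    for (d2 in list(NULL, 1L, -1L))
      attempts[[length(attempts) + 1L]] <- list(start1 = off %% n1 + 1L, dir2 = d2)
  last_err <- NULL
  for (at in attempts) {
    z <- zipper_triangulation(q1, q2, start1 = at$start1, dir2 = at$dir2)
    band <- tri_surface(rbind(q1, q2), z$triangles,
                        cell_tags = rep(as.integer(band_tag), nrow(z$triangles)))
    out <- merge_surfaces(list(s1, s2, band))
    ok <- tryCatch({
      validate_surface(out)
      TRUE
    }, error = function(e) { last_err <<- e; FALSE })
    if (ok) return(out)
  }
  stop(sprintf("zipper failed to build a manifold band (%s)",
               conditionMessage(last_err)), call. = FALSE)
}

check_ring_of <- function(s, ring) {
  be <- boundary_edge_table(s)
  keys <- edge_key(be$i, be$j)
  r <- as.integer(ring)
  n <- length(r)
  rk <- edge_key(r, r[c(2:n, 1L)])
  if (!all(rk %in% keys))
    stop("ring is not a boundary ring of its surface", call. = FALSE)
  invisible(TRUE)
}

surfaces_share_points <- function(s1, s2, tol = 0) {
  k1 <- paste(s1$points[, 1], s1$points[, 2], s1$points[, 3])
  k2 <- paste(s2$points[, 1], s2$points[, 2], s2$points[, 3])
  any(k1 %in% k2)
}

#' Rigid registration of one ring onto another
#'
#' `centroid` mode returns the pure translation aligning the geometric
#' centers.  `icp` mode alternates closest-point correspondence (point to
#' segment on the fixed ring) with a least-squares rigid fit
#' (cross-covariance SVD with reflection guard) until the relative change
#' of the mean distance falls below `tol` or `max_iter` is reached.
#'
#' @param moving,fixed Rings as k x 3 coordinate matrices (or rings plus
#'   their surfaces via `moving_surface` / `fixed_surface`).
#' @param mode `"centroid"` or `"icp"`.
#' @param moving_surface,fixed_surface Parent surfaces when rings are
#'   index vectors.
#' @param tol Relative-change stopping tolerance.
#' @param max_iter Iteration cap.
#' @return List with 3 x 3 `rotation` and length-3 `translation`; the
#'   transform maps x to `rotation %*% x + translation`.
#' @export
register_rings <- function(moving, fixed, mode = c("centroid", "icp"),
                           moving_surface = NULL, fixed_surface = NULL,
                           tol = 1e-6, max_iter = 50L) {
  mode <- match.arg(mode)
  pm <- if (is.matrix(moving)) moving else moving_surface$points[as.integer(moving), , drop = FALSE]
  pf <- if (is.matrix(fixed)) fixed else fixed_surface$points[as.integer(fixed), , drop = FALSE]
  if (mode == "centroid") {
    return(list(rotation = diag(3), translation = colMeans(pf) - colMeans(pm)))
  }
  R <- diag(3); t <- c(0, 0, 0)
  cur <- pm
  prev_err <- Inf
  for (it in seq_len(max_iter)) {
    cp <- ring_distance(cur, pf, vector = TRUE)
    target <- cur + cp$vector
    err <- mean(cp$distance)
    # rigid Kabsch fit from the ORIGINAL points to current targets
    mu_m <- colMeans(pm); mu_t <- colMeans(target)
    H <- crossprod(sweep(pm, 2, mu_m), sweep(target, 2, mu_t))
    sv <- svd(H)
    if (min(sv$d) < 1e-12 * max(sv$d) && sum(sv$d > 1e-12 * max(sv$d)) < 2)
      stop("degenerate (collinear) ring: rank-deficient ICP fit", call. = FALSE)
    D <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
    R <- sv$v %*% D %*% t(sv$u)
    t <- mu_t - as.vector(R %*% mu_m)
    cur <- sweep(pm %*% t(R), 2, t, `+`)
    if (is.finite(prev_err) && abs(prev_err - err) <= tol * max(err, 1e-300)) break
    prev_err <- err
  }
  list(rotation = R, translation = t)
}

#' Apply a rigid transform to a surface
#' @param s A [tri_surface()].
#' @param transform List with `rotation` and `translation` as returned by
#'   [register_rings()].
#' @return The transformed surface.
#' @export
apply_rigid <- function(s, transform) {
  s$points <- sweep(s$points %*% t(transform$rotation), 2, transform$translation, `+`)
  s
}

#' Boolean connection of two intersecting closed surfaces
#'
#' Computes the difference, union or intersection of two closed
#' outward-oriented surfaces, but -- instead of stitching exactly at the
#' intersection curve -- clips the kept parts back a distance `epsilon`
#' from the intersection, optionally remeshes a `3h` buffer around the new
#' rims at constant mesh-size `h`, and joins the rims with the zipper.  The
#' output carries three tag classes: part of `s1` (`tag1`), part of `s2`
#' (`tag2`) and the connection band (`band_tag`); multiple intersection
#' curves are paired nearest first.
#'
#' @param s1,s2 Closed intersecting [tri_surface()]s with outward normals.
#' @param operation `"difference"`, `"union"` or `"intersection"`.
#' @param epsilon Clip offset from the intersection (mm); default `2 * h`.
#' @param h Connection mesh-size (mm).
#' @param clip_both Clip both inputs back by epsilon (`TRUE`) or only the
#'   first (`FALSE`), preserving the sharpness of the second.
#' @param buffer_only Remesh only the 3h band near the rims.
#' @param remesh Remesh the rim region at all.
#' @param tag1,tag2,band_tag Output tags.
#' @return A closed [tri_surface()].
#' @export
boolean_connection <- function(s1, s2,
                               operation = c("difference", "union", "intersection"),
                               epsilon = NULL, h = NULL, clip_both = TRUE,
                               buffer_only = TRUE, remesh = !is.null(h),
                               tag1 = 1L, tag2 = 2L, band_tag = 3L) {
  operation <- match.arg(operation)
  for (s in list(s1, s2)) if (!is_closed(s)) stop("boolean connection requires closed inputs", call. = FALSE)
  if (is.null(epsilon)) {
    if (is.null(h)) stop("give epsilon or h", call. = FALSE)
    epsilon <- 2 * h
  }
  d1 <- surface_distance(s1$points, s2, signed = TRUE)
  d2 <- surface_distance(s2$points, s1, signed = TRUE)
  if (all(d1 > 0) || all(d1 < 0) || all(d2 > 0) || all(d2 < 0))
    stop("surfaces do not intersect", call. = FALSE)
  keep1 <- if (operation == "intersection") "below" else "above"
  keep2 <- if (operation == "union") "above" else "below"
  s1$point_data$signed_distance <- d1
  s2$point_data$signed_distance <- d2
  p1 <- clip_at_level(s1, "signed_distance", 0, keep = keep1)
  p2 <- clip_at_level(s2, "signed_distance", 0, keep = keep2)
  # for difference the kept part of s2 bounds the output from inside:
  # flip it so the final closed surface is outward-oriented
  if (operation == "difference") p2 <- flip_orientation(p2)
  # clip back by epsilon from the intersection rims
  clip_back <- function(p, eps) {
    rings <- extract_boundary_rings(p)
    rp <- do.call(rbind, lapply(rings, function(r) p$points[r, , drop = FALSE]))
    p$point_data$rim_distance <- ring_distance(p$points, rp)
    clip_at_level(p, "rim_distance", eps, keep = "above")
  }
  p1 <- clip_back(p1, epsilon)
  if (clip_both) p2 <- clip_back(p2, epsilon)
  if (remesh && !is.null(h)) {
    rem <- function(p) {
      rings <- extract_boundary_rings(p)
      rp <- do.call(rbind, lapply(rings, function(r) p$points[r, , drop = FALSE]))
      p$point_data$rim_distance <- ring_distance(p$points, rp)
      if (buffer_only) {
        p$cell_tags[] <- 0L
        bary_d <- cell_barycenter_values(p, p$point_data$rim_distance)
        p$cell_tags[bary_d <= 3 * h] <- 999L
        out <- isotropic_remesh(p, h = h, target_tags = 999L, preserve_boundary = FALSE)
      } else out <- isotropic_remesh(p, h = h, preserve_boundary = FALSE)
      out$cell_tags[] <- 0L
      out
    }
    p1 <- tryCatch(rem(p1), error = function(e) p1)
    p2 <- tryCatch(rem(p2), error = function(e) p2)
  }
  p1$cell_tags[] <- as.integer(tag1)
  p2$cell_tags[] <- as.integer(tag2)
  p1$point_data <- list(); p2$point_data <- list()
  p1$cell_data <- list(); p2$cell_data <- list()
  # pair and zip the boundary rings nearest first
  r1 <- extract_boundary_rings(p1)
  r2 <- extract_boundary_rings(p2)
  if (length(r1) != length(r2)) stop("rim count mismatch after clipping", call. = FALSE)
  out_parts <- list(p1, p2)
  used <- logical(length(r2))
  for (i in seq_along(r1)) {
    dmin <- vapply(seq_along(r2), function(j) {
      if (used[j]) return(Inf)
      mean(ring_distance(p1$points[r1[[i]], , drop = FALSE],
                         p2$points[r2[[j]], , drop = FALSE]))
    }, numeric(1))
    j <- which.min(dmin); used[j] <- TRUE
    band <- zipper_band(p1, r1[[i]], p2, r2[[j]], band_tag = band_tag)
    out_parts[[length(out_parts) + 1L]] <- band
  }
  out <- merge_surfaces(out_parts)
  if (!is_closed(out)) stop("boolean connection failed to close", call. = FALSE)
  if (surface_volume(out) < 0) out <- flip_orientation(out)
  out
}

cell_barycenter_values <- function(s, f) {
  (f[s$triangles[, 1]] + f[s$triangles[, 2]] + f[s$triangles[, 3]]) / 3
}

#' Harmonic connection of a surface onto a reference surface
#'
#' Deforms `s_in` so that its boundary ring lands on a boundary ring of the
#' reference surface, extending the ring displacement harmonically over the
#' deformation domain (Laplace-Beltrami with the ring vector-distance as
#' Dirichlet data, zero on the boundary of any excluded tags, natural
#' conditions elsewhere), then clips the deformed surface a distance `h`
#' from the target ring and zipper-connects it to the reference.
#'
#' @param s_in Input (template) [tri_surface()].
#' @param s_ref Reference [tri_surface()].
#' @param ring_in,ring_ref Boundary rings; defaults as in
#'   [surface_connection()].
#' @param registration `"none"`, `"centroid"` or `"icp"` rigid
#'   pre-alignment of `ring_in` onto `ring_ref` (applied to all of `s_in`).
#' @param excluded_tags Tags of `s_in` fixed to zero deformation; their
#'   interface rings become homogeneous-Dirichlet boundaries.
#' @param free_ring_dirichlet If `TRUE`, remaining free rings are pinned to
#'   zero displacement instead of the natural condition.
#' @param h Gap width for the clip and band remesh size; `NULL` skips the
#'   clip (surfaces are only zipped).
#' @param band_tag Tag for the connection band.
#' @param remesh_deformed Remesh the deformed part at `h`.
#' @return A single [tri_surface()].
#' @export
harmonic_connection <- function(s_in, s_ref, ring_in = NULL, ring_ref = NULL,
                                registration = c("none", "centroid", "icp"),
                                excluded_tags = integer(0),
                                free_ring_dirichlet = FALSE,
                                h = NULL, band_tag = 99L,
                                remesh_deformed = FALSE) {
  registration <- match.arg(registration)
  pick_ring <- function(s, r) {
    if (!is.null(r)) return(r)
    rings <- extract_boundary_rings(s)
    if (length(rings) != 1L) stop("surface has several rings; specify one", call. = FALSE)
    rings[[1]]
  }
  ring_in <- pick_ring(s_in, ring_in); ring_ref <- pick_ring(s_ref, ring_ref)
  if (registration != "none") {
    tf <- register_rings(s_in$points[ring_in, , drop = FALSE],
                         s_ref$points[ring_ref, , drop = FALSE], mode = registration)
    s_in <- apply_rigid(s_in, tf)
  }
  ref_ring_pts <- s_ref$points[ring_ref, , drop = FALSE]
  # deformation domain: input minus excluded tags
  excl_cells <- which(s_in$cell_tags %in% excluded_tags)
  if (length(excl_cells) == n_cells(s_in)) stop("excluded tags cover the whole surface", call. = FALSE)
  dom_cells <- setdiff(seq_len(n_cells(s_in)), excl_cells)
  dom <- subset_cells(s_in, dom_cells)
  dom_pts_parent <- sort(unique(as.vector(s_in$triangles[dom_cells, , drop = FALSE])))
  to_dom <- integer(n_points(s_in)); to_dom[dom_pts_parent] <- seq_along(dom_pts_parent)

  # Dirichlet sets on the domain
  ring_in_dom <- to_dom[as.integer(ring_in)]
  if (any(ring_in_dom == 0L)) stop("connection ring lies inside excluded tags", call. = FALSE)
  dvec <- ring_distance(dom$points[ring_in_dom, , drop = FALSE], ref_ring_pts, vector = TRUE)$vector
  dir_idx <- ring_in_dom
  dir_val <- dvec
  excl_pts <- if (length(excl_cells))
    sort(unique(as.vector(s_in$triangles[excl_cells, , drop = FALSE]))) else integer(0)
  gamma0 <- setdiff(intersect(excl_pts, dom_pts_parent), as.integer(ring_in))
  if (length(gamma0)) {
    dir_idx <- c(dir_idx, to_dom[gamma0])
    dir_val <- rbind(dir_val, matrix(0, length(gamma0), 3))
  }
  if (free_ring_dirichlet) {
    other <- setdiff(unlist(lapply(extract_boundary_rings(dom), as.integer)),
                     c(ring_in_dom, to_dom[gamma0]))
    if (length(other)) {
      dir_idx <- c(dir_idx, other)
      dir_val <- rbind(dir_val, matrix(0, length(other), 3))
    }
  }
  phi_dom <- solve_harmonic(dom, dir_idx, dir_val)
  phi <- matrix(0, n_points(s_in), 3)
  phi[dom_pts_parent, ] <- phi_dom
  s_def <- warp_surface(s_in, phi)
  s_def$point_data$deformation <- phi

  if (!is.null(h)) {
    s_def$point_data$ring_ref_distance <- ring_distance(s_def$points, ref_ring_pts)
    s_def <- clip_at_level(s_def, "ring_ref_distance", h, keep = "above")
    if (remesh_deformed) {
      s_def <- tryCatch(isotropic_remesh(s_def, h = h, preserve_boundary = FALSE),
                        error = function(e) s_def)
    }
    s_def$point_data <- list(); s_def$cell_data <- list()
    # connect at the newly created rim nearest the reference ring
    rims <- extract_boundary_rings(s_def)
    dmin <- vapply(rims, function(r)
      mean(ring_distance(s_def$points[r, , drop = FALSE], ref_ring_pts)), numeric(1))
    rim <- rims[[which.min(dmin)]]
    return(surface_connection(s_def, s_ref, rim, ring_ref, band_tag = band_tag))
  }
  s_def$point_data <- s_def$point_data["deformation"]
  surface_connection(s_def, s_ref, extract_boundary_rings(s_def)[[
    which.min(vapply(extract_boundary_rings(s_def), function(r)
      mean(ring_distance(s_def$points[r, , drop = FALSE], ref_ring_pts)), numeric(1)))]],
    ring_ref, band_tag = band_tag)
}
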