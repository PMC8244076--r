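#' Wall thickness of a tagged closed structure
#'
#' Computes the local thickness `tau` on the tagged walls of a closed
#' surface from unsigned distances between the walls.  With a single
#' internal wall, `tau = max(D_ext, D_int1)`: the distance to the external
#' wall evaluated on the internal one and vice versa.  With two internal
#' walls (biventricular septum case),
#' `tau = max( min( max(D_int1, D_int2), D_ext ), D_int )`, which returns
#' the inter-cavity distance across the septum and the cavity-to-outside
#' distance elsewhere.  On the remaining cells (e.g. a valvular annulus)
#' `tau` is projected by nearest neighbour from the computed region.
#'
#' @param s A tagged [tri_surface()].
#' @param internal_tags_1 Tags of the (first) internal wall.
#' @param external_tags Tags of the external wall.
#' @param internal_tags_2 Optional tags of the second internal wall.
#' @param name Name of the output point field.
#' @return `s` with the thickness point field.
#' @export
surface_thickness <- function(s, internal_tags_1, external_tags,
                              internal_tags_2 = integer(0), name = "thickness") {
  tags_of <- function(tags) {
    cells <- which(s$cell_tags %in% tags)
    if (length(cells) == 0L) stop("tag set selects no cells", call. = FALSE)
    subset_cells(s, cells)
  }
  ext <- tags_of(external_tags)
  int1 <- tags_of(internal_tags_1)
  all_tags <- c(internal_tags_1, external_tags, internal_tags_2)
  t_cells <- which(s$cell_tags %in% all_tags)
  t_pts <- sort(unique(as.vector(s$triangles[t_cells, , drop = FALSE])))
  q <- s$points[t_pts, , drop = FALSE]
  d_ext <- surface_distance(q, ext)
  d_int1 <- surface_distance(q, int1)
  if (length(internal_tags_2)) {
    int2 <- tags_of(internal_tags_2)
    int_all <- tags_of(c(internal_tags_1, internal_tags_2))
    d_int2 <- surface_distance(q, int2)
    d_int <- surface_distance(q, int_all)
    tau_t <- pmax(pmin(pmax(d_int1, d_int2), d_ext), d_int)
  } else {
    tau_t <- pmax(d_ext, d_int1)
  }
  tau <- numeric(n_points(s))
  tau[t_pts] <- tau_t
  rest <- setdiff(seq_len(n_points(s)), t_pts)
  if (length(rest)) {
    # nearest-neighbour projection from the computed region
    nn <- vapply(rest, function(i)
      which.min(rowSums(sweep(q, 2, s$points[i, ], `-`)^2)), integer(1))
    tau[rest] <- tau_t[nn]
  }
  s$point_data[[name]] <- tau
  s
}

#' Thicken a structure where it is too thin
#'
#' Displaces every point whose thickness is below the target `sigma` by
#' `w = 0.5 * alpha * (sigma - tau) * n` along the outward point normal;
#' the factor one half accounts for the deformation acting on both the
#' internal and external walls.  `invert = TRUE` instead thins the regions
#' where `tau > sigma`.  Points in `excluded_tags` stay fixed, which
#' together with `alpha = 2` localizes the full correction on the
#' non-excluded wall (e.g. fix the epicardium, move only the endocardium).
#'
#' @param s A [tri_surface()] carrying a thickness point field.
#' @param sigma Target thickness (mm).
#' @param alpha Scale factor on the deformation (default 1).
#' @param excluded_tags Tags whose points do not move.
#' @param invert Thin instead of thicken.
#' @param field Thickness field name.
#' @return The warped [tri_surface()].
#' @export
surface_thicken <- function(s, sigma, alpha = 1, excluded_tags = integer(0),
                            invert = FALSE, field = "thickness") {
  stopifnot(sigma > 0)
  tau <- s$point_data[[field]]
  if (is.null(tau)) stop(sprintf("thickness field '%s' not found", field), call. = FALSE)
  n <- point_normals(s)    # recomputed immediately before warping
  sel <- if (invert) tau > sigma else tau < sigma
  excl_pts <- if (length(excluded_tags)) {
    cells <- which(s$cell_tags %in% excluded_tags)
    unique(as.vector(s$triangles[cells, , drop = FALSE]))
  } else integer(0)
  sel[excl_pts] <- FALSE
  w <- matrix(0, n_points(s), 3)
  w[sel, ] <- 0.5 * alpha * (sigma - tau[sel]) * n[sel, , drop = FALSE]
  out <- warp_surface(s, w)
  ints <- self_intersection_hint(out)
  if (length(ints))
    warning(sprintf("possible self-intersection after thickening near cells: %s",
                    paste(utils::head(ints, 10), collapse = ",")), call. = FALSE)
  out
}

# cheap heuristic: triangles whose area collapsed or flipped vs. neighbours
self_intersection_hint <- function(s) {
  a <- triangle_areas(s)
  which(a <= 1e-12 * stats::median(a))
}

#' Mesh-size function from one or several point fields
#'
#' Each sizing rule maps a field `f` to
#' `h_i = clamp(alpha * f^beta + gamma, m, M)` and the final mesh-size is
#' the pointwise minimum over the rules, giving local priority to the
#' smallest requested size.  A rule with `field = NULL` is the constant
#' rule `h = gamma`.  When `target_tags` is given and a mesh-size field
#' already exists, only points of those tags are recomputed.  The smoothed
#' companion field is produced with [smooth_field()].
#'
#' @param s A [tri_surface()].
#' @param specs A list of sizing rules, each a list with entries `field`,
#'   `alpha`, `beta`, `gamma`, `m`, `M` (defaults 1, 1, 0, 0, Inf).
#' @param target_tags Restrict the update to these cell tags.
#' @param name,smooth_name Output field names.
#' @param smooth_iterations Iterations for the smoothed copy.
#' @return `s` with fields `name` and `smooth_name`.
#' @export
mesh_size <- function(s, specs, target_tags = NULL, name = "meshsize",
                      smooth_name = "meshsize_smooth", smooth_iterations = 10L) {
  if (!is.null(specs$field) || !is.null(specs$gamma)) specs <- list(specs)
  hs <- lapply(specs, function(sp) {
    alpha <- sp$alpha %||% 1; beta <- sp$beta %||% 1
    gamma <- sp$gamma %||% 0; m <- sp$m %||% 0; M <- sp$M %||% Inf
    if (m > M) stop("sizing clamp requires m <= M", call. = FALSE)
    if (is.null(sp$field)) return(rep(gamma, n_points(s)))
    f <- s$point_data[[sp$field]]
    if (is.null(f)) stop(sprintf("field '%s' not found", sp$field), call. = FALSE)
    f <- as.numeric(f)
    if (any(f <= 0) && beta %% 1 != 0)
      stop(sprintf("field '%s' has non-positive values; power %.3g undefined", sp$field, beta),
           call. = FALSE)
    pmax(m, pmin(alpha * f^beta + gamma, M))
  })
  h <- Reduce(pmin, hs)
  if (!is.null(target_tags) && !is.null(s$point_data[[name]])) {
    cells <- which(s$cell_tags %in% target_tags)
    pts <- unique(as.vector(s$triangles[cells, , drop = FALSE]))
    old <- as.numeric(s$point_data[[name]])
    old[pts] <- h[pts]
    h <- old
  }
  s$point_data[[name]] <- h
  s <- smooth_field(s, name, iterations = smooth_iterations, output = smooth_name)
  s
}

#' Smooth a point field by local averaging
#'
#' Fixed-point iterations of `v <- (1 - lambda) v + lambda * mean(one-ring
#' neighbours)`; a convex combination, so the global field bounds are
#' preserved.
#'
#' @param s A [tri_surface()].
#' @param field Field name.
#' @param iterations Number of sweeps.
#' @param relaxation Blend factor `lambda` in (0, 1].
#' @param output Output field name (defaults to overwriting `field`).
#' @return `s` with the smoothed field.
#' @export
smooth_field <- function(s, field, iterations = 10L, relaxation = 1.0,
                         output = field) {
  f <- s$point_data[[field]]
  if (is.null(f)) stop(sprintf("field '%s' not found", field), call. = FALSE)
  v <- as.numeric(f)
  ek <- surface_edges(s)
  first <- !duplicated(ek$key)
  i <- c(ek$i[first], ek$j[first]); j <- c(ek$j[first], ek$i[first])
  deg <- tabulate(i, n_points(s))
  for (it in seq_len(iterations)) {
    nbr_sum <- unname(rowsum(v[j], i, reorder = TRUE))
    avg <- v
    nz <- deg > 0
    avg[sort(unique(i))] <- nbr_sum / deg[sort(unique(i))]
    v <- (1 - relaxation) * v + relaxation * avg
  }
  s$point_data[[output]] <- v
  s
}

#' Discrete mean-curvature magnitude
#'
#' `|c| = |L x| / (2 A)` with the cotangent Laplace-Beltrami operator and
#' mixed Voronoi vertex areas; equals `1/R` on a sphere of radius `R` up to
#' tessellation error.
#'
#' @param s A [tri_surface()].
#' @param name Output point-field name.
#' @return `s` with the curvature field.
#' @export
mean_curvature <- function(s, name = "curvature") {
  if (any(triangle_areas(s) <= 0)) stop("degenerate triangles", call. = FALSE)
  L <- cotan_laplacian(s)
  A <- mixed_voronoi_areas(s)
  hvec <- as.matrix(L %*% s$points)
  s$point_data[[name]] <- row_norms(hvec) / (2 * A)
  s
}

# Meyer et al. mixed areas: Voronoi area for non-obtuse triangles,
# area/2 at the obtuse corner and area/4 elsewhere otherwise.
mixed_voronoi_areas <- function(s) {
  p <- s$points; tr <- s$triangles
  A <- numeric(n_points(s))
  area <- triangle_areas(s)
  cots <- matrix(0, nrow(tr), 3)
  for (k in 1:3) {
    o <- tr[, k]; a <- tr[, k %% 3L + 1L]; b <- tr[, (k + 1L) %% 3L + 1L]
    u <- p[a, , drop = FALSE] - p[o, , drop = FALSE]
    v <- p[b, , drop = FALSE] - p[o, , drop = FALSE]
    cots[, k] <- rowSums(u * v) / row_norms(row_cross(u, v))
  }
  obtuse_any <- cots[, 1] < 0 | cots[, 2] < 0 | cots[, 3] < 0
  for (k in 1:3) {
    vert <- tr[, k]
    # edge lengths opposite the other two corners
    a <- tr[, k %% 3L + 1L]; b <- tr[, (k + 1L) %% 3L + 1L]
    l_ab2 <- rowSums((p[vert, , drop = FALSE] - p[a, , drop = FALSE])^2)
    l_ac2 <- rowSums((p[vert, , drop = FALSE] - p[b, , drop = FALSE])^2)
    # voronoi contribution at `vert`: (|vb|^2 cot(beta) + |vc|^2 cot(gamma))/8
    contrib <- (l_ab2 * cots[, (k + 1L) %% 3L + 1L] + l_ac2 * cots[, k %% 3L + 1L]) / 8
    contrib[obtuse_any] <- ifelse(cots[obtuse_any, k] < 0,
                                  area[obtuse_any] / 2, area[obtuse_any] / 4)
    agg <- rowsum(contrib, vert, reorder = TRUE)
    tmp <- numeric(n_points(s))
    tmp[as.integer(rownames(agg))] <- agg
    A <- A + tmp
  }
  A
}
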