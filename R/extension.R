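#' Harmonic extension of a field from a tagged subregion
#'
#' Extends a scalar or vector point field, known only on the cells of
#' `source_tags`, to the rest of the surface by solving a Laplace-Beltrami
#' problem on the complement: the shared interface ring carries the known
#' values as Dirichlet data, optional `zero_tags` are forced to zero (their
#' interfaces become homogeneous-Dirichlet rings), free boundary rings are
#' natural (homogeneous Neumann) by default or pinned to per-ring constants
#' through `ring_values`.  Vector fields are extended componentwise and are
#' not renormalized (an optional `normalize` flag restores unit length for
#' fiber-like fields).
#'
#' @param s A [tri_surface()].
#' @param field Point-field name (scalar vector or n x 3 matrix).
#' @param source_tags Tags where the field is authoritative.
#' @param zero_tags Tags forced to zero.
#' @param ring_values Optional numeric vector: one constant per remaining
#'   free boundary ring (in [extract_boundary_rings()] order), used as
#'   Dirichlet data; `NULL` entries (or a `NULL` argument) mean natural.
#' @param normalize Renormalize vector results to unit length.
#' @return `s` with `field` replaced by its extension.
#' @export
harmonic_extension <- function(s, field, source_tags, zero_tags = integer(0),
                               ring_values = NULL, normalize = FALSE) {
  f <- s$point_data[[field]]
  if (is.null(f)) stop(sprintf("point field '%s' not found", field), call. = FALSE)
  fmat <- if (is.matrix(f)) f else matrix(as.numeric(f), ncol = 1)
  src_cells <- which(s$cell_tags %in% source_tags)
  zero_cells <- which(s$cell_tags %in% zero_tags)
  if (length(src_cells) == 0L) stop("source tags select no cells", call. = FALSE)
  dom_cells <- setdiff(seq_len(n_cells(s)), c(src_cells, zero_cells))
  if (length(dom_cells) == 0L) stop("nothing to extend: domain is empty", call. = FALSE)
  src_pts <- sort(unique(as.vector(s$triangles[src_cells, , drop = FALSE])))
  zero_pts <- sort(unique(as.vector(s$triangles[zero_cells, , drop = FALSE])))
  dom <- subset_cells(s, dom_cells)
  dom_parent <- sort(unique(as.vector(s$triangles[dom_cells, , drop = FALSE])))
  to_dom <- integer(n_points(s)); to_dom[dom_parent] <- seq_along(dom_parent)

  gamma_t <- intersect(dom_parent, src_pts)           # interface with sources
  gamma_zero <- setdiff(intersect(dom_parent, zero_pts), gamma_t)
  dir_idx <- c(to_dom[gamma_t], to_dom[gamma_zero])
  dir_val <- rbind(fmat[gamma_t, , drop = FALSE],
                   matrix(0, length(gamma_zero), ncol(fmat)))
  if (!is.null(ring_values)) {
    rings <- extract_boundary_rings(dom)
    constrained <- unique(c(to_dom[gamma_t], to_dom[gamma_zero]))
    free_rings <- Filter(function(r) !any(as.integer(r) %in% constrained), rings)
    for (k in seq_along(free_rings)) {
      g <- if (k <= length(ring_values)) ring_values[[k]] else NULL
      if (is.null(g) || is.na(g)) next
      idx <- as.integer(free_rings[[k]])
      dir_idx <- c(dir_idx, idx)
      dir_val <- rbind(dir_val, matrix(as.numeric(g), length(idx), ncol(fmat)))
    }
  }
  sol <- solve_harmonic(dom, dir_idx, dir_val)
  sol <- if (is.matrix(sol)) sol else matrix(sol, ncol = 1)
  out <- fmat
  out[dom_parent, ] <- sol
  out[zero_pts, ] <- 0
  out[src_pts, ] <- fmat[src_pts, , drop = FALSE]   # identity on the source
  if (normalize && ncol(out) == 3L) out <- normalize_rows(out)
  s$point_data[[field]] <- if (ncol(out) == 1L) drop(out) else out
  s
}
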