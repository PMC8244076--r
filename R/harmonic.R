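#' Cotangent Laplace-Beltrami stiffness matrix
#'
#' Standard piecewise-linear finite-element stiffness matrix on a
#' triangulated surface: `L[i,j] = -(cot a_ij + cot b_ij) / 2` for the
#' angles opposite edge `ij`, and row sums zero.  Obtuse triangles are
#' permitted; the weights are not clamped because clamping would change the
#' operator.
#'
#' @param s A [tri_surface()].
#' @return A sparse symmetric `dgCMatrix` (n x n).
#' @export
cotan_laplacian <- function(s) {
  p <- s$points; tr <- s$triangles
  n <- n_points(s)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (k in 1:3) {
    o <- tr[, k]                        # vertex opposite the edge
    a <- tr[, k %% 3L + 1L]; b <- tr[, (k + 1L) %% 3L + 1L]
    u <- p[a, , drop = FALSE] - p[o, , drop = FALSE]
    v <- p[b, , drop = FALSE] - p[o, , drop = FALSE]
    cot <- rowSums(u * v) / row_norms(row_cross(u, v))
    ii <- c(ii, a, b); jj <- c(jj, b, a); xx <- c(xx, -cot / 2, -cot / 2)
  }
  L <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  Matrix::Diagonal(n, -Matrix::rowSums(L)) + L
}

#' Solve a Laplace-Beltrami problem on a surface
#'
#' Discrete harmonic interpolation: solves `L phi = 0` with prescribed
#' values at the Dirichlet points; all other boundary points get the
#' natural (homogeneous Neumann, do-nothing) condition.  Vector data is
#' solved componentwise.
#'
#' @param s A [tri_surface()] (the solve domain).
#' @param dirichlet_idx Integer point indices with prescribed values.
#' @param dirichlet_val Numeric vector (or k x d matrix) of prescribed
#'   values, one row per index.
#' @return Length-n vector (or n x d matrix) matching the Dirichlet data
#'   exactly at constrained points.
#' @export
solve_harmonic <- function(s, dirichlet_idx, dirichlet_val) {
  dirichlet_idx <- as.integer(dirichlet_idx)
  if (length(dirichlet_idx) == 0L)
    stop("at least one Dirichlet point is required (singular system)", call. = FALSE)
  if (any(dirichlet_idx < 1L | dirichlet_idx > n_points(s)))
    stop("Dirichlet index out of range", call. = FALSE)
  vals <- if (is.matrix(dirichlet_val)) dirichlet_val else matrix(dirichlet_val, ncol = 1)
  if (nrow(vals) == 1L && length(dirichlet_idx) > 1L)
    vals <- vals[rep(1L, length(dirichlet_idx)), , drop = FALSE]
  stopifnot(nrow(vals) == length(dirichlet_idx))
  L <- cotan_laplacian(s)
  n <- n_points(s)
  fixed <- sort(unique(dirichlet_idx))
  vfix <- vals[match(fixed, dirichlet_idx), , drop = FALSE]
  free <- setdiff(seq_len(n), fixed)
  out <- matrix(0, n, ncol(vals))
  out[fixed, ] <- vfix
  if (length(free)) {
    A <- L[free, free, drop = FALSE]
    B <- L[free, fixed, drop = FALSE]
    rhs <- -B %*% vfix
    sol <- tryCatch(Matrix::solve(A, rhs),
                    error = function(e) {
                      q <- min(triangle_quality(s))
                      stop(sprintf("harmonic solve failed (%s); min triangle quality %.3g",
                                   conditionMessage(e), q), call. = FALSE)
                    })
    out[free, ] <- as.matrix(sol)
  }
  if (ncol(out) == 1L) drop(out) else out
}

#' Minimum-angle triangle quality
#' @param s A [tri_surface()].
#' @return Per-triangle minimum interior angle (radians).
#' @export
triangle_quality <- function(s) {
  p <- s$points; tr <- s$triangles
  ang <- matrix(0, nrow(tr), 3)
  for (k in 1:3) {
    o <- tr[, k]; a <- tr[, k %% 3L + 1L]; b <- tr[, (k + 1L) %% 3L + 1L]
    u <- normalize_rows(p[a, , drop = FALSE] - p[o, , drop = FALSE])
    v <- normalize_rows(p[b, , drop = FALSE] - p[o, , drop = FALSE])
    ang[, k] <- acos(pmin(1, pmax(-1, rowSums(u * v))))
  }
  apply(ang, 1, min)
}
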