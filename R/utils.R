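# Small vector-geometry helpers shared across the package.
# Points are always n x 3 numeric matrices in mm.

row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

row_norms <- function(a) sqrt(rowSums(a * a))

normalize_rows <- function(a) {
  n <- row_norms(a)
  n[n == 0] <- 1
  a / n
}

as_point_matrix <- function(x) {
  x <- as.matrix(x)
  if (is.vector(x) || ncol(x) == 1L) x <- matrix(as.numeric(x), ncol = 3)
  storage.mode(x) <- "double"
  if (ncol(x) != 3L) stop("points must be an n x 3 matrix", call. = FALSE)
  dimnames(x) <- NULL
  x
}

# Undirected edge key (i < j) for matching edges across triangles.
edge_key <- function(i, j) {
  lo <- pmin(i, j); hi <- pmax(i, j)
  paste(lo, hi, sep = "-")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
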