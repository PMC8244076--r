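#' Read a surface or volume mesh from disk
#'
#' Formats: VTK legacy ASCII (`POLYDATA` for surfaces,
#' `UNSTRUCTURED_GRID` for tet/hex meshes -- the canonical tagged format,
#' carrying cell tags as an integer `CELL_DATA` array named `"tag"` and
#' point/cell fields as `SCALARS`/`VECTORS` arrays), STL (ASCII and
#' binary; triangle soup is deduplicated on read), OBJ, and ASCII PLY.
#' Cell indices are 0-based on disk and 1-based in memory.
#'
#' @param path File path.
#' @param format One of `"vtk"`, `"stl"`, `"obj"`, `"ply"`; guessed from
#'   the extension when `NULL`.
#' @return A [tri_surface()] or [tet_mesh()].
#' @export
read_mesh <- function(path, format = NULL) {
  format <- tolower(format %||% tools::file_ext(path))
  switch(format,
         vtk = read_vtk(path),
         stl = read_stl(path),
         obj = read_obj(path),
         ply = read_ply(path),
         stop(sprintf("unsupported format '%s'", format), call. = FALSE))
}

#' Write a mesh to disk
#'
#' @param mesh A [tri_surface()], [tet_mesh()] or [hex_mesh()].
#' @param path Output path.
#' @param format As in [read_mesh()]; guessed from the extension.
#' @param binary Write binary STL instead of ASCII.
#' @return Invisibly `path`.
#' @export
write_mesh <- function(mesh, path, format = NULL, binary = FALSE) {
  format <- tolower(format %||% tools::file_ext(path))
  switch(format,
         vtk = write_vtk(mesh, path),
         stl = write_stl(mesh, path, binary = binary),
         obj = write_obj(mesh, path),
         ply = write_ply(mesh, path),
         stop(sprintf("unsupported format '%s'", format), call. = FALSE))
  invisible(path)
}

## ------------------------------------------------------------------ VTK

write_vtk <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("# vtk DataFile Version 3.0")
  wl("cardiomesh output")
  wl("ASCII")
  p <- mesh$points
  fmt_rows <- function(m) apply(m, 1, function(r) paste(formatC(r, format = "g", digits = 17), collapse = " "))
  if (inherits(mesh, "tri_surface")) {
    wl("DATASET POLYDATA")
    wl("POINTS %d double", nrow(p))
    writeLines(fmt_rows(p), con)
    tr <- mesh$triangles - 1L
    wl("POLYGONS %d %d", nrow(tr), nrow(tr) * 4L)
    writeLines(paste(3L, tr[, 1], tr[, 2], tr[, 3]), con)
    write_vtk_data(con, mesh$cell_tags, mesh$cell_data, mesh$point_data, nrow(tr), nrow(p))
  } else if (inherits(mesh, "tet_mesh")) {
    wl("DATASET UNSTRUCTURED_GRID")
    wl("POINTS %d double", nrow(p))
    writeLines(fmt_rows(p), con)
    tt <- mesh$tets - 1L
    bf <- mesh$boundary_faces - 1L
    ncell <- nrow(tt) + nrow(bf)
    wl("CELLS %d %d", ncell, nrow(tt) * 5L + nrow(bf) * 4L)
    if (nrow(tt)) writeLines(paste(4L, tt[, 1], tt[, 2], tt[, 3], tt[, 4]), con)
    if (nrow(bf)) writeLines(paste(3L, bf[, 1], bf[, 2], bf[, 3]), con)
    wl("CELL_TYPES %d", ncell)
    writeLines(as.character(c(rep(10L, nrow(tt)), rep(5L, nrow(bf)))), con)
    write_vtk_data(con, c(mesh$cell_tags, mesh$boundary_tags), mesh$cell_data,
                   mesh$point_data, ncell, nrow(p))
  } else if (inherits(mesh, "hex_mesh")) {
    wl("DATASET UNSTRUCTURED_GRID")
    wl("POINTS %d double", nrow(p))
    writeLines(fmt_rows(p), con)
    hx <- mesh$hexes - 1L
    qd <- mesh$boundary_quads - 1L
    ncell <- nrow(hx) + nrow(qd)
    wl("CELLS %d %d", ncell, nrow(hx) * 9L + nrow(qd) * 5L)
    if (nrow(hx)) writeLines(paste(8L, hx[, 1], hx[, 2], hx[, 3], hx[, 4],
                                   hx[, 5], hx[, 6], hx[, 7], hx[, 8]), con)
    if (nrow(qd)) writeLines(paste(4L, qd[, 1], qd[, 2], qd[, 3], qd[, 4]), con)
    wl("CELL_TYPES %d", ncell)
    writeLines(as.character(c(rep(12L, nrow(hx)), rep(9L, nrow(qd)))), con)
    write_vtk_data(con, c(mesh$cell_tags, mesh$boundary_tags), list(), mesh$point_data %||% list(),
                   ncell, nrow(p))
  } else stop("unsupported mesh class", call. = FALSE)
}

write_vtk_data <- function(con, cell_tags, cell_data, point_data, ncell, npoint) {
  wl <- function(...) writeLines(sprintf(...), con)
  fmt <- function(v) formatC(v, format = "g", digits = 17)
  wl("CELL_DATA %d", ncell)
  wl("SCALARS tag int 1")
  wl("LOOKUP_TABLE default")
  writeLines(as.character(cell_tags), con)
  for (nm in names(cell_data)) {
    f <- cell_data[[nm]]
    if (is.matrix(f)) { wl("VECTORS %s double", nm); writeLines(apply(f, 1, function(r) paste(fmt(r), collapse = " ")), con) }
    else { wl("SCALARS %s double 1", nm); wl("LOOKUP_TABLE default"); writeLines(fmt(f), con) }
  }
  if (length(point_data)) {
    wl("POINT_DATA %d", npoint)
    for (nm in names(point_data)) {
      f <- point_data[[nm]]
      if (is.matrix(f)) { wl("VECTORS %s double", nm); writeLines(apply(f, 1, function(r) paste(fmt(r), collapse = " ")), con) }
      else { wl("SCALARS %s double 1", nm); wl("LOOKUP_TABLE default"); writeLines(fmt(f), con) }
    }
  }
}

read_vtk <- function(path) {
  lines <- readLines(path, warn = FALSE)
  toks_of <- function(l) strsplit(trimws(l), "\\s+")[[1]]
  i <- 1L
  fail <- function(msg, ln) stop(sprintf("%s (line %d of %s)", msg, ln, path), call. = FALSE)
  while (i <= length(lines) && !grepl("^DATASET", lines[i])) i <- i + 1L
  if (i > length(lines)) fail("no DATASET keyword", i)
  dtype <- toks_of(lines[i])[2]
  if (!dtype %in% c("POLYDATA", "UNSTRUCTURED_GRID"))
    fail(sprintf("unsupported DATASET %s", dtype), i)
  # read numeric stream helper
  read_numbers <- function(start, n) {
    vals <- numeric(0); j <- start
    while (length(vals) < n) {
      if (j > length(lines)) fail("unexpected end of file", j)
      vals <- c(vals, suppressWarnings(as.numeric(toks_of(lines[j]))))
      j <- j + 1L
    }
    if (anyNA(vals)) fail("malformed numeric data", j - 1L)
    list(vals = vals, nxt = j)
  }
  # POINTS
  while (i <= length(lines) && !grepl("^POINTS", lines[i])) i <- i + 1L
  if (i > length(lines)) fail("no POINTS section", i)
  np <- as.integer(toks_of(lines[i])[2])
  got <- read_numbers(i + 1L, np * 3L)
  pts <- matrix(got$vals, ncol = 3, byrow = TRUE)
  i <- got$nxt
  cells <- NULL; cell_types <- NULL
  if (dtype == "POLYDATA") {
    while (i <= length(lines) && !grepl("^POLYGONS", lines[i])) i <- i + 1L
    if (i > length(lines)) fail("no POLYGONS section", i)
    hdr <- toks_of(lines[i]); ncell <- as.integer(hdr[2]); tot <- as.integer(hdr[3])
    got <- read_numbers(i + 1L, tot)
    i <- got$nxt
    vals <- as.integer(got$vals)
    cells <- list(); k <- 1L
    for (c1 in seq_len(ncell)) {
      cnt <- vals[k]
      cells[[c1]] <- vals[(k + 1L):(k + cnt)] + 1L
      k <- k + cnt + 1L
    }
    cell_types <- rep(5L, ncell)
  } else {
    while (i <= length(lines) && !grepl("^CELLS", lines[i])) i <- i + 1L
    if (i > length(lines)) fail("no CELLS section", i)
    hdr <- toks_of(lines[i]); ncell <- as.integer(hdr[2]); tot <- as.integer(hdr[3])
    got <- read_numbers(i + 1L, tot)
    i <- got$nxt
    vals <- as.integer(got$vals)
    cells <- list(); k <- 1L
    for (c1 in seq_len(ncell)) {
      cnt <- vals[k]
      cells[[c1]] <- vals[(k + 1L):(k + cnt)] + 1L
      k <- k + cnt + 1L
    }
    while (i <= length(lines) && !grepl("^CELL_TYPES", lines[i])) i <- i + 1L
    if (i > length(lines)) fail("no CELL_TYPES section", i)
    got <- read_numbers(i + 1L, ncell)
    cell_types <- as.integer(got$vals)
    i <- got$nxt
  }
  # data sections
  cell_arrays <- list(); point_arrays <- list()
  mode <- NULL; nexp <- 0L
  while (i <= length(lines)) {
    l <- trimws(lines[i])
    if (grepl("^CELL_DATA", l)) { mode <- "cell"; nexp <- as.integer(toks_of(l)[2]); i <- i + 1L; next }
    if (grepl("^POINT_DATA", l)) { mode <- "point"; nexp <- as.integer(toks_of(l)[2]); i <- i + 1L; next }
    if (grepl("^SCALARS", l)) {
      tk <- toks_of(l); nm <- tk[2]
      i <- i + 1L
      if (i <= length(lines) && grepl("^LOOKUP_TABLE", trimws(lines[i]))) i <- i + 1L
      got <- read_numbers(i, nexp)
      arr <- got$vals; i <- got$nxt
      if (mode == "cell") cell_arrays[[nm]] <- arr else point_arrays[[nm]] <- arr
      next
    }
    if (grepl("^VECTORS", l)) {
      tk <- toks_of(l); nm <- tk[2]
      got <- read_numbers(i + 1L, nexp * 3L)
      arr <- matrix(got$vals, ncol = 3, byrow = TRUE); i <- got$nxt
      if (mode == "cell") cell_arrays[[nm]] <- arr else point_arrays[[nm]] <- arr
      next
    }
    i <- i + 1L
  }
  if (dtype == "POLYDATA" || all(cell_types == 5L)) {
    tr <- do.call(rbind, cells[cell_types == 5L])
    tags <- cell_arrays[["tag"]]
    if (!is.null(tags)) tags <- as.integer(tags[cell_types == 5L])
    cd <- lapply(cell_arrays[setdiff(names(cell_arrays), "tag")], function(a)
      if (is.matrix(a)) a[cell_types == 5L, , drop = FALSE] else a[cell_types == 5L])
    return(tri_surface(pts, tr, cell_tags = tags, point_data = point_arrays,
                       cell_data = cd))
  }
  # unstructured: tets (10) + boundary triangles (5) [+ hex 12 unsupported read-back to hex]
  tet_idx <- which(cell_types == 10L)
  tri_idx <- which(cell_types == 5L)
  tags <- cell_arrays[["tag"]]
  tt <- do.call(rbind, cells[tet_idx])
  bf <- if (length(tri_idx)) do.call(rbind, cells[tri_idx]) else NULL
  m <- tet_mesh(pts, tt,
                cell_tags = if (!is.null(tags)) as.integer(tags[tet_idx]) else NULL,
                point_data = point_arrays,
                boundary_faces = bf,
                boundary_tags = if (!is.null(tags) && length(tri_idx)) as.integer(tags[tri_idx]) else NULL)
  if (is.null(bf)) {
    bfc <- compute_boundary_faces(tt)
    m$boundary_faces <- bfc; m$boundary_tags <- integer(nrow(bfc))
  }
  m
}

## ------------------------------------------------------------------ STL

write_stl <- function(mesh, path, binary = FALSE) {
  if (!inherits(mesh, "tri_surface")) stop("STL supports surfaces only", call. = FALSE)
  if (any(mesh$cell_tags != 0L) || length(mesh$point_data) || length(mesh$cell_data))
    warning("STL cannot carry tags/fields; they are dropped", call. = FALSE)
  p <- mesh$points; tr <- mesh$triangles
  n <- triangle_normals(mesh)
  if (binary) {
    con <- file(path, "wb"); on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nrow(tr)), con, size = 4, endian = "little")
    for (k in seq_len(nrow(tr))) {
      writeBin(as.numeric(c(n[k, ], p[tr[k, 1], ], p[tr[k, 2], ], p[tr[k, 3], ])),
               con, size = 4, endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines("solid cardiomesh", con)
    for (k in seq_len(nrow(tr))) {
      writeLines(sprintf("  facet normal %.9g %.9g %.9g", n[k, 1], n[k, 2], n[k, 3]), con)
      writeLines("    outer loop", con)
      for (v in tr[k, ])
        writeLines(sprintf("      vertex %.17g %.17g %.17g", p[v, 1], p[v, 2], p[v, 3]), con)
      writeLines("    endloop", con)
      writeLines("  endfacet", con)
    }
    writeLines("endsolid cardiomesh", con)
  }
}

read_stl <- function(path) {
  # detect binary: ASCII files start with "solid" and contain "facet"
  head_raw <- readBin(path, "raw", n = 512)
  printable <- head_raw >= as.raw(32) & head_raw < as.raw(127)
  head_txt <- rawToChar(head_raw[printable])
  is_ascii <- grepl("^\\s*solid", head_txt, useBytes = TRUE) &&
    grepl("facet", head_txt, useBytes = TRUE)
  if (is_ascii) {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    nums <- lapply(strsplit(trimws(vl), "\\s+"), function(t) as.numeric(t[2:4]))
    v <- do.call(rbind, nums)
    if (anyNA(v)) stop(sprintf("malformed STL vertex (line %d of %s)",
                               grep("^\\s*vertex", lines)[which(vapply(nums, anyNA, logical(1)))[1]],
                               path), call. = FALSE)
  } else {
    con <- file(path, "rb"); on.exit(close(con))
    readBin(con, "raw", n = 80)
    nt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
    v <- matrix(0, nt * 3L, 3L)
    for (k in seq_len(nt)) {
      rec <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
      readBin(con, "integer", n = 1, size = 2, endian = "little")
      v[(k - 1L) * 3L + 1:3, ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
    }
  }
  # triangle soup -> deduplicate identical coordinates
  key <- paste(v[, 1], v[, 2], v[, 3])
  first <- !duplicated(key)
  idx <- match(key, key[first])
  tri_surface(v[first, , drop = FALSE], matrix(idx, ncol = 3, byrow = TRUE))
}

## ------------------------------------------------------------------ OBJ

write_obj <- function(mesh, path) {
  if (!inherits(mesh, "tri_surface")) stop("OBJ supports surfaces only", call. = FALSE)
  con <- file(path, "w"); on.exit(close(con))
  p <- mesh$points; tr <- mesh$triangles
  writeLines(sprintf("v %.17g %.17g %.17g", p[, 1], p[, 2], p[, 3]), con)
  writeLines(sprintf("f %d %d %d", tr[, 1], tr[, 2], tr[, 3]), con)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines); flv <- grep("^f\\s", lines)
  v <- do.call(rbind, lapply(strsplit(trimws(lines[vl]), "\\s+"),
                             function(t) as.numeric(t[2:4])))
  f <- do.call(rbind, lapply(strsplit(trimws(lines[flv]), "\\s+"), function(t) {
    as.integer(vapply(strsplit(t[2:4], "/", fixed = TRUE), `[[`, "", 1))
  }))
  if (anyNA(v) || anyNA(f)) stop(sprintf("malformed OBJ file %s", path), call. = FALSE)
  tri_surface(v, f)
}

## ------------------------------------------------------------------ PLY

write_ply <- function(mesh, path) {
  if (!inherits(mesh, "tri_surface")) stop("PLY supports surfaces only", call. = FALSE)
  con <- file(path, "w"); on.exit(close(con))
  p <- mesh$points; tr <- mesh$triangles
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(p)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(tr)),
               "property list uchar int vertex_indices",
               "property int tag",
               "end_header"), con)
  writeLines(sprintf("%.17g %.17g %.17g", p[, 1], p[, 2], p[, 3]), con)
  writeLines(sprintf("3 %d %d %d %d", tr[, 1] - 1L, tr[, 2] - 1L, tr[, 3] - 1L,
                     mesh$cell_tags), con)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  endh <- match("end_header", trimws(lines))
  if (is.na(endh)) stop(sprintf("malformed PLY: no end_header (%s)", path), call. = FALSE)
  hdr <- trimws(lines[seq_len(endh)])
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", hdr, value = TRUE)))
  face_props <- hdr[seq(grep("^element face", hdr) + 1L, endh - 1L)]
  has_tag <- any(grepl("property int tag", face_props))
  vlines <- lines[endh + seq_len(nv)]
  v <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"), function(t) as.numeric(t[1:3])))
  flines <- lines[endh + nv + seq_len(nf)]
  ft <- strsplit(trimws(flines), "\\s+")
  f <- do.call(rbind, lapply(ft, function(t) as.integer(t[2:4]) + 1L))
  tags <- if (has_tag) vapply(ft, function(t) as.integer(t[5]), integer(1)) else NULL
  tri_surface(v, f, cell_tags = tags)
}
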