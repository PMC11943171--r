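#' Read a triangulated surface mesh
#'
#' Supports VTK legacy PolyData (ASCII), PLY (ASCII) and STL (ASCII and
#' binary little-endian). Coordinates are interpreted as millimetres. STL
#' files carry no shared-vertex topology, so identical vertex records are
#' merged on read.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"vtk"`, `"ply"`, `"stl"`; `"auto"` infers
#'   from the file extension.
#' @return a [surface_mesh()]. A `POINT_DATA` scalar array in a VTK file is
#'   attached as attribute `"point_scalars"` (named list of numeric vectors).
#' @export
read_mesh <- function(path, format = c("auto", "vtk", "ply", "stl")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read mesh: no such file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("vtk", "ply", "stl")) stop("cannot infer mesh format from: ", path)
    format <- ext
  }
  switch(format,
    vtk = read_vtk_polydata(path),
    ply = read_ply(path),
    stl = read_stl(path)
  )
}

#' Write a triangulated surface mesh
#'
#' @param mesh a [surface_mesh()].
#' @param path output file path.
#' @param format as in [read_mesh()]; `"auto"` uses the extension.
#' @param binary write binary STL instead of ASCII (STL only).
#' @param point_scalars optional named list of per-vertex numeric vectors
#'   written as `POINT_DATA` scalars (VTK only), e.g. signed distances for
#'   surface colouring.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "vtk", "ply", "stl"),
                       binary = FALSE, point_scalars = NULL) {
  format <- match.arg(format)
  if (format == "auto") format <- tolower(tools::file_ext(path))
  switch(format,
    vtk = write_vtk_polydata(mesh, path, point_scalars = point_scalars),
    ply = write_ply(mesh, path),
    stl = write_stl(mesh, path, binary = binary),
    stop("unknown mesh format: ", format)
  )
  invisible(path)
}

read_vtk_polydata <- function(path) {
  lines <- readLines(path, warn = FALSE)
  up <- toupper(lines)
  if (!any(grepl("DATASET\\s+POLYDATA", up))) stop("not a VTK PolyData file: ", path)
  ip <- grep("^POINTS", up)
  if (!length(ip)) stop("VTK file has no POINTS block")
  n <- as.integer(strsplit(trimws(lines[ip[1]]), "\\s+")[[1]][2])
  toks <- scan_numbers_after(lines, ip[1], 3 * n)
  vertices <- matrix(toks, ncol = 3, byrow = TRUE)
  ifc <- grep("^POLYGONS|^TRIANGLE_STRIPS", up)
  if (!length(ifc)) stop("malformed mesh: VTK file has no POLYGONS block")
  hdr <- as.integer(strsplit(trimws(lines[ifc[1]]), "\\s+")[[1]][2:3])
  conn <- scan_numbers_after(lines, ifc[1], hdr[2])
  faces <- parse_vtk_polygons(conn, hdr[1])
  mesh <- surface_mesh(vertices, faces)
  isc <- grep("^SCALARS", up)
  if (length(isc)) {
    scalars <- list()
    for (i in isc) {
      nm <- strsplit(trimws(lines[i]), "\\s+")[[1]][2]
      # skip LOOKUP_TABLE line if present
      start <- if (grepl("^LOOKUP_TABLE", up[i + 1])) i + 1 else i
      scalars[[nm]] <- scan_numbers_after(lines, start, n)
    }
    attr(mesh, "point_scalars") <- scalars
  }
  mesh
}

# collect `count` whitespace-separated numbers from the lines following `at`
scan_numbers_after <- function(lines, at, count) {
  out <- numeric(0)
  i <- at + 1
  while (length(out) < count && i <= length(lines)) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) && is.na(suppressWarnings(as.numeric(toks[1])))) break
    out <- c(out, as.numeric(toks))
    i <- i + 1
  }
  if (length(out) < count) stop("truncated numeric block in VTK file")
  out[seq_len(count)]
}

parse_vtk_polygons <- function(conn, n_poly) {
  faces <- matrix(0L, 0, 3)
  pos <- 1L
  out <- vector("list", n_poly)
  for (p in seq_len(n_poly)) {
    k <- as.integer(conn[pos])
    idx <- as.integer(conn[(pos + 1):(pos + k)]) + 1L
    if (k == 3L) {
      out[[p]] <- matrix(idx, 1, 3)
    } else if (k > 3L) {
      # fan-triangulate larger polygons
      out[[p]] <- cbind(idx[1], idx[2:(k - 1)], idx[3:k])
    } else {
      stop("VTK polygon with fewer than 3 vertices")
    }
    pos <- pos + k + 1L
  }
  do.call(rbind, out)
}

write_vtk_polydata <- function(mesh, path, point_scalars = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh$vertices
  f <- mesh$faces
  writeLines(c(
    "# vtk DataFile Version 3.0",
    "surface mesh (mm)",
    "ASCII",
    "DATASET POLYDATA",
    sprintf("POINTS %d float", nrow(v))
  ), con)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("POLYGONS %d %d", nrow(f), 4L * nrow(f)), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  if (!is.null(point_scalars)) {
    writeLines(sprintf("POINT_DATA %d", nrow(v)), con)
    for (nm in names(point_scalars)) {
      writeLines(c(sprintf("SCALARS %s float 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.9g", point_scalars[[nm]]), con)
    }
  }
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!grepl("^ply", lines[1])) stop("not a PLY file: ", path)
  endh <- grep("^end_header", lines)[1]
  if (is.na(endh)) stop("PLY file missing end_header")
  if (any(grepl("^format\\s+binary", lines[seq_len(endh)]))) {
    stop("binary PLY is not supported; convert to ASCII PLY, VTK or STL")
  }
  nv <- as.integer(sub("^element vertex\\s+", "", grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub("^element face\\s+", "", grep("^element face", lines, value = TRUE)[1]))
  body <- lines[(endh + 1):length(lines)]
  vtok <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  vertices <- t(vapply(vtok, function(t) as.numeric(t[1:3]), numeric(3)))
  ftok <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  faces <- do.call(rbind, lapply(ftok, function(t) {
    k <- as.integer(t[1])
    idx <- as.integer(t[2:(k + 1)]) + 1L
    if (k == 3L) matrix(idx, 1, 3) else cbind(idx[1], idx[2:(k - 1)], idx[3:k])
  }))
  surface_mesh(vertices, faces)
}

write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh$vertices
  f <- mesh$faces
  writeLines(c(
    "ply", "format ascii 1.0", "comment units mm",
    sprintf("element vertex %d", nrow(v)),
    "property float x", "property float y", "property float z",
    sprintf("element face %d", nrow(f)),
    "property list uchar int vertex_indices",
    "end_header"
  ), con)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
}

read_stl <- function(path) {
  # binary STL: 80-byte header then uint32 triangle count matching file size
  sz <- file.info(path)$size
  con <- file(path, "rb")
  hdr <- readBin(con, "raw", 80)
  nt <- readBin(con, "integer", 1, size = 4, endian = "little")
  is_binary <- length(nt) == 1 && !is.na(nt) && sz == 84 + 50 * as.numeric(nt)
  if (is_binary) {
    raw <- readBin(con, "raw", 50 * nt)
    close(con)
    m <- matrix(raw, nrow = 50)
    tri <- vapply(seq_len(nt), function(i) {
      readBin(m[1:48, i], "numeric", 12, size = 4, endian = "little")
    }, numeric(12))
    verts <- t(tri)[, 4:12, drop = FALSE] # drop facet normal
    pts <- do.call(rbind, lapply(seq_len(nt), function(i) {
      rbind(verts[i, 1:3], verts[i, 4:6], verts[i, 7:9])
    }))
  } else {
    close(con)
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
    if (!length(vl)) stop("not an STL file (no vertex records): ", path)
    toks <- strsplit(trimws(vl), "\\s+")
    pts <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
  }
  if (nrow(pts) %% 3 != 0) stop("malformed STL: vertex count not divisible by 3")
  merge_triangle_soup(pts)
}

# weld a triangle soup (3 consecutive rows per face) into an indexed mesh
merge_triangle_soup <- function(pts) {
  key <- paste(sprintf("%.7g", pts[, 1]), sprintf("%.7g", pts[, 2]),
               sprintf("%.7g", pts[, 3]))
  idx <- match(key, key)
  uniq <- !duplicated(idx)
  remap <- integer(nrow(pts))
  remap[which(uniq)] <- seq_len(sum(uniq))
  vid <- remap[idx]
  vertices <- pts[uniq, , drop = FALSE]
  faces <- matrix(vid, ncol = 3, byrow = TRUE)
  surface_mesh(vertices, faces)
}

write_stl <- function(mesh, path, binary = FALSE) {
  v <- mesh$vertices
  f <- mesh$faces
  fg <- face_geometry(mesh)
  fn <- fg$normals / pmax(fg$areas, .Machine$double.eps)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0, 80)), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(c(fn[i, ], v[f[i, 1], ], v[f[i, 2], ], v[f[i, 3], ]),
               con, size = 4, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid mesh", con)
    for (i in seq_len(nrow(f))) {
      writeLines(c(
        sprintf("  facet normal %.9g %.9g %.9g", fn[i, 1], fn[i, 2], fn[i, 3]),
        "    outer loop",
        sprintf("      vertex %.9g %.9g %.9g",
                v[f[i, 1:3], 1], v[f[i, 1:3], 2], v[f[i, 1:3], 3]),
        "    endloop",
        "  endfacet"
      ), con)
    }
    writeLines("endsolid mesh", con)
  }
}
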