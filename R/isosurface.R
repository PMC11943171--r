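#' Binary label volume
#'
#' A 3D binary occupancy array with physical voxel spacing and origin, the
#' synthetic stand-in for a CT segmentation label map.
#'
#' @param array 3D array (logical or 0/1 numeric).
#' @param spacing mm per voxel along each axis (length 3, strictly positive).
#' @param origin physical position (mm) of the centre of voxel (1, 1, 1).
#' @return object of class `label_volume`.
#' @export
label_volume <- function(array, spacing = c(0.87, 0.87, 0.87),
                         origin = c(0, 0, 0)) {
  if (length(dim(array)) != 3L) stop("label volume must be a 3D array")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("voxel spacing must be strictly positive")
  structure(
    list(array = (array != 0), spacing = spacing, origin = rep_len(as.numeric(origin), 3L)),
    class = "label_volume"
  )
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf(
    "label_volume: %d x %d x %d voxels, spacing (%.3f, %.3f, %.3f) mm, %d foreground\n",
    dim(x$array)[1], dim(x$array)[2], dim(x$array)[3],
    x$spacing[1], x$spacing[2], x$spacing[3], sum(x$array)
  ))
  invisible(x)
}

#' Extract an isosurface from a binary label volume
#'
#' Marching tetrahedra on the voxel grid: the scalar field is the binary
#' occupancy (0/1) sampled at voxel centres, each grid cube is split into six
#' tetrahedra, and the `level` isosurface is triangulated with linear
#' interpolation along tetrahedron edges. For a solid foreground component
#' away from the volume border this produces a closed, crack-free surface.
#'
#' @param volume a [label_volume()] with non-empty foreground.
#' @param level iso level in (0, 1); 0.5 gives the midpoint surface between
#'   foreground and background voxel centres.
#' @return a [surface_mesh()] in mm with outward-oriented faces.
#' @export
extract_isosurface <- function(volume, level = 0.5) {
  if (!inherits(volume, "label_volume")) stop("need a label_volume")
  if (level <= 0 || level >= 1) stop("iso level must be in (0, 1)")
  a <- volume$array
  if (!any(a)) stop("empty foreground: nothing to extract")
  # pad with background so surfaces close at the volume border
  d <- dim(a)
  f <- array(0, d + 2L)
  f[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- a
  # smooth away the staircase bias of the binary field; back off passes when
  # smoothing would erase the foreground (single-voxel features)
  for (pass in 1:3) {
    fs <- smooth_field(f)
    if (!any(fs > level)) break
    f <- fs
  }
  res <- marching_tetrahedra(f, level)
  if (nrow(res$vertices) == 0L) stop("empty isosurface at level ", level)
  # grid index -> physical mm (padding shifted indices by 1)
  v <- sweep(res$vertices - 2, 2, volume$spacing, "*")
  v <- sweep(v, 2, volume$origin, "+")
  m <- merge_triangle_soup_indexed(v, res$faces)
  compute_vertex_normals(m)
}

# one pass of centre-weighted 6-neighbour smoothing: turns the binary
# occupancy into a piecewise-linear field so the 0.5 isosurface loses its
# staircase bias; the 0.6 centre weight keeps isolated voxels above level
smooth_field <- function(f) {
  d <- dim(f)
  g <- array(0, d + 2L)
  g[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- f
  i <- 2:(d[1] + 1); j <- 2:(d[2] + 1); k <- 2:(d[3] + 1)
  nb <- g[i - 1, j, k] + g[i + 1, j, k] + g[i, j - 1, k] + g[i, j + 1, k] +
    g[i, j, k - 1] + g[i, j, k + 1]
  0.6 * f + 0.4 * nb / 6
}

# six-tetrahedra decomposition of the unit cube; corner order:
# 1:(0,0,0) 2:(1,0,0) 3:(1,1,0) 4:(0,1,0) 5:(0,0,1) 6:(1,0,1) 7:(1,1,1) 8:(0,1,1)
tet_table <- matrix(c(
  1, 2, 3, 7,
  1, 3, 4, 7,
  1, 4, 8, 7,
  1, 8, 5, 7,
  1, 5, 6, 7,
  1, 6, 2, 7
), ncol = 4, byrow = TRUE)

cube_offsets <- matrix(c(
  0, 0, 0,  1, 0, 0,  1, 1, 0,  0, 1, 0,
  0, 0, 1,  1, 0, 1,  1, 1, 1,  0, 1, 1
), ncol = 3, byrow = TRUE)

# vectorised marching tetrahedra over all active cubes of a 3D field
marching_tetrahedra <- function(field, level) {
  d <- dim(field)
  # cubes whose 8 corners straddle the level
  nx <- d[1] - 1L; ny <- d[2] - 1L; nz <- d[3] - 1L
  # corner occupancy sums to find mixed cubes cheaply
  s <- array(0L, c(nx, ny, nz))
  for (k in 1:8) {
    o <- cube_offsets[k, ]
    s <- s + (field[(1:nx) + o[1], (1:ny) + o[2], (1:nz) + o[3], drop = FALSE] > level)
  }
  act <- which(s > 0L & s < 8L)
  if (!length(act)) {
    return(list(vertices = matrix(0, 0, 3), faces = matrix(0L, 0, 3)))
  }
  ijk <- arrayInd(act, c(nx, ny, nz))
  # corner coordinates and values for active cubes: n x 8
  cv <- matrix(0, length(act), 8)
  cx <- cy <- cz <- matrix(0, length(act), 8)
  for (k in 1:8) {
    o <- cube_offsets[k, ]
    cx[, k] <- ijk[, 1] + o[1]
    cy[, k] <- ijk[, 2] + o[2]
    cz[, k] <- ijk[, 3] + o[3]
    cv[, k] <- field[cbind(cx[, k], cy[, k], cz[, k])]
  }
  tris <- list()
  for (t in 1:6) {
    corn <- tet_table[t, ]
    vals <- cv[, corn, drop = FALSE]
    inside <- vals > level
    code <- inside[, 1] + 2L * inside[, 2] + 4L * inside[, 3] + 8L * inside[, 4]
    px <- cx[, corn, drop = FALSE]; py <- cy[, corn, drop = FALSE]; pz <- cz[, corn, drop = FALSE]
    interp <- function(rows, i, j) {
      tt <- (level - vals[rows, i]) / (vals[rows, j] - vals[rows, i])
      cbind(px[rows, i] + tt * (px[rows, j] - px[rows, i]),
            py[rows, i] + tt * (py[rows, j] - py[rows, i]),
            pz[rows, i] + tt * (pz[rows, j] - pz[rows, i]))
    }
    corner_pos <- function(rows, i) cbind(px[rows, i], py[rows, i], pz[rows, i])
    # orient each triangle so its normal points away from the inside region
    # (reference point: centroid of the inside corners)
    orient_away <- function(a, b, cc, ref) {
      e1 <- b - a
      e2 <- cc - a
      n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                 e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                 e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
      ctr <- (a + b + cc) / 3
      flip <- rowSums(n * (ctr - ref)) < 0
      out <- cbind(a, b, cc)
      out[flip, ] <- cbind(a, cc, b)[flip, ]
      out
    }
    # one corner inside (or three inside): single clipped triangle
    one_in <- list(c(1L, 1, 2, 3, 4), c(2L, 2, 3, 1, 4), c(4L, 3, 1, 2, 4), c(8L, 4, 1, 3, 2))
    for (cs in one_in) {
      rows <- which(code == cs[1])
      if (length(rows)) {
        a <- interp(rows, cs[2], cs[3]); b <- interp(rows, cs[2], cs[4]); cc <- interp(rows, cs[2], cs[5])
        tris[[length(tris) + 1L]] <- orient_away(a, b, cc, corner_pos(rows, cs[2]))
      }
      rows <- which(code == 15L - cs[1])
      if (length(rows)) {
        a <- interp(rows, cs[2], cs[3]); b <- interp(rows, cs[2], cs[4]); cc <- interp(rows, cs[2], cs[5])
        ref <- (corner_pos(rows, cs[3]) + corner_pos(rows, cs[4]) + corner_pos(rows, cs[5])) / 3
        tris[[length(tris) + 1L]] <- orient_away(a, b, cc, ref)
      }
    }
    # two-in/two-out: quad split into two triangles
    two_in <- list(
      c(3L, 1, 2, 3, 4),   # corners 1,2 inside
      c(5L, 1, 3, 2, 4),   # corners 1,3 inside
      c(9L, 1, 4, 2, 3),   # corners 1,4 inside
      c(6L, 2, 3, 1, 4),   # corners 2,3 inside
      c(10L, 2, 4, 1, 3),  # corners 2,4 inside
      c(12L, 3, 4, 1, 2)   # corners 3,4 inside
    )
    for (cs in two_in) {
      rows <- which(code == cs[1])
      if (length(rows)) {
        i1 <- cs[2]; i2 <- cs[3]; o1 <- cs[4]; o2 <- cs[5]
        ref <- (corner_pos(rows, i1) + corner_pos(rows, i2)) / 2
        p11 <- interp(rows, i1, o1); p12 <- interp(rows, i1, o2)
        p21 <- interp(rows, i2, o1); p22 <- interp(rows, i2, o2)
        tris[[length(tris) + 1L]] <- orient_away(p11, p21, p22, ref)
        tris[[length(tris) + 1L]] <- orient_away(p11, p22, p12, ref)
      }
    }
  }
  soup <- do.call(rbind, tris)  # n x 9: three vertices per row
  verts <- rbind(soup[, 1:3, drop = FALSE], soup[, 4:6, drop = FALSE], soup[, 7:9, drop = FALSE])
  n <- nrow(soup)
  ord <- as.vector(rbind(seq_len(n), seq_len(n) + n, seq_len(n) + 2L * n))
  verts <- verts[ord, , drop = FALSE]
  faces <- matrix(seq_len(3L * n), ncol = 3, byrow = TRUE)
  # drop degenerate (zero-area) triangles arising at exact grid contacts
  list(vertices = verts, faces = faces)
}

# weld an indexed soup (duplicate coordinates across faces) and fix global
# orientation so total signed volume is positive (outward normals)
merge_triangle_soup_indexed <- function(vertices, faces) {
  key <- paste(sprintf("%.10g", vertices[, 1]), sprintf("%.10g", vertices[, 2]),
               sprintf("%.10g", vertices[, 3]))
  first <- match(key, key)
  uniq <- !duplicated(first)
  remap <- integer(nrow(vertices))
  remap[which(uniq)] <- seq_len(sum(uniq))
  vid <- remap[first]
  f <- matrix(vid[faces], ncol = 3)
  keep <- !(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3])
  f <- f[keep, , drop = FALSE]
  out <- drop_unused_vertices(vertices[uniq, , drop = FALSE], f)
  m <- surface_mesh(out$vertices, out$faces, validate = FALSE)
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2), drop = FALSE]
  m
}

#' Voxelize a closed mesh into a binary label volume
#'
#' Occupancy by ray-parity: a voxel centre is foreground when a ray along +x
#' crosses the surface an odd number of times. Requires a closed mesh.
#'
#' @param mesh a closed [surface_mesh()].
#' @param spacing isotropic voxel spacing in mm (default emulates the 0.87 mm
#'   CT pixel spacing regime).
#' @param pad margin (in voxels) added around the mesh bounding box.
#' @return a [label_volume()].
#' @export
voxelize <- function(mesh, spacing = 0.87, pad = 2L) {
  if (n_faces(mesh) == 0L) stop("cannot voxelize an empty mesh")
  # closedness check: every edge in exactly two faces
  f <- mesh$faces
  ed <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  ed <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  if (any(table(ed) != 2L)) stop("cannot voxelize an open (non-watertight) mesh")
  spacing <- as.numeric(spacing)[1]
  lo <- apply(mesh$vertices, 2, min) - pad * spacing
  hi <- apply(mesh$vertices, 2, max) + pad * spacing
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  ys <- lo[2] + (seq_len(dims[2]) - 1) * spacing
  zs <- lo[3] + (seq_len(dims[3]) - 1) * spacing
  xs <- lo[1] + (seq_len(dims[1]) - 1) * spacing
  v <- mesh$vertices
  tri <- list(v[f[, 1], , drop = FALSE], v[f[, 2], , drop = FALSE], v[f[, 3], , drop = FALSE])
  occ <- array(FALSE, dims)
  # for each (y, z) ray, find x-crossings with all triangles (2D point-in-tri
  # on the yz projection, crossing x by barycentric interpolation)
  ay <- tri[[1]][, 2]; az <- tri[[1]][, 3]
  by <- tri[[2]][, 2]; bz <- tri[[2]][, 3]
  cy <- tri[[3]][, 2]; cz <- tri[[3]][, 3]
  ax <- tri[[1]][, 1]; bx <- tri[[2]][, 1]; cx <- tri[[3]][, 1]
  den <- (by - ay) * (cz - az) - (bz - az) * (cy - ay)
  ok <- abs(den) > 1e-14
  for (j in seq_len(dims[2])) {
    y <- ys[j]
    for (k in seq_len(dims[3])) {
      z <- zs[k]
      # barycentric coordinates of (y, z) in each projected triangle
      w1 <- ((by - ay) * (z - az) - (bz - az) * (y - ay)) / den
      w2 <- -((cy - ay) * (z - az) - (cz - az) * (y - ay)) / den
      w0 <- 1 - w1 - w2
      hit <- ok & w0 >= 0 & w1 >= 0 & w2 >= 0 & w0 <= 1 & w1 <= 1 & w2 <= 1
      if (!any(hit)) next
      xc <- w0[hit] * ax[hit] + w2[hit] * bx[hit] + w1[hit] * cx[hit]
      xc <- sort(unique(round(xc, 9)))
      if (length(xc) < 2L) next
      inside <- outer(xs, xc, ">") %*% rep(1, length(xc))
      occ[, j, k] <- (inside %% 2) == 1
    }
  }
  label_volume(occ, spacing = rep(spacing, 3), origin = lo)
}
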