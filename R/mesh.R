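#' Triangulated surface mesh
#'
#' The universal currency of the pipeline: a triangulated surface in
#' millimetres, stored as an `n x 3` vertex matrix and an `m x 3` integer
#' face matrix (1-based vertex indices). Optional per-vertex outward unit
#' normals are kept in sync by the operations that move vertices rigidly and
#' recomputed after operations that change the triangulation.
#'
#' @param vertices numeric matrix, `n x 3`, vertex coordinates in mm.
#' @param faces integer matrix, `m x 3`, 1-based vertex indices per triangle.
#' @param normals optional numeric `n x 3` matrix of per-vertex unit normals.
#' @param validate check invariants (in-range distinct indices, no isolated
#'   vertices). Disable only in inner loops on meshes already validated.
#'
#' @return An object of class `surface_mesh` with elements `vertices`,
#'   `faces` and (possibly `NULL`) `normals`.
#' @export
surface_mesh <- function(vertices, faces, normals = NULL, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  mesh <- structure(
    list(vertices = vertices, faces = faces, normals = normals),
    class = "surface_mesh"
  )
  if (validate) validate_mesh(mesh)
  mesh
}

#' Validate surface-mesh invariants
#'
#' Checks that every face references three distinct, in-range vertex indices
#' and that no vertex is isolated (each vertex belongs to at least one face).
#'
#' @param mesh a [surface_mesh()].
#' @return `mesh`, invisibly; otherwise an error.
#' @export
validate_mesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (!all(is.finite(v))) stop("mesh has non-finite vertex coordinates")
  if (nrow(f) < 1L) stop("malformed mesh: zero faces")
  if (any(f < 1L) || any(f > nrow(v))) stop("face index out of range")
  if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3])) {
    stop("degenerate face: repeated vertex index")
  }
  if (!all(seq_len(nrow(v)) %in% f)) stop("mesh has isolated vertices")
  invisible(mesh)
}

#' @export
print.surface_mesh <- function(x, ...) {
  bb <- apply(x$vertices, 2, range)
  cat(sprintf(
    "surface_mesh: %d vertices, %d faces\n  bounding box (mm): x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f]\n",
    nrow(x$vertices), nrow(x$faces),
    bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]
  ))
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)
n_faces <- function(mesh) nrow(mesh$faces)

#' Per-face geometry: centres, area-weighted normals, areas
#'
#' Face centres are vertex means; the area-weighted normal of a triangle
#' `(a, b, c)` is `0.5 * (b - a) x (c - a)` whose norm is the face area.
#'
#' @param mesh a [surface_mesh()].
#' @return list with `centers` (m x 3), `normals` (m x 3, area-weighted),
#'   `areas` (length m).
#' @export
face_geometry <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  centers <- (a + b + c3) / 3
  e1 <- b - a
  e2 <- c3 - a
  normals <- 0.5 * cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  )
  areas <- sqrt(rowSums(normals^2))
  list(centers = centers, normals = normals, areas = areas)
}

#' Total surface area of a mesh (mm^2)
#' @param mesh a [surface_mesh()].
#' @return scalar area in mm^2.
#' @export
mesh_area <- function(mesh) sum(face_geometry(mesh)$areas)

#' Signed enclosed volume of a closed mesh (mm^3)
#'
#' Divergence-theorem volume `sum(det(a, b, c)) / 6` over faces; positive for
#' consistently outward-wound closed surfaces.
#'
#' @param mesh a [surface_mesh()].
#' @return signed volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  det3 <- a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
    a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
    a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])
  sum(det3) / 6
}

#' Compute per-vertex outward unit normals
#'
#' Area-weighted average of incident face normals, normalised to unit length.
#' When the winding is consistent and outward, the result points outward.
#'
#' @param mesh a [surface_mesh()].
#' @return the mesh with its `normals` element filled in.
#' @export
compute_vertex_normals <- function(mesh) {
  fg <- face_geometry(mesh)
  n <- matrix(0, nrow(mesh$vertices), 3)
  f <- mesh$faces
  for (k in 1:3) {
    for (d in 1:3) {
      acc <- rowsum(fg$normals[, d], group = f[, k], reorder = FALSE)
      idx <- as.integer(rownames(acc))
      n[idx, d] <- n[idx, d] + acc[, 1]
    }
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  mesh$normals <- n / len
  mesh
}

#' Mean edge length of a mesh (mm)
#' @param mesh a [surface_mesh()].
#' @return scalar mean over unique edges.
#' @export
mean_edge_length <- function(mesh) {
  e <- mesh_edges(mesh)
  d <- mesh$vertices[e[, 1], , drop = FALSE] - mesh$vertices[e[, 2], , drop = FALSE]
  mean(sqrt(rowSums(d^2)))
}

# unique undirected edges, m x 2, sorted pairs
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Euler characteristic V - E + F
#' @param mesh a [surface_mesh()].
#' @return integer; 2 for a closed surface of genus 0.
#' @export
euler_characteristic <- function(mesh) {
  n_vertices(mesh) - nrow(mesh_edges(mesh)) + n_faces(mesh)
}

# drop vertices not referenced by faces, remapping indices
drop_unused_vertices <- function(vertices, faces, carry = NULL) {
  used <- sort(unique(as.vector(faces)))
  remap <- integer(nrow(vertices))
  remap[used] <- seq_along(used)
  out <- list(
    vertices = vertices[used, , drop = FALSE],
    faces = matrix(remap[faces], ncol = 3),
    kept = used
  )
  if (!is.null(carry)) out$carry <- carry[used]
  out
}

#' Distance from points to a triangulated surface
#'
#' Exact point-to-triangle distances, evaluated against the `k` faces with
#' nearest centroids per point (exact when the true nearest face is among
#' them, which holds for reasonably shaped triangulations).
#'
#' @param points `n x 3` matrix (mm).
#' @param mesh a [surface_mesh()].
#' @param k number of candidate faces per point.
#' @return numeric vector of distances (mm), one per point.
#' @export
point_surface_distance <- function(points, mesh, k = 24L) {
  points <- as.matrix(points)
  fg <- face_geometry(mesh)
  k <- min(k, nrow(fg$centers))
  d2 <- outer(rowSums(points^2), rowSums(fg$centers^2), "+") -
    2 * tcrossprod(points, fg$centers)
  cand <- t(apply(d2, 1, function(r) order(r)[seq_len(k)]))
  n <- nrow(points)
  pi_idx <- rep(seq_len(n), k)
  fi_idx <- as.vector(cand)
  f <- mesh$faces
  P <- points[pi_idx, , drop = FALSE]
  A <- mesh$vertices[f[fi_idx, 1], , drop = FALSE]
  B <- mesh$vertices[f[fi_idx, 2], , drop = FALSE]
  C <- mesh$vertices[f[fi_idx, 3], , drop = FALSE]
  d <- point_triangle_distance(P, A, B, C)
  apply(matrix(d, n, k), 1, min)
}

# exact distance from each point P to triangle (A, B, C), all m x 3:
# plane distance when the projection falls inside, else nearest edge
point_triangle_distance <- function(P, A, B, C) {
  seg_d2 <- function(P, S, E) {
    SE <- E - S
    t <- rowSums((P - S) * SE) / pmax(rowSums(SE^2), 1e-300)
    t <- pmin(pmax(t, 0), 1)
    Q <- S + t * SE
    rowSums((P - Q)^2)
  }
  E0 <- B - A
  E1 <- C - A
  N <- cross3(E0, E1)
  nn <- pmax(rowSums(N^2), 1e-300)
  dist_plane <- rowSums((P - A) * N) / sqrt(nn)
  # barycentric coordinates of the in-plane projection
  W <- P - A
  d00 <- rowSums(E0^2)
  d01 <- rowSums(E0 * E1)
  d11 <- rowSums(E1^2)
  d20 <- rowSums(W * E0)
  d21 <- rowSums(W * E1)
  den <- pmax(d00 * d11 - d01^2, 1e-300)
  v <- (d11 * d20 - d01 * d21) / den
  w <- (d00 * d21 - d01 * d20) / den
  inside <- v >= 0 & w >= 0 & (v + w) <= 1
  d2 <- pmin(seg_d2(P, A, B), seg_d2(P, B, C), seg_d2(P, C, A))
  ifelse(inside, abs(dist_plane), sqrt(d2))
}

#' Symmetric Hausdorff surface distance between meshes
#'
#' Max over both directions of the vertex-to-surface distance
#' ([point_surface_distance()]); robust to resolution differences, unlike a
#' vertex-to-vertex comparison.
#'
#' @param a,b [surface_mesh()] objects.
#' @return scalar distance in mm.
#' @export
hausdorff_surface_distance <- function(a, b) {
  max(max(point_surface_distance(a$vertices, b)),
      max(point_surface_distance(b$vertices, a)))
}

#' Symmetric Hausdorff-style distance between vertex clouds
#'
#' Max over both directions of the per-vertex nearest-neighbour distance
#' between the vertex sets of two meshes. A vertex-sampled surrogate for the
#' surface Hausdorff distance, adequate at the mesh resolutions used here.
#'
#' @param a,b [surface_mesh()] objects.
#' @return scalar distance in mm.
#' @export
hausdorff_vertex_distance <- function(a, b) {
  d1 <- nn_dist(a$vertices, b$vertices)
  d2 <- nn_dist(b$vertices, a$vertices)
  max(max(d1), max(d2))
}

# nearest-neighbour distances from each row of x to the point set y,
# blocked to bound memory
nn_dist <- function(x, y, block = 2048L) {
  n <- nrow(x)
  out <- numeric(n)
  y2 <- rowSums(y^2)
  for (s in seq(1L, n, by = block)) {
    e <- min(s + block - 1L, n)
    xb <- x[s:e, , drop = FALSE]
    d2 <- outer(rowSums(xb^2), y2, "+") - 2 * tcrossprod(xb, y)
    out[s:e] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}
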