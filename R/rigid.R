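#' Proper rigid transform (rotation + translation)
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation length-3 numeric vector (mm).
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3, 3))) stop("rotation must be 3x3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6) stop("rotation not orthonormal")
  if (det(rotation) < 0) stop("rotation must be proper (det +1), not a reflection")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("rigid_transform: rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Apply a rigid transform to points, a mesh, or landmarks
#'
#' Points map as `x -> R x + t`. Mesh normals rotate without translation.
#'
#' @param transform a [rigid_transform()].
#' @param x an `n x 3` matrix, [surface_mesh()] or [landmark_set()].
#' @return transformed object of the same type.
#' @export
apply_transform <- function(transform, x) {
  if (inherits(x, "surface_mesh")) {
    x$vertices <- apply_transform(transform, x$vertices)
    if (!is.null(x$normals)) x$normals <- x$normals %*% t(transform$rotation)
    return(x)
  }
  if (inherits(x, "landmark_set")) {
    return(landmark_set(apply_transform(transform, unclass(x)), names = rownames(x)))
  }
  sweep(as.matrix(x) %*% t(transform$rotation), 2, transform$translation, "+")
}

#' Compose two rigid transforms: `(a %then% b)(x) = b(a(x))`
#' @param a,b [rigid_transform()] objects.
#' @return the composed [rigid_transform()].
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(b$rotation %*% a$rotation,
                  as.numeric(b$rotation %*% a$translation) + b$translation)
}

#' Invert a rigid transform
#' @param transform a [rigid_transform()].
#' @return the inverse [rigid_transform()].
#' @export
invert_transform <- function(transform) {
  rt <- t(transform$rotation)
  rigid_transform(rt, as.numeric(-rt %*% transform$translation))
}

#' Rodrigues' rotation matrix
#'
#' Rotation by `angle` radians about the unit `axis`:
#' `R = I + sin(angle) K + (1 - cos(angle)) K^2` with `K` the cross-product
#' matrix of the axis.
#'
#' @param axis length-3 vector (normalised internally).
#' @param angle rotation angle in radians.
#' @return 3x3 rotation matrix.
#' @export
rodrigues_rotation <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) return(diag(3))
  a <- axis / n
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Mirror a mesh and its landmarks across the x = 0 plane
#'
#' Negates x coordinates of vertices and landmarks and flips face winding so
#' that outward normals stay outward (a reflection alone reverses
#' orientation).
#'
#' @param mesh a [surface_mesh()].
#' @param landmarks optional [landmark_set()] mirrored alongside.
#' @return list with `mesh` and `landmarks` (NULL if not supplied).
#' @export
mirror_x <- function(mesh, landmarks = NULL) {
  mesh$vertices[, 1] <- -mesh$vertices[, 1]
  mesh$faces <- mesh$faces[, c(1, 3, 2), drop = FALSE]
  if (!is.null(mesh$normals)) mesh$normals[, 1] <- -mesh$normals[, 1]
  if (!is.null(landmarks)) {
    lm <- unclass(landmarks)
    lm[, 1] <- -lm[, 1]
    landmarks <- landmark_set(lm, names = rownames(landmarks))
  }
  list(mesh = mesh, landmarks = landmarks)
}

#' Align the principal axis of a mesh with +z
#'
#' The first principal axis of the vertex cloud (leading eigenvector of the
#' vertex covariance) is rotated onto +z with a single Rodrigues rotation
#' about `cross(axis, z)`. The axis sign is fixed anatomically: the end
#' nearer the RS landmark (the flared articular end) gets larger z.
#'
#' @param mesh a [surface_mesh()] with at least 3 non-collinear vertices.
#' @param landmarks a [landmark_set()] containing `RS`, co-rotated.
#' @return list with `mesh`, `landmarks`, `transform` (the applied
#'   [rigid_transform()], rotation about the centroid-free origin).
#' @export
principal_axis_align <- function(mesh, landmarks) {
  v <- mesh$vertices
  ev <- eigen(stats::cov(v), symmetric = TRUE)
  if (ev$values[1] < 1e-9 || ev$values[1] / max(ev$values[2], 1e-300) < 1 + 1e-6) {
    if (ev$values[1] - ev$values[2] < 1e-9 * ev$values[1]) {
      stop("ambiguous principal axis: vertex cloud is isotropic in its leading directions")
    }
  }
  axis1 <- ev$vectors[, 1]
  ctr <- colMeans(v)
  rs <- get_landmark(landmarks, "RS")
  # articular end (nearer RS) toward +z
  if (sum((rs - ctr) * axis1) < 0) axis1 <- -axis1
  zhat <- c(0, 0, 1)
  cr <- c(axis1[2] * zhat[3] - axis1[3] * zhat[2],
          axis1[3] * zhat[1] - axis1[1] * zhat[3],
          axis1[1] * zhat[2] - axis1[2] * zhat[1])
  s <- sqrt(sum(cr^2))
  cth <- sum(axis1 * zhat)
  R <- if (s < 1e-12) {
    if (cth > 0) diag(3) else rodrigues_rotation(c(1, 0, 0), pi)
  } else {
    rodrigues_rotation(cr, atan2(s, cth))
  }
  tr <- rigid_transform(R, c(0, 0, 0))
  list(mesh = apply_transform(tr, mesh),
       landmarks = apply_transform(tr, landmarks),
       transform = tr)
}

#' Translate the lowest vertex of a z-aligned mesh to the origin
#'
#' The full 3D position of the minimum-z vertex is moved to (0, 0, 0);
#' landmarks are co-translated.
#'
#' @param mesh a [surface_mesh()].
#' @param landmarks optional [landmark_set()].
#' @return list with `mesh`, `landmarks`, `transform`.
#' @export
shift_lowest_to_origin <- function(mesh, landmarks = NULL) {
  i <- which.min(mesh$vertices[, 3])
  tr <- rigid_transform(diag(3), -mesh$vertices[i, ])
  list(mesh = apply_transform(tr, mesh),
       landmarks = if (is.null(landmarks)) NULL else apply_transform(tr, landmarks),
       transform = tr)
}

#' Crop a mesh with a cutting plane
#'
#' Keeps the half-space `(x - point) . normal <= 0` (`keep = "below"`) or
#' `>= 0` (`keep = "above"`). Faces crossing the plane are clipped, with new
#' vertices interpolated on the plane, so the cut is geometrically exact.
#'
#' @param mesh a [surface_mesh()].
#' @param point a point on the plane (mm).
#' @param normal plane normal (need not be unit length).
#' @param keep `"below"` or `"above"`.
#' @return the cropped [surface_mesh()] (open along the cut).
#' @export
crop_by_plane <- function(mesh, point, normal, keep = c("below", "above")) {
  keep <- match.arg(keep)
  nrm <- as.numeric(normal)
  if (keep == "above") nrm <- -nrm
  v <- mesh$vertices
  d <- as.numeric((v - matrix(point, nrow(v), 3, byrow = TRUE)) %*% nrm)
  eps <- 1e-12 * max(1, max(abs(d)))
  inside <- d <= eps
  f <- mesh$faces
  fin <- matrix(inside[f], ncol = 3)
  nin <- rowSums(fin)
  keep_faces <- f[nin == 3L, , drop = FALSE]
  cross_idx <- which(nin == 1L | nin == 2L)

  new_v <- list()
  new_f <- list()
  # interpolated cut vertex on edge (i, j), cached per directed-sorted edge
  edge_cache <- new.env(hash = TRUE)
  next_id <- nrow(v)
  cut_vertex <- function(i, j) {
    key <- paste(min(i, j), max(i, j))
    hit <- edge_cache[[key]]
    if (!is.null(hit)) return(hit)
    t <- d[i] / (d[i] - d[j])
    p <- v[i, ] + t * (v[j, ] - v[i, ])
    next_id <<- next_id + 1L
    new_v[[length(new_v) + 1L]] <<- p
    edge_cache[[key]] <- next_id
    next_id
  }
  for (fi in cross_idx) {
    tri <- f[fi, ]
    ins <- inside[tri]
    if (sum(ins) == 1L) {
      # one vertex kept: single clipped triangle; cyclic rotation keeps winding
      k <- which(ins)
      rot <- tri[c(k, (k %% 3) + 1, ((k + 1) %% 3) + 1)]
      p1 <- cut_vertex(rot[1], rot[2])
      p2 <- cut_vertex(rot[1], rot[3])
      new_f[[length(new_f) + 1L]] <- c(rot[1], p1, p2)
    } else {
      # two vertices kept: quad split into two triangles
      out_pos <- which(!ins)
      rot <- tri[c(out_pos, (out_pos %% 3) + 1, ((out_pos + 1) %% 3) + 1)]
      # rot[1] outside, rot[2], rot[3] inside
      p1 <- cut_vertex(rot[2], rot[1])
      p2 <- cut_vertex(rot[3], rot[1])
      new_f[[length(new_f) + 1L]] <- c(rot[2], rot[3], p1)
      new_f[[length(new_f) + 1L]] <- c(rot[3], p2, p1)
    }
  }
  all_v <- rbind(v, do.call(rbind, new_v))
  all_f <- rbind(keep_faces, do.call(rbind, new_f))
  if (is.null(all_f) || nrow(all_f) == 0L) stop("crop removed the whole mesh")
  out <- drop_unused_vertices(all_v, all_f)
  m <- surface_mesh(out$vertices, out$faces, validate = FALSE)
  if (!is.null(mesh$normals)) m <- compute_vertex_normals(m)
  m
}

#' Least-squares rigid alignment of paired points (Kabsch)
#'
#' Finds the proper rotation (det +1, no scaling, no reflection) and
#' translation minimising the sum of squared residuals mapping
#' `source_points` onto `target_points`.
#'
#' @param source_points,target_points matched `k x 3` matrices, `k >= 3`,
#'   non-collinear.
#' @return a [rigid_transform()].
#' @export
rigid_align_landmarks <- function(source_points, target_points) {
  s <- as.matrix(source_points)
  t2 <- as.matrix(target_points)
  if (nrow(s) != nrow(t2) || nrow(s) < 3) stop("need >= 3 paired points")
  cs <- colMeans(s)
  ct <- colMeans(t2)
  sc <- sweep(s, 2, cs)
  tc <- sweep(t2, 2, ct)
  sv <- svd(crossprod(sc, tc))
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1e-300)) {
    stop("degenerate configuration: points are collinear")
  }
  sgn <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, sgn))
  R <- sv$v %*% D %*% t(sv$u)
  rigid_transform(R, ct - as.numeric(R %*% cs))
}

#' Per-vertex articular mask from the DSN plane
#'
#' Vertices at or distal to the plane through the DSN landmark,
#' perpendicular to the bone (z) axis.
#'
#' @param mesh a z-aligned [surface_mesh()].
#' @param landmarks a [landmark_set()] with `DSN`.
#' @return logical vector, one flag per vertex.
#' @export
articular_mask <- function(mesh, landmarks) {
  z_dsn <- get_landmark(landmarks, "DSN")[3]
  mesh$vertices[, 3] >= z_dsn - 1e-9
}

#' Isolate the articular surface
#'
#' Sub-mesh of vertices with `z >= z(DSN)` (faces kept when all three
#' vertices qualify), matching a brute-force vertex filter exactly.
#'
#' @inheritParams articular_mask
#' @return the articular [surface_mesh()].
#' @export
isolate_articular_surface <- function(mesh, landmarks) {
  keep <- articular_mask(mesh, landmarks)
  if (!any(keep)) stop("DSN plane above all vertices: empty articular surface")
  f <- mesh$faces
  fk <- f[keep[f[, 1]] & keep[f[, 2]] & keep[f[, 3]], , drop = FALSE]
  if (nrow(fk) == 0L) stop("no complete faces distal to the DSN plane")
  out <- drop_unused_vertices(mesh$vertices, fk)
  m <- surface_mesh(out$vertices, out$faces, validate = FALSE)
  if (!is.null(mesh$normals)) m$normals <- mesh$normals[out$kept, , drop = FALSE]
  m
}
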