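# face centers and area-weighted normals, with zero-area faces dropped
varifold_faces <- function(mesh, warn = TRUE) {
  fg <- face_geometry(mesh)
  ok <- fg$areas > 1e-12
  if (!all(ok) && warn) {
    warning(sum(!ok), " zero-area face(s) skipped in varifold computation")
  }
  list(centers = fg$centers[ok, , drop = FALSE],
       normals = fg$normals[ok, , drop = FALSE],
       areas = fg$areas[ok])
}

# <A,B> = sum_pq exp(-||f_p - g_q||^2 / s^2) (n_p . m_q)^2 / (|n_p| |m_q|)
varifold_inner <- function(fa, fb, sigma) {
  Km <- gaussian_kernel(fa$centers, fb$centers, sigma)
  Dot <- tcrossprod(fa$normals, fb$normals)
  sum(Km * Dot^2 / outer(fa$areas, fb$areas))
}

#' Squared varifold distance between two surfaces
#'
#' Unoriented kernel discrepancy built from face centres `f` and
#' area-weighted face normals `n`:
#' `<A,B> = sum_pq exp(-||f_p - g_q||^2/sigma_W^2) (n_p . m_q)^2 / (|n_p||m_q|)`
#' and `d^2 = <A,A> - 2<A,B> + <B,B>`. The squared-cosine normal term makes
#' the value invariant to face orientation flips, so inconsistent winding
#' cannot masquerade as shape difference.
#'
#' @param a,b [surface_mesh()] objects with at least one face each.
#' @param sigma_w spatial kernel width in mm.
#' @return non-negative scalar (squared pseudo-metric).
#' @export
varifold_distance_sq <- function(a, b, sigma_w) {
  stopifnot(sigma_w > 0)
  fa <- varifold_faces(a)
  fb <- varifold_faces(b)
  if (nrow(fa$centers) == 0L || nrow(fb$centers) == 0L) {
    stop("varifold distance needs at least one non-degenerate face per mesh")
  }
  d2 <- varifold_inner(fa, fa, sigma_w) - 2 * varifold_inner(fa, fb, sigma_w) +
    varifold_inner(fb, fb, sigma_w)
  max(d2, 0)
}

# gradient of varifold_distance_sq(a, b) with respect to the vertices of
# mesh `a` (faces of `a` fixed, mesh `b` fixed). Returns an n x 3 matrix.
varifold_gradient <- function(vertices_a, faces_a, fb, sigma_w) {
  mesh_a <- surface_mesh(vertices_a, faces_a, validate = FALSE)
  fg <- face_geometry(mesh_a)
  areas <- pmax(fg$areas, 1e-12)
  FA <- fg$centers
  NA_ <- fg$normals
  s2 <- sigma_w^2

  grad_F <- matrix(0, nrow(FA), 3)   # d E / d face-centers
  grad_N <- matrix(0, nrow(FA), 3)   # d E / d area-normals

  accumulate <- function(Fb, Nb, ab, coef) {
    # coef = +1 for the <A,A> self term (factor 2 from symmetry applied
    # here), coef = -2 for the cross term
    Km <- gaussian_kernel(FA, Fb, sigma_w)
    Dot <- tcrossprod(NA_, Nb)
    Ainv <- outer(areas, ab)
    Psi <- Dot^2 / Ainv
    W <- Km * Psi
    mult <- if (coef > 0) 2 else -2   # both-slots factor for self term
    # center path: d k / d f = -(2/s2) (f - g) k
    cf <- mult * (-2 / s2)
    grad_F <<- grad_F + cf * (rowSums(W) * FA - W %*% Fb)
    # normal path: d psi / d n = 2 (n.m) m / (|n||m|) - psi n / |n|^2
    U <- Km * Dot / Ainv
    grad_N <<- grad_N + mult * (2 * (U %*% Nb) - (rowSums(W) / areas^2) * NA_)
  }
  accumulate(FA, NA_, areas, +1)
  accumulate(fb$centers, fb$normals, fb$areas, -2)

  # chain to vertices: center = (a+b+c)/3; N = 0.5 (b-a) x (c-a)
  v <- vertices_a
  f <- faces_a
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  u <- grad_N
  ca <- c3 - a
  ba <- b - a
  gb <- 0.5 * cross3(ca, u)          # dN/db^T u = 0.5 (c-a) x u
  gc <- 0.5 * cross3(u, ba)          # dN/dc^T u = 0.5 u x (b-a)
  ga <- -gb - gc
  gcen <- grad_F / 3
  out <- matrix(0, nrow(v), 3)
  for (k in 1:3) {
    g <- switch(k, ga, gb, gc) + gcen
    for (d in 1:3) {
      acc <- rowsum(g[, d], group = f[, k], reorder = FALSE)
      idx <- as.integer(rownames(acc))
      out[idx, d] <- out[idx, d] + acc[, 1]
    }
  }
  out
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}
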