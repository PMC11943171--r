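#' Icosphere test surface
#'
#' Geodesic sphere: subdivided icosahedron projected onto the sphere.
#' Closed, manifold, nearly uniform triangles; the standard analytic test
#' surface (area `4 pi r^2`, volume `4/3 pi r^3`).
#'
#' @param radius sphere radius in mm.
#' @param subdivisions number of 4-to-1 face subdivisions (0 gives the
#'   icosahedron, n gives `20 * 4^n` faces).
#' @param center sphere centre (mm).
#' @return a [surface_mesh()] with outward normals.
#' @export
icosphere <- function(radius = 1, subdivisions = 3, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (s in seq_len(subdivisions)) {
    edge_mid <- new.env(hash = TRUE)
    nv <- nrow(v)
    newv <- list()
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- edge_mid[[key]]
      if (!is.null(hit)) return(hit)
      m <- v[i, ] + v[j, ]
      m <- m / sqrt(sum(m^2))
      nv <<- nv + 1L
      newv[[length(newv) + 1L]] <<- m
      edge_mid[[key]] <- nv
      nv
    }
    nf <- matrix(0L, 4 * nrow(f), 3)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; cc <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf[(4 * t - 3):(4 * t), ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc), c(ab, bc, ca)
      )
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- nf
  }
  verts <- sweep(radius * v, 2, center, "+")
  m <- surface_mesh(verts, f)
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2), drop = FALSE]
  compute_vertex_normals(m)
}
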