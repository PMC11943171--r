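#' Gaussian kernel matrix
#'
#' `K[i, j] = exp(-||x_i - y_j||^2 / sigma^2)`. Note the convention: no
#' factor 2 in the denominator, so `sigma` is the e-folding distance of the
#' squared separation. All kernel widths in the package (deformation
#' `sigma_V`, attachment `sigma_W`, their defaults 2 mm and 4 mm) follow
#' this convention.
#'
#' @param x,y point matrices (`N x 3`, `M x 3`), mm.
#' @param sigma kernel width in mm, `> 0`.
#' @return `N x M` matrix with entries in (0, 1].
#' @export
gaussian_kernel <- function(x, y, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("kernel width sigma must be a positive scalar")
  }
  x <- as.matrix(x)
  y <- as.matrix(y)
  d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
  exp(-pmax(d2, 0) / sigma^2)
}

#' Regular control-point grid around a mesh
#'
#' Axis-aligned grid with step `spacing` covering the mesh bounding box
#' padded by one spacing, keeping only points within `2 * spacing` of the
#' surface (vertex cloud) so momenta are not wasted far from the shape.
#'
#' @param mesh a [surface_mesh()].
#' @param spacing grid step in mm (the deformation kernel width is the
#'   natural choice).
#' @param keep_radius_factor discard points farther than this multiple of
#'   `spacing` from the nearest vertex.
#' @return `K x 3` matrix of control points.
#' @export
make_control_grid <- function(mesh, spacing, keep_radius_factor = 2) {
  stopifnot(spacing > 0)
  lo <- apply(mesh$vertices, 2, min) - spacing
  hi <- apply(mesh$vertices, 2, max) + spacing
  ax <- lapply(1:3, function(d) seq(lo[d], hi[d] + spacing / 2, by = spacing))
  grid <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]], KEEP.OUT.ATTRS = FALSE))
  colnames(grid) <- NULL
  d <- nn_dist(grid, mesh$vertices)
  pts <- grid[d <= keep_radius_factor * spacing, , drop = FALSE]
  if (nrow(pts) == 0L) stop("control grid is empty; spacing too large?")
  pts
}
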