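#' Decimate a mesh to a target vertex count
#'
#' Quadric-error-metric edge collapse with boundary preservation. Collapses
#' proceed in increasing quadric-cost order until the target vertex count is
#' reached; the placement of each merged vertex minimises the summed quadric
#' of its endpoints.
#'
#' @param mesh a [surface_mesh()].
#' @param target_vertex_count desired vertex count; the result lands within
#'   about 2% (exact for manifold interiors, collapses stop at the first
#'   count `<=` target).
#' @return the decimated [surface_mesh()] (normals recomputed if present on
#'   input). If `target_vertex_count >= n_vertices(mesh)`, the input is
#'   returned unchanged with a warning.
#' @export
decimate <- function(mesh, target_vertex_count) {
  stopifnot(target_vertex_count > 0)
  if (target_vertex_count >= nrow(mesh$vertices)) {
    if (target_vertex_count > nrow(mesh$vertices)) {
      warning("target vertex count >= current count: returning mesh unchanged")
    }
    return(mesh)
  }
  res <- .decimate_qem(mesh$vertices, mesh$faces, as.integer(target_vertex_count))
  out <- surface_mesh(res$vertices, res$faces, validate = FALSE)
  if (!is.null(mesh$normals)) out <- compute_vertex_normals(out)
  out
}
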