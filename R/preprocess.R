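#' Default preprocessing configuration
#'
#' Constants of the rigid preprocessing chain: first crop at 50 mm, final
#' crop at 43 mm, decimation budget of 5295 vertices.
#'
#' @param crop_long_mm length of the first crop from the distal end (mm).
#' @param crop_final_mm final uniform mesh length (mm).
#' @param target_vertices decimation target vertex count.
#' @return a named list of preprocessing constants.
#' @export
preprocess_config <- function(crop_long_mm = 50, crop_final_mm = 43,
                              target_vertices = 5295) {
  stopifnot(crop_long_mm > 0, crop_final_mm > 0, crop_final_mm <= crop_long_mm,
            target_vertices > 0)
  list(crop_long_mm = crop_long_mm, crop_final_mm = crop_final_mm,
       target_vertices = target_vertices)
}

# z-align, origin-shift and crop one mesh to `crop_mm` from the distal (+z)
# end; the distal end is put at high z by the RS-guided axis sign
align_and_crop <- function(mesh, landmarks, crop_mm) {
  al <- principal_axis_align(mesh, landmarks)
  sh <- shift_lowest_to_origin(al$mesh, al$landmarks)
  mesh <- sh$mesh
  landmarks <- sh$landmarks
  zmax <- max(mesh$vertices[, 3])
  if (zmax > crop_mm) {
    # keep the distal `crop_mm` millimetres, then re-seat the cut at z = 0
    mesh <- crop_by_plane(mesh, c(0, 0, zmax - crop_mm), c(0, 0, 1), keep = "above")
    sh <- shift_lowest_to_origin(mesh, landmarks)
    mesh <- sh$mesh
    landmarks <- sh$landmarks
  }
  list(mesh = mesh, landmarks = landmarks)
}

#' Rigid preprocessing of a left/right mesh pair into a corresponded frame
#'
#' Runs the four-step chain: (1) mirror the right mesh (and landmarks)
#' across the x axis; (2) align both meshes along z by principal axis
#' (Rodrigues rotation), shift the lowest vertex to the origin and crop to
#' `crop_long_mm`; (3) rigidly align the mirrored right onto the left by
#' least squares over RS, DSN and the mesh centroid; (4) crop both to
#' `crop_final_mm` and decimate to the target vertex budget.
#'
#' @param left,right lists with elements `mesh` ([surface_mesh()]) and
#'   `landmarks` ([landmark_set()] with RS and DSN).
#' @param config a [preprocess_config()].
#' @param mirror_right mirror the right mesh first (disable when the input
#'   pair is already in one chirality).
#' @return list with `left` and `right` (each `mesh` + `landmarks`), ready
#'   for registration.
#' @export
preprocess_pair <- function(left, right, config = preprocess_config(),
                            mirror_right = TRUE) {
  validate_landmarks(left$landmarks, left$mesh)
  validate_landmarks(right$landmarks, right$mesh)
  # Step 1: mirror right
  if (mirror_right) {
    mr <- mirror_x(right$mesh, right$landmarks)
    right <- list(mesh = mr$mesh, landmarks = mr$landmarks)
  }
  # Step 2: z-align, origin shift, first crop
  lt <- align_and_crop(left$mesh, left$landmarks, config$crop_long_mm)
  rt <- align_and_crop(right$mesh, right$landmarks, config$crop_long_mm)
  # Step 3: rigid-align right onto left via RS, DSN, centroid
  src <- rbind(get_landmark(rt$landmarks, "RS"),
               get_landmark(rt$landmarks, "DSN"),
               colMeans(rt$mesh$vertices))
  tgt <- rbind(get_landmark(lt$landmarks, "RS"),
               get_landmark(lt$landmarks, "DSN"),
               colMeans(lt$mesh$vertices))
  tr <- rigid_align_landmarks(src, tgt)
  rt$mesh <- apply_transform(tr, rt$mesh)
  rt$landmarks <- apply_transform(tr, rt$landmarks)
  # Step 4: final crop to a common length and decimation. Only z moves here:
  # a full lowest-vertex shift per side would break the shared lateral frame
  # established in step 3.
  finalize <- function(s) {
    zmax <- max(s$mesh$vertices[, 3])
    if (zmax > config$crop_final_mm) {
      m <- crop_by_plane(s$mesh, c(0, 0, zmax - config$crop_final_mm),
                         c(0, 0, 1), keep = "above")
      tr <- rigid_transform(diag(3), c(0, 0, -(zmax - config$crop_final_mm)))
      s$mesh <- apply_transform(tr, m)
      s$landmarks <- apply_transform(tr, s$landmarks)
    }
    s$mesh <- compute_vertex_normals(decimate(s$mesh, config$target_vertices))
    s
  }
  lt <- finalize(lt)
  rt <- finalize(rt)
  list(left = lt, right = rt)
}
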