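#' Run configuration for the analysis pipelines
#'
#' Bundles every knob of a pairwise or atlas run; the configuration is
#' serialized verbatim into the output manifest so a run is reproducible
#' from the manifest alone.
#'
#' @param mode `"pairwise"` or `"atlas"`.
#' @param deformation a [deformation_params()].
#' @param preprocess a [preprocess_config()].
#' @param articular compute articular-subset statistics (DSN plane mask).
#' @param kpca_gamma RBF bandwidth for the momenta kernel PCA (`NULL`: the
#'   `1 / (p * var)` default).
#' @param kpca_components number of score columns to keep.
#' @param seed integer seed for any stochastic component.
#' @return a named list of class `run_config`.
#' @export
run_config <- function(mode = c("pairwise", "atlas"),
                       deformation = deformation_params(),
                       preprocess = preprocess_config(),
                       articular = TRUE,
                       kpca_gamma = NULL,
                       kpca_components = 2L,
                       seed = 1L) {
  mode <- match.arg(mode)
  structure(list(mode = mode, deformation = deformation,
                 preprocess = preprocess, articular = articular,
                 kpca_gamma = kpca_gamma,
                 kpca_components = as.integer(kpca_components),
                 seed = as.integer(seed)),
            class = "run_config")
}

as_cohort <- function(cohort) {
  if (inherits(cohort, "phantom_cohort")) return(cohort)
  if (is.character(cohort) && dir.exists(cohort)) return(read_cohort(cohort))
  stop("cohort must be a phantom_cohort or a cohort directory")
}

write_manifest <- function(config, out_dir, extra = list()) {
  m <- c(list(package = "radsym",
              version = as.character(utils::packageVersion("radsym")),
              mode = config$mode,
              deformation = unclass(config$deformation),
              preprocess = config$preprocess,
              articular = config$articular,
              kpca_gamma = config$kpca_gamma,
              kpca_components = config$kpca_components,
              seed = config$seed),
         extra)
  jsonlite::write_json(m, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

log_stage <- function(log, subject, stage, t0, note = "") {
  msg <- sprintf("[%s] %s: %.2fs %s", subject, stage,
                 as.numeric(Sys.time()) - t0, note)
  message(msg)
  c(log, msg)
}

#' Pairwise (intra-individual) symmetry analysis of a cohort
#'
#' For every subject: rigid preprocessing of the left/right pair
#' ([preprocess_pair()]), diffeomorphic registration of the mirrored right
#' onto the left, signed correspondence distances (whole bone and articular
#' subset) and per-subject summaries. Cohort level: summary and boxplot
#' CSVs, the momenta matrix, kernel PCA of standardized momenta and the
#' group-testing cascade. A shared control-point grid (built over the
#' preprocessed meshes of all subjects, which live in compatible
#' origin-anchored frames) makes the momenta comparable across subjects.
#'
#' Subject failures are logged and skipped; the run fails only when every
#' subject fails.
#'
#' @param cohort a `phantom_cohort` or a cohort directory
#'   ([write_cohort()] layout).
#' @param config a [run_config()] with `mode = "pairwise"`.
#' @param out_dir results directory (created).
#' @return invisible list: `per_subject` (data.frame), `fields`, `momenta`,
#'   `kpca`, `tests`, `out_dir`.
#' @export
run_pairwise_analysis <- function(cohort, config = run_config("pairwise"),
                                  out_dir = "pairwise_results") {
  cohort <- as_cohort(cohort)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- character(0)

  # pass 1: rigid preprocessing of every pair
  pre <- list()
  for (s in cohort$subjects) {
    t0 <- as.numeric(Sys.time())
    res <- tryCatch(preprocess_pair(s$left, s$right, config$preprocess),
                    error = function(e) e)
    if (inherits(res, "error")) {
      log <- log_stage(log, s$id, "preprocess FAILED", t0, conditionMessage(res))
      next
    }
    pre[[s$id]] <- res
    log <- log_stage(log, s$id, "preprocess", t0)
  }
  if (!length(pre)) stop("all subjects failed preprocessing")

  # shared control grid over the union bounding box of all preprocessed
  # meshes (frames are origin-anchored and z-cropped identically)
  allv <- do.call(rbind, lapply(pre, function(p) {
    rbind(p$left$mesh$vertices, p$right$mesh$vertices)
  }))
  grid_mesh <- surface_mesh(allv, matrix(c(1L, 2L, 3L), 1, 3), validate = FALSE)
  spacing <- if (is.null(config$deformation$control_spacing)) {
    config$deformation$deformation_kernel_width
  } else {
    config$deformation$control_spacing
  }
  ctrl <- make_control_grid(grid_mesh, spacing)

  fields <- list()
  momenta <- list()
  reginfo <- list()
  for (id in names(pre)) {
    t0 <- as.numeric(Sys.time())
    p <- pre[[id]]
    res <- tryCatch({
      reg <- register(p$right$mesh, p$left$mesh, config$deformation,
                      control_points = ctrl)
      mask <- if (config$articular) articular_mask(p$right$mesh, p$right$landmarks) else NULL
      fld <- signed_distance(p$right$mesh, reg$deformed_source, mask = mask)
      list(reg = reg, fld = fld)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      log <- log_stage(log, id, "register FAILED", t0, conditionMessage(res))
      next
    }
    fields[[id]] <- res$fld
    momenta[[id]] <- res$reg$state$momenta
    reginfo[[id]] <- data.frame(
      subject = id, n_iterations = res$reg$n_iterations,
      converged = res$reg$converged,
      initial_attachment = res$reg$initial_attachment,
      final_attachment = res$reg$final_attachment,
      final_regularity = res$reg$final_regularity
    )
    log <- log_stage(log, id, "register", t0,
                     sprintf("(%d iter, attach %.3g -> %.3g)",
                             res$reg$n_iterations, res$reg$initial_attachment,
                             res$reg$final_attachment))
  }
  if (!length(fields)) stop("all subjects failed registration")

  groups <- cohort$metadata$group[match(names(fields), cohort$metadata$subject)]
  rep_out <- render_distance_report(fields, groups, out_dir)
  utils::write.csv(do.call(rbind, reginfo),
                   file.path(out_dir, "registration_log.csv"), row.names = FALSE)

  kp <- NULL
  tests <- NULL
  if (length(momenta) >= 3) {
    X <- standardize_momenta(momenta)
    utils::write.table(X, file.path(out_dir, "momenta_standardized.txt"),
                       row.names = FALSE, col.names = FALSE)
    kp <- kpca_rbf(X, gamma = config$kpca_gamma,
                   n_components = config$kpca_components)
    if (length(unique(groups)) > 1 && all(table(groups) >= 3)) {
      tests <- group_tests(kp$scores, groups)
      write_test_report(tests, file.path(out_dir, "group_tests.csv"))
    }
    utils::write.csv(
      data.frame(subject = names(fields), group = groups, kp$scores),
      file.path(out_dir, "kpca_scores.csv"), row.names = FALSE
    )
  }
  write_manifest(config, out_dir,
                 list(n_subjects = length(fields),
                      n_control_points = nrow(ctrl)))
  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(list(per_subject = rep_out$summary, fields = fields,
                 momenta = momenta, kpca = kp, tests = tests,
                 control_points = ctrl, out_dir = out_dir))
}

write_test_report <- function(tests, path) {
  rows <- do.call(rbind, lapply(names(tests$components), function(nm) {
    comp <- tests$components[[nm]]
    rbind(
      data.frame(component = nm, test = "shapiro_wilk", group1 = NA, group2 = NA,
                 p = comp$shapiro_p),
      data.frame(component = nm, test = "kruskal_wallis", group1 = NA, group2 = NA,
                 p = comp$kruskal_p),
      data.frame(component = nm, test = "welch",
                 group1 = comp$welch$group1, group2 = comp$welch$group2,
                 p = comp$welch$p)
    )
  }))
  rows$significant <- rows$p < tests$alpha & rows$test != "shapiro_wilk"
  utils::write.csv(rows, path, row.names = FALSE)
}

# atlas-mode rigid preprocessing: mirror left sides into the reference
# (right) chirality, z-align, origin-shift, crop, then rigid-align onto the
# reference via RS, DSN, DDR and the centroid
atlas_preprocess_one <- function(mesh, landmarks, side, reference, config) {
  if (side == "left") {
    mr <- mirror_x(mesh, landmarks)
    mesh <- mr$mesh
    landmarks <- mr$landmarks
  }
  ac <- align_and_crop(mesh, landmarks, config$crop_long_mm)
  if (!is.null(reference)) {
    src <- rbind(get_landmark(ac$landmarks, "RS"),
                 get_landmark(ac$landmarks, "DSN"),
                 get_landmark(ac$landmarks, "DDR"),
                 colMeans(ac$mesh$vertices))
    tgt <- rbind(get_landmark(reference$landmarks, "RS"),
                 get_landmark(reference$landmarks, "DSN"),
                 get_landmark(reference$landmarks, "DDR"),
                 colMeans(reference$mesh$vertices))
    tr <- rigid_align_landmarks(src, tgt)
    ac$mesh <- apply_transform(tr, ac$mesh)
    ac$landmarks <- apply_transform(tr, ac$landmarks)
  }
  zmax <- max(ac$mesh$vertices[, 3])
  if (zmax > config$crop_final_mm) {
    m <- crop_by_plane(ac$mesh, c(0, 0, zmax - config$crop_final_mm),
                       c(0, 0, 1), keep = "above")
    tr <- rigid_transform(diag(3), c(0, 0, -(zmax - config$crop_final_mm)))
    ac$mesh <- apply_transform(tr, m)
    ac$landmarks <- apply_transform(tr, ac$landmarks)
  }
  ac$mesh <- compute_vertex_normals(decimate(ac$mesh, config$target_vertices))
  ac
}

#' Atlas (inter-individual) shape analysis of a cohort
#'
#' Two-pass atlas scheme: all meshes (both sides, left sides mirrored into
#' the reference chirality) are rigidly aligned to the first subject's
#' right mesh via RS, DSN, DDR and the centroid; a deterministic atlas with
#' the first subject's right mesh as frozen template yields corresponded
#' deformations, whose mean ([build_mean_shape()]) becomes the atlas; the
#' atlas is then re-registered to every mesh and signed distances from the
#' atlas are summarised per mesh (`l`/`r` rows per subject). Momenta of the
#' second pass feed the kernel PCA and group tests.
#'
#' @inheritParams run_pairwise_analysis
#' @param config a [run_config()] with `mode = "atlas"`.
#' @return invisible list: `atlas` mesh, `mean_landmarks`, `per_mesh`
#'   summary data.frame, `fields`, `momenta`, `kpca`, `tests`, `out_dir`.
#' @export
run_atlas_analysis <- function(cohort, config = run_config("atlas"),
                               out_dir = "atlas_results") {
  cohort <- as_cohort(cohort)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- character(0)

  ids <- names(cohort$subjects)
  first <- cohort$subjects[[1]]
  t0 <- as.numeric(Sys.time())
  reference <- atlas_preprocess_one(first$right$mesh, first$right$landmarks,
                                    side = "right", reference = NULL,
                                    config = config$preprocess)
  log <- log_stage(log, ids[1], "reference preprocess", t0)

  meshes <- list()
  lms <- list()
  for (id in ids) {
    s <- cohort$subjects[[id]]
    for (side in c("l", "r")) {
      t0 <- as.numeric(Sys.time())
      key <- paste0(id, "_", side)
      inp <- if (side == "l") s$left else s$right
      res <- tryCatch(
        atlas_preprocess_one(inp$mesh, inp$landmarks,
                             side = if (side == "l") "left" else "right",
                             reference = reference, config = config$preprocess),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        log <- log_stage(log, key, "preprocess FAILED", t0, conditionMessage(res))
        next
      }
      meshes[[key]] <- res$mesh
      lms[[key]] <- res$landmarks
      log <- log_stage(log, key, "preprocess", t0)
    }
  }
  if (!length(meshes)) stop("all meshes failed atlas preprocessing")

  # pass 1: deterministic atlas from the reference template
  t0 <- as.numeric(Sys.time())
  template <- reference$mesh
  spacing <- if (is.null(config$deformation$control_spacing)) {
    config$deformation$deformation_kernel_width
  } else {
    config$deformation$control_spacing
  }
  ctrl <- make_control_grid(template, spacing)
  at1 <- deterministic_atlas(template, meshes, config$deformation,
                             control_points = ctrl)
  atlas_mesh <- build_mean_shape(lapply(at1$registrations, `[[`, "deformed"))
  mean_lm <- mean_landmarks(lms)
  log <- log_stage(log, "cohort", "atlas pass 1", t0,
                   sprintf("(%d meshes, cost %.4g)", length(meshes), at1$final_cost))

  # pass 2: register the frozen atlas to every mesh
  fields <- list()
  momenta <- list()
  per_mesh <- list()
  mask <- if (config$articular) articular_mask(atlas_mesh, mean_lm) else NULL
  for (key in names(meshes)) {
    t0 <- as.numeric(Sys.time())
    res <- tryCatch({
      reg <- register(atlas_mesh, meshes[[key]], config$deformation,
                      control_points = ctrl)
      fld <- signed_distance(atlas_mesh, reg$deformed_source, mask = mask)
      list(reg = reg, fld = fld)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      log <- log_stage(log, key, "atlas register FAILED", t0, conditionMessage(res))
      next
    }
    fields[[key]] <- res$fld
    momenta[[key]] <- res$reg$state$momenta
    log <- log_stage(log, key, "atlas register", t0)
  }
  if (!length(fields)) stop("all atlas registrations failed")

  mesh_ids <- names(fields)
  subj_of <- sub("_(l|r)$", "", mesh_ids)
  groups <- cohort$metadata$group[match(subj_of, cohort$metadata$subject)]
  rep_out <- render_distance_report(fields, groups, out_dir)
  write_mesh(atlas_mesh, file.path(out_dir, "atlas_mean_shape.vtk"))
  write_landmarks(mean_lm, file.path(out_dir, "atlas_mean_landmarks.csv"))

  kp <- NULL
  tests <- NULL
  if (length(momenta) >= 3) {
    X <- standardize_momenta(momenta)
    kp <- kpca_rbf(X, gamma = config$kpca_gamma,
                   n_components = config$kpca_components)
    if (length(unique(groups)) > 1 && all(table(groups) >= 3)) {
      tests <- group_tests(kp$scores, groups)
      write_test_report(tests, file.path(out_dir, "group_tests.csv"))
    }
    utils::write.csv(
      data.frame(mesh = mesh_ids, subject = subj_of, group = groups, kp$scores),
      file.path(out_dir, "kpca_scores.csv"), row.names = FALSE
    )
  }
  write_manifest(config, out_dir,
                 list(n_meshes = length(fields), n_control_points = nrow(ctrl)))
  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(list(atlas = atlas_mesh, mean_landmarks = mean_lm,
                 per_mesh = rep_out$summary, fields = fields,
                 momenta = momenta, kpca = kp, tests = tests,
                 out_dir = out_dir))
}
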