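# single-pair cost: varifold attachment of the flowed source against the
# target, weighted by 1/(2 noise_std^2), plus the geodesic kinetic energy
registration_cost <- function(C0, A0, source_vertices, source_faces, fb_target,
                              params, target_self = NULL) {
  st <- deformation_state(C0, A0, params)
  traj <- shoot(st, points = source_vertices)
  Xf <- traj$states[[length(traj$states)]]$X
  fa <- varifold_faces(surface_mesh(Xf, source_faces, validate = FALSE), warn = FALSE)
  if (is.null(target_self)) {
    target_self <- varifold_inner(fb_target, fb_target, params$attachment_kernel_width)
  }
  attach <- varifold_inner(fa, fa, params$attachment_kernel_width) -
    2 * varifold_inner(fa, fb_target, params$attachment_kernel_width) +
    target_self
  attach <- max(attach, 0)
  reg <- kinetic_energy(st)
  list(cost = attach / (2 * params$noise_std^2) + reg,
       attachment = attach, regularity = reg, trajectory = traj,
       deformed_vertices = Xf)
}

# gradient of registration_cost with respect to the momenta (and optionally
# the source vertices, for free-template atlas estimation)
registration_gradient <- function(cost_eval, C0, A0, source_faces, fb_target,
                                  params, want_template_grad = FALSE) {
  traj <- cost_eval$trajectory
  Xf <- cost_eval$deformed_vertices
  w <- 1 / (2 * params$noise_std^2)
  bX <- w * varifold_gradient(Xf, source_faces, fb_target,
                              params$attachment_kernel_width)
  K <- nrow(C0)
  back <- backpropagate_flow(traj,
                             bC_final = matrix(0, K, 3),
                             bA_final = matrix(0, K, 3),
                             bX_final = bX)
  G0 <- gaussian_kernel(C0, C0, params$deformation_kernel_width)
  gA <- back$A + G0 %*% A0
  out <- list(momenta = gA)
  if (want_template_grad) out$template <- back$X
  out
}

#' Register one surface onto another by geodesic shooting
#'
#' Estimates initial momenta on a control-point grid such that the flowed
#' source surface matches the target in the varifold metric. The cost
#' `varifold^2 / (2 sigma_eps^2) + kinetic energy` is minimised by steepest
#' descent with a backtracking line search (step halved on an increase,
#' grown 1.5x after success); control points stay frozen. The first update
#' is capped at a motion of `0.1 sigma_V` per control point.
#'
#' @param source,target [surface_mesh()] objects in a common frame (e.g.
#'   from [preprocess_pair()]).
#' @param params a [deformation_params()].
#' @param control_points optional `K x 3` matrix; defaults to
#'   [make_control_grid()] on the source with spacing `sigma_V`.
#' @param initial_momenta optional warm start, `K x 3`.
#' @param verbose print per-iteration cost.
#' @return object of class `registration_result`: `state`
#'   ([deformation_state()]), `deformed_source` ([surface_mesh()] with
#'   normals), `final_cost`, `final_attachment`, `final_regularity`,
#'   `initial_attachment`, `n_iterations`, `converged`, `cost_trace`.
#' @export
register <- function(source, target, params = deformation_params(),
                     control_points = NULL, initial_momenta = NULL,
                     verbose = FALSE) {
  stopifnot(inherits(source, "surface_mesh"), inherits(target, "surface_mesh"))
  if (is.null(control_points)) {
    spacing <- if (is.null(params$control_spacing)) {
      params$deformation_kernel_width
    } else {
      params$control_spacing
    }
    control_points <- make_control_grid(source, spacing)
  }
  C0 <- as.matrix(control_points)
  K <- nrow(C0)
  A <- if (is.null(initial_momenta)) matrix(0, K, 3) else as.matrix(initial_momenta)
  fb_target <- varifold_faces(target)
  target_self <- varifold_inner(fb_target, fb_target, params$attachment_kernel_width)
  V <- source$vertices
  Fc <- source$faces

  ev <- registration_cost(C0, A, V, Fc, fb_target, params, target_self)
  initial_attachment <- ev$attachment
  step <- NULL
  trace <- ev$cost
  converged <- FALSE
  iter <- 0L
  while (iter < params$max_iterations) {
    iter <- iter + 1L
    gr <- registration_gradient(ev, C0, A, Fc, fb_target, params)$momenta
    gmax <- max(sqrt(rowSums(gr^2)))
    if (gmax < 1e-14) { converged <- TRUE; break }
    if (is.null(step)) {
      step <- 0.1 * params$deformation_kernel_width / gmax
    }
    accepted <- FALSE
    for (ls in 1:25) {
      A_try <- A - step * gr
      ev_try <- tryCatch(
        registration_cost(C0, A_try, V, Fc, fb_target, params, target_self),
        error = function(e) NULL
      )
      if (!is.null(ev_try) && is.finite(ev_try$cost) && ev_try$cost <= ev$cost) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) break
    rel <- (ev$cost - ev_try$cost) / max(abs(ev$cost), 1e-300)
    A <- A_try
    ev <- ev_try
    step <- step * 1.5
    trace <- c(trace, ev$cost)
    if (verbose) {
      message(sprintf("iter %3d  cost %.6e  attach %.6e  reg %.6e",
                      iter, ev$cost, ev$attachment, ev$regularity))
    }
    if (rel < params$convergence_tol) { converged <- TRUE; break }
  }
  deformed <- compute_vertex_normals(
    surface_mesh(ev$deformed_vertices, Fc, validate = FALSE)
  )
  structure(list(
    state = deformation_state(C0, A, params),
    deformed_source = deformed,
    final_cost = ev$cost,
    final_attachment = ev$attachment,
    final_regularity = ev$regularity,
    initial_attachment = initial_attachment,
    n_iterations = iter,
    converged = converged,
    cost_trace = trace
  ), class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf(
    "registration_result: %d iterations (%s)\n  attachment %.4g -> %.4g, regularity %.4g, cost %.4g\n",
    x$n_iterations, if (x$converged) "converged" else "not converged",
    x$initial_attachment, x$final_attachment, x$final_regularity, x$final_cost
  ))
  invisible(x)
}

#' Deterministic atlas: one template, per-target momenta
#'
#' Joint estimation of per-target initial momenta (one shared control-point
#' grid on the template) minimising the summed registration cost of the
#' template flowed towards every target. With `freeze_template = FALSE` the
#' template vertices are optimised jointly with the momenta.
#'
#' @param template a [surface_mesh()] (e.g. the first cohort subject).
#' @param targets list of [surface_mesh()] objects in the template's frame.
#' @param params a [deformation_params()]; `freeze_template` controls the
#'   template update.
#' @param control_points optional shared `K x 3` grid.
#' @param verbose print per-iteration total cost.
#' @return object of class `atlas_result`: `template` (possibly updated
#'   [surface_mesh()]), `control_points`, `momenta` (list of `K x 3`, one
#'   per target), `registrations` (per-target final attachment/regularity),
#'   `final_cost`, `n_iterations`, `converged`.
#' @export
deterministic_atlas <- function(template, targets, params = deformation_params(),
                                control_points = NULL, verbose = FALSE) {
  stopifnot(length(targets) >= 1)
  if (is.null(control_points)) {
    spacing <- if (is.null(params$control_spacing)) {
      params$deformation_kernel_width
    } else {
      params$control_spacing
    }
    control_points <- make_control_grid(template, spacing)
  }
  C0 <- as.matrix(control_points)
  K <- nrow(C0)
  N <- length(targets)
  V <- template$vertices
  Fc <- template$faces
  fbs <- lapply(targets, varifold_faces)
  selfs <- vapply(fbs, function(fb) {
    varifold_inner(fb, fb, params$attachment_kernel_width)
  }, numeric(1))
  A <- replicate(N, matrix(0, K, 3), simplify = FALSE)
  free_template <- !params$freeze_template

  total_eval <- function(V, A) {
    evs <- lapply(seq_len(N), function(k) {
      registration_cost(C0, A[[k]], V, Fc, fbs[[k]], params, selfs[[k]])
    })
    list(cost = sum(vapply(evs, `[[`, numeric(1), "cost")), evs = evs)
  }
  ev <- total_eval(V, A)
  step <- NULL
  converged <- FALSE
  iter <- 0L
  while (iter < params$max_iterations) {
    iter <- iter + 1L
    grads <- lapply(seq_len(N), function(k) {
      registration_gradient(ev$evs[[k]], C0, A[[k]], Fc, fbs[[k]], params,
                            want_template_grad = free_template)
    })
    gA <- lapply(grads, `[[`, "momenta")
    gV <- if (free_template) Reduce(`+`, lapply(grads, `[[`, "template")) else NULL
    gmax <- max(vapply(gA, function(g) max(sqrt(rowSums(g^2))), numeric(1)),
                if (free_template) max(sqrt(rowSums(gV^2))) else 0)
    if (gmax < 1e-14) { converged <- TRUE; break }
    if (is.null(step)) step <- 0.1 * params$deformation_kernel_width / gmax
    accepted <- FALSE
    for (ls in 1:25) {
      A_try <- lapply(seq_len(N), function(k) A[[k]] - step * gA[[k]])
      V_try <- if (free_template) V - step * gV else V
      ev_try <- tryCatch(total_eval(V_try, A_try), error = function(e) NULL)
      if (!is.null(ev_try) && is.finite(ev_try$cost) && ev_try$cost <= ev$cost) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) break
    rel <- (ev$cost - ev_try$cost) / max(abs(ev$cost), 1e-300)
    A <- A_try
    V <- V_try
    ev <- ev_try
    step <- step * 1.5
    if (verbose) message(sprintf("atlas iter %3d  total cost %.6e", iter, ev$cost))
    if (rel < params$convergence_tol) { converged <- TRUE; break }
  }
  out_template <- compute_vertex_normals(surface_mesh(V, Fc, validate = FALSE))
  registrations <- lapply(ev$evs, function(e) {
    list(final_attachment = e$attachment, final_regularity = e$regularity,
         deformed = surface_mesh(e$deformed_vertices, Fc, validate = FALSE))
  })
  structure(list(
    template = out_template,
    control_points = C0,
    momenta = A,
    registrations = registrations,
    final_cost = ev$cost,
    n_iterations = iter,
    converged = converged
  ), class = "atlas_result")
}

#' @export
print.atlas_result <- function(x, ...) {
  cat(sprintf("atlas_result: %d targets, %d control points, cost %.4g (%s)\n",
              length(x$momenta), nrow(x$control_points), x$final_cost,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Serialize a deformation state to plain-text files
#'
#' Control points and momenta as whitespace-separated `x y z` rows plus a
#' JSON sidecar holding the deformation parameters (format tag
#' `radsym-momenta-v1`).
#'
#' @param state a [deformation_state()].
#' @param prefix output path prefix; writes `<prefix>_control_points.txt`,
#'   `<prefix>_momenta.txt`, `<prefix>_params.json`.
#' @return `prefix`, invisibly.
#' @export
write_deformation_state <- function(state, prefix) {
  utils::write.table(state$control_points,
                     paste0(prefix, "_control_points.txt"),
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(state$momenta, paste0(prefix, "_momenta.txt"),
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    c(list(format = "radsym-momenta-v1"), unclass(state$params)),
    paste0(prefix, "_params.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(prefix)
}

#' Read a deformation state written by [write_deformation_state()]
#' @param prefix path prefix used at write time.
#' @return a [deformation_state()].
#' @export
read_deformation_state <- function(prefix) {
  cp <- as.matrix(utils::read.table(paste0(prefix, "_control_points.txt")))
  mo <- as.matrix(utils::read.table(paste0(prefix, "_momenta.txt")))
  meta <- jsonlite::read_json(paste0(prefix, "_params.json"), simplifyVector = TRUE)
  params <- deformation_params(
    deformation_kernel_width = meta$deformation_kernel_width,
    attachment_kernel_width = meta$attachment_kernel_width,
    noise_std = meta$noise_std,
    n_time_points = meta$n_time_points,
    convergence_tol = meta$convergence_tol,
    max_iterations = meta$max_iterations,
    freeze_control_points = meta$freeze_control_points,
    freeze_template = meta$freeze_template,
    control_spacing = meta$control_spacing
  )
  dimnames(cp) <- NULL
  dimnames(mo) <- NULL
  deformation_state(cp, mo, params)
}
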