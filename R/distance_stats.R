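#' Mean shape of vertex-corresponded meshes
#'
#' Vertex `i` of the output is the arithmetic mean of vertex `i` across all
#' inputs; faces are copied from the template. All meshes must share the
#' template's vertex count and ordering (as produced by deforming one
#' template in [deterministic_atlas()]).
#'
#' @param meshes list of corresponded [surface_mesh()] objects.
#' @param template_index which input supplies the face list (default 1).
#' @return the mean [surface_mesh()] with recomputed normals.
#' @export
build_mean_shape <- function(meshes, template_index = 1L) {
  stopifnot(length(meshes) >= 1)
  n <- nrow(meshes[[template_index]]$vertices)
  acc <- matrix(0, n, 3)
  for (m in meshes) {
    if (nrow(m$vertices) != n) {
      stop("correspondence error: meshes have different vertex counts")
    }
    acc <- acc + m$vertices
  }
  compute_vertex_normals(surface_mesh(acc / length(meshes),
                                      meshes[[template_index]]$faces,
                                      validate = FALSE))
}

#' Signed correspondence distances between corresponded meshes
#'
#' For each vertex `i`, the Euclidean distance between `source` vertex `i`
#' and `deformed` vertex `i`, signed by the direction of the displacement
#' against the source's outward normal: positive when the deformed surface
#' lies outward of the source, negative when inward.
#'
#' @param source a [surface_mesh()]; normals are computed if absent.
#' @param deformed a vertex-corresponded [surface_mesh()] (or `n x 3`
#'   matrix).
#' @param mask optional logical per-vertex articular mask stored alongside.
#' @return object of class `correspondence_field`: list with `distance`
#'   (signed mm per vertex), `mask`, `source`.
#' @export
signed_distance <- function(source, deformed, mask = NULL) {
  dv <- if (inherits(deformed, "surface_mesh")) deformed$vertices else as.matrix(deformed)
  if (nrow(dv) != nrow(source$vertices)) {
    stop("correspondence error: vertex counts differ")
  }
  if (is.null(source$normals)) source <- compute_vertex_normals(source)
  disp <- dv - source$vertices
  mag <- sqrt(rowSums(disp^2))
  sgn <- sign(rowSums(disp * source$normals))
  sgn[sgn == 0] <- 1
  if (!is.null(mask)) stopifnot(length(mask) == nrow(dv))
  structure(list(distance = sgn * mag, mask = mask, source = source),
            class = "correspondence_field")
}

#' @export
print.correspondence_field <- function(x, ...) {
  cat(sprintf(
    "correspondence_field: %d vertices, mean |d| %.3f mm, range [%.3f, %.3f] mm\n",
    length(x$distance), mean(abs(x$distance)), min(x$distance), max(x$distance)
  ))
  invisible(x)
}

#' Per-subject summary of a correspondence field
#'
#' Statistics of the absolute signed distance over the whole bone or the
#' articular subset. Absolute values are used for the summaries (the sign
#' only matters for maps and boxplots); set `absolute = FALSE` to summarise
#' the raw signed values instead.
#'
#' @param field a `correspondence_field` from [signed_distance()].
#' @param mask `"whole"` or `"articular"` (requires the field's mask).
#' @param absolute summarise `|d|` (default) or signed `d`.
#' @return named numeric vector: `mean`, `sd`, `max`, `median` (mm), plus
#'   `n` vertices used.
#' @export
summarize_subject <- function(field, mask = c("whole", "articular"),
                              absolute = TRUE) {
  mask <- match.arg(mask)
  d <- field$distance
  if (mask == "articular") {
    if (is.null(field$mask)) stop("field has no articular mask")
    d <- d[field$mask]
    if (!length(d)) stop("empty articular mask")
  }
  if (absolute) d <- abs(d)
  c(mean = mean(d), sd = stats::sd(d), max = max(d),
    median = stats::median(d), n = length(d))
}

#' Group-level summary table of per-subject distances
#'
#' Group mean is the unweighted mean of per-subject means; the group SD
#' pools all selected vertices of the group's subjects (per-subject vertex
#' values concatenated). A cohort row aggregates all subjects the same way.
#'
#' @param subject_means numeric vector of per-subject mean distances (mm).
#' @param groups factor/character of group labels, same length.
#' @param subject_values optional list of per-vertex absolute distances per
#'   subject, for the pooled SD; when absent the SD of subject means is
#'   reported.
#' @return data.frame with columns `group`, `n`, `mean_mm`, `sd_mm`;
#'   the last row (`group == "all"`) is the cohort aggregate.
#' @export
summarize_group <- function(subject_means, groups, subject_values = NULL) {
  stopifnot(length(subject_means) == length(groups))
  groups <- as.character(groups)
  if (any(!stats::complete.cases(subject_means))) stop("NA subject means")
  lev <- unique(groups)
  rows <- lapply(c(lev, "all"), function(g) {
    sel <- if (g == "all") rep(TRUE, length(groups)) else groups == g
    if (!any(sel)) stop("empty group: ", g)
    sd_val <- if (is.null(subject_values)) {
      stats::sd(subject_means[sel])
    } else {
      stats::sd(abs(unlist(subject_values[sel])))
    }
    data.frame(group = g, n = sum(sel), mean_mm = mean(subject_means[sel]),
               sd_mm = sd_val)
  })
  do.call(rbind, rows)
}
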