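#' Distance report: tables, boxplot data, coloured meshes
#'
#' Writes the standard outputs of a symmetry or atlas analysis from
#' per-subject correspondence fields: a per-subject summary CSV (subject,
#' group, mean, SD over whole bone and articular subset, with group and
#' cohort aggregate rows), per-subject boxplot statistics of the signed
#' distances (median, quartiles, whiskers at the 99.8th percentile outlier
#' rule), meshes exported as VTK PolyData carrying a `signed_distance_mm`
#' point scalar for surface colouring, and (when ggplot2 is installed) a
#' boxplot figure.
#'
#' @param fields named list of `correspondence_field` objects, one per
#'   subject (names are subject ids).
#' @param groups character/factor of group labels parallel to `fields`.
#' @param out_dir output directory (created if needed).
#' @param write_meshes export coloured VTK meshes (default TRUE).
#' @param figure write `boxplot.png` via ggplot2 when available.
#' @return invisible list with the summary and boxplot data.frames and the
#'   paths written.
#' @export
render_distance_report <- function(fields, groups, out_dir,
                                   write_meshes = TRUE, figure = TRUE) {
  stopifnot(length(fields) == length(groups))
  ids <- names(fields)
  if (is.null(ids)) ids <- sprintf("subject%03d", seq_along(fields))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  groups <- as.character(groups)

  rows <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    w <- summarize_subject(f, "whole")
    a <- if (!is.null(f$mask)) summarize_subject(f, "articular") else rep(NA_real_, 5)
    data.frame(subject = ids[i], group = groups[i],
               mean_mm = w[["mean"]], sd_mm = w[["sd"]],
               articular_mean_mm = a[[1]], articular_sd_mm = a[[2]])
  })
  per_subject <- do.call(rbind, rows)
  grp <- summarize_group(per_subject$mean_mm, groups,
                         lapply(fields, function(f) abs(f$distance)))
  agg <- data.frame(subject = paste0("group:", grp$group), group = grp$group,
                    mean_mm = grp$mean_mm, sd_mm = grp$sd_mm,
                    articular_mean_mm = NA_real_, articular_sd_mm = NA_real_)
  if (!all(is.na(per_subject$articular_mean_mm))) {
    agg_art <- summarize_group(
      per_subject$articular_mean_mm, groups,
      lapply(fields, function(f) abs(f$distance[f$mask]))
    )
    agg$articular_mean_mm <- agg_art$mean_mm
    agg$articular_sd_mm <- agg_art$sd_mm
  }
  summary_df <- rbind(per_subject, agg)
  summary_path <- file.path(out_dir, "distance_summary.csv")
  utils::write.csv(summary_df, summary_path, row.names = FALSE)

  # boxplot statistics on signed values; outliers above the 99.8th
  # percentile of |d| per subject
  box <- do.call(rbind, lapply(seq_along(fields), function(i) {
    d <- fields[[i]]$distance
    q <- stats::quantile(d, c(0.25, 0.5, 0.75), names = FALSE)
    cutoff <- stats::quantile(abs(d), 0.998, names = FALSE)
    data.frame(subject = ids[i], group = groups[i],
               q1 = q[1], median = q[2], q3 = q[3],
               lower = min(d[abs(d) <= cutoff]), upper = max(d[abs(d) <= cutoff]),
               outlier_cutoff_mm = cutoff, n_outliers = sum(abs(d) > cutoff))
  }))
  box_path <- file.path(out_dir, "boxplot_stats.csv")
  utils::write.csv(box, box_path, row.names = FALSE)

  mesh_paths <- character(0)
  if (write_meshes) {
    mesh_dir <- file.path(out_dir, "meshes")
    dir.create(mesh_dir, showWarnings = FALSE)
    mesh_paths <- vapply(seq_along(fields), function(i) {
      p <- file.path(mesh_dir, paste0(ids[i], "_distance.vtk"))
      write_mesh(fields[[i]]$source, p, format = "vtk",
                 point_scalars = list(signed_distance_mm = fields[[i]]$distance))
      p
    }, character(1))
  }

  fig_path <- NULL
  if (figure && requireNamespace("ggplot2", quietly = TRUE)) {
    df <- do.call(rbind, lapply(seq_along(fields), function(i) {
      data.frame(subject = ids[i], group = groups[i], d = fields[[i]]$distance)
    }))
    gp <- ggplot2::ggplot(df, ggplot2::aes(x = .data$subject, y = .data$d,
                                           fill = .data$group)) +
      ggplot2::geom_boxplot(outlier.size = 0.3) +
      ggplot2::geom_hline(yintercept = mean(abs(df$d)), colour = "red") +
      ggplot2::labs(x = NULL, y = "signed distance (mm)") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
    fig_path <- file.path(out_dir, "boxplot.png")
    ggplot2::ggsave(fig_path, gp, width = max(6, length(fields) * 0.35),
                    height = 4, dpi = 150)
  }
  invisible(list(summary = summary_df, boxplot = box,
                 paths = c(summary_path, box_path, mesh_paths, fig_path)))
}
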