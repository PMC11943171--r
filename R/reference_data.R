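#' Reference per-patient correspondence-distance tables
#'
#' Published per-patient summary statistics (mean and SD of absolute
#' correspondence distances, mm) from a bilateral distal-radius CT cohort
#' of 40 adults in four sex-by-age groups: the pairwise left/right
#' comparison (one row per patient and region) and the atlas comparison
#' (one row per mesh, `l`/`r` per patient, per region). These tables are
#' the cohort's only released data and anchor the aggregation conventions
#' used by [summarize_group()].
#'
#' @return list with data.frames `pairwise` (columns subject, group,
#'   region, mean_mm, sd_mm) and `atlas` (additionally `side`).
#' @export
reference_distance_tables <- function() {
  pw <- utils::read.csv(
    system.file("extdata", "reference_pairwise_distances.csv", package = "radsym"),
    stringsAsFactors = FALSE, colClasses = c(subject = "character")
  )
  at <- utils::read.csv(
    system.file("extdata", "reference_atlas_distances.csv", package = "radsym"),
    stringsAsFactors = FALSE, colClasses = c(subject = "character")
  )
  list(pairwise = pw, atlas = at)
}

#' Aggregate the reference tables into cohort and group means
#'
#' Unweighted means of the per-patient (pairwise) or per-mesh (atlas) mean
#' distances, per group and over the whole cohort, for each region.
#'
#' @param tables output of [reference_distance_tables()] (loaded fresh when
#'   omitted).
#' @return data.frame with columns `analysis` (pairwise/atlas), `region`,
#'   `group` (`all` for the cohort row), `n`, `mean_mm`.
#' @export
reference_group_means <- function(tables = reference_distance_tables()) {
  agg_one <- function(df, analysis) {
    do.call(rbind, lapply(unique(df$region), function(reg) {
      d <- df[df$region == reg, ]
      rows <- rbind(
        data.frame(group = "all", n = nrow(d), mean_mm = mean(d$mean_mm)),
        do.call(rbind, lapply(unique(d$group), function(g) {
          data.frame(group = g, n = sum(d$group == g),
                     mean_mm = mean(d$mean_mm[d$group == g]))
        }))
      )
      cbind(analysis = analysis, region = reg, rows)
    }))
  }
  out <- rbind(agg_one(tables$pairwise, "pairwise"), agg_one(tables$atlas, "atlas"))
  rownames(out) <- NULL
  out
}
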