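#' Named anatomical landmark set
#'
#' Named 3D points in mm used only for rigid alignment and articular-plane
#' definition: the radial styloid (`RS`), the distal styloid notch (`DSN`)
#' and, for atlas-mode alignment, a dorsal distal-radius point (`DDR`).
#'
#' @param points numeric matrix with one row per landmark and 3 columns, or a
#'   named list of length-3 vectors.
#' @param names character vector of landmark names (row names used if absent).
#' @return object of class `landmark_set`: a named k x 3 matrix.
#' @export
landmark_set <- function(points, names = NULL) {
  if (is.list(points)) {
    names <- base::names(points)
    points <- do.call(rbind, points)
  }
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) stop("landmarks must be k x 3")
  if (is.null(names)) names <- rownames(points)
  if (is.null(names) || anyDuplicated(names)) stop("landmarks need unique names")
  dimnames(points) <- list(names, NULL)
  structure(points, class = c("landmark_set", "matrix", "array"))
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("landmark_set (mm):\n")
  print(unclass(x))
  invisible(x)
}

landmark_names <- function(lm) rownames(lm)

get_landmark <- function(lm, name) {
  if (!name %in% rownames(lm)) stop("missing landmark: ", name)
  as.numeric(lm[name, ])
}

#' Check landmark/mesh consistency
#'
#' `RS` and `DSN` must be present (`DDR` additionally when
#' `require_ddr = TRUE`), and every landmark must lie within the mesh
#' bounding box expanded by `slack_mm`.
#'
#' @param lm a [landmark_set()].
#' @param mesh a [surface_mesh()].
#' @param require_ddr require the dorsal `DDR` landmark (atlas mode).
#' @param slack_mm bounding-box expansion tolerance in mm.
#' @return `lm` invisibly, or an error.
#' @export
validate_landmarks <- function(lm, mesh, require_ddr = FALSE, slack_mm = 2) {
  need <- c("RS", "DSN", if (require_ddr) "DDR")
  missing <- setdiff(need, rownames(lm))
  if (length(missing)) stop("missing landmark(s): ", paste(missing, collapse = ", "))
  lo <- apply(mesh$vertices, 2, min) - slack_mm
  hi <- apply(mesh$vertices, 2, max) + slack_mm
  ok <- sweep(unclass(lm), 2, lo, ">=") & sweep(unclass(lm), 2, hi, "<=")
  if (!all(ok)) {
    stop("landmark(s) outside expanded mesh bounding box: ",
         paste(rownames(lm)[!apply(ok, 1, all)], collapse = ", "))
  }
  invisible(lm)
}

#' Read landmarks from CSV or JSON
#'
#' CSV dialect: header `name,x,y,z`, coordinates in mm. JSON dialect: object
#' mapping names to `[x, y, z]` arrays.
#'
#' @param path file path; format inferred from the `.csv`/`.json` extension
#'   unless given.
#' @param format `"csv"` or `"json"`.
#' @return a [landmark_set()].
#' @export
read_landmarks <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(landmark_set(do.call(rbind, obj), names = names(obj)))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("name", "x", "y", "z") %in% names(df))) {
    stop("landmark CSV needs columns name,x,y,z")
  }
  landmark_set(as.matrix(df[, c("x", "y", "z")]), names = df$name)
}

#' Write landmarks to CSV or JSON
#' @param lm a [landmark_set()].
#' @inheritParams read_landmarks
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(lm, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") {
    obj <- lapply(seq_len(nrow(lm)), function(i) as.numeric(lm[i, ]))
    names(obj) <- rownames(lm)
    jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  } else {
    df <- data.frame(name = rownames(lm), x = lm[, 1], y = lm[, 2], z = lm[, 3])
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Mean of several landmark sets
#'
#' Per-name arithmetic mean across sets; all sets must share the names of the
#' first. Used to define the mean articular surface of an atlas.
#'
#' @param landmark_sets list of [landmark_set()] objects.
#' @return a [landmark_set()] of per-name mean points.
#' @export
mean_landmarks <- function(landmark_sets) {
  stopifnot(length(landmark_sets) >= 1)
  nm <- rownames(landmark_sets[[1]])
  acc <- matrix(0, length(nm), 3)
  for (lm in landmark_sets) {
    if (!all(nm %in% rownames(lm))) stop("landmark name missing in one set")
    acc <- acc + unclass(lm)[nm, , drop = FALSE]
  }
  landmark_set(acc / length(landmark_sets), names = nm)
}
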