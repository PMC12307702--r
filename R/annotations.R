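#' Coordinate frame of a region of interest
#'
#' A `coord_frame` records the pixel grid and physical resolution of one
#' region of interest (ROI) or mark-up image: its width and height in
#' pixels and the edge length of a pixel in micrometres. The physical
#' extent of the frame is `width_px * um_per_px` by `height_px * um_per_px`
#' micrometres. The study design this package targets uses square ROIs of
#' 200 um edge scanned at 0.23 um/pixel (roughly 870 x 870 px).
#'
#' @param width_px,height_px Positive integers, frame size in pixels.
#' @param um_per_px Positive real, micrometres per pixel.
#' @return An object of class `coord_frame`.
#' @examples
#' coord_frame(870, 870, 0.23)
#' @export
coord_frame <- function(width_px, height_px, um_per_px) {
  if (!is.numeric(width_px) || length(width_px) != 1L || width_px < 1 ||
      width_px != trunc(width_px)) {
    stop("`width_px` must be a single integer >= 1", call. = FALSE)
  }
  if (!is.numeric(height_px) || length(height_px) != 1L || height_px < 1 ||
      height_px != trunc(height_px)) {
    stop("`height_px` must be a single integer >= 1", call. = FALSE)
  }
  if (!is.numeric(um_per_px) || length(um_per_px) != 1L || um_per_px <= 0) {
    stop("`um_per_px` must be a single positive number", call. = FALSE)
  }
  structure(
    list(width_px = as.integer(width_px), height_px = as.integer(height_px),
         um_per_px = as.numeric(um_per_px)),
    class = "coord_frame"
  )
}

#' @export
print.coord_frame <- function(x, ...) {
  cat(sprintf("<coord_frame> %d x %d px @ %g um/px (%.1f x %.1f um)\n",
              x$width_px, x$height_px, x$um_per_px,
              x$width_px * x$um_per_px, x$height_px * x$um_per_px))
  invisible(x)
}

#' Physical extent of a frame in micrometres
#'
#' @param frame A [coord_frame()].
#' @return Numeric vector `c(width_um, height_um)`.
#' @export
frame_extent_um <- function(frame) {
  stopifnot(inherits(frame, "coord_frame"))
  c(width_um = frame$width_px * frame$um_per_px,
    height_um = frame$height_px * frame$um_per_px)
}

frames_equal <- function(a, b) {
  a$width_px == b$width_px && a$height_px == b$height_px &&
    isTRUE(all.equal(a$um_per_px, b$um_per_px))
}

ki67_labels <- c("negative", "positive")

#' Dot-annotation set for one ROI from one source
#'
#' An `annotation_set` holds all dot markings of one region of interest
#' from one source (the pathologist reference standard or one detector),
#' together with the coordinate frame the pixel coordinates live in.
#' Coordinates follow the image-viewer convention: pixel units, origin at
#' the top-left corner, x rightward, y downward, continuous (sub-pixel)
#' values allowed. Containment uses the half-open interval `[0, width_px)`
#' (and likewise for y), so a point exactly on the far edge is rejected.
#'
#' @param points A data frame with numeric columns `x`, `y` and a `label`
#'   column with values `"positive"`/`"negative"`. `label` may be omitted,
#'   in which case all points are recorded as negative and the set is
#'   flagged unlabeled.
#' @param frame The [coord_frame()] the coordinates refer to.
#' @param roi_id,case_id,source Identifier strings.
#' @param labeled Logical; whether the labels are meaningful. Defaults to
#'   `TRUE` when `points` carries a `label` column.
#' @return An object of class `annotation_set` with elements `roi_id`,
#'   `case_id`, `source`, `frame`, `labeled` and `points` (data frame with
#'   columns `x`, `y`, `label`).
#' @examples
#' fr <- coord_frame(870, 870, 0.23)
#' annotation_set(data.frame(x = c(10, 30), y = c(20, 40),
#'                           label = c("positive", "negative")),
#'                fr, roi_id = "roi1", case_id = "case1", source = "reference")
#' @export
annotation_set <- function(points, frame, roi_id = "roi", case_id = "case",
                           source = "unknown", labeled = NULL) {
  stopifnot(inherits(frame, "coord_frame"))
  points <- as.data.frame(points)
  if (nrow(points) == 0L && !all(c("x", "y") %in% names(points))) {
    points <- data.frame(x = numeric(0), y = numeric(0),
                         label = character(0))
  }
  if (!all(c("x", "y") %in% names(points))) {
    stop("`points` must have columns `x` and `y`", call. = FALSE)
  }
  has_label <- "label" %in% names(points)
  if (is.null(labeled)) labeled <- has_label
  if (!has_label) {
    points$label <- rep("negative", nrow(points))
  }
  points$x <- as.numeric(points$x)
  points$y <- as.numeric(points$y)
  points$label <- as.character(points$label)
  bad <- !(points$label %in% ki67_labels)
  if (any(bad)) {
    stop(sprintf("invalid label(s) %s in row(s) %s: labels must be one of %s",
                 paste(unique(points$label[bad]), collapse = ", "),
                 paste(which(bad), collapse = ", "),
                 paste(ki67_labels, collapse = "/")), call. = FALSE)
  }
  oob <- points$x < 0 | points$x >= frame$width_px |
    points$y < 0 | points$y >= frame$height_px |
    !is.finite(points$x) | !is.finite(points$y)
  if (any(oob)) {
    stop(sprintf(
      "point(s) in row(s) %s fall outside the frame [0, %d) x [0, %d)",
      paste(which(oob), collapse = ", "),
      frame$width_px, frame$height_px), call. = FALSE)
  }
  rownames(points) <- NULL
  structure(
    list(roi_id = as.character(roi_id), case_id = as.character(case_id),
         source = as.character(source), frame = frame,
         labeled = isTRUE(labeled), points = points[c("x", "y", "label")]),
    class = "annotation_set"
  )
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %s / %s / %s: %d points (%d positive)%s\n",
              x$case_id, x$roi_id, x$source, n_points(x), n_positive(x),
              if (x$labeled) "" else " [unlabeled]"))
  invisible(x)
}

#' Point counts of an annotation set
#'
#' `n_points()` returns the total number of dot annotations, `n_positive()`
#' and `n_negative()` the per-class counts; the three always satisfy
#' `n_points = n_positive + n_negative`.
#'
#' @param set An [annotation_set()].
#' @return An integer count.
#' @export
n_points <- function(set) {
  stopifnot(inherits(set, "annotation_set"))
  nrow(set$points)
}

#' @rdname n_points
#' @export
n_positive <- function(set) {
  stopifnot(inherits(set, "annotation_set"))
  sum(set$points$label == "positive")
}

#' @rdname n_points
#' @export
n_negative <- function(set) {
  stopifnot(inherits(set, "annotation_set"))
  sum(set$points$label == "negative")
}

#' Keep only the Ki67-positive points of a set
#'
#' @param set A labeled [annotation_set()].
#' @return An [annotation_set()] containing only the positive points, in
#'   their original order.
#' @export
subset_positive <- function(set) {
  stopifnot(inherits(set, "annotation_set"))
  if (!set$labeled) {
    stop("cannot take the positive stratum of an unlabeled set",
         call. = FALSE)
  }
  annotation_set(set$points[set$points$label == "positive", , drop = FALSE],
                 set$frame, roi_id = set$roi_id, case_id = set$case_id,
                 source = set$source, labeled = TRUE)
}

#' Read dot annotations from a CSV file
#'
#' Parses point exports in the style of ImageJ multi-point measurements: a
#' comma-separated file with a header containing columns `X` and `Y`
#' (pixel coordinates in `frame`) and optionally `Label`. Column names are
#' matched case-insensitively; extra columns are ignored. When the label
#' column is absent every point is recorded as negative and the returned
#' set is flagged unlabeled.
#'
#' @param path Path to the CSV file.
#' @param frame The [coord_frame()] the coordinates refer to.
#' @param source Source name stored in the set (e.g. `"reference"`).
#' @param roi_id,case_id Identifiers stored in the set.
#' @return An [annotation_set()] preserving the file's row order.
#' @seealso [write_points()] for the inverse operation.
#' @export
read_points <- function(path, frame, source = "unknown",
                        roi_id = "roi", case_id = "case") {
  if (!file.exists(path)) {
    stop(sprintf("annotation file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  nm <- tolower(names(df))
  ix <- match("x", nm)
  iy <- match("y", nm)
  if (is.na(ix) || is.na(iy)) {
    stop(sprintf("%s: required column(s) %s missing (header: %s)", path,
                 paste(c("X", "Y")[c(is.na(ix), is.na(iy))], collapse = ", "),
                 paste(names(df), collapse = ", ")), call. = FALSE)
  }
  il <- match("label", nm)
  pts <- data.frame(x = as.numeric(df[[ix]]), y = as.numeric(df[[iy]]))
  if (!is.na(il)) pts$label <- as.character(df[[il]])
  annotation_set(pts, frame, roi_id = roi_id, case_id = case_id,
                 source = source, labeled = !is.na(il))
}

#' Write dot annotations to a CSV file
#'
#' Writes the set's points as a CSV with columns `X`, `Y`, `Label` (the
#' label column is omitted for unlabeled sets). Coordinates are written
#' with enough digits that [read_points()] reproduces them to at least
#' 1e-6 px; a read/write round trip preserves labels exactly.
#'
#' @param set An [annotation_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_points <- function(set, path) {
  stopifnot(inherits(set, "annotation_set"))
  df <- data.frame(X = sprintf("%.9g", set$points$x),
                   Y = sprintf("%.9g", set$points$y))
  if (set$labeled) df$Label <- set$points$label
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) {
    stop(sprintf("cannot write %s: %s", path, conditionMessage(ok)),
         call. = FALSE)
  }
  invisible(path)
}

#' Serialize an annotation set to and from JSON
#'
#' `annotation_set_to_json()` writes the full set (identifiers, frame and
#' points) as a JSON object; `annotation_set_from_json()` reads it back.
#' Used for the pipeline's intermediate artifacts.
#'
#' @param set An [annotation_set()].
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return `annotation_set_to_json()`: the JSON string (invisibly when
#'   written to a file); `annotation_set_from_json()`: an [annotation_set()].
#' @export
annotation_set_to_json <- function(set, path = NULL) {
  stopifnot(inherits(set, "annotation_set"))
  obj <- list(
    roi_id = set$roi_id, case_id = set$case_id, source = set$source,
    labeled = set$labeled,
    frame = list(width_px = set$frame$width_px,
                 height_px = set$frame$height_px,
                 um_per_px = set$frame$um_per_px),
    points = set$points
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname annotation_set_to_json
#' @param json A JSON string or path to a JSON file produced by
#'   `annotation_set_to_json()`.
#' @export
annotation_set_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  fr <- coord_frame(obj$frame$width_px, obj$frame$height_px,
                    obj$frame$um_per_px)
  pts <- as.data.frame(obj$points)
  annotation_set(pts, fr, roi_id = obj$roi_id, case_id = obj$case_id,
                 source = obj$source, labeled = isTRUE(obj$labeled))
}
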