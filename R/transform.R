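#' Build a coordinate mapping between two frames of the same region
#'
#' Detector mark-up images are typically resampled renderings of the
#' original ROI and therefore have a different pixel grid. To compare dot
#' annotations, all coordinates are transformed onto one grid by pure
#' axis-aligned scaling: `sx = target$width_px / source$width_px` and
#' `sy = target$height_px / source$height_px`. Both frames must describe
#' the same physical region; the physical extents are checked and a
#' mismatch beyond `tol` (relative) is an error unless
#' `allow_extent_mismatch = TRUE`.
#'
#' Anisotropic mappings (`sx != sy`) are permitted but trigger a warning,
#' because the distance-capped matching downstream assumes isotropic
#' distances.
#'
#' @param source,target [coord_frame()] objects.
#' @param tol Relative tolerance on the physical-extent check (default 1%).
#' @param allow_extent_mismatch Set `TRUE` to override the extent check.
#' @return An object of class `frame_mapping` with elements `source`,
#'   `target`, `sx`, `sy`.
#' @examples
#' src <- coord_frame(500, 500, 0.4)      # 200 um edge
#' tgt <- coord_frame(870, 870, 0.2299)   # same region, finer grid
#' build_mapping(src, tgt)                # sx = sy = 1.74
#' @export
build_mapping <- function(source, target, tol = 0.01,
                          allow_extent_mismatch = FALSE) {
  stopifnot(inherits(source, "coord_frame"), inherits(target, "coord_frame"))
  es <- frame_extent_um(source)
  et <- frame_extent_um(target)
  rel <- abs(es - et) / es
  if (!allow_extent_mismatch && any(rel > tol)) {
    stop(sprintf(paste0(
      "frames describe different physical regions: source %.2f x %.2f um, ",
      "target %.2f x %.2f um (relative mismatch %.1f%% > %.1f%%); ",
      "use allow_extent_mismatch = TRUE to override"),
      es[1], es[2], et[1], et[2], 100 * max(rel), 100 * tol), call. = FALSE)
  }
  sx <- target$width_px / source$width_px
  sy <- target$height_px / source$height_px
  if (abs(sx - sy) > 1e-9 * max(sx, sy)) {
    warning(sprintf(
      "anisotropic mapping (sx = %g, sy = %g): capped matching assumes isotropic distances",
      sx, sy), call. = FALSE)
  }
  structure(list(source = source, target = target, sx = sx, sy = sy),
            class = "frame_mapping")
}

#' @export
print.frame_mapping <- function(x, ...) {
  cat(sprintf("<frame_mapping> %dx%d px -> %dx%d px (sx = %g, sy = %g)\n",
              x$source$width_px, x$source$height_px,
              x$target$width_px, x$target$height_px, x$sx, x$sy))
  invisible(x)
}

#' Invert a frame mapping
#'
#' @param mapping A [build_mapping()] result.
#' @return The `frame_mapping` from `mapping$target` back to
#'   `mapping$source`.
#' @export
invert_mapping <- function(mapping) {
  stopifnot(inherits(mapping, "frame_mapping"))
  structure(list(source = mapping$target, target = mapping$source,
                 sx = 1 / mapping$sx, sy = 1 / mapping$sy),
            class = "frame_mapping")
}

#' Apply a frame mapping to an annotation set
#'
#' Rescales every point `(x, y)` to `(x * sx, y * sy)`; labels and point
#' order are preserved and the result's frame is the mapping's target.
#' The set's frame must equal the mapping's source frame.
#'
#' @param mapping A [build_mapping()] result.
#' @param set An [annotation_set()] in the mapping's source frame.
#' @return The transformed [annotation_set()].
#' @export
apply_mapping <- function(mapping, set) {
  stopifnot(inherits(mapping, "frame_mapping"),
            inherits(set, "annotation_set"))
  if (!frames_equal(set$frame, mapping$source)) {
    stop("the set's frame does not match the mapping's source frame",
         call. = FALSE)
  }
  pts <- set$points
  pts$x <- pts$x * mapping$sx
  pts$y <- pts$y * mapping$sy
  annotation_set(pts, mapping$target, roi_id = set$roi_id,
                 case_id = set$case_id, source = set$source,
                 labeled = set$labeled)
}

#' Transform a set onto a target frame (convenience wrapper)
#'
#' Builds the mapping from `set$frame` to `target` and applies it. A
#' no-op when the frames are already identical.
#'
#' @param set An [annotation_set()].
#' @param target The target [coord_frame()].
#' @param ... Passed on to [build_mapping()].
#' @return The [annotation_set()] on the target frame.
#' @export
transform_to_frame <- function(set, target, ...) {
  stopifnot(inherits(set, "annotation_set"), inherits(target, "coord_frame"))
  if (frames_equal(set$frame, target)) return(set)
  apply_mapping(build_mapping(set$frame, target, ...), set)
}
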