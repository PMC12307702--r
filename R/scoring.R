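#' Ki67 proliferation score
#'
#' The Ki67 score (proliferation index) is the percentage of tumor cells
#' staining positive for Ki67: `100 * n_positive / n_total`. With no
#' cells the score is undefined (`NA`). Scores are kept unrounded
#' internally; format for display separately, since the clinically
#' decisive 3% boundary must be applied to the exact value.
#'
#' @param n_positive,n_total Non-negative counts, `n_positive <= n_total`.
#' @return An object of class `ki67_score` with `n_positive`, `n_total`,
#'   `score_pct`.
#' @examples
#' ki67_score(10, 200)   # 5%
#' @export
ki67_score <- function(n_positive, n_total) {
  stopifnot(length(n_positive) == 1L, length(n_total) == 1L,
            n_positive >= 0, n_total >= 0)
  if (n_positive > n_total) {
    stop("`n_positive` cannot exceed `n_total`", call. = FALSE)
  }
  structure(
    list(n_positive = as.integer(n_positive), n_total = as.integer(n_total),
         score_pct = if (n_total > 0) 100 * n_positive / n_total
                     else NA_real_),
    class = "ki67_score"
  )
}

#' @export
print.ki67_score <- function(x, ...) {
  cat(sprintf("<ki67_score> %d / %d = %s\n", x$n_positive, x$n_total,
              if (is.na(x$score_pct)) "undefined"
              else sprintf("%.2f%%", x$score_pct)))
  invisible(x)
}

#' Ki67 score of one ROI
#'
#' Counts the positive and total dot annotations of a labeled set.
#'
#' @param set A labeled [annotation_set()].
#' @return A [ki67_score()].
#' @export
roi_score <- function(set) {
  stopifnot(inherits(set, "annotation_set"))
  if (!set$labeled) {
    stop("cannot score an unlabeled annotation set", call. = FALSE)
  }
  ki67_score(n_positive(set), n_points(set))
}

#' Ki67 score of one case from its ROI scores
#'
#' The case-level score sums the positive and total cell counts across
#' the case's ROIs and divides the sums — it is *not* the mean of the
#' per-ROI percentages. The two rules differ whenever ROI cell counts
#' differ: ROIs of 0/50 and 5/150 give 5/200 = 2.5% under the summation
#' rule but 1.67% as a mean of ratios.
#'
#' @param rois Non-empty list of [ki67_score()] objects (or labeled
#'   [annotation_set()]s, which are scored first).
#' @return A [ki67_score()] built from the summed counts.
#' @export
case_score <- function(rois) {
  if (!is.list(rois) || length(rois) == 0L) {
    stop("`rois` must be a non-empty list", call. = FALSE)
  }
  rois <- lapply(rois, function(r) {
    if (inherits(r, "annotation_set")) roi_score(r)
    else if (inherits(r, "ki67_score")) r
    else stop("expected ki67_score or annotation_set elements",
              call. = FALSE)
  })
  ki67_score(sum(vapply(rois, `[[`, 0L, "n_positive")),
             sum(vapply(rois, `[[`, 0L, "n_total")))
}

#' WHO grade from a Ki67 score
#'
#' Assigns the WHO grade band for well-differentiated neuroendocrine
#' tumors by Ki67 score: G1 for scores below 3%, G2 for 3–20%
#' (inclusive on both ends), G3 above 20%. Grading uses the unrounded
#' score.
#'
#' @param score A defined [ki67_score()], or a bare numeric percentage.
#' @return `"G1"`, `"G2"` or `"G3"` (character).
#' @examples
#' ki67_grade(2.99)  # "G1"
#' ki67_grade(3.0)   # "G2"
#' ki67_grade(20.01) # "G3"
#' @export
ki67_grade <- function(score) {
  pct <- if (inherits(score, "ki67_score")) score$score_pct
         else as.numeric(score)
  if (length(pct) != 1L || is.na(pct)) {
    stop("cannot grade an undefined Ki67 score", call. = FALSE)
  }
  if (pct < 0 || pct > 100) {
    stop("Ki67 score must lie in [0, 100] percent", call. = FALSE)
  }
  if (pct < 3) "G1" else if (pct <= 20) "G2" else "G3"
}
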