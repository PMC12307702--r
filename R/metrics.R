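#' Detection metrics from TP/FP/FN counts
#'
#' Builds a `detection_metrics` object from raw counts: false discovery
#' rate `fdr = fp / (tp + fp)`, `precision = tp / (tp + fp)`,
#' `recall = tp / (tp + fn)` and the F-score, the harmonic mean
#' `2 * precision * recall / (precision + recall)`. A ratio whose
#' denominator is zero is undefined and returned as `NA`; undefined
#' ratios are excluded from median aggregation and absorbed naturally by
#' pooled aggregation. This case is routine: an ROI with no
#' Ki67-positive reference cells has undefined positive-stratum recall.
#'
#' @param tp,fp,fn Non-negative counts.
#' @return An object of class `detection_metrics` with fields `tp`, `fp`,
#'   `fn`, `fdr`, `precision`, `recall`, `f_score`.
#' @examples
#' detection_metrics(tp = 70, fp = 30, fn = 0)   # precision 0.70, fdr 0.30
#' @export
detection_metrics <- function(tp, fp, fn) {
  stopifnot(length(tp) == 1L, length(fp) == 1L, length(fn) == 1L,
            tp >= 0, fp >= 0, fn >= 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f_score <- if (!is.na(precision) && !is.na(recall) &&
                 precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    NA_real_
  }
  structure(
    list(tp = as.integer(round(tp)), fp = as.integer(round(fp)),
         fn = as.integer(round(fn)),
         fdr = 1 - precision, precision = precision, recall = recall,
         f_score = f_score),
    class = "detection_metrics"
  )
}

#' @export
print.detection_metrics <- function(x, ...) {
  cat(sprintf(
    "<detection_metrics> TP %d, FP %d, FN %d | FDR %.3f, precision %.3f, recall %.3f, F %.3f\n",
    x$tp, x$fp, x$fn, x$fdr, x$precision, x$recall, x$f_score))
  invisible(x)
}

#' Detection metrics of one capped assignment
#'
#' Converts a [match_points()] result into [detection_metrics()]:
#' matched pairs are TP, unmatched detector points FP, unmatched
#' reference points FN.
#'
#' @param m A `match_result`.
#' @return A `detection_metrics` object.
#' @export
metrics_from_match <- function(m) {
  stopifnot(inherits(m, "match_result"))
  detection_metrics(tp = nrow(m$pairs), fp = length(m$fp_det),
                    fn = length(m$fn_ref))
}

as_metrics_list <- function(x) {
  lapply(x, function(el) {
    if (inherits(el, "match_result")) metrics_from_match(el)
    else if (inherits(el, "detection_metrics")) el
    else stop("expected match_result or detection_metrics elements",
              call. = FALSE)
  })
}

#' Aggregate per-ROI detection metrics over a case
#'
#' Two aggregation modes are supported. `"pooled"` sums TP/FP/FN over the
#' ROIs of a case and derives the ratios from the summed counts — the
#' natural per-case value when every ROI contributes its cells to one
#' case-level count. `"median"` takes the median of the per-ROI ratios,
#' dropping undefined (`NA`) ratios — the summary used when comparing
#' per-ROI metric distributions between tools.
#'
#' @param x A non-empty list of `detection_metrics` or `match_result`
#'   objects (one per ROI).
#' @param mode `"pooled"` or `"median"`.
#' @return For `"pooled"`, a `detection_metrics` object; for `"median"`,
#'   a list with fields `fdr`, `precision`, `recall`, `f_score` (medians
#'   of the defined per-ROI values).
#' @export
aggregate_case <- function(x, mode = c("pooled", "median")) {
  mode <- match.arg(mode)
  if (!is.list(x) || length(x) == 0L) {
    stop("`x` must be a non-empty list of per-ROI results", call. = FALSE)
  }
  ms <- as_metrics_list(x)
  if (mode == "pooled") {
    detection_metrics(tp = sum(vapply(ms, `[[`, 0L, "tp")),
                      fp = sum(vapply(ms, `[[`, 0L, "fp")),
                      fn = sum(vapply(ms, `[[`, 0L, "fn")))
  } else {
    med <- function(field) {
      v <- vapply(ms, `[[`, 0, field)
      v <- v[!is.na(v)]
      if (length(v)) stats::median(v) else NA_real_
    }
    list(fdr = med("fdr"), precision = med("precision"),
         recall = med("recall"), f_score = med("f_score"))
  }
}

#' Over/under/equal tally of paired counts
#'
#' Counts, over paired per-unit series (e.g. per-ROI cell counts), how
#' many units the detector over-counted (`det > ref`), under-counted
#' (`det < ref`) or matched exactly.
#'
#' @param ref_counts,det_counts Equal-length numeric vectors.
#' @return A list with `n_over`, `n_under`, `n_equal`, `n_units`.
#' @export
compare_counts <- function(ref_counts, det_counts) {
  if (length(ref_counts) != length(det_counts)) {
    stop("`ref_counts` and `det_counts` must have equal length",
         call. = FALSE)
  }
  list(n_over = sum(det_counts > ref_counts),
       n_under = sum(det_counts < ref_counts),
       n_equal = sum(det_counts == ref_counts),
       n_units = length(ref_counts))
}

#' Ordinary least-squares line through paired counts
#'
#' Slope and intercept of the regression of detector counts on reference
#' counts, summarising the linear association between the two series.
#'
#' @param x,y Numeric vectors of equal length, `n >= 2`, `x` not constant.
#' @return A list with `slope` and `intercept`.
#' @export
linear_fit <- function(x, y) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length", call. = FALSE)
  }
  if (length(x) < 2L) stop("need at least 2 points", call. = FALSE)
  if (stats::var(x) == 0) {
    stop("`x` is constant; the regression line is undefined", call. = FALSE)
  }
  cf <- stats::coef(stats::lm(y ~ x))
  list(slope = unname(cf[2L]), intercept = unname(cf[1L]))
}
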