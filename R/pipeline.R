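#' Write a simulated study to disk
#'
#' Lays a [simulate_study()] result out as the directory tree the
#' evaluation pipeline consumes: one CSV of dot annotations per ROI and
#' source under `points/`, plus a `manifest.json` listing, for every ROI
#' of every case, the reference file, the detector files and their
#' coordinate frames. Frames are recorded per source because detector
#' exports may live on a different pixel grid than the original ROI.
#'
#' @param study A `ki67_study`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "ki67_study"))
  dir.create(file.path(dir, "points"), recursive = TRUE,
             showWarnings = FALSE)
  frame_to_list <- function(fr) {
    list(width_px = fr$width_px, height_px = fr$height_px,
         um_per_px = fr$um_per_px)
  }
  entry_for <- function(set, fname) {
    write_points(set, file.path(dir, "points", fname))
    list(path = file.path("points", fname),
         frame = frame_to_list(set$frame))
  }
  rois <- lapply(study$rois, function(r) {
    base <- sprintf("%s_%s", r$case_id, r$roi_id)
    dets <- lapply(names(r$detectors), function(nm) {
      entry_for(r$detectors[[nm]], sprintf("%s_%s.csv", base, nm))
    })
    names(dets) <- names(r$detectors)
    list(case_id = r$case_id, roi_id = r$roi_id,
         reference = entry_for(r$reference,
                               sprintf("%s_reference.csv", base)),
         detectors = dets)
  })
  manifest <- list(detectors = study$detectors, seed = study$seed,
                   rois = rois)
  mpath <- file.path(dir, "manifest.json")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), mpath)
  invisible(mpath)
}

manifest_frame <- function(fl) {
  coord_frame(fl$width_px, fl$height_px, fl$um_per_px)
}

#' Read a study from a manifest
#'
#' Loads the directory layout written by [write_study()] (or assembled by
#' hand for real annotation exports) back into a `ki67_study` object.
#' Every referenced file must exist; a missing or malformed file is an
#' error naming the offending ROI.
#'
#' @param manifest_path Path to `manifest.json`.
#' @return A `ki67_study`.
#' @export
read_study <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop(sprintf("manifest not found: %s", manifest_path), call. = FALSE)
  }
  m <- jsonlite::fromJSON(manifest_path, simplifyVector = FALSE)
  if (is.null(m$rois) || !length(m$rois)) {
    stop("manifest lists no ROIs", call. = FALSE)
  }
  base <- dirname(manifest_path)
  load_set <- function(entry, source, case_id, roi_id) {
    p <- file.path(base, entry$path)
    if (!file.exists(p)) {
      stop(sprintf("%s/%s: annotation file missing: %s",
                   case_id, roi_id, p), call. = FALSE)
    }
    read_points(p, manifest_frame(entry$frame), source = source,
                roi_id = roi_id, case_id = case_id)
  }
  rois <- lapply(m$rois, function(r) {
    dets <- lapply(names(r$detectors), function(nm) {
      load_set(r$detectors[[nm]], nm, r$case_id, r$roi_id)
    })
    names(dets) <- names(r$detectors)
    list(case_id = r$case_id, roi_id = r$roi_id,
         reference = load_set(r$reference, "reference",
                              r$case_id, r$roi_id),
         detectors = dets)
  })
  case_ids <- unique(vapply(rois, `[[`, "", "case_id"))
  det_names <- names(rois[[1]]$detectors)
  structure(
    list(rois = rois, n_cases = length(case_ids),
         rois_per_case = length(rois) / length(case_ids),
         detectors = det_names, seed = m$seed,
         ref_cfg = NULL, models = NULL),
    class = "ki67_study"
  )
}

# An agreement series with zero total variance (e.g. a detector replaying
# a constant reference count) has no defined ICC; report NA rather than
# abort the evaluation.
na_icc <- function(variant, n) {
  structure(
    list(icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
         f_value = NA_real_, df1 = NA_integer_, df2 = NA_integer_,
         p_value = NA_real_, variant = variant, n = n, k = 2L,
         ms = NULL, conf_level = 0.95),
    class = "icc_result")
}

safe_agreement_report <- function(a, b, label) {
  tryCatch(agreement_report(a, b, label), error = function(e) {
    structure(
      list(label = label, n = length(a),
           icc_consistency = na_icc("consistency", length(a)),
           icc_absolute = na_icc("absolute_agreement", length(a)),
           bland_altman = bland_altman_nonparametric(a, b),
           wilcoxon = wilcoxon_signed_rank(a, b),
           note = conditionMessage(e)),
      class = "agreement_report")
  })
}

metrics_row <- function(dm) {
  data.frame(tp = dm$tp, fp = dm$fp, fn = dm$fn, fdr = dm$fdr,
             precision = dm$precision, recall = dm$recall,
             f_score = dm$f_score)
}

#' Evaluate detectors against the reference standard over a study
#'
#' Runs the full cell-level evaluation for every detector of a study:
#' detector coordinates are mapped onto the reference frame, paired with
#' the reference standard by distance-capped optimal assignment
#' ([match_points()]) both over all cells and over the Ki67-positive
#' stratum, and summarised as per-ROI detection metrics, per-case pooled
#' metrics, Ki67 scores and WHO grades, over/under-count tallies, the
#' detector-vs-reference regression line, and the agreement-statistics
#' suite (ICC in both variants, nonparametric Bland-Altman, paired
#' Wilcoxon) on per-ROI total counts, positive counts and Ki67 scores,
#' plus case-level score agreement.
#'
#' When `out_dir` is given, the results are also written as fixed-format
#' CSV tables (`per_roi_metrics.csv`, `roi_counts.csv`,
#' `per_case_metrics.csv`, `case_scores.csv`) and a machine-readable
#' `report.json`; outputs are byte-reproducible for identical inputs.
#'
#' @param study A `ki67_study` (from [simulate_study()] or
#'   [read_study()]).
#' @param max_dist_um Matching cap in micrometres (see [match_config()]).
#' @param out_dir Optional output directory.
#' @return An object of class `ki67_evaluation`; see Details.
#' @details The returned list carries `per_roi` (per-ROI, per-stratum
#'   metric table), `roi_counts` (per-ROI counts and scores),
#'   `per_case` (pooled and median-aggregated per-case metrics),
#'   `case_scores` (per-case Ki67 scores, grades and grade-change
#'   flags), `agreement` (per detector, per series), `count_comparisons`,
#'   `regression` and the cap used (`tau_um`).
#' @export
evaluate_study <- function(study, max_dist_um = 15, out_dir = NULL) {
  stopifnot(inherits(study, "ki67_study"))
  cfg <- match_config(max_dist_um)
  per_roi <- NULL
  roi_counts <- NULL
  for (r in study$rois) {
    ref <- r$reference
    ref_sc <- roi_score(ref)
    for (nm in names(r$detectors)) {
      det <- transform_to_frame(r$detectors[[nm]], ref$frame)
      sm <- stratified_match(ref, det, cfg)
      det_sc <- roi_score(det)
      for (stratum in c("total", "positive")) {
        dm <- metrics_from_match(sm[[stratum]])
        per_roi <- rbind(per_roi, cbind(
          data.frame(case_id = r$case_id, roi_id = r$roi_id,
                     detector = nm, stratum = stratum),
          metrics_row(dm)))
      }
      roi_counts <- rbind(roi_counts, data.frame(
        case_id = r$case_id, roi_id = r$roi_id, detector = nm,
        ref_total = n_points(ref), det_total = n_points(det),
        ref_positive = n_positive(ref), det_positive = n_positive(det),
        ref_score = ref_sc$score_pct, det_score = det_sc$score_pct))
    }
  }
  ord <- order(per_roi$case_id, per_roi$roi_id, per_roi$detector,
               per_roi$stratum)
  per_roi <- per_roi[ord, , drop = FALSE]
  rownames(per_roi) <- NULL
  roi_counts <- roi_counts[order(roi_counts$case_id, roi_counts$roi_id,
                                 roi_counts$detector), , drop = FALSE]
  rownames(roi_counts) <- NULL

  # per-case aggregation: pooled counts and per-ROI-median ratios
  per_case <- NULL
  case_scores <- NULL
  for (cid in unique(per_roi$case_id)) {
    cc <- roi_counts[roi_counts$case_id == cid, , drop = FALSE]
    for (nm in study$detectors) {
      ccd <- cc[cc$detector == nm, , drop = FALSE]
      ref_case <- ki67_score(sum(ccd$ref_positive), sum(ccd$ref_total))
      det_case <- ki67_score(sum(ccd$det_positive), sum(ccd$det_total))
      ref_grade <- ki67_grade(ref_case)
      det_grade <- ki67_grade(det_case)
      case_scores <- rbind(case_scores, data.frame(
        case_id = cid, detector = nm,
        ref_score = ref_case$score_pct, det_score = det_case$score_pct,
        ref_grade = ref_grade, det_grade = det_grade,
        grade_change = ref_grade != det_grade))
      for (stratum in c("total", "positive")) {
        sel <- per_roi$case_id == cid & per_roi$detector == nm &
          per_roi$stratum == stratum
        rows <- per_roi[sel, , drop = FALSE]
        ms <- lapply(seq_len(nrow(rows)), function(i) {
          detection_metrics(rows$tp[i], rows$fp[i], rows$fn[i])
        })
        pooled <- aggregate_case(ms, "pooled")
        med <- aggregate_case(ms, "median")
        per_case <- rbind(per_case, cbind(
          data.frame(case_id = cid, detector = nm, stratum = stratum),
          metrics_row(pooled),
          data.frame(fdr_median = med$fdr, precision_median = med$precision,
                     recall_median = med$recall,
                     f_score_median = med$f_score)))
      }
    }
  }
  rownames(per_case) <- NULL
  rownames(case_scores) <- NULL

  # agreement suite, count tallies and regression per detector
  agreement <- list()
  count_comparisons <- list()
  regression <- list()
  for (nm in study$detectors) {
    dc <- roi_counts[roi_counts$detector == nm, , drop = FALSE]
    csd <- case_scores[case_scores$detector == nm, , drop = FALSE]
    ok_score <- !is.na(dc$ref_score) & !is.na(dc$det_score)
    agreement[[nm]] <- list(
      roi_total_counts = safe_agreement_report(
        dc$ref_total, dc$det_total,
        sprintf("%s: per-ROI total cell counts", nm)),
      roi_positive_counts = safe_agreement_report(
        dc$ref_positive, dc$det_positive,
        sprintf("%s: per-ROI Ki67-positive counts", nm)),
      roi_scores = safe_agreement_report(
        dc$ref_score[ok_score], dc$det_score[ok_score],
        sprintf("%s: per-ROI Ki67 scores", nm)),
      # undefined for single-case studies
      case_scores = tryCatch(
        bland_altman_nonparametric(csd$ref_score, csd$det_score),
        error = function(e) {
          structure(list(bias = NA_real_, loa_low = NA_real_,
                         loa_high = NA_real_, means = numeric(0),
                         diffs = numeric(0), n = nrow(csd),
                         note = conditionMessage(e)),
                    class = "bland_altman_result")
        }))
    count_comparisons[[nm]] <- list(
      total = compare_counts(dc$ref_total, dc$det_total),
      positive = compare_counts(dc$ref_positive, dc$det_positive),
      score = compare_counts(dc$ref_score[ok_score],
                             dc$det_score[ok_score]))
    # a constant reference series (e.g. simulated ROIs with a fixed cell
    # count) has no defined regression line; record NA rather than fail
    regression[[nm]] <- tryCatch(
      linear_fit(dc$ref_total, dc$det_total),
      error = function(e) list(slope = NA_real_, intercept = NA_real_))
  }

  res <- structure(
    list(per_roi = per_roi, roi_counts = roi_counts, per_case = per_case,
         case_scores = case_scores, agreement = agreement,
         count_comparisons = count_comparisons, regression = regression,
         tau_um = max_dist_um, detectors = study$detectors),
    class = "ki67_evaluation"
  )
  if (!is.null(out_dir)) write_evaluation(res, out_dir)
  res
}

#' @export
print.ki67_evaluation <- function(x, ...) {
  cat(sprintf(
    "<ki67_evaluation> %d ROI rows, detectors: %s, cap %g um\n",
    nrow(x$roi_counts) / length(x$detectors),
    paste(x$detectors, collapse = ", "), x$tau_um))
  for (nm in x$detectors) {
    pooled <- x$per_case[x$per_case$detector == nm &
                           x$per_case$stratum == "total", , drop = FALSE]
    tot <- aggregate_case(lapply(seq_len(nrow(pooled)), function(i) {
      detection_metrics(pooled$tp[i], pooled$fp[i], pooled$fn[i])
    }), "pooled")
    cat(sprintf(
      "  %s (all cells, pooled): FDR %.2f, precision %.2f, recall %.2f, F %.2f\n",
      nm, tot$fdr, tot$precision, tot$recall, tot$f_score))
  }
  invisible(x)
}

#' Pooled study-level metrics of an evaluation
#'
#' Sums TP/FP/FN over every ROI of the study for one detector and
#' stratum and derives the pooled FDR/precision/recall/F-score.
#'
#' @param eval_res A `ki67_evaluation`.
#' @param detector Detector name.
#' @param stratum `"total"` or `"positive"`.
#' @return A `detection_metrics` object.
#' @export
pooled_metrics <- function(eval_res, detector,
                           stratum = c("total", "positive")) {
  stopifnot(inherits(eval_res, "ki67_evaluation"))
  stratum <- match.arg(stratum)
  rows <- eval_res$per_roi[eval_res$per_roi$detector == detector &
                             eval_res$per_roi$stratum == stratum, ,
                           drop = FALSE]
  if (!nrow(rows)) stop(sprintf("unknown detector: %s", detector),
                        call. = FALSE)
  detection_metrics(sum(rows$tp), sum(rows$fp), sum(rows$fn))
}

write_evaluation <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  wcsv(res$per_roi, "per_roi_metrics.csv")
  wcsv(res$roi_counts, "roi_counts.csv")
  wcsv(res$per_case, "per_case_metrics.csv")
  wcsv(res$case_scores, "case_scores.csv")
  report <- list(
    max_dist_um = res$tau_um,
    detectors = res$detectors,
    agreement = lapply(res$agreement, function(a) {
      list(roi_total_counts = agreement_report_to_list(a$roi_total_counts),
           roi_positive_counts =
             agreement_report_to_list(a$roi_positive_counts),
           roi_scores = agreement_report_to_list(a$roi_scores),
           case_scores = list(bias = a$case_scores$bias,
                              loa_low = a$case_scores$loa_low,
                              loa_high = a$case_scores$loa_high,
                              n = a$case_scores$n))
    }),
    count_comparisons = res$count_comparisons,
    regression = res$regression,
    grade_changes = res$case_scores[res$case_scores$grade_change,
                                    c("case_id", "detector", "ref_grade",
                                      "det_grade")]
  )
  writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, dataframe = "rows"),
             file.path(out_dir, "report.json"))
  invisible(out_dir)
}

#' Read a per-ROI count table
#'
#' Loads a CSV of per-ROI cell counts (such as a study's deposited
#' supplementary count tables) into a data frame. The file must contain
#' `case` and `roi` columns (case-insensitive); all remaining columns are
#' returned as numeric count/score series, so paired columns (for
#' example reference and detector counts) can be fed straight into
#' [icc_two_way_mixed_single()] or [compare_counts()].
#'
#' @param path CSV path.
#' @return A data frame with `case`, `roi` and the numeric count columns.
#' @export
read_roi_counts <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("count table not found: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("case", "roi") %in% names(df))) {
    stop(sprintf("%s: need `case` and `roi` columns (header: %s)", path,
                 paste(names(df), collapse = ", ")), call. = FALSE)
  }
  num_cols <- setdiff(names(df), c("case", "roi"))
  for (cl in num_cols) df[[cl]] <- as.numeric(df[[cl]])
  df
}
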