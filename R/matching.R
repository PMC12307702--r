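#' Matching configuration
#'
#' The only tunable of the assignment step is the maximum permitted match
#' distance `max_dist_um` (the cap, in micrometres). Dot annotations are
#' not guaranteed to sit at the nucleus centre — annotators and detectors
#' alike may place the dot near the edge of a cell — so two markings of
#' the same cell can be up to roughly one cell diameter apart. The cap
#' encodes that maximum plausible diameter of a tumor cell; pairs farther
#' apart are never matched. The default of 15 um is a realistic maximum
#' nuclear diameter for well-differentiated neuroendocrine tumor cells
#' and is converted to pixels with the shared frame's `um_per_px`.
#'
#' @param max_dist_um Positive real, the cap in micrometres.
#' @return An object of class `match_config`.
#' @export
match_config <- function(max_dist_um = 15) {
  if (!is.numeric(max_dist_um) || length(max_dist_um) != 1L ||
      !is.finite(max_dist_um) || max_dist_um <= 0) {
    stop("`max_dist_um` must be a single positive number", call. = FALSE)
  }
  structure(list(max_dist_um = as.numeric(max_dist_um)),
            class = "match_config")
}

# Euclidean distance matrix between the points of two sets (pixels).
cross_distances <- function(ref, det) {
  rx <- ref$points$x; ry <- ref$points$y
  dx <- det$points$x; dy <- det$points$y
  sqrt(outer(rx, dx, "-")^2 + outer(ry, dy, "-")^2)
}

new_match_result <- function(pairs, n_ref, n_det, tau_um, tau_px) {
  pairs <- pairs[order(pairs$ref, pairs$det), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(
    list(pairs = pairs,
         fn_ref = setdiff(seq_len(n_ref), pairs$ref),
         fp_det = setdiff(seq_len(n_det), pairs$det),
         n_ref = n_ref, n_det = n_det,
         tau_um = tau_um, tau_px = tau_px),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(
    "<match_result> %d ref vs %d det points, cap %g um: %d TP, %d FN, %d FP\n",
    x$n_ref, x$n_det, x$tau_um, nrow(x$pairs),
    length(x$fn_ref), length(x$fp_det)))
  invisible(x)
}

# Lexicographic canonicalization of exact distance ties: an assignment
# optimal in (count, total distance) stays optimal when a matched point is
# swapped for an unmatched one at identical distance; prefer the lower
# index so the returned pair set is deterministic across solvers.
canonicalize_ties <- function(pairs, fn_ref, fp_det, D, tol = 1e-9) {
  repeat {
    changed <- FALSE
    ord <- order(pairs$ref, pairs$det)
    pairs <- pairs[ord, , drop = FALSE]
    for (k in seq_len(nrow(pairs))) {
      r <- pairs$ref[k]; d <- pairs$det[k]; dist <- pairs$dist_px[k]
      cand_r <- fn_ref[fn_ref < r & abs(D[fn_ref, d] - dist) <= tol]
      if (length(cand_r)) {
        r2 <- min(cand_r)
        fn_ref <- sort(c(setdiff(fn_ref, r2), r))
        pairs$ref[k] <- r2
        changed <- TRUE
        break
      }
      cand_d <- fp_det[fp_det < d & abs(D[r, fp_det] - dist) <= tol]
      if (length(cand_d)) {
        d2 <- min(cand_d)
        fp_det <- sort(c(setdiff(fp_det, d2), d))
        pairs$det[k] <- d2
        changed <- TRUE
        break
      }
    }
    if (!changed) break
  }
  pairs
}

# Solve one connected component exactly via a padded square assignment:
# real pair (i, j) costs its distance when <= tau and a prohibitive cost
# otherwise; every point owns a dedicated dummy partner costing P, with
# P large enough that leaving a matchable point unmatched is never
# cheaper than any extra match. This realises "maximise matches first,
# then minimise total distance".
solve_component <- function(D, tau_px, ref_idx, det_idx) {
  m <- length(ref_idx); n <- length(det_idx)
  s <- m + n
  P <- s * tau_px + 1
  BIG <- 2 * s * (P + tau_px) + 1
  cost <- matrix(BIG, s, s)
  sub <- D[ref_idx, det_idx, drop = FALSE]
  allowed <- sub <= tau_px
  block <- sub
  block[!allowed] <- BIG
  cost[seq_len(m), seq_len(n)] <- block
  for (i in seq_len(m)) cost[i, n + i] <- P
  for (j in seq_len(n)) cost[m + j, j] <- P
  cost[m + seq_len(n), n + seq_len(m)] <- 0
  sol <- lap_solve(cost)
  out <- NULL
  for (i in seq_len(m)) {
    j <- sol[i]
    if (j <= n && allowed[i, j]) {
      out <- rbind(out, data.frame(ref = ref_idx[i], det = det_idx[j],
                                   dist_px = sub[i, j]))
    }
  }
  out
}

#' Distance-capped optimal assignment of detector to reference points
#'
#' Pairs the points of a detector's annotation set with those of the
#' reference standard by optimal one-to-one assignment (the Hungarian
#' method), using only pairs whose Euclidean distance does not exceed the
#' cap of `cfg`. Among all one-to-one assignments respecting the cap the
#' result (1) maximises the number of matched pairs and (2) among those,
#' minimises the total matched distance. Matched pairs are true-positive
#' detections; unmatched reference points are false negatives and
#' unmatched detector points false positives.
#'
#' Both sets must already live on the same coordinate frame (see
#' [transform_to_frame()]). The result is deterministic: exact distance
#' ties are resolved toward the lexicographically smallest
#' `(ref_index, det_index)` pair set.
#'
#' Internally the bipartite graph of allowed pairs is split into connected
#' components, and each component is solved exactly on a padded square
#' cost matrix in which every point also has a dedicated "stay unmatched"
#' partner whose cost exceeds any achievable distance total.
#'
#' @param ref,det [annotation_set()]s on one common frame.
#' @param cfg A [match_config()].
#' @return An object of class `match_result`: `pairs` (data frame with
#'   1-based `ref`, `det` indices and `dist_px`), `fn_ref`, `fp_det`,
#'   `n_ref`, `n_det`, and the cap used (`tau_um`, `tau_px`).
#' @examples
#' fr <- coord_frame(100, 100, 1)
#' ref <- annotation_set(data.frame(x = c(0, 10), y = 0), fr)
#' det <- annotation_set(data.frame(x = 4, y = 0), fr)
#' match_points(ref, det, match_config(max_dist_um = 6))
#' @export
match_points <- function(ref, det, cfg = match_config()) {
  stopifnot(inherits(ref, "annotation_set"), inherits(det, "annotation_set"),
            inherits(cfg, "match_config"))
  if (!frames_equal(ref$frame, det$frame)) {
    stop("`ref` and `det` must share one coordinate frame; transform first",
         call. = FALSE)
  }
  tau_px <- cfg$max_dist_um / ref$frame$um_per_px
  m <- n_points(ref); n <- n_points(det)
  empty <- data.frame(ref = integer(0), det = integer(0),
                      dist_px = numeric(0))
  if (m == 0L || n == 0L) {
    return(new_match_result(empty, m, n, cfg$max_dist_um, tau_px))
  }
  D <- cross_distances(ref, det)
  A <- D <= tau_px
  # Connected components of the bipartite "within cap" graph; points with
  # no admissible partner are FN/FP immediately, and each component is
  # solved independently (optimal because no admissible pair crosses
  # components).
  comp_ref <- integer(m); comp_det <- integer(n)
  ncomp <- 0L
  for (i0 in seq_len(m)) {
    if (comp_ref[i0] != 0L || !any(A[i0, ])) next
    ncomp <- ncomp + 1L
    queue_r <- i0
    while (length(queue_r)) {
      newly_r <- queue_r[comp_ref[queue_r] == 0L]
      comp_ref[newly_r] <- ncomp
      if (!length(newly_r)) break
      js <- which(colSums(A[newly_r, , drop = FALSE]) > 0 & comp_det == 0L)
      comp_det[js] <- ncomp
      if (!length(js)) break
      queue_r <- which(rowSums(A[, js, drop = FALSE]) > 0 & comp_ref == 0L)
    }
  }
  pairs <- empty
  for (k in seq_len(ncomp)) {
    ref_idx <- which(comp_ref == k)
    det_idx <- which(comp_det == k)
    if (!length(ref_idx) || !length(det_idx)) next
    pk <- solve_component(D, tau_px, ref_idx, det_idx)
    if (!is.null(pk)) pairs <- rbind(pairs, pk)
  }
  res <- new_match_result(pairs, m, n, cfg$max_dist_um, tau_px)
  res$pairs <- canonicalize_ties(res$pairs, res$fn_ref, res$fp_det, D)
  new_match_result(res$pairs, m, n, cfg$max_dist_um, tau_px)
}

#' Exhaustive small-instance matching oracle
#'
#' Finds the same optimum as [match_points()] — maximum pair count, then
#' minimum total distance under the cap — by exhaustive dynamic
#' programming over all injective partial assignments (a bitmask over the
#' detector points). Exponential in the detector count, hence restricted
#' to at most 8 points per side; intended as an independent check of the
#' assignment solver, never as the production path.
#'
#' @inheritParams match_points
#' @return A `match_result` attaining the same optimal pair count and
#'   total distance as [match_points()] (the pairing itself may differ on
#'   exact distance ties).
#' @export
match_oracle <- function(ref, det, cfg = match_config()) {
  stopifnot(inherits(ref, "annotation_set"), inherits(det, "annotation_set"),
            inherits(cfg, "match_config"))
  if (!frames_equal(ref$frame, det$frame)) {
    stop("`ref` and `det` must share one coordinate frame; transform first",
         call. = FALSE)
  }
  m <- n_points(ref); n <- n_points(det)
  if (m > 8L || n > 8L) {
    stop("match_oracle is limited to at most 8 points per side",
         call. = FALSE)
  }
  tau_px <- cfg$max_dist_um / ref$frame$um_per_px
  empty <- data.frame(ref = integer(0), det = integer(0),
                      dist_px = numeric(0))
  if (m == 0L || n == 0L) {
    return(new_match_result(empty, m, n, cfg$max_dist_um, tau_px))
  }
  D <- cross_distances(ref, det)
  nmask <- bitwShiftL(1L, n)
  # memo[count/dist][ref row i (1..m+1), used-detector mask + 1]
  cnt <- matrix(NA_integer_, m + 1L, nmask)
  tot <- matrix(NA_real_, m + 1L, nmask)
  cnt[m + 1L, ] <- 0L
  tot[m + 1L, ] <- 0
  for (i in m:1) {
    for (mask in 0:(nmask - 1L)) {
      bc <- cnt[i + 1L, mask + 1L]
      bd <- tot[i + 1L, mask + 1L]
      for (j in seq_len(n)) {
        bit <- bitwShiftL(1L, j - 1L)
        if (bitwAnd(mask, bit) != 0L || D[i, j] > tau_px) next
        cc <- 1L + cnt[i + 1L, bitwOr(mask, bit) + 1L]
        cd <- D[i, j] + tot[i + 1L, bitwOr(mask, bit) + 1L]
        if (cc > bc || (cc == bc && cd < bd)) { bc <- cc; bd <- cd }
      }
      cnt[i, mask + 1L] <- bc
      tot[i, mask + 1L] <- bd
    }
  }
  # reconstruct one optimal assignment
  pairs <- empty
  mask <- 0L
  for (i in seq_len(m)) {
    bc <- cnt[i, mask + 1L]; bd <- tot[i, mask + 1L]
    chosen <- 0L
    for (j in seq_len(n)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(mask, bit) != 0L || D[i, j] > tau_px) next
      cc <- 1L + cnt[i + 1L, bitwOr(mask, bit) + 1L]
      cd <- D[i, j] + tot[i + 1L, bitwOr(mask, bit) + 1L]
      if (cc == bc && abs(cd - bd) <= 1e-12 * max(1, abs(bd))) {
        chosen <- j
        break
      }
    }
    if (chosen > 0L) {
      pairs <- rbind(pairs, data.frame(ref = i, det = chosen,
                                       dist_px = D[i, chosen]))
      mask <- bitwOr(mask, bitwShiftL(1L, chosen - 1L))
    }
  }
  new_match_result(pairs, m, n, cfg$max_dist_um, tau_px)
}

#' Matching stratified into all cells and Ki67-positive cells
#'
#' Detection quality is evaluated both over all tumor cells (labels
#' ignored) and, independently, over the Ki67-positive cells only: the
#' positive stratum re-runs the capped assignment restricted to the
#' positive-labeled points of both sets, so a cell detected in the right
#' place but with the wrong label counts against the positive stratum.
#'
#' @inheritParams match_points
#' @return A list with elements `total` and `positive`, each a
#'   `match_result`. Indices in `positive` refer to the positive-only
#'   subsets (in original point order).
#' @export
stratified_match <- function(ref, det, cfg = match_config()) {
  stopifnot(inherits(ref, "annotation_set"), inherits(det, "annotation_set"))
  if (!ref$labeled || !det$labeled) {
    stop("stratified matching requires labeled sets on both sides",
         call. = FALSE)
  }
  list(total = match_points(ref, det, cfg),
       positive = match_points(subset_positive(ref), subset_positive(det),
                               cfg))
}
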