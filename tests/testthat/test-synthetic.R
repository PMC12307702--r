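test_that("reference generation honors count, spacing and bounds", {
  cfg <- reference_config(n_cells = 200, seed = 53)
  ref <- generate_reference(cfg)
  expect_equal(n_points(ref), 200L)
  d_um <- as.matrix(dist(ref$points[, c("x", "y")])) * ref$frame$um_per_px
  diag(d_um) <- Inf
  expect_gte(min(d_um), cfg$min_spacing_um)
  expect_true(all(ref$points$x >= 0 & ref$points$x < 870))
  expect_identical(ref$source, "reference")

  all_neg <- generate_reference(reference_config(n_cells = 50,
                                                 p_positive = 0, seed = 1))
  expect_equal(n_positive(all_neg), 0L)

  expect_error(reference_config(n_cells = 5000, min_spacing_um = 10),
               "infeasible density")
})

test_that("the positive fraction concentrates around p_positive", {
  cfg <- reference_config(n_cells = 200, p_positive = 0.03)
  set.seed(59)
  seeds <- sample.int(1e6, 300)
  fracs <- vapply(seeds, function(s) {
    cfg$seed <- s
    r <- generate_reference(cfg)
    n_positive(r) / n_points(r)
  }, 0)
  expect_lt(abs(mean(fracs) - 0.03), 0.005)
})

test_that("generation and simulation are deterministic under a seed", {
  cfg <- reference_config(n_cells = 80, seed = 61)
  r1 <- generate_reference(cfg)
  r2 <- generate_reference(cfg)
  expect_identical(r1$points, r2$points)

  mdl <- detector_error_model(jitter_sd_um = 1, p_fn_neg = 0.1,
                              fp_per_roi = 10, p_split = 0.05,
                              p_merge = 0.3, p_label_flip = 0.05,
                              seed = 67)
  d1 <- simulate_detector(r1, mdl)
  d2 <- simulate_detector(r1, mdl)
  expect_identical(d1$points, d2$points)

  s1 <- simulate_study(2, 2, reference_config(n_cells = 40), seed = 71)
  s2 <- simulate_study(2, 2, reference_config(n_cells = 40), seed = 71)
  expect_identical(s1$rois[[3]]$detectors$cnn$points,
                   s2$rois[[3]]$detectors$cnn$points)
})

test_that("the all-zero error model reproduces the reference exactly", {
  ref <- generate_reference(reference_config(n_cells = 120, seed = 73))
  zero <- detector_error_model(jitter_sd_um = 0, name = "perfect")
  det <- simulate_detector(ref, zero)
  expect_equal(det$points, ref$points)
  expect_identical(det$source, "perfect")
})

test_that("total dropout with no clutter leaves an empty detection set", {
  ref <- generate_reference(reference_config(n_cells = 60, seed = 79))
  gone <- simulate_detector(ref, detector_error_model(
    jitter_sd_um = 0, p_fn_neg = 1, p_fn_pos = 1, fp_per_roi = 0))
  expect_equal(n_points(gone), 0L)
})

test_that("error-model validation rejects out-of-range rates", {
  expect_error(detector_error_model(p_fn_neg = 1.2), "out of \\[0, 1\\]")
  expect_error(detector_error_model(fp_per_roi = -1), "fp_per_roi")
})

test_that("measured miss rate recovers the configured dropout", {
  # no clutter, jitter well below the cap: the matching pipeline must
  # measure recall = 1 - dropout up to binomial noise (10 ROIs x 200)
  mdl <- list(d = detector_error_model(jitter_sd_um = 1, p_fn_neg = 0.1,
                                       p_fn_pos = 0.1, fp_per_roi = 0))
  study <- simulate_study(2, 5, reference_config(), models = mdl,
                          seed = 83)
  ev <- evaluate_study(study)
  pm <- pooled_metrics(ev, "d", "total")
  expect_lt(abs(pm$recall - 0.9), 0.03)
  expect_equal(pm$fp, 0L)
})

test_that("measured clutter recovers the configured mean away from cells", {
  # sparse ROIs and a cap below the cell spacing keep clutter from being
  # absorbed as matches, so the measured FP count estimates the Poisson
  # mean; 3 standard errors of tolerance over the replicates
  mdl <- list(d = detector_error_model(jitter_sd_um = 0.2,
                                       fp_per_roi = 12))
  study <- simulate_study(4, 5,
                          reference_config(n_cells = 30,
                                           min_spacing_um = 12),
                          models = mdl, seed = 89)
  ev <- evaluate_study(study, max_dist_um = 3)
  fp <- ev$per_roi$fp[ev$per_roi$stratum == "total"]
  se <- sd(fp) / sqrt(length(fp))
  expect_lt(abs(mean(fp) - 12), 3 * se)
})

test_that("preset detectors order as expected on a small study", {
  study <- simulate_study(4, 4, reference_config(),
                          models = preset_detectors(), seed = 97)
  ev <- evaluate_study(study)
  for (stratum in c("total", "positive")) {
    cls <- pooled_metrics(ev, "classical", stratum)
    cnn <- pooled_metrics(ev, "cnn", stratum)
    expect_lt(cnn$fdr, cls$fdr)
    expect_gt(cnn$precision, cls$precision)
    expect_gt(cnn$f_score, cls$f_score)
  }
  # the learned-style preset detects positives with recall above precision
  cnn_pos <- pooled_metrics(ev, "cnn", "positive")
  expect_gt(cnn_pos$recall, cnn_pos$precision)
})
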