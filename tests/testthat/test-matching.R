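test_that("identical point sets match perfectly at distance zero", {
  s <- random_set(30, seed = 1)
  m <- match_points(s, s, match_config(5))
  expect_equal(nrow(m$pairs), 30L)
  expect_equal(m$pairs$dist_px, rep(0, 30))
  expect_length(m$fn_ref, 0)
  expect_length(m$fp_det, 0)
})

test_that("empty sides yield pure FN or FP", {
  ref <- pset(0, 0)
  det <- pset(numeric(0), numeric(0))
  m <- match_points(ref, det)
  expect_equal(nrow(m$pairs), 0L)
  expect_equal(m$fn_ref, 1L)
  m2 <- match_points(det, ref)
  expect_equal(m2$fp_det, 1L)
})

test_that("the cap excludes distant pairs and ties break to low indices", {
  # detector point reaches (0,0) at d = 4 and (10,0) exactly at the cap 6:
  # optimum pairs it with the nearer reference point
  ref <- pset(c(0, 10), c(0, 0))
  det <- pset(4, 0)
  m <- match_points(ref, det, match_config(6))
  expect_equal(m$pairs$ref, 1L)
  expect_equal(m$pairs$dist_px, 4)
  expect_equal(m$fn_ref, 2L)

  # both reference points at d = 1: deterministic tie toward ref index 1
  refT <- pset(c(0, 2), c(0, 0))
  detT <- pset(1, 0)
  mT <- match_points(refT, detT, match_config(10))
  expect_equal(mT$pairs$ref, 1L)

  # two close chains resolve jointly
  ref2 <- pset(c(0, 5), c(0, 0))
  det2 <- pset(c(1, 6), c(0, 0))
  m2 <- match_points(ref2, det2, match_config(10))
  expect_equal(m2$pairs$ref, c(1L, 2L))
  expect_equal(m2$pairs$det, c(1L, 2L))
  expect_equal(sum(m2$pairs$dist_px), 2)
})

test_that("matching rejects mismatched frames and non-positive caps", {
  a <- pset(1, 1)
  b <- pset(1, 1, frame = coord_frame(50, 50, 2))
  expect_error(match_points(a, b), "share one coordinate frame")
  expect_error(match_config(0), "positive")
  expect_error(match_config(-3), "positive")
})

test_that("solver agrees with the exhaustive oracle on random instances", {
  set.seed(101)
  for (i in 1:150) {
    nr <- sample(0:7, 1)
    nd <- sample(0:7, 1)
    ref <- pset(runif(nr, 0, 40), runif(nr, 0, 40))
    det <- pset(runif(nd, 0, 40), runif(nd, 0, 40))
    cfg <- match_config(runif(1, 2, 25))
    a <- match_points(ref, det, cfg)
    b <- match_oracle(ref, det, cfg)
    expect_equal(nrow(a$pairs), nrow(b$pairs))
    expect_equal(sum(a$pairs$dist_px), sum(b$pairs$dist_px),
                 tolerance = 1e-9)
  }
})

test_that("oracle finds full feasibility when every pair is allowed", {
  ref <- random_set(8, seed = 7)
  det <- random_set(8, seed = 8)
  m <- match_oracle(ref, det, match_config(1000))
  expect_equal(nrow(m$pairs), 8L)
  expect_error(match_oracle(random_set(9, seed = 1), det), "at most 8")
  e <- pset(numeric(0), numeric(0))
  expect_equal(nrow(match_oracle(e, e)$pairs), 0L)
})

test_that("matching is symmetric, cap-respecting and monotone in the cap", {
  set.seed(77)
  for (i in 1:25) {
    ref <- random_set(sample(3:12, 1))
    det <- random_set(sample(3:12, 1))
    tau <- runif(1, 3, 20)
    m <- match_points(ref, det, match_config(tau))
    expect_true(all(m$pairs$dist_px <= tau / ref$frame$um_per_px + 1e-12))
    # swap sides: FN and FP swap, pair multiset is preserved
    ms <- match_points(det, ref, match_config(tau))
    expect_equal(nrow(ms$pairs), nrow(m$pairs))
    expect_equal(sum(ms$pairs$dist_px), sum(m$pairs$dist_px),
                 tolerance = 1e-9)
    expect_equal(length(ms$fn_ref), length(m$fp_det))
    expect_equal(length(ms$fp_det), length(m$fn_ref))
    # larger cap never matches fewer pairs
    m2 <- match_points(ref, det, match_config(tau * 1.7))
    expect_gte(nrow(m2$pairs), nrow(m$pairs))
  }
})

test_that("one-to-one bookkeeping identities hold", {
  ref <- random_set(40, seed = 21)
  det <- random_set(35, seed = 22)
  m <- match_points(ref, det, match_config(8))
  expect_equal(anyDuplicated(m$pairs$ref), 0L)
  expect_equal(anyDuplicated(m$pairs$det), 0L)
  expect_equal(nrow(m$pairs) + length(m$fn_ref), 40L)
  expect_equal(nrow(m$pairs) + length(m$fp_det), 35L)
})

test_that("stratified matching evaluates positives independently", {
  ref <- pset(c(10, 20, 30), c(10, 10, 10),
              c("positive", "negative", "negative"))
  det_same <- pset(c(10, 20, 30), c(10, 10, 10),
                   c("positive", "negative", "negative"))
  sm <- stratified_match(ref, det_same, match_config(5))
  expect_equal(nrow(sm$total$pairs), 3L)
  expect_equal(nrow(sm$positive$pairs), 1L)

  # right place, wrong label: total stratum matches all three, the
  # positive stratum records a miss
  det_flip <- pset(c(10, 20, 30), c(10, 10, 10),
                   c("negative", "negative", "negative"))
  sm2 <- stratified_match(ref, det_flip, match_config(5))
  expect_equal(nrow(sm2$total$pairs), 3L)
  expect_equal(nrow(sm2$positive$pairs), 0L)
  expect_length(sm2$positive$fn_ref, 1L)

  expect_error(
    stratified_match(random_set(3, seed = 1, labeled = FALSE), det_flip),
    "labeled")
})

test_that("each stratum of a random labeled instance equals its oracle", {
  set.seed(303)
  for (i in 1:30) {
    ref <- random_set(sample(2:6, 1), p_positive = 0.5)
    det <- random_set(sample(2:6, 1), p_positive = 0.5)
    cfg <- match_config(runif(1, 4, 20))
    sm <- stratified_match(ref, det, cfg)
    for (pair in list(
      list(sm$total, match_oracle(ref, det, cfg)),
      list(sm$positive, match_oracle(subset_positive(ref),
                                     subset_positive(det), cfg)))) {
      expect_equal(nrow(pair[[1]]$pairs), nrow(pair[[2]]$pairs))
      expect_equal(sum(pair[[1]]$pairs$dist_px),
                   sum(pair[[2]]$pairs$dist_px), tolerance = 1e-9)
    }
  }
})
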