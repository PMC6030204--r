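# a tiny movie with known disks, used across the image-processing tests
movie_fixture <- function(motion_amplitude = 0, seed = 5, n_neurons = 6,
                          noise_sd = 0.05) {
  g <- archetype_session("stimulus", n_neurons = n_neurons,
                         noise_sd = noise_sd, n_trials_per_block = 5,
                         n_blocks = 2, seed = seed)
  mv <- generate_movie(g$session, g$ground_truth,
                       motion_amplitude = motion_amplitude, seed = seed)
  list(g = g, mv = mv)
}

test_that("motion correction: identical frames give zero shifts", {
  img <- matrix(rnorm(32 * 32), 32, 32)
  movie <- array(rep(img, 5), c(32, 32, 5))
  mc <- motion_correct(movie)
  expect_true(all(mc$shifts == 0))
})

test_that("motion correction recovers planted rigid shifts exactly", {
  fx <- movie_fixture(motion_amplitude = 3)
  mc <- motion_correct(fx$mv$movie)
  expect_identical(mc$shifts, fx$mv$shifts)
  # a single frame translated by (+3, -2)
  base <- movie_fixture(motion_amplitude = 0)$mv$movie[, , 1:10]
  base[, , 7] <- gonogo2p:::.shift_image(base[, , 7], -2, 3,
                                         fill = median(base[, , 7]))
  mc2 <- motion_correct(base)
  expect_equal(unname(mc2$shifts[7, ]), c(3, -2))
})

test_that("motion correction is idempotent to within one pixel", {
  fx <- movie_fixture(motion_amplitude = 2)
  mc1 <- motion_correct(fx$mv$movie)
  mc2 <- motion_correct(mc1$movie)
  expect_lte(max(abs(mc2$shifts)), 1)
})

test_that("zero-variance frames yield a warning and zero shift", {
  movie <- array(rnorm(16 * 16 * 4), c(16, 16, 4))
  movie[, , 2] <- 3
  expect_warning(mc <- motion_correct(movie), "zero variance")
  expect_equal(unname(mc$shifts[2, ]), c(0, 0))
})

test_that("segmentation finds planted disks and ignores blank noise", {
  set.seed(2)
  blank <- array(rnorm(48 * 48 * 60, 30, 1), c(48, 48, 60))
  expect_length(segment_rois(blank), 0)
  fx <- movie_fixture()
  masks <- segment_rois(fx$mv$movie)
  k <- nrow(fx$g$ground_truth)
  expect_gte(length(masks), ceiling(0.9 * k))
  # each recovered mask overlaps its nearest true disk (Jaccard > 0.5)
  gt <- fx$g$ground_truth
  for (m in masks) {
    ctr <- roi_centroid(m)
    j <- which.min((gt$centroid_x - ctr["x"])^2 +
                     (gt$centroid_y - ctr["y"])^2)
    true_mask <- matrix(FALSE, 64, 64)
    px <- expand.grid(r = 1:64, c = 1:64)
    keep <- (px$r - gt$centroid_y[j])^2 + (px$c - gt$centroid_x[j])^2 <= 9
    true_mask[as.matrix(px[keep, ])] <- TRUE
    jac <- sum(m & true_mask) / sum(m | true_mask)
    expect_gt(jac, 0.5)
  }
  # masks disjoint
  expect_lte(max(Reduce(`+`, lapply(masks, function(m) m * 1))), 1)
})

test_that("well-separated disks are never merged", {
  fx <- movie_fixture()
  masks <- segment_rois(fx$mv$movie)
  gt <- fx$g$ground_truth
  # every mask is within one disk radius of exactly one true centroid
  for (m in masks) {
    ctr <- roi_centroid(m)
    d <- sqrt((gt$centroid_x - ctr["x"])^2 + (gt$centroid_y - ctr["y"])^2)
    expect_equal(sum(d < 6), 1)
  }
})

test_that("neuropil correction is the stated pointwise formula", {
  expect_equal(neuropil_correct(100, 20, 0.7), 86)
  f <- c(10, 12, 9)
  expect_equal(neuropil_correct(f, rep(0, 3)), f)
  expect_equal(neuropil_correct(f, c(1, 2, 3), r = 0), f)
  expect_error(neuropil_correct(1:3, 1:2), "length")
  # linearity in both arguments
  a <- rnorm(5); b <- rnorm(5); c2 <- rnorm(5)
  expect_equal(neuropil_correct(a + c2, b, 0.7),
               neuropil_correct(a, b, 0.7) + c2)
  expect_equal(neuropil_correct(a, b + c2, 0.7),
               neuropil_correct(a, b, 0.7) - 0.7 * c2)
})

test_that("dF/F uses the density mode as F0", {
  expect_equal(as.numeric(compute_dff(rep(5, 10))), rep(0, 10))
  set.seed(3)
  # 90% of frames at ~100 with sparse positive transients
  f <- c(rnorm(900, 100, 1), runif(100, 110, 160))
  dff <- compute_dff(f)
  expect_lt(abs(attr(dff, "F0") - 100) / 100, 0.01)
  # positive scaling leaves dF/F unchanged
  expect_equal(as.numeric(compute_dff(3 * f)), as.numeric(dff),
               tolerance = 1e-6)
  expect_error(compute_dff(c(-5, -5, -5)), "F0")
})

test_that("extracted annulus excludes ROI pixels and recovers the soma", {
  fx <- movie_fixture()
  masks <- segment_rois(fx$mv$movie)
  recs <- extract_roi_traces(fx$mv$movie, masks)
  all_rois <- Reduce(`|`, masks)
  for (r in recs) {
    # neuropil-corrected, dF/F-normalised trace correlates with the truth
    fc <- neuropil_correct(r$F_raw_soma, r$F_neuropil, 0.7)
    dff <- compute_dff(fc)
    gt <- fx$g$ground_truth
    j <- which.min((gt$centroid_x - r$centroid["x"])^2 +
                     (gt$centroid_y - r$centroid["y"])^2)
    expect_gt(cor(as.numeric(dff), fx$g$session$traces[j, ]), 0.95)
  }
})

test_that("cross-session alignment recovers global translations", {
  fx <- movie_fixture()
  imgA <- apply(fx$mv$movie, c(1, 2), mean)
  masks <- segment_rois(fx$mv$movie)
  # keep ROIs away from the borders so the +4 warp stays in the image
  central <- vapply(masks, function(m) {
    ctr <- roi_centroid(m)
    all(ctr > 16 & ctr < 48)
  }, logical(1))
  masks <- masks[central]
  expect_gte(length(masks), 2)
  anchors0 <- data.frame(x = 32, y = 32, dx = 0, dy = 0)
  al0 <- align_rois_across_sessions(imgA, imgA, masks, anchors0)
  expect_true(all(al0$comp_dx == 0 & al0$comp_dy == 0))
  expect_false(any(al0$flagged))
  imgB <- gonogo2p:::.shift_image(imgA, 4, 4, fill = median(imgA))
  al <- align_rois_across_sessions(imgA, imgB, masks,
                                   data.frame(x = c(10, 50), y = c(10, 50),
                                              dx = 4, dy = 4))
  expect_true(all(abs(al$comp_dx - 4) <= 1 & abs(al$comp_dy - 4) <= 1))
  expect_false(any(al$flagged))
})

test_that("a private 8 px offset is flagged by the 5 px rule", {
  fx <- movie_fixture()
  imgA <- apply(fx$mv$movie, c(1, 2), mean)
  masks <- segment_rois(fx$mv$movie)
  central <- vapply(masks, function(m) {
    ctr <- roi_centroid(m); all(ctr > 20 & ctr < 44)
  }, logical(1))
  m1 <- masks[central][1]
  expect_length(m1, 1)
  # build image B where only this ROI's neighbourhood moved by (8, 8)
  imgB <- imgA
  ctr <- roi_centroid(m1[[1]])
  rows <- max(1, round(ctr["y"]) - 16):min(56, round(ctr["y"]) + 16)
  cols <- max(1, round(ctr["x"]) - 16):min(56, round(ctr["x"]) + 16)
  imgB[rows, cols] <- median(imgA)
  imgB[rows + 8, cols + 8] <- imgA[rows, cols]
  al <- align_rois_across_sessions(imgA, imgB, m1,
                                   data.frame(x = 32, y = 32, dx = 0,
                                              dy = 0))
  expect_true(al$flagged[1])
})

test_that("alignment skips ROIs whose window leaves the image", {
  img <- matrix(rnorm(64 * 64), 64, 64)
  m <- matrix(FALSE, 64, 64); m[2:6, 2:6] <- TRUE
  expect_warning(
    al <- align_rois_across_sessions(img, img, list(m),
                                     data.frame(x = 32, y = 32, dx = 0,
                                                dy = 0)),
    "skipped")
  expect_true(is.na(al$comp_dx[1]))
})
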