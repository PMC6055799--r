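# Contrast enhancement, feature bank, trainable classification, closing.

test_that("contrast enhancement handles degenerate and linear cases", {
  expect_error(enhance_contrast(matrix(1, 4, 4), saturation_fraction = 0.5),
               "saturation_fraction")
  const <- enhance_contrast(matrix(7, 8, 8))
  expect_true(all(const == 0))
  f <- matrix(c(10, 30, 50, 90), 2, 2)
  out <- enhance_contrast(f, 0)
  expect_equal(out, (f - 10) / 80)
})

test_that("contrast enhancement preserves intensity rank order", {
  set.seed(42)
  for (i in 1:5) {
    f <- matrix(runif(400), 20, 20)
    out <- enhance_contrast(f, 0)
    o <- order(f)
    expect_true(all(diff(out[o]) >= 0))
  }
})

test_that("feature stack has the contracted shape and zero derivatives on constants", {
  expect_error(extract_pixel_features(matrix(0, 8, 8), scales = c(1, -2)),
               "positive")
  fs <- extract_pixel_features(matrix(5, 16, 16), scales = c(1, 2))
  expect_equal(dim(fs$features), c(16, 16, 8))
  # gradient, laplacian and DoG channels are exactly zero
  for (k in c(2, 3, 4, 6, 7, 8))
    expect_true(all(abs(fs$features[, , k]) < 1e-10))
})

test_that("smoothed-intensity variance is non-increasing in scale", {
  set.seed(7)
  for (i in 1:3) {
    f <- matrix(runif(64 * 64), 64, 64)
    fs <- extract_pixel_features(f, scales = c(1, 2, 4))
    v <- c(var(as.vector(fs$features[, , 1])),
           var(as.vector(fs$features[, , 5])),
           var(as.vector(fs$features[, , 9])))
    expect_true(all(diff(v) <= 1e-12))
  }
})

test_that("classifier training is validated, seeded, and separates a 3-level image", {
  set.seed(3)
  frame <- matrix(0.1, 60, 60)
  frame[, 21:40] <- 0.5
  frame[, 41:60] <- 0.9
  labels <- matrix(2L, 60, 60)
  labels[, 21:40] <- 1L
  labels[, 41:60] <- 3L
  fs <- extract_pixel_features(frame, scales = 1)
  bad <- labels; bad[bad == 3L] <- 0L
  expect_error(train_pixel_classifier(fs, bad), "rejected")
  clf <- train_pixel_classifier(fs, labels, seed = 2)
  expect_equal(unname(clf$training_recall), c(1, 1, 1))
  m1 <- predict_class_map(clf, frame)
  m2 <- predict_class_map(clf, frame)
  expect_identical(m1, m2)
  expect_true(mean(m1 == labels) > 0.99)
})

test_that("trained classifier rejects bright distractors and recovers the ER mask", {
  fx <- classifier_fixture()
  seg <- segment_image(fx$frame, classifier = fx$classifier)
  truth <- fx$phantom$truth
  # held-out rejected-class recall on the distractor truth mask
  expect_gte(mean(seg$class_map[truth$distractor_mask == 1L] == 3L), 0.95)
  expect_gte(jaccard(seg$er_mask, truth$er_mask), 0.8)
  # distractor leakage into the ER mask stays below 1% of distractor area
  expect_lt(sum(seg$er_mask & truth$distractor_mask) /
              sum(truth$distractor_mask), 0.01)
})

test_that("threshold segmentation matches the classifier on clean images and degrades gracefully", {
  spec <- noiseless_spec(6, cisternae_fraction = 0.05)
  ph <- render_phantom(generate_network_graph(spec))
  seg_thr <- segment_image(ph$image$frames[[1]], threshold = 0.5)
  expect_identical(seg_thr$er_mask, ph$truth$er_mask)
  seg_otsu <- segment_image(ph$image$frames[[1]])
  expect_identical(seg_otsu$er_mask, ph$truth$er_mask)
  # moderate noise: after the connectivity-repairing closing, Jaccard
  # against truth stays high
  spn <- noisy_spec(23, peak_photons = 50)
  phn <- render_phantom(generate_network_graph(spn))
  segn <- segment_image(phn$image$frames[[1]])
  expect_gte(jaccard(close_mask(segn$er_mask, 2, 1), phn$truth$er_mask),
             0.8)
  expect_error(segment_image(phn$image$frames[[1]], threshold = 2),
               "threshold")
})

test_that("segmentation quality is monotone in SNR", {
  jac <- vapply(c(20, 50, 200), function(pk) {
    ph <- render_phantom(generate_network_graph(
      noisy_spec(22, peak_photons = pk, cisternae_fraction = 0.08,
                 tubule_width_px = 3)))
    seg <- segment_image(ph$image$frames[[1]])
    jaccard(seg$er_mask, ph$truth$er_mask)
  }, 0)
  expect_true(all(diff(jac) > 0))
})

test_that("classifier applied to pure background yields an essentially empty ER mask", {
  fx <- classifier_fixture()
  set.seed(31)
  bg <- matrix(fx$spec$bg_level, 128, 128)
  bg <- bg + matrix(rnorm(128 * 128, 0, 0.01), 128, 128) +
    matrix(rpois(128 * 128, bg * 50), 128, 128) / 50 - bg
  seg <- segment_image(bg, classifier = fx$classifier)
  expect_lt(mean(seg$er_mask), 0.01)
})

test_that("closing seals sub-element gaps, is extensive and idempotent", {
  m <- matrix(0L, 20, 40)
  m[10:11, ] <- 1L
  m[10:11, 20] <- 0L   # 1-px gap in a tubule
  expect_equal(max(ernet:::label8(m)), 2L)
  closed <- close_mask(m, radius_px = 2)
  expect_equal(max(ernet:::label8(closed)), 1L)
  expect_true(all(closed >= m))
  expect_identical(close_mask(m, 2, 3), close_mask(m, 2, 1))
  set.seed(8)
  r <- matrix(rbinom(900, 1, 0.3), 30, 30)
  expect_true(all(close_mask(r, 2) >= r))
  expect_error(close_mask(m, radius_px = 0), "radius")
})
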