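# Persistency composites, CFI statistics, puncta tracking, motion classes.

frozen_fixture <- function() {
  cached("frozen_tl", function() {
    spec <- noiseless_spec(9, n_seeds = 25, size = 128,
                           cisternae_fraction = 0.05)
    g <- generate_network_graph(spec)
    generate_timelapse(g, spec,
      motion_spec(mobile_fraction = 0, jitter_scale_px = 0, frames = 8))
  })
}

test_that("a static stack gives an all-white persistency composite over the structure", {
  tl <- frozen_fixture()
  pm <- persistency_composite(tl$stack, c(1, 4, 8))
  on_struct <- pm$occupancy == 3L
  expect_identical(ernet:::check_mask(on_struct), tl$truth$er_mask)
  for (ch in 1:3)
    expect_true(all(pm$composite[, , ch][on_struct] == 1))
  expect_true(all(pm$occupancy %in% 0:3))
  expect_error(persistency_composite(tl$stack, c(1, 99)), "out of range")
  expect_error(persistency_composite(tl$stack, 2), "at least 2")
})

test_that("occupancy equals a brute-force per-pixel sum of binarized frames", {
  spec <- noisy_spec(14, peak_photons = 200, size = 128, n_seeds = 25)
  g <- generate_network_graph(spec)
  tl <- generate_timelapse(g, spec,
    motion_spec(mobile_fraction = 0.5, jitter_scale_px = 1.5, frames = 6))
  idx <- c(1, 3, 6)
  pm <- persistency_composite(tl$stack, idx, threshold = 0.4)
  brute <- Reduce(`+`, lapply(tl$stack$frames[idx], function(f) {
    norm <- enhance_contrast(f, 0.003)
    (norm > 0.4) + 0L
  }))
  expect_equal(unname(pm$occupancy), unname(brute))
})

test_that("a punctum present only in frame one carries the frame-one colour", {
  frames <- replicate(3, matrix(0.02, 64, 64), simplify = FALSE)
  frames[[1]][30:32, 30:32] <- 1
  # a static anchor structure so every frame binarizes sensibly
  for (t in 1:3) frames[[t]][10:12, 5:60] <- 0.8
  pm <- persistency_composite(image_stack(frames), 1:3, threshold = 0.5)
  expect_true(all(pm$occupancy[30:32, 30:32] == 1L))
  px <- pm$composite[31, 31, ]
  expect_equal(px, c(0, 0, 1))  # earliest-frame hue is blue
})

test_that("CFI of a frozen network equals the frame count on occupied pixels", {
  tl <- frozen_fixture()
  cfi <- compute_cfi(tl$stack)
  expect_true(all(cfi$values == 8L))
  expect_equal(sum(cfi$distribution), 1)
  expect_error(compute_cfi(image_stack(list(matrix(0, 8, 8),
                                            matrix(0, 8, 8)))),
               "no occupied")
})

test_that("a punctum visiting disjoint pixels once each has CFI one everywhere", {
  frames <- lapply(1:4, function(t) {
    f <- matrix(0.02, 48, 48)
    f[(10 * t):(10 * t + 2), 5:7] <- 1
    f
  })
  cfi <- compute_cfi(image_stack(frames), threshold = 0.5)
  expect_true(all(cfi$values == 1L))
})

test_that("CFI mass is conserved: pixel-sum equals frame occupancy totals", {
  spec <- noisy_spec(15, peak_photons = 100, size = 128, n_seeds = 25)
  g <- generate_network_graph(spec)
  tl <- generate_timelapse(g, spec,
    motion_spec(mobile_fraction = 0.6, jitter_scale_px = 2, frames = 6))
  cfi <- compute_cfi(tl$stack, threshold = 0.4)
  per_frame <- vapply(tl$stack$frames, function(f)
    sum(enhance_contrast(f, 0.003) > 0.4), 0)
  expect_equal(sum(cfi$cfi), sum(per_frame))
})

test_that("ratio curve of a sample against itself is one and scale-invariant", {
  tl <- frozen_fixture()
  cfi <- compute_cfi(tl$stack)
  rc <- suppressWarnings(cfi_ratio_curve(cfi, cfi))
  defined <- !is.na(rc$curve$ratio)
  expect_true(all(abs(rc$curve$ratio[defined] - 1) < 1e-12))
  # undefined bins are reported as NA, not zero
  expect_true(any(is.na(rc$curve$ratio)))
  # scaling both pixel populations leaves the curve unchanged
  big <- cfi
  big$values <- rep(cfi$values, 10)
  big$distribution <- tabulate(big$values, cfi$n_frames) / length(big$values)
  rc2 <- suppressWarnings(cfi_ratio_curve(big, big))
  expect_equal(rc2$curve$ratio, rc$curve$ratio)
})

test_that("frozen CFI stochastically dominates mobile CFI on matched phantoms", {
  spec <- noisy_spec(16, peak_photons = 200, size = 192, n_seeds = 50,
                     cisternae_fraction = 0.05, tubule_width_px = 3)
  g <- generate_network_graph(spec)
  frozen <- generate_timelapse(g, spec,
    motion_spec(mobile_fraction = 0, jitter_scale_px = 0, frames = 15))
  mobile <- generate_timelapse(g, spec,
    motion_spec(mobile_fraction = 0.7, jitter_scale_px = 2, frames = 15))
  cf <- compute_cfi(frozen$stack)
  cm <- compute_cfi(mobile$stack)
  expect_gt(mean(cf$values), mean(cm$values))
  rc <- cfi_ratio_curve(cf, cm)
  expect_lt(rc$p_greater, 0.01)
  expect_gt(rc$curve$ratio[15], 1)
})

test_that("one stationary punctum yields one track with zero net displacement", {
  frames <- replicate(10, {
    f <- matrix(0.02, 64, 64)
    f[10:12, 5:60] <- 0.7    # anchor structure
    f[40:44, 40:44] <- 1
    f
  }, simplify = FALSE)
  tk <- track_puncta(image_stack(frames), max_disp_px = 5)
  expect_equal(length(unique(tk$tracks$track_id)), 1L)
  tr <- tk$tracks
  expect_equal(nrow(tr), 10L)
  net <- sqrt((tr$x[10] - tr$x[1])^2 + (tr$y[10] - tr$y[1])^2)
  expect_equal(net, 0)
  dyn <- classify_motion(tk)
  expect_equal(dyn$per_track$class, "stationary")
})

test_that("two converging puncta produce one merge event near the scheduled frame", {
  spec <- noiseless_spec(9, n_seeds = 20, size = 128,
                         cisternae_fraction = 0)
  g <- generate_network_graph(spec)
  tl <- generate_timelapse(g, spec,
    motion_spec(mobile_fraction = 0, jitter_scale_px = 0, frames = 15,
                n_puncta = 2, puncta_jitter_px = 0.3,
                events = list(list(type = "merge", frame = 10,
                                   ids = c(1, 2)))))
  tk <- track_puncta(tl$stack)
  merges <- tk$events[tk$events$type == "merge", ]
  expect_equal(nrow(merges), 1L)
  expect_lte(abs(merges$frame - 10), 2)
})

test_that("gated-motion phantom tracks are recovered one-to-one", {
  spec <- noisy_spec(1, peak_photons = 500, size = 256, n_seeds = 90,
                     cisternae_fraction = 0.05, tubule_width_px = 3)
  spec$psf_sigma_px <- 0.8
  g <- generate_network_graph(spec)
  tl <- generate_timelapse(g, spec,
    motion_spec(mobile_fraction = 0.5, jitter_scale_px = 1,
                frames = 20, n_puncta = 20, puncta_jitter_px = 0.8))
  tk <- track_puncta(tl$stack)
  m <- match_tracks(tl$truth$tracks, tk$tracks)
  expect_gte(m$rate, 0.9)
})

test_that("motion classification reproduces the reported arithmetic and track classes", {
  d <- dynamics_summary(59, 31, 16, 7)
  expect_equal(d$total, 90)
  expect_equal(d$moved_pct, 100 * 59 / 90)
  expect_equal(round(d$moved_pct), 66)
  expect_equal(round(d$fixed_pct), 34)
  expect_equal(d$moved_fraction + d$fixed_fraction, 1)
  # a straight constant-velocity track is directed
  tr <- data.frame(track_id = 1, frame = 1:10, x = seq(0, 18, by = 2),
                   y = rep(5, 10), area = 10)
  cls <- classify_motion(tr)
  expect_equal(cls$per_track$class, "directed")
  # zero-displacement track is stationary
  tr0 <- data.frame(track_id = 1, frame = 1:5, x = rep(3, 5),
                    y = rep(4, 5), area = 10)
  expect_equal(classify_motion(tr0)$per_track$class, "stationary")
})
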