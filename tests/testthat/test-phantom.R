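# Synthetic phantom generator: graph geometry, rendering, time-lapse.

test_that("degenerate inputs are rejected with a message", {
  expect_error(phantom_spec(n_seeds = 0), "n_seeds")
  expect_error(phantom_spec(cisternae_fraction = 1), "cisternae_fraction")
  expect_error(phantom_spec(tubule_width_px = 0.5), "tubule_width_px")
  expect_error(phantom_spec(width = 64, height = 64,
                            roi = matrix(0L, 64, 64)), "zero area")
  expect_error(phantom_spec(width = 32, height = 32, margin_px = 20) |>
                 generate_network_graph(), "margin")
})

test_that("a single seed spans no cycle and no junction", {
  g <- generate_network_graph(phantom_spec(width = 128, height = 128,
                                           n_seeds = 1, seed = 5))
  expect_equal(nrow(g$vertices), 1L)
  expect_equal(nrow(g$edges), 0L)
  expect_length(g$faces, 0)
  expect_length(g$junctions, 0)
})

test_that("graph generation is deterministic for a fixed seed", {
  spec <- noiseless_spec(3, n_seeds = 40)
  g1 <- generate_network_graph(spec)
  g2 <- generate_network_graph(spec)
  expect_identical(g1$vertices, g2$vertices)
  expect_identical(g1$edges, g2$edges)
})

test_that("bounded-face count satisfies Euler's relation on connected planar graphs", {
  for (sd in c(2, 7, 11)) {
    for (n in c(25, 90)) {
      g <- generate_network_graph(noiseless_spec(sd, n_seeds = n))
      expect_equal(length(g$faces), nrow(g$edges) - nrow(g$vertices) + 1,
                   info = sprintf("seed %d, n_seeds %d", sd, n))
      expect_true(all(g$face_area_px2 > 0))
      expect_equal(g$face_area_um2,
                   g$face_area_px2 * g$spec$pixel_size_um^2)
    }
  }
})

test_that("generated graphs are planar straight-line embeddings (no crossings)", {
  seg_cross <- function(p1, p2, p3, p4) {
    d <- function(a, b, c)
      (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    d1 <- d(p1, p2, p3); d2 <- d(p1, p2, p4)
    d3 <- d(p3, p4, p1); d4 <- d(p3, p4, p2)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  g <- generate_network_graph(noiseless_spec(13, n_seeds = 40))
  E <- g$edges; V <- g$vertices
  for (i in seq_len(nrow(E) - 1)) for (j in (i + 1):nrow(E)) {
    if (length(intersect(E[i, ], E[j, ])) > 0) next
    expect_false(seg_cross(V[E[i, 1], ], V[E[i, 2], ],
                           V[E[j, 1], ], V[E[j, 2], ]))
  }
})

test_that("rendered truth masks obey the mask algebra and the target fraction", {
  spec <- phantom_spec(width = 256, height = 256, n_seeds = 90,
                       cisternae_fraction = 0.10, n_distractors = 5,
                       seed = 4)
  ph <- render_phantom(generate_network_graph(spec))
  tr <- ph$truth
  expect_true(all(tr$cisternae_mask <= tr$er_mask))
  expect_equal(sum(tr$distractor_mask & tr$er_mask), 0L)
  expect_equal(abs(tr$achieved_cisternae_fraction - 0.10) < 0.01, TRUE)
  dl <- max(ernet:::label8(tr$distractor_mask))
  expect_equal(dl, 5L)
})

test_that("rendering is bit-reproducible and thresholding a clean render recovers truth", {
  spec <- noiseless_spec(6, cisternae_fraction = 0.05)
  g <- generate_network_graph(spec)
  ph1 <- render_phantom(g)
  ph2 <- render_phantom(g)
  expect_identical(ph1$image$frames[[1]], ph2$image$frames[[1]])
  img <- ph1$image$frames[[1]]
  for (thr in c(0.1, 0.3, 0.5)) {
    expect_identical(ernet:::check_mask(img > thr), ph1$truth$er_mask)
  }
})

test_that("a frozen time-lapse has identical frames and frame 1 matches the still render", {
  spec <- noiseless_spec(9, n_seeds = 20, size = 128,
                         cisternae_fraction = 0.05)
  g <- generate_network_graph(spec)
  tl <- generate_timelapse(g, spec,
                           motion_spec(mobile_fraction = 0,
                                       jitter_scale_px = 0, frames = 5))
  for (t in 2:5)
    expect_identical(tl$stack$frames[[t]], tl$stack$frames[[1]])
  ph <- render_phantom(g)
  expect_identical(tl$stack$frames[[1]], ph$image$frames[[1]])
})

test_that("scheduled events are validated and logged in the truth tracks", {
  expect_error(motion_spec(n_puncta = 2, frames = 10,
                           events = list(list(type = "merge", frame = 5,
                                              ids = c(1, 3)))),
               "unknown punctum id")
  expect_error(motion_spec(n_puncta = 2, frames = 10,
                           events = list(list(type = "warp", frame = 5,
                                              ids = 1))),
               "unknown event type")
  spec <- noiseless_spec(9, n_seeds = 20, size = 128,
                         cisternae_fraction = 0.05)
  g <- generate_network_graph(spec)
  tl <- generate_timelapse(g, spec,
    motion_spec(mobile_fraction = 0, jitter_scale_px = 0, frames = 12,
                n_puncta = 4, puncta_jitter_px = 0.5,
                events = list(list(type = "merge", frame = 10,
                                   ids = c(1, 2)))))
  ev <- tl$truth$events
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$type, "merge")
  expect_equal(ev$frame, 10L)
  tr <- tl$truth$tracks
  expect_false(any(tr$active[tr$track_id == 2 & tr$frame >= 10]))
  # the two merged puncta coincide at the merge frame
  p1 <- tr[tr$track_id == 1 & tr$frame == 10, ]
  p2 <- tr[tr$track_id == 2 & tr$frame == 10, ]
  expect_lt(sqrt((p1$x - p2$x)^2 + (p1$y - p2$y)^2), 1e-9)
})

test_that("mean-reverting jitter reaches its stationary scale", {
  s <- 1.5
  spec <- noiseless_spec(11, n_seeds = 15, size = 128)
  g <- generate_network_graph(spec)
  tl <- generate_timelapse(g, spec,
    motion_spec(mobile_fraction = 1, jitter_scale_px = s,
                jitter_correlation = 0.8, frames = 50))
  D <- tl$truth$vertex_displacement
  disp <- do.call(rbind, D[-1])
  expect_lt(abs(sd(as.vector(disp)) - s) / s, 0.2)
})
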