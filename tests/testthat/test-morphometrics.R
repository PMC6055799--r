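# Polygon analysis, cisternae isolation, skeleton, junctions, summaries.

test_that("a closed ring encloses exactly one polygon with the interior area", {
  m <- matrix(0L, 30, 30)
  m[10:20, 10:20] <- 1L
  m[12:18, 12:18] <- 0L   # square annulus with a 7x7 interior
  ps <- extract_polygons(m, pixel_size_um = 0.1)
  expect_equal(nrow(ps$polygons), 1L)
  expect_equal(ps$polygons$area_px2, 49)
  expect_equal(ps$polygons$area_um2, 49 * 0.01)
})

test_that("a 3x3 grid of closed cells gives nine polygons", {
  m <- matrix(0L, 40, 40)
  for (l in c(5, 15, 25, 35)) { m[l, 5:35] <- 1L; m[5:35, l] <- 1L }
  ps <- extract_polygons(m)
  expect_equal(nrow(ps$polygons), 9L)
  expect_true(all(ps$polygons$area_px2 == 81))
})

test_that("background not enclosed by the network is excluded, and an empty mask warns", {
  m <- matrix(0L, 20, 20)
  m[5, 1:20] <- 1L   # a line does not enclose anything
  ps <- extract_polygons(m)
  expect_equal(nrow(ps$polygons), 0L)
  expect_warning(extract_polygons(matrix(0L, 10, 10)), "empty ER mask")
  expect_error(extract_polygons(m, matrix(0L, 20, 20)), "zero area")
})

test_that("polygon count equals the truth bounded-face count on noiseless phantoms", {
  for (sd in 1:5) {
    g <- generate_network_graph(noiseless_spec(sd))
    ph <- render_phantom(g)
    ps <- extract_polygons(ph$truth$er_mask)
    expect_equal(nrow(ps$polygons), length(g$faces), info = paste("seed", sd))
  }
})

test_that("polygons, ER and excluded background partition the ROI exactly", {
  g <- generate_network_graph(noiseless_spec(2, cisternae_fraction = 0.05))
  ph <- render_phantom(g)
  er <- ph$truth$er_mask
  ps <- extract_polygons(er)
  poly_px <- sum(ps$polygons$area_px2)
  excl_px <- sum(ps$label_image == 0L & er == 0L)
  expect_equal(poly_px + excl_px + sum(er), length(er))
})

test_that("opening erases thin tubules but keeps sheets, and matches a direct computation", {
  tub <- matrix(0L, 40, 40)
  tub[20:21, ] <- 1L  # 2-px tubule
  cis <- isolate_cisternae(tub, open_radius_px = 3, iterations = 1,
                           min_area_um2 = 0, pixel_size_um = 0.05)
  expect_equal(sum(cis$mask), 0L)
  # a disk survives; retained pixels equal erode-then-dilate applied directly
  disk <- ernet:::rasterize_disks(matrix(c(20, 20), 1, 2), 10, 40, 40)
  disk <- ernet:::check_mask(disk)
  kern <- ernet:::disc_brush(3)
  oracle <- EBImage::dilate(EBImage::erode(disk, kern), kern)
  oracle <- ernet:::check_mask(oracle > 0 & disk == 1L)
  got <- isolate_cisternae(disk, 3, 1, 0, 0.05)
  expect_identical(got$mask, oracle)
  both <- ernet:::check_mask(disk == 1L | tub == 1L)
  mix <- isolate_cisternae(both, 3, 1, 0, 0.05)
  expect_true(all(mix$mask <= disk))
  expect_gt(sum(mix$mask), 0)
})

test_that("opening is anti-extensive and the cisternae mask never grows with iterations", {
  g <- generate_network_graph(noiseless_spec(3, cisternae_fraction = 0.08))
  er <- render_phantom(g)$truth$er_mask
  prev <- er
  for (it in 1:3) {
    cur <- isolate_cisternae(er, 3, it, 0, 0.05)$mask
    expect_true(all(cur <= prev))
    prev <- cur
  }
})

test_that("cisternae fraction endpoints and phantom recovery are correct", {
  roi <- matrix(1L, 50, 50)
  expect_equal(cisternae_fraction(matrix(0L, 50, 50), roi), 0)
  expect_equal(cisternae_fraction(roi, roi), 100)
  expect_error(cisternae_fraction(roi, matrix(0L, 50, 50)), "zero area")
  for (frac in c(0.02, 0.05, 0.10)) {
    spec <- noiseless_spec(7, cisternae_fraction = frac,
                           tubule_width_px = 2)
    ph <- render_phantom(generate_network_graph(spec))
    cis <- isolate_cisternae(ph$truth$er_mask, 3, 3, 0.25, 0.05)
    est <- cisternae_fraction(cis, matrix(1L, 256, 256))
    expect_lt(abs(est - 100 * ph$truth$achieved_cisternae_fraction), 1.5)
  }
})

test_that("a solid bar thins to a single path with two endpoints", {
  bar <- matrix(0L, 20, 60)
  bar[8:12, 10:49] <- 1L
  skel <- skeletonize_tubules(bar)
  sg <- detect_junctions_endpoints(skel)
  expect_equal(sg$junction_count, 0L)
  expect_equal(sg$endpoint_count, 2L)
  expect_true(all(skel <= bar))
  # 1-px wide: no pixel has more than 2 neighbours
  expect_true(all(ernet:::neighbour_count8(skel)[skel == 1L] <= 2))
})

test_that("skeleton is disjoint from cisternae and contained in the mask", {
  g <- generate_network_graph(noiseless_spec(5, cisternae_fraction = 0.08))
  er <- render_phantom(g)$truth$er_mask
  cis <- isolate_cisternae(er, 3, 3, 0.25, 0.05)
  skel <- skeletonize_tubules(er, cis)
  expect_equal(sum(skel & cis$mask), 0L)
  expect_true(all(skel <= er))
  expect_equal(sum(skeletonize_tubules(matrix(0L, 10, 10))), 0L)
})

test_that("junctions and endpoints of canonical shapes are detected", {
  plus <- matrix(0L, 21, 21)
  plus[11, 3:19] <- 1L
  plus[3:19, 11] <- 1L
  sg <- detect_junctions_endpoints(plus)
  expect_equal(sg$junction_count, 1L)
  expect_equal(sg$endpoint_count, 4L)
  line <- matrix(0L, 9, 30)
  line[5, 4:26] <- 1L
  sg2 <- detect_junctions_endpoints(line)
  expect_equal(sg2$junction_count, 0L)
  expect_equal(sg2$endpoint_count, 2L)
})

test_that("junction recovery is within 5% of truth on noiseless phantoms", {
  for (sd in 1:5) {
    spec <- noiseless_spec(sd, cisternae_fraction = 0.10,
                           tubule_width_px = 2)
    ph <- render_phantom(generate_network_graph(spec))
    s <- summarize_cell(ph$truth$er_mask, pixel_size_um = 0.05)
    tj <- truth_junction_count(ph$truth)
    expect_lte(abs(s$junction_count - tj) / tj, 0.05,
               label = sprintf("seed %d: |%d - %d|/truth", sd,
                               s$junction_count, tj))
  }
})

test_that("junction density is count over area and scale-invariant", {
  expect_equal(junction_density(10, 100), 0.1)
  expect_equal(junction_density(0, 50), 0)
  expect_error(junction_density(3, 0), "positive")
  # the same geometry at two pixel sizes gives consistent densities
  d <- vapply(c(0.05, 0.025), function(px) {
    spec <- noiseless_spec(4, cisternae_fraction = 0)
    ph <- render_phantom(generate_network_graph(spec))
    s <- summarize_cell(ph$truth$er_mask, pixel_size_um = px)
    s$junction_density_per_um2
  }, 0)
  expect_equal(d[2] / d[1], 4, tolerance = 1e-9)  # area scales by (2x)^2
})

test_that("summarize_cell handles empty masks and serializes stably", {
  expect_warning(s <- summarize_cell(matrix(0L, 64, 64)), "empty ER mask")
  expect_equal(s$n_polygons, 0L)
  expect_equal(s$cisternae_pct, 0)
  expect_equal(s$junction_count, 0L)
  row <- summary_row(s, "empty")
  expect_equal(nrow(row), 1L)
  expect_true(all(c("cell_id", "n_polygons", "polygon_area_mean_um2",
                    "cisternae_pct", "junction_count",
                    "junction_density_per_um2", "roi_area_um2",
                    "open_radius_px") %in% names(row)))
})
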