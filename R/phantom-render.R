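# Rasterization and confocal-style image formation for ER phantoms.

# Paint the band of half-width w/2 around each graph edge. verts holds
# (x, y) = (col, row) positions; the mask is indexed [row, col].
rasterize_segments <- function(verts, edges, width, H, W) {
  m <- matrix(FALSE, H, W)
  if (nrow(edges) == 0L) {
    if (nrow(verts) >= 1L)
      m <- rasterize_disks(verts, rep(width / 2, nrow(verts)), H, W)
    return(m)
  }
  r <- width / 2
  pad <- ceiling(r) + 1L
  for (k in seq_len(nrow(edges))) {
    p <- verts[edges[k, 1], ]; q <- verts[edges[k, 2], ]
    cx0 <- max(1L, floor(min(p[1], q[1]) - pad))
    cx1 <- min(W, ceiling(max(p[1], q[1]) + pad))
    cy0 <- max(1L, floor(min(p[2], q[2]) - pad))
    cy1 <- min(H, ceiling(max(p[2], q[2]) + pad))
    if (cx1 < cx0 || cy1 < cy0) next
    xs <- cx0:cx1; ys <- cy0:cy1
    X <- matrix(xs, length(ys), length(xs), byrow = TRUE)
    Y <- matrix(ys, length(ys), length(xs))
    vx <- q[1] - p[1]; vy <- q[2] - p[2]; L2 <- vx^2 + vy^2
    if (L2 < 1e-12) {
      d2 <- (X - p[1])^2 + (Y - p[2])^2
    } else {
      tt <- pmin(pmax(((X - p[1]) * vx + (Y - p[2]) * vy) / L2, 0), 1)
      d2 <- (X - (p[1] + tt * vx))^2 + (Y - (p[2] + tt * vy))^2
    }
    m[ys, xs] <- m[ys, xs] | (d2 <= r^2)
  }
  m
}

# Fill enclosed background holes of at most max_px pixels: the union of
# tubule bands can leave single-pixel pinholes at junctions, which are
# raster artifacts, not lacunae (real faces are orders of magnitude larger).
fill_small_holes <- function(mask, max_px = 8L) {
  m <- check_mask(mask)
  bg <- check_mask(m == 0L)
  lab <- matrix(as.integer(EBImage::bwlabel(bg)), nrow(m), ncol(m))
  if (max(lab) == 0L) return(m)
  border <- unique(c(lab[1, ], lab[nrow(m), ], lab[, 1], lab[, ncol(m)]))
  areas <- tabulate(lab, nbins = max(lab))
  fill <- setdiff(which(areas <= max_px), border)
  if (length(fill)) m[lab %in% fill] <- 1L
  m
}

# centers: n x 2 (x, y); radii: length n
rasterize_disks <- function(centers, radii, H, W) {
  m <- matrix(FALSE, H, W)
  for (k in seq_len(nrow(centers))) {
    r <- radii[k]
    cx0 <- max(1L, floor(centers[k, 1] - r - 1))
    cx1 <- min(W, ceiling(centers[k, 1] + r + 1))
    cy0 <- max(1L, floor(centers[k, 2] - r - 1))
    cy1 <- min(H, ceiling(centers[k, 2] + r + 1))
    if (cx1 < cx0 || cy1 < cy0) next
    xs <- cx0:cx1; ys <- cy0:cy1
    X <- matrix(xs, length(ys), length(xs), byrow = TRUE)
    Y <- matrix(ys, length(ys), length(xs))
    m[ys, xs] <- m[ys, xs] |
      ((X - centers[k, 1])^2 + (Y - centers[k, 2])^2 <= r^2)
  }
  m
}

rasterize_ellipse <- function(cx, cy, a, b, theta, H, W) {
  r <- max(a, b)
  cx0 <- max(1L, floor(cx - r - 1)); cx1 <- min(W, ceiling(cx + r + 1))
  cy0 <- max(1L, floor(cy - r - 1)); cy1 <- min(H, ceiling(cy + r + 1))
  m <- matrix(FALSE, H, W)
  if (cx1 < cx0 || cy1 < cy0) return(m)
  xs <- cx0:cx1; ys <- cy0:cy1
  X <- matrix(xs, length(ys), length(xs), byrow = TRUE) - cx
  Y <- matrix(ys, length(ys), length(xs)) - cy
  u <- X * cos(theta) + Y * sin(theta)
  v <- -X * sin(theta) + Y * cos(theta)
  m[ys, xs] <- (u / a)^2 + (v / b)^2 <= 1
  m
}

# Grow cisternal patches anchored at junction vertices until the target
# ROI-area fraction is met; the final patch radius is tuned by bisection so
# the achieved fraction lands within 0.5 percentage points of the target.
grow_cisternae <- function(graph, spec, roi, anchor_disp = NULL) {
  H <- spec$height; W <- spec$width
  target <- spec$cisternae_fraction
  mask <- matrix(FALSE, H, W)
  if (target <= 0) return(list(mask = mask, anchors = integer(0),
                               radii = numeric(0)))
  roi_area <- sum(roi)
  cand <- graph$junctions
  if (length(cand) == 0L) cand <- seq_len(nrow(graph$vertices))
  anchors <- integer(0); radii <- numeric(0)
  frac <- 0
  pool <- sample(cand, length(cand))
  i <- 0L
  while (frac < target) {
    i <- i + 1L
    a <- pool[((i - 1L) %% length(pool)) + 1L]
    r <- spec$cisterna_radius_px * runif(1, 0.7, 1.3)
    anchors <- c(anchors, a); radii <- c(radii, r)
    ctr <- graph$vertices[a, , drop = FALSE]
    if (!is.null(anchor_disp)) ctr <- ctr + anchor_disp[a, , drop = FALSE]
    mask <- mask | (rasterize_disks(ctr, r, H, W) & (roi > 0))
    frac <- sum(mask) / roi_area
    if (i > 50L * length(pool)) break
  }
  if (frac > target && length(radii) > 0) {
    # bisect the last patch radius to land near the target
    base <- mask & !last_patch(graph, spec, anchors, radii, roi, anchor_disp)
    lo <- 0; hi <- radii[length(radii)]
    for (it in 1:25) {
      mid <- (lo + hi) / 2
      radii[length(radii)] <- mid
      m2 <- base | last_patch(graph, spec, anchors, radii, roi, anchor_disp)
      f2 <- sum(m2) / roi_area
      if (f2 < target) lo <- mid else hi <- mid
      if (abs(f2 - target) < 0.005) break
    }
    radii[length(radii)] <- hi
    mask <- base | last_patch(graph, spec, anchors, radii, roi, anchor_disp)
  }
  list(mask = mask, anchors = anchors, radii = radii)
}

last_patch <- function(graph, spec, anchors, radii, roi, anchor_disp = NULL) {
  k <- length(anchors)
  ctr <- graph$vertices[anchors[k], , drop = FALSE]
  if (!is.null(anchor_disp)) ctr <- ctr + anchor_disp[anchors[k], , drop = FALSE]
  rasterize_disks(ctr, radii[k], spec$height, spec$width) & (roi > 0)
}

place_distractors <- function(er_mask, spec, roi) {
  H <- spec$height; W <- spec$width
  mask <- matrix(FALSE, H, W)
  if (spec$n_distractors == 0L) return(mask)
  rmax <- max(spec$distractor_radius_px)
  forbidden <- EBImage::dilate(er_mask | !(roi > 0),
                               disc_brush(ceiling(rmax) + 2L)) > 0
  placed <- 0L; tries <- 0L
  while (placed < spec$n_distractors && tries < 4000L) {
    tries <- tries + 1L
    cx <- runif(1, rmax + 2, W - rmax - 1)
    cy <- runif(1, rmax + 2, H - rmax - 1)
    if (forbidden[round(cy), round(cx)]) next
    a <- runif(1, spec$distractor_radius_px[1], rmax)
    b <- runif(1, spec$distractor_radius_px[1], rmax)
    blob <- rasterize_ellipse(cx, cy, a, b, runif(1, 0, pi), H, W)
    if (any(blob & forbidden) || any(blob & mask)) next
    # keep blobs mutually separated so the component count equals the
    # requested distractor count
    mask <- mask | blob
    forbidden <- forbidden | (EBImage::dilate(blob, disc_brush(2L)) > 0)
    placed <- placed + 1L
  }
  if (placed < spec$n_distractors)
    warning("placed only ", placed, " of ", spec$n_distractors,
            " distractors", call. = FALSE)
  mask
}

apply_optics <- function(clean, spec) {
  img <- clean
  if (spec$psf_sigma_px > 0) img <- gauss_smooth(img, spec$psf_sigma_px)
  if (is.finite(spec$peak_photons))
    img <- matrix(rpois(length(img), pmax(img, 0) * spec$peak_photons),
                  nrow(img), ncol(img)) / spec$peak_photons
  if (spec$read_noise_sd > 0)
    img <- img + matrix(rnorm(length(img), 0, spec$read_noise_sd),
                        nrow(img), ncol(img))
  img
}

#' Render a single-frame ER phantom with ground truth
#'
#' Rasterizes the tubule graph at the requested width, embeds cisternal
#' patches until the target area fraction is met, places distractor blobs in
#' the background, and forms the image through a Gaussian PSF with Poisson
#' photon noise and Gaussian read noise. Truth masks are recorded before any
#' optical corruption.
#'
#' @param graph a [generate_network_graph()] result.
#' @param spec the [phantom_spec()] used (normally `graph$spec`).
#' @return A list with `image` (an [image_stack()] of one noisy frame) and
#'   `truth` (class `phantom_truth`): `er_mask`, `cisternae_mask`,
#'   `distractor_mask`, `graph`, `junctions_xy`,
#'   `achieved_cisternae_fraction`, `clean` (noise-free frame).
#' @export
render_phantom <- function(graph, spec = graph$spec) {
  stopifnot(inherits(graph, "tubule_graph"), inherits(spec, "phantom_spec"))
  if (spec$tubule_width_px < 1) stop_ernet("tubule_width_px must be >= 1 px")
  roi <- roi_mask_of(spec)
  with_seed(derive_seed(spec$seed, 7), {
    H <- spec$height; W <- spec$width
    tub <- fill_small_holes(rasterize_segments(graph$vertices, graph$edges,
                                               spec$tubule_width_px, H, W) &
                            (roi > 0)) == 1L
    cis <- grow_cisternae(graph, spec, roi)
    er <- tub | cis$mask
    dis <- place_distractors(er, spec, roi)
    clean <- matrix(spec$bg_level, H, W)
    clean[tub] <- spec$tubule_level
    clean[cis$mask] <- spec$cisterna_level
    clean[dis] <- spec$distractor_level
    img <- apply_optics(clean, spec)
    truth <- structure(list(
      er_mask = check_mask(er), cisternae_mask = check_mask(cis$mask),
      distractor_mask = check_mask(dis), graph = graph,
      junctions_xy = graph$vertices[graph$junctions, , drop = FALSE],
      achieved_cisternae_fraction = sum(cis$mask) / sum(roi),
      cisterna_anchors = cis$anchors, cisterna_radii = cis$radii,
      clean = clean, roi = roi), class = "phantom_truth")
    list(image = image_stack(img, spec$pixel_size_um), truth = truth)
  })
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("phantom_truth: ER %d px, cisternae %.1f%%, %d junctions, %d distractor px\n",
              sum(x$er_mask), 100 * x$achieved_cisternae_fraction,
              nrow(x$junctions_xy), sum(x$distractor_mask)))
  invisible(x)
}
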