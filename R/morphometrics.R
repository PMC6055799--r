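# ER network morphometry: enclosed polygonal lacunae, cisternae isolation by
# iterated opening, tubular skeleton with three-way junction / endpoint
# detection, and area-normalized per-cell summaries.

#' Enclosed polygonal-region analysis
#'
#' Finds the background lacunae that are completely enclosed by the ER
#' network inside the ROI. Background components use 4-connectivity (the
#' digital-topology dual of the 8-connected foreground), and a component is
#' excluded when it touches the image border or any non-ROI pixel, i.e. when
#' it is not bounded entirely by ER signal.
#'
#' @param er_mask binary ER mask.
#' @param roi_mask binary ROI mask (defaults to the whole frame).
#' @param pixel_size_um pixel size for area conversion.
#' @return A `polygon_set`: `polygons` data.frame (id, area_px2, area_um2,
#'   centroid_x, centroid_y), `label_image`, `excluded_count` and the
#'   pixel size.
#' @export
extract_polygons <- function(er_mask, roi_mask = NULL,
                             pixel_size_um = 0.05) {
  er <- check_mask(er_mask, "er_mask")
  roi <- if (is.null(roi_mask)) matrix(1L, nrow(er), ncol(er))
         else check_mask(roi_mask, "roi_mask")
  if (!identical(dim(er), dim(roi)))
    stop_ernet("er_mask and roi_mask must have the same shape")
  if (sum(roi) == 0L) stop_ernet("degenerate ROI: zero area")
  if (sum(er) == 0L)
    warning("empty ER mask: no polygons", call. = FALSE)
  H <- nrow(er); W <- ncol(er)
  bg <- check_mask(roi == 1L & er == 0L)
  lab <- EBImage::bwlabel(bg)  # 4-connected
  lab <- matrix(as.integer(lab), H, W)
  excluded <- integer(0)
  if (max(lab) > 0L) {
    # pixels adjacent (4-connectivity) to outside-ROI or off-image
    pr <- matrix(0L, H + 2L, W + 2L)      # 0 = outside ROI
    pr[2:(H + 1L), 2:(W + 1L)] <- roi
    open_nb <- (pr[1:H, 2:(W + 1L)] == 0L) | (pr[3:(H + 2L), 2:(W + 1L)] == 0L) |
               (pr[2:(H + 1L), 1:W] == 0L) | (pr[2:(H + 1L), 3:(W + 2L)] == 0L)
    excluded <- sort(unique(lab[bg == 1L & open_nb]))
    excluded <- excluded[excluded > 0L]
  }
  keep <- setdiff(seq_len(max(lab)), excluded)
  if (length(keep)) {
    areas <- tabulate(lab, nbins = max(lab))[keep]
    idx <- which(lab %in% keep)
    labs <- lab[idx]
    rows <- (idx - 1L) %% H + 1L
    cols <- (idx - 1L) %/% H + 1L
    cx <- tapply(cols, labs, mean)[as.character(keep)]
    cy <- tapply(rows, labs, mean)[as.character(keep)]
    polys <- data.frame(id = seq_along(keep), area_px2 = areas,
                        area_um2 = areas * pixel_size_um^2,
                        centroid_x = as.numeric(cx),
                        centroid_y = as.numeric(cy))
  } else {
    polys <- data.frame(id = integer(0), area_px2 = numeric(0),
                        area_um2 = numeric(0), centroid_x = numeric(0),
                        centroid_y = numeric(0))
  }
  relab <- matrix(0L, H, W)
  for (i in seq_along(keep)) relab[lab == keep[i]] <- i
  structure(list(polygons = polys, label_image = relab,
                 excluded_count = length(excluded),
                 pixel_size_um = pixel_size_um), class = "polygon_set")
}

#' @export
print.polygon_set <- function(x, ...) {
  cat(sprintf("polygon_set: %d enclosed polygons (mean %.3f um2), %d excluded\n",
              nrow(x$polygons), mean(x$polygons$area_um2), x$excluded_count))
  invisible(x)
}

#' Isolate cisternae by iterated morphological opening
#'
#' Erodes `iterations` times then dilates `iterations` times with a disc
#' element (ImageJ-style iterated opening), which erases tubules thinner
#' than the accumulated element while sheet-like regions survive. Surviving
#' 8-connected components smaller than `min_area_um2` are dropped.
#'
#' @param er_mask binary ER mask.
#' @param open_radius_px disc radius in px (>= 1).
#' @param iterations erosion/dilation passes (>= 1).
#' @param min_area_um2 minimum retained component area.
#' @param pixel_size_um pixel size for area conversion.
#' @return A `cisternae_mask`: `mask` (0/1, subset of the input),
#'   `component_areas_um2`, and the parameters used.
#' @export
isolate_cisternae <- function(er_mask, open_radius_px = 3, iterations = 3,
                              min_area_um2 = 0.25, pixel_size_um = 0.05) {
  er <- check_mask(er_mask, "er_mask")
  if (open_radius_px < 1) stop_ernet("open_radius_px must be >= 1")
  if (iterations < 1) stop_ernet("iterations must be >= 1")
  kern <- disc_brush(open_radius_px)
  m <- er
  for (i in seq_len(iterations)) m <- EBImage::erode(m, kern)
  for (i in seq_len(iterations)) m <- EBImage::dilate(m, kern)
  m <- check_mask(m > 0 & er == 1L)
  lab <- label8(m)
  areas_px <- if (max(lab) > 0) tabulate(lab, nbins = max(lab)) else integer(0)
  min_px <- min_area_um2 / pixel_size_um^2
  keep <- which(areas_px >= min_px)
  out <- matrix(0L, nrow(er), ncol(er))
  if (length(keep)) out[lab %in% keep] <- 1L
  structure(list(mask = out,
                 component_areas_um2 = areas_px[keep] * pixel_size_um^2,
                 open_radius_px = open_radius_px, iterations = iterations,
                 min_area_um2 = min_area_um2,
                 pixel_size_um = pixel_size_um), class = "cisternae_mask")
}

#' @export
print.cisternae_mask <- function(x, ...) {
  cat(sprintf("cisternae_mask: %d components, %d px (radius %g, %d iter)\n",
              length(x$component_areas_um2), sum(x$mask),
              x$open_radius_px, x$iterations))
  invisible(x)
}

#' Percentage of the cell surface classified as cisternae
#'
#' @param cisternae a [isolate_cisternae()] result or binary mask.
#' @param roi_mask binary ROI mask.
#' @return percent of ROI area in `[0, 100]`.
#' @export
cisternae_fraction <- function(cisternae, roi_mask) {
  m <- if (inherits(cisternae, "cisternae_mask")) cisternae$mask
       else check_mask(cisternae)
  roi <- check_mask(roi_mask, "roi_mask")
  if (sum(roi) == 0L) stop_ernet("degenerate ROI: zero area")
  100 * sum(m == 1L & roi == 1L) / sum(roi)
}

#' Skeletonize the tubular ER network
#'
#' Topology-preserving thinning of the ER mask to 1-px width, followed by
#' subtraction of the cisternae mask so that only the tubular network
#' remains.
#'
#' @param er_mask binary ER mask.
#' @param cisternae optional [isolate_cisternae()] result or binary mask.
#' @param prune_spurs_px side branches shorter than this (from an endpoint
#'   to the first junction) are removed; they are thinning artifacts at the
#'   scale of the tubule width, not tubules. 0 disables pruning.
#' @param cisternae_margin_px the cisternae mask is dilated by this margin
#'   before subtraction: skeleton pixels within a tubule width of a sheet
#'   trace the sheet boundary, not tubules, and would contribute spurious
#'   junctions. 0 subtracts the bare mask.
#' @return 0/1 skeleton matrix (subset of `er_mask`, disjoint from the
#'   cisternae mask).
#' @export
skeletonize_tubules <- function(er_mask, cisternae = NULL,
                                prune_spurs_px = 3,
                                cisternae_margin_px = 2) {
  er <- check_mask(er_mask, "er_mask")
  skel <- thin_mask(er)
  if (!is.null(cisternae)) {
    cm <- if (inherits(cisternae, "cisternae_mask")) cisternae$mask
          else check_mask(cisternae)
    if (!identical(dim(cm), dim(er)))
      stop_ernet("cisternae mask shape mismatch")
    if (cisternae_margin_px > 0 && sum(cm) > 0)
      cm <- check_mask(EBImage::dilate(cm, disc_brush(cisternae_margin_px)) > 0)
    skel[cm == 1L] <- 0L
  }
  if (prune_spurs_px > 0) skel <- prune_spurs(skel, prune_spurs_px)
  skel
}

# Remove skeleton side branches shorter than min_len px: walk inward from
# each endpoint; if a branch point is reached within min_len steps the
# walked pixels are deleted. Two passes settle the cascades that matter.
prune_spurs <- function(skel, min_len) {
  H <- nrow(skel)
  for (pass in 1:2) {
    nc <- neighbour_count8(skel)
    eps <- which(skel == 1L & nc == 1L)
    if (length(eps) == 0L) break
    removed <- FALSE
    for (e in eps) {
      path <- integer(0)
      cur <- e
      prev <- -1L
      ok <- FALSE
      for (step in seq_len(min_len)) {
        path <- c(path, cur)
        r <- (cur - 1L) %% H + 1L; c <- (cur - 1L) %/% H + 1L
        nbr <- integer(0)
        for (dr in -1:1) for (dc in -1:1) {
          if (dr == 0L && dc == 0L) next
          rr <- r + dr; cc <- c + dc
          if (rr < 1L || rr > H || cc < 1L || cc > ncol(skel)) next
          id <- (cc - 1L) * H + rr
          if (skel[id] == 1L && id != prev && !(id %in% path))
            nbr <- c(nbr, id)
        }
        if (length(nbr) == 0L) break          # isolated stub
        if (length(nbr) >= 2L || nc[nbr[1]] >= 3L) { ok <- TRUE; break }
        prev <- cur
        cur <- nbr[1]
      }
      if (ok) { skel[path] <- 0L; removed <- TRUE }
    }
    if (!removed) break
  }
  skel
}

#' Detect three-way junctions and endpoints on a skeleton
#'
#' A junction pixel is a skeleton pixel with >= 3 skeleton neighbours
#' (8-connectivity); 8-adjacent junction pixels are merged into one junction
#' cluster reported at its centroid (thinning can emit 2-px clusters at one
#' anatomical junction). Endpoints have exactly one skeleton neighbour.
#'
#' @param skeleton 0/1 skeleton matrix (1-px-wide).
#' @param merge_radius_px junction clusters with centroids closer than this
#'   are counted as one junction (thinning can split one anatomical junction
#'   into two pixel clusters a couple of pixels apart).
#' @return A `skeleton_graph`: `skeleton`, `junctions` data.frame
#'   (id, x, y, n_pixels), `endpoints` data.frame (x, y),
#'   `junction_count`, `endpoint_count`.
#' @export
detect_junctions_endpoints <- function(skeleton, merge_radius_px = 3) {
  skel <- check_mask(skeleton, "skeleton")
  H <- nrow(skel); W <- ncol(skel)
  nc <- neighbour_count8(skel)
  cross <- ring_transitions(skel)
  ep_idx <- which(skel == 1L & nc == 1L)
  endpoints <- data.frame(x = (ep_idx - 1L) %/% H + 1L,
                          y = (ep_idx - 1L) %% H + 1L)
  jmask <- check_mask(skel == 1L & nc >= 3L & cross >= 3L)
  jlab <- label8(jmask)
  if (max(jlab) > 0L) {
    idx <- which(jlab > 0L)
    labs <- jlab[idx]
    rows <- (idx - 1L) %% H + 1L
    cols <- (idx - 1L) %/% H + 1L
    junctions <- data.frame(
      id = seq_len(max(jlab)),
      x = as.numeric(tapply(cols, labs, mean)),
      y = as.numeric(tapply(rows, labs, mean)),
      n_pixels = as.integer(table(factor(labs, levels = seq_len(max(jlab))))))
    if (merge_radius_px > 0 && nrow(junctions) > 1L) {
      d <- as.matrix(dist(junctions[, c("x", "y")]))
      adj <- d <= merge_radius_px
      comp <- igraph::components(
        igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))
      grp <- comp$membership
      junctions <- data.frame(
        id = seq_len(comp$no),
        x = as.numeric(tapply(junctions$x * junctions$n_pixels, grp, sum) /
                         tapply(junctions$n_pixels, grp, sum)),
        y = as.numeric(tapply(junctions$y * junctions$n_pixels, grp, sum) /
                         tapply(junctions$n_pixels, grp, sum)),
        n_pixels = as.integer(tapply(junctions$n_pixels, grp, sum)))
    }
  } else {
    junctions <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                            n_pixels = integer(0))
  }
  structure(list(skeleton = skel, junctions = junctions,
                 endpoints = endpoints,
                 junction_count = nrow(junctions),
                 endpoint_count = nrow(endpoints)),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("skeleton_graph: %d px skeleton, %d junctions, %d endpoints\n",
              sum(x$skeleton), x$junction_count, x$endpoint_count))
  invisible(x)
}

#' Three-way junctions per unit cell area
#' @param junction_count number of junctions.
#' @param roi_area_um2 cell surface area in square micrometres (> 0).
#' @return junctions per square micrometre.
#' @export
junction_density <- function(junction_count, roi_area_um2) {
  if (roi_area_um2 <= 0) stop_ernet("roi_area_um2 must be positive")
  junction_count / roi_area_um2
}

#' Full per-cell morphometric summary
#'
#' Chains [extract_polygons()], [isolate_cisternae()],
#' [cisternae_fraction()], [skeletonize_tubules()],
#' [detect_junctions_endpoints()] and [junction_density()] and packages the
#' three headline metrics (polygon areas, cisternae %, junction density)
#' with a parameter echo.
#'
#' @param er_mask binary ER mask.
#' @param roi_mask binary ROI mask (defaults to the whole frame).
#' @param pixel_size_um pixel size.
#' @param open_radius_px,open_iterations,min_cisterna_area_um2 passed to
#'   [isolate_cisternae()].
#' @return A `morphometric_summary` list; use [summary_row()] to serialize
#'   it as one data.frame row per cell.
#' @export
summarize_cell <- function(er_mask, roi_mask = NULL, pixel_size_um = 0.05,
                           open_radius_px = 3, open_iterations = 3,
                           min_cisterna_area_um2 = 0.25) {
  er <- check_mask(er_mask, "er_mask")
  roi <- if (is.null(roi_mask)) matrix(1L, nrow(er), ncol(er))
         else check_mask(roi_mask, "roi_mask")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_ernet("stage '", name, "' failed: ", conditionMessage(e)))
  }
  polys <- stage("extract_polygons",
                 extract_polygons(er, roi, pixel_size_um))
  cis <- stage("isolate_cisternae",
               isolate_cisternae(er, open_radius_px, open_iterations,
                                 min_cisterna_area_um2, pixel_size_um))
  cpct <- stage("cisternae_fraction", cisternae_fraction(cis, roi))
  skel <- stage("skeletonize_tubules", skeletonize_tubules(er, cis))
  sg <- stage("detect_junctions_endpoints", detect_junctions_endpoints(skel))
  roi_area <- sum(roi) * pixel_size_um^2
  jd <- stage("junction_density",
              junction_density(sg$junction_count, roi_area))
  structure(list(
    polygon_areas_um2 = polys$polygons$area_um2,
    polygons = polys, cisternae = cis, skeleton_graph = sg,
    n_polygons = nrow(polys$polygons),
    polygon_area_mean_um2 = if (nrow(polys$polygons)) mean(polys$polygons$area_um2) else NA_real_,
    polygon_area_median_um2 = if (nrow(polys$polygons)) median(polys$polygons$area_um2) else NA_real_,
    cisternae_pct = cpct,
    junction_count = sg$junction_count,
    junction_density_per_um2 = jd,
    endpoint_count = sg$endpoint_count,
    roi_area_um2 = roi_area,
    params = list(pixel_size_um = pixel_size_um,
                  open_radius_px = open_radius_px,
                  open_iterations = open_iterations,
                  min_cisterna_area_um2 = min_cisterna_area_um2)),
    class = "morphometric_summary")
}

#' @export
print.morphometric_summary <- function(x, ...) {
  cat(sprintf("morphometric_summary: %d polygons (mean %.3f um2), cisternae %.2f%%, %d junctions (%.4f per um2)\n",
              x$n_polygons, x$polygon_area_mean_um2, x$cisternae_pct,
              x$junction_count, x$junction_density_per_um2))
  invisible(x)
}

#' One-row serialization of a morphometric summary
#' @param x a `morphometric_summary`.
#' @param cell_id optional identifier column value.
#' @return one-row data.frame with stable column names.
#' @export
summary_row <- function(x, cell_id = NA_character_) {
  stopifnot(inherits(x, "morphometric_summary"))
  data.frame(cell_id = cell_id,
             n_polygons = x$n_polygons,
             polygon_area_mean_um2 = x$polygon_area_mean_um2,
             polygon_area_median_um2 = x$polygon_area_median_um2,
             cisternae_pct = x$cisternae_pct,
             junction_count = x$junction_count,
             junction_density_per_um2 = x$junction_density_per_um2,
             endpoint_count = x$endpoint_count,
             roi_area_um2 = x$roi_area_um2,
             pixel_size_um = x$params$pixel_size_um,
             open_radius_px = x$params$open_radius_px,
             open_iterations = x$params$open_iterations,
             min_cisterna_area_um2 = x$params$min_cisterna_area_um2,
             stringsAsFactors = FALSE)
}

#' Ground-truth junction count of a phantom
#'
#' Counts degree->=3 vertices of the truth graph whose coordinate falls
#' outside the cisternae mask — the junctions the tubular-skeleton pathway
#' is expected to recover after cisternae subtraction.
#'
#' @param truth a `phantom_truth`.
#' @param cisternae_mask mask used for exclusion (defaults to the truth
#'   cisternae mask).
#' @param exclusion_margin_px a junction whose vertex lies within this
#'   distance of the cisternae mask has incident tubules running into the
#'   sheet and is not recoverable from the tubular skeleton; default is one
#'   tubule width.
#' @param resolution_px junction vertices closer than this count as one
#'   resolvable junction (single-linkage clustering). The generator already
#'   contracts edges below twice the tubule width, so the default of 1 px
#'   only merges coincident vertices.
#' @return integer count.
#' @export
truth_junction_count <- function(truth,
                                 cisternae_mask = truth$cisternae_mask,
                                 exclusion_margin_px = 2,
                                 resolution_px = 1) {
  stopifnot(inherits(truth, "phantom_truth"))
  g <- truth$graph
  j <- g$junctions
  if (length(j) == 0L) return(0L)
  cm <- check_mask(cisternae_mask)
  if (exclusion_margin_px > 0 && sum(cm) > 0)
    cm <- check_mask(EBImage::dilate(cm, disc_brush(exclusion_margin_px)) > 0)
  xy <- g$vertices[j, , drop = FALSE]
  H <- nrow(cm); W <- ncol(cm)
  r <- pmin(pmax(round(xy[, 2]), 1L), H)
  c <- pmin(pmax(round(xy[, 1]), 1L), W)
  xy <- xy[cm[cbind(r, c)] == 0L, , drop = FALSE]
  if (nrow(xy) <= 1L) return(nrow(xy))
  adj <- as.matrix(dist(xy)) <= resolution_px
  igraph::components(
    igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))$no
}
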