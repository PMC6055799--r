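# Time-lapse analysis: persistency (temporal colour-code) composites,
# cumulative fluorescence intensity (CFI) distributions and ratio curves,
# puncta tracking with merge detection, and motion classification.

binarize_frames <- function(stack, threshold = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  lapply(stack$frames, function(f)
    segment_image(f, threshold = threshold)$er_mask)
}

#' Persistency composite over selected frames
#'
#' Binarizes each selected frame (per-frame Otsu threshold unless given),
#' sums the per-pixel occupancy, and renders a temporal colour-code:
#' pixels occupied in every selected frame are white (persistent), all
#' other occupied pixels are hue-coded by the latest frame in which they
#' were occupied (blue = early, red = late/most mobile).
#'
#' @param stack an [image_stack()] time-lapse.
#' @param frame_indices indices of the frames to compare (>= 2), e.g. the
#'   frames closest to 0, 30 and 60 s.
#' @param threshold optional fixed binarization threshold in (0, 1).
#' @return A `persistency_map`: `occupancy` (integer matrix in
#'   `[0, n_selected]`), `composite` (H x W x 3 RGB array), `frame_indices`
#'   and `times_s`.
#' @export
persistency_composite <- function(stack, frame_indices = NULL,
                                  threshold = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  n <- length(stack$frames)
  if (is.null(frame_indices)) frame_indices <- seq_len(n)
  frame_indices <- as.integer(frame_indices)
  if (any(frame_indices < 1L | frame_indices > n))
    stop_ernet("frame index out of range 1..", n)
  if (length(frame_indices) < 2L)
    stop_ernet("need at least 2 selected frames")
  sub <- image_stack(stack$frames[frame_indices], stack$pixel_size_um,
                     stack$frame_interval_s)
  masks <- binarize_frames(sub, threshold)
  k <- length(masks)
  occ <- Reduce(`+`, masks)
  latest <- matrix(0L, nrow(occ), ncol(occ))
  for (i in seq_len(k)) latest[masks[[i]] == 1L] <- i
  comp <- array(0, c(nrow(occ), ncol(occ), 3L))
  persistent <- occ == k
  partial <- occ > 0L & !persistent
  if (any(partial)) {
    hues <- (2 / 3) * (1 - (latest[partial] - 1) / max(k - 1, 1))  # blue -> red
    cols <- t(col2rgb(hsv(h = hues, s = 1, v = 1))) / 255
    for (ch in 1:3) {
      pl <- comp[, , ch]
      pl[partial] <- cols[, ch]
      comp[, , ch] <- pl
    }
  }
  for (ch in 1:3) {
    pl <- comp[, , ch]
    pl[persistent] <- 1
    comp[, , ch] <- pl
  }
  structure(list(occupancy = occ, composite = comp,
                 frame_indices = frame_indices,
                 times_s = (frame_indices - 1L) * stack$frame_interval_s),
            class = "persistency_map")
}

#' @export
print.persistency_map <- function(x, ...) {
  k <- length(x$frame_indices)
  cat(sprintf("persistency_map: %d frames (t = %s s), %d persistent px\n",
              k, paste(x$times_s, collapse = ", "),
              sum(x$occupancy == k)))
  invisible(x)
}

#' Cumulative fluorescence intensity (CFI) of a time-lapse
#'
#' CFI of a pixel is the number of frames in which the pixel is occupied
#' (after per-frame binarization). A higher proportion of high CFI values
#' indicates a more static network; a higher proportion of low values a
#' more dynamic one. The distribution is reported over ever-occupied
#' pixels only and sums to one.
#'
#' @inheritParams persistency_composite
#' @return A `cfi_result`: `cfi` (integer matrix, 0 where never occupied),
#'   `values` (CFI of ever-occupied pixels), `distribution` (named vector
#'   over CFI bins 1..n_frames), `n_frames`.
#' @export
compute_cfi <- function(stack, threshold = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  if (length(stack$frames) < 2L) stop_ernet("need >= 2 frames")
  masks <- binarize_frames(stack, threshold)
  occ <- Reduce(`+`, masks)
  if (sum(occ) == 0L)
    stop_ernet("all frames empty after binarization: no occupied pixels")
  n <- length(masks)
  vals <- occ[occ > 0L]
  dist <- tabulate(vals, nbins = n) / length(vals)
  names(dist) <- as.character(seq_len(n))
  structure(list(cfi = occ, values = as.integer(vals),
                 distribution = dist, n_frames = n), class = "cfi_result")
}

#' @export
print.cfi_result <- function(x, ...) {
  cat(sprintf("cfi_result: %d frames, %d occupied px, mean CFI %.2f\n",
              x$n_frames, length(x$values), mean(x$values)))
  invisible(x)
}

#' CFI ratio curve of a sample against a control
#'
#' Per-CFI-bin ratio of normalized frequencies sample/control (a sample
#' compared with itself is identically one), plus a one-sided Wilcoxon
#' rank-sum test on the per-pixel CFI values as the significance surface
#' for "sample more static than control".
#'
#' @param sample,control [compute_cfi()] results with equal `n_frames`.
#' @return A `cfi_ratio`: data.frame `curve` (cfi, sample_freq,
#'   control_freq, ratio; ratio is `NA` where the control bin is empty),
#'   plus `p_greater`, the one-sided p-value that the sample CFI
#'   distribution is shifted towards higher values.
#' @export
cfi_ratio_curve <- function(sample, control) {
  stopifnot(inherits(sample, "cfi_result"), inherits(control, "cfi_result"))
  if (sample$n_frames != control$n_frames)
    stop_ernet("sample and control must have the same number of frames")
  n <- sample$n_frames
  curve <- data.frame(cfi = seq_len(n),
                      sample_freq = as.numeric(sample$distribution),
                      control_freq = as.numeric(control$distribution))
  curve$ratio <- ifelse(curve$control_freq > 0,
                        curve$sample_freq / curve$control_freq, NA_real_)
  ct <- wilcoxon_rank_sum(sample$values, control$values,
                          alternative = "greater", mode = "normal")
  structure(list(curve = curve, p_greater = ct$p_value, n_frames = n),
            class = "cfi_ratio")
}

#' @export
print.cfi_ratio <- function(x, ...) {
  cat(sprintf("cfi_ratio: %d bins, top-bin ratio %.3f, one-sided p = %.3g\n",
              x$n_frames, x$curve$ratio[x$n_frames], x$p_greater))
  invisible(x)
}

# bright compact components within an area window -> centroids
detect_puncta <- function(frame, intensity_min = 0.9,
                          area_px = c(8, 200)) {
  norm <- enhance_contrast(frame, 0)
  m <- check_mask(norm >= intensity_min)
  lab <- label8(m)
  if (max(lab) == 0L)
    return(data.frame(x = numeric(0), y = numeric(0), area = integer(0)))
  H <- nrow(frame)
  areas <- tabulate(lab, nbins = max(lab))
  keep <- which(areas >= area_px[1] & areas <= area_px[2])
  if (!length(keep))
    return(data.frame(x = numeric(0), y = numeric(0), area = integer(0)))
  idx <- which(lab %in% keep)
  labs <- lab[idx]
  rows <- (idx - 1L) %% H + 1L
  cols <- (idx - 1L) %/% H + 1L
  data.frame(x = as.numeric(tapply(cols, labs, mean)),
             y = as.numeric(tapply(rows, labs, mean)),
             area = areas[keep])
}

#' Track bright puncta across a time-lapse
#'
#' Detects puncta per frame as bright compact components within an area
#' window and links them frame-to-frame by greedy nearest-neighbour
#' assignment under a maximum-displacement gate. When two live tracks map
#' to the same detection a merge event is logged and the younger track
#' ends; a track whose last position overlaps `cisternae_mask` is marked
#' absorbed, otherwise a track that ends early is lost.
#'
#' @param stack an [image_stack()] time-lapse.
#' @param intensity_min detection threshold on the contrast-normalized
#'   frame.
#' @param area_px length-2 allowed component area window (px).
#' @param max_disp_px maximum linking displacement per frame.
#' @param cisternae_mask optional binary mask of persistent sheets for
#'   absorption calls.
#' @return A `puncta_tracks`: `tracks` data.frame (track_id, frame, x, y,
#'   area), `events` data.frame (frame, type, id1, id2), `fates` named
#'   character vector.
#' @export
track_puncta <- function(stack, intensity_min = 0.9, area_px = c(8, 200),
                         max_disp_px = 5, cisternae_mask = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  if (length(stack$frames) < 2L) stop_ernet("need >= 2 frames")
  n <- length(stack$frames)
  dets <- lapply(stack$frames, detect_puncta, intensity_min = intensity_min,
                 area_px = area_px)
  if (all(vapply(dets, nrow, 0L) == 0L)) {
    warning("no puncta detected in any frame", call. = FALSE)
    return(structure(list(
      tracks = data.frame(track_id = integer(0), frame = integer(0),
                          x = numeric(0), y = numeric(0), area = integer(0)),
      events = data.frame(frame = integer(0), type = character(0),
                          id1 = integer(0), id2 = integer(0)),
      fates = character(0)), class = "puncta_tracks"))
  }
  rows <- list(); ri <- 1L
  events <- list(); ei <- 1L
  next_id <- 0L
  live <- data.frame(id = integer(0), x = numeric(0), y = numeric(0))
  add_row <- function(id, t, x, y, a) {
    rows[[ri]] <<- data.frame(track_id = id, frame = t, x = x, y = y,
                              area = a)
    ri <<- ri + 1L
  }
  for (i in seq_len(nrow(dets[[1]]))) {
    next_id <- next_id + 1L
    add_row(next_id, 1L, dets[[1]]$x[i], dets[[1]]$y[i], dets[[1]]$area[i])
    live <- rbind(live, data.frame(id = next_id, x = dets[[1]]$x[i],
                                   y = dets[[1]]$y[i]))
  }
  ended <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                      frame = integer(0), why = character(0))
  for (t in 2:n) {
    d <- dets[[t]]
    assigned_det <- rep(NA_integer_, nrow(d))   # detection -> track id
    if (nrow(live) > 0L && nrow(d) > 0L) {
      # greedy: process candidate pairs by increasing distance
      dx <- outer(live$x, d$x, `-`); dy <- outer(live$y, d$y, `-`)
      dist <- sqrt(dx^2 + dy^2)
      cand <- which(dist <= max_disp_px, arr.ind = TRUE)
      track_done <- rep(FALSE, nrow(live))
      if (nrow(cand)) {
        # pass 1: greedy one-to-one assignment by increasing distance
        for (k in order(dist[cand])) {
          tr <- cand[k, 1]; de <- cand[k, 2]
          if (track_done[tr] || !is.na(assigned_det[de])) next
          assigned_det[de] <- live$id[tr]
          track_done[tr] <- TRUE
          add_row(live$id[tr], t, d$x[de], d$y[de], d$area[de])
        }
      }
      # pass 2: a still-unassigned track whose gate only holds taken
      # detections has converged onto another track: merge; otherwise lost
      for (tr in which(!track_done)) {
        ingate <- which(dist[tr, ] <= max_disp_px)
        if (length(ingate)) {
          de <- ingate[which.min(dist[tr, ingate])]
          events[[ei]] <- data.frame(frame = t, type = "merge",
                                     id1 = assigned_det[de],
                                     id2 = live$id[tr])
          ei <- ei + 1L
          ended <- rbind(ended, data.frame(id = live$id[tr], x = live$x[tr],
                                           y = live$y[tr], frame = t,
                                           why = "merged"))
        } else {
          ended <- rbind(ended, data.frame(id = live$id[tr], x = live$x[tr],
                                           y = live$y[tr], frame = t,
                                           why = "ended"))
        }
      }
    } else if (nrow(live) > 0L) {
      ended <- rbind(ended, data.frame(id = live$id, x = live$x, y = live$y,
                                       frame = t, why = "ended"))
    }
    new_live <- data.frame(id = integer(0), x = numeric(0), y = numeric(0))
    for (de in seq_len(nrow(d))) {
      id <- assigned_det[de]
      if (is.na(id)) {
        next_id <- next_id + 1L
        id <- next_id
        add_row(id, t, d$x[de], d$y[de], d$area[de])
      }
      new_live <- rbind(new_live, data.frame(id = id, x = d$x[de],
                                             y = d$y[de]))
    }
    live <- new_live
  }
  tracks <- do.call(rbind, rows)
  tracks <- tracks[order(tracks$track_id, tracks$frame), ]
  events <- if (length(events)) do.call(rbind, events)
            else data.frame(frame = integer(0), type = character(0),
                            id1 = integer(0), id2 = integer(0))
  ids <- sort(unique(tracks$track_id))
  fates <- setNames(rep("persisted", length(ids)), ids)
  for (k in seq_len(nrow(ended))) {
    id <- as.character(ended$id[k])
    if (ended$why[k] == "merged") { fates[id] <- "merged"; next }
    if (!is.null(cisternae_mask)) {
      r <- min(max(round(ended$y[k]), 1L), nrow(cisternae_mask))
      c <- min(max(round(ended$x[k]), 1L), ncol(cisternae_mask))
      fates[id] <- if (cisternae_mask[r, c] == 1L) "absorbed" else "lost"
    } else fates[id] <- "lost"
  }
  structure(list(tracks = tracks, events = events, fates = fates),
            class = "puncta_tracks")
}

#' @export
print.puncta_tracks <- function(x, ...) {
  cat(sprintf("puncta_tracks: %d tracks, %d events (%s)\n",
              length(unique(x$tracks$track_id)), nrow(x$events),
              paste(names(table(x$fates)), table(x$fates), sep = ":",
                    collapse = ", ")))
  invisible(x)
}

#' Classify puncta motion and summarize dynamics
#'
#' A punctum counts as moved when its maximum centroid displacement from
#' the starting position exceeds `d_min_px`; a moved punctum is directed
#' when its net-over-path-length straightness is at least
#' `straightness_min`, otherwise mobile-undirected. Unmoved puncta are
#' stationary (Brownian-like in place).
#'
#' @param tracks a [track_puncta()] result (or a compatible data.frame).
#' @param d_min_px displacement threshold (px).
#' @param straightness_min net/path ratio threshold for directed motion.
#' @return A `dynamics_summary`: per-track table (`track_id`, `class`,
#'   `max_disp_px`, `straightness`, `fate`) and the moved/fixed/
#'   fused/absorbed counts and fractions.
#' @export
classify_motion <- function(tracks, d_min_px = 2, straightness_min = 0.7) {
  tr <- if (inherits(tracks, "puncta_tracks")) tracks$tracks else tracks
  fates <- if (inherits(tracks, "puncta_tracks")) tracks$fates else NULL
  ids <- sort(unique(tr$track_id))
  per <- do.call(rbind, lapply(ids, function(id) {
    p <- tr[tr$track_id == id, ]
    p <- p[order(p$frame), ]
    if (nrow(p) < 2L)
      return(data.frame(track_id = id, class = "stationary",
                        max_disp_px = 0, straightness = NA_real_))
    disp <- sqrt((p$x - p$x[1])^2 + (p$y - p$y[1])^2)
    steps <- sqrt(diff(p$x)^2 + diff(p$y)^2)
    path <- sum(steps)
    net <- disp[nrow(p)]
    straight <- if (path > 0) net / path else 0
    cls <- if (max(disp) <= d_min_px) "stationary"
           else if (straight >= straightness_min) "directed"
           else "mobile-undirected"
    data.frame(track_id = id, class = cls, max_disp_px = max(disp),
               straightness = straight)
  }))
  per$fate <- if (!is.null(fates)) unname(fates[as.character(per$track_id)])
              else NA_character_
  n_moved <- sum(per$class != "stationary")
  n_fixed <- sum(per$class == "stationary")
  n_fused <- sum(per$fate == "merged", na.rm = TRUE)
  n_absorbed <- sum(per$fate == "absorbed", na.rm = TRUE)
  dynamics_summary(n_moved, n_fixed, n_fused, n_absorbed, per_track = per,
                   d_min_px = d_min_px, straightness_min = straightness_min)
}

#' Dynamics summary arithmetic on puncta counts
#'
#' Packages moved/fixed/fused/absorbed counts with their fractions of the
#' total (moved + fixed = total puncta). Also usable directly on reported
#' counts, e.g. 59 moved of 90 gives 65.6% moved / 34.4% fixed.
#'
#' @param n_moved,n_fixed,n_fused,n_absorbed non-negative counts.
#' @param per_track optional per-track classification table.
#' @param d_min_px,straightness_min parameter echo.
#' @return A `dynamics_summary` list with counts, `total`, and
#'   `moved_fraction`, `fixed_fraction`, `moved_pct`, `fixed_pct`.
#' @export
dynamics_summary <- function(n_moved, n_fixed, n_fused = 0, n_absorbed = 0,
                             per_track = NULL, d_min_px = NA_real_,
                             straightness_min = NA_real_) {
  if (n_moved < 0 || n_fixed < 0 || n_fused < 0 || n_absorbed < 0)
    stop_ernet("counts must be non-negative")
  total <- n_moved + n_fixed
  structure(list(n_moved = n_moved, n_fixed = n_fixed, n_fused = n_fused,
                 n_absorbed = n_absorbed, total = total,
                 moved_fraction = if (total > 0) n_moved / total else NA_real_,
                 fixed_fraction = if (total > 0) n_fixed / total else NA_real_,
                 moved_pct = if (total > 0) 100 * n_moved / total else NA_real_,
                 fixed_pct = if (total > 0) 100 * n_fixed / total else NA_real_,
                 per_track = per_track, d_min_px = d_min_px,
                 straightness_min = straightness_min),
            class = "dynamics_summary")
}

#' @export
print.dynamics_summary <- function(x, ...) {
  cat(sprintf("dynamics_summary: %d/%d moved (%.1f%%), %d fixed (%.1f%%), %d fused, %d absorbed\n",
              x$n_moved, x$total, x$moved_pct, x$n_fixed, x$fixed_pct,
              x$n_fused, x$n_absorbed))
  invisible(x)
}
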