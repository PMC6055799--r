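# Scripted time-lapse phantoms: mean-reverting network motion, puncta with
# merge/split/absorption events, per-frame confocal noise.

#' Specify phantom time-lapse motion
#'
#' The mobile part of the network follows a discrete Ornstein-Uhlenbeck
#' (AR(1)) displacement process per vertex and coordinate:
#' `d[t+1] = rho * d[t] + sqrt(1 - rho^2) * s * eps`, which is mean-reverting
#' with stationary standard deviation `s` — bounded, Brownian-like locally,
#' and it never tears the network. Labelled puncta ride on their anchor
#' vertex plus their own jitter; merge, split and absorb events can be
#' scheduled explicitly and are logged in the ground-truth tracks.
#'
#' @param mobile_fraction fraction of the ROI designated mobile, in `[0, 1]`;
#'   vertices inside a disk covering that fraction of the ROI move, the rest
#'   stay put (static and mobile regions coexist as in cortical ER).
#' @param jitter_scale_px stationary s.d. `s` of the vertex displacement (px).
#' @param jitter_correlation AR(1) coefficient `rho` in `[0, 1)`.
#' @param frames number of frames (>= 2).
#' @param frame_interval_s frame interval in seconds.
#' @param n_puncta number of labelled puncta seeded at junctions.
#' @param puncta_radius_px rendered punctum radius (px).
#' @param puncta_jitter_px stationary s.d. of each punctum's own jitter (px).
#' @param events list of scheduled events, each a list with `type`
#'   (`"merge"`, `"split"` or `"absorb"`), `frame`, and `ids` (two punctum
#'   ids for merge, one otherwise).
#' @param seed optional integer; defaults to the phantom seed.
#' @return A `motion_spec` object.
#' @export
motion_spec <- function(mobile_fraction = 0.5, jitter_scale_px = 1.5,
                        jitter_correlation = 0.8, frames = 50,
                        frame_interval_s = 1, n_puncta = 0,
                        puncta_radius_px = 2.5, puncta_jitter_px = 1.0,
                        events = list(), seed = NULL) {
  if (mobile_fraction < 0 || mobile_fraction > 1)
    stop_ernet("mobile_fraction must lie in [0, 1]")
  if (frames < 2) stop_ernet("frames must be >= 2")
  if (jitter_correlation < 0 || jitter_correlation >= 1)
    stop_ernet("jitter_correlation must lie in [0, 1)")
  for (ev in events) {
    if (!is.list(ev) || is.null(ev$type) || is.null(ev$frame) ||
        is.null(ev$ids))
      stop_ernet("each event needs fields type, frame, ids")
    if (!ev$type %in% c("merge", "split", "absorb"))
      stop_ernet("unknown event type: ", ev$type)
    if (ev$frame < 2 || ev$frame > frames)
      stop_ernet("event frame ", ev$frame, " outside 2..frames")
    if (ev$type == "merge" && length(ev$ids) != 2L)
      stop_ernet("merge events need exactly two punctum ids")
    if (ev$type != "merge" && length(ev$ids) != 1L)
      stop_ernet(ev$type, " events need exactly one punctum id")
    if (any(ev$ids < 1 | ev$ids > n_puncta))
      stop_ernet("event references unknown punctum id ",
                 paste(ev$ids, collapse = ","))
  }
  structure(list(mobile_fraction = mobile_fraction,
                 jitter_scale_px = jitter_scale_px,
                 jitter_correlation = jitter_correlation,
                 frames = as.integer(frames),
                 frame_interval_s = frame_interval_s,
                 n_puncta = as.integer(n_puncta),
                 puncta_radius_px = puncta_radius_px,
                 puncta_jitter_px = puncta_jitter_px,
                 events = events, seed = seed), class = "motion_spec")
}

# AR(1) displacement series: list of n x 2 matrices, one per frame, frame 1
# all-zero so the first frame matches the still phantom exactly.
ou_displacements <- function(n, frames, s, rho, mobile) {
  D <- vector("list", frames)
  D[[1]] <- matrix(0, n, 2)
  if (n == 0L || s <= 0 || !any(mobile)) {
    for (t in seq_len(frames)[-1]) D[[t]] <- D[[1]]
    return(D)
  }
  innov_sd <- s * sqrt(1 - rho^2)
  for (t in seq_len(frames)[-1]) {
    step <- matrix(rnorm(2 * n, 0, innov_sd), n, 2)
    D[[t]] <- rho * D[[t - 1]] + step
    D[[t]][!mobile, ] <- 0
  }
  D
}

#' Generate a synthetic ER time-lapse with ground-truth tracks
#'
#' Frame 1 is exactly the [render_phantom()] output for the same spec.
#' Mobile vertices follow a seeded mean-reverting jitter; cisternae ride on
#' their anchor vertices; distractors stay put. Labelled puncta are seeded at
#' junctions and scheduled merge/split/absorb events are executed and logged.
#'
#' @inheritParams render_phantom
#' @param motion a [motion_spec()].
#' @return A list with `stack` (noisy [image_stack()]) and `truth`
#'   (the frame-1 `phantom_truth` extended with `tracks` — a data.frame of
#'   `track_id, frame, x, y, active` — `events`, `fates`,
#'   `mobile_vertices`, and `vertex_displacement`, the per-frame list of
#'   displacement matrices).
#' @export
generate_timelapse <- function(graph, spec = graph$spec, motion) {
  stopifnot(inherits(graph, "tubule_graph"), inherits(motion, "motion_spec"))
  base <- render_phantom(graph, spec)
  truth <- base$truth
  H <- spec$height; W <- spec$width
  roi <- roi_mask_of(spec)
  nv <- nrow(graph$vertices)
  seed <- derive_seed(motion$seed %||% spec$seed, 77)
  with_seed(seed, {
    # mobile region: a disk covering mobile_fraction of the ROI
    mobile <- rep(FALSE, nv)
    if (motion$mobile_fraction >= 1) {
      mobile <- rep(TRUE, nv)
    } else if (motion$mobile_fraction > 0) {
      r <- sqrt(motion$mobile_fraction * sum(roi) / pi)
      ctr <- c(runif(1, 1, W), runif(1, 1, H))
      mobile <- (graph$vertices[, 1] - ctr[1])^2 +
                (graph$vertices[, 2] - ctr[2])^2 <= r^2
    }
    D <- ou_displacements(nv, motion$frames, motion$jitter_scale_px,
                          motion$jitter_correlation, mobile)

    # ---- puncta trajectories -------------------------------------------
    np <- motion$n_puncta
    traj <- NULL; active <- NULL; fates <- character(0)
    n_tracks <- np
    if (np > 0L) {
      cand <- graph$junctions
      if (length(cand) < np) cand <- seq_len(nv)
      # puncta label distinct junctions: greedy minimum-separation pick so
      # spots are resolvable as separate components
      min_sep <- 4 * motion$puncta_radius_px
      pool <- sample(cand, length(cand))
      anchors <- integer(0)
      for (a in pool) {
        if (length(anchors) == np) break
        if (length(anchors) == 0L ||
            min(sqrt((graph$vertices[anchors, 1] - graph$vertices[a, 1])^2 +
                     (graph$vertices[anchors, 2] - graph$vertices[a, 2])^2)) >=
              min_sep)
          anchors <- c(anchors, a)
      }
      if (length(anchors) < np)
        anchors <- c(anchors, sample(setdiff(pool, anchors),
                                     np - length(anchors)))
      # merging puncta are adjacent structures: re-anchor the consumed
      # punctum at the vertex nearest its partner so the approach stays
      # within a plausible per-frame step
      for (ev in motion$events) {
        if (ev$type != "merge") next
        i <- ev$ids[1]; j <- ev$ids[2]
        d2 <- (graph$vertices[, 1] - graph$vertices[anchors[i], 1])^2 +
              (graph$vertices[, 2] - graph$vertices[anchors[i], 2])^2
        d2[anchors[i]] <- Inf
        anchors[j] <- which.min(d2)
      }
      extra <- sum(vapply(motion$events, function(e) e$type == "split", TRUE))
      n_tracks <- np + extra
      traj <- array(NA_real_, c(n_tracks, motion$frames, 2))
      active <- matrix(FALSE, n_tracks, motion$frames)
      own <- ou_displacements(np, motion$frames, motion$puncta_jitter_px,
                              motion$jitter_correlation, rep(TRUE, np))
      for (i in seq_len(np)) {
        for (t in seq_len(motion$frames)) {
          traj[i, t, ] <- graph$vertices[anchors[i], ] +
            D[[t]][anchors[i], ] + own[[t]][i, ]
        }
        active[i, ] <- TRUE
      }
      fates <- rep("persisted", n_tracks)
      next_id <- np
      for (ev in motion$events) {
        f <- ev$frame
        if (ev$type == "merge") {
          i <- ev$ids[1]; j <- ev$ids[2]
          L <- min(6L, f - 1L)
          t0 <- f - L
          meet <- (traj[i, t0, ] + traj[j, t0, ]) / 2
          # the surviving track keeps its jitter increments, re-based at the
          # meeting point from the merge frame on
          base_at_f <- traj[i, f, ]
          if (f < motion$frames)
            for (t in (f + 1):motion$frames)
              traj[i, t, ] <- meet + (traj[i, t, ] - base_at_f)
          for (t in t0:f) {
            w <- (t - t0) / L
            traj[i, t, ] <- (1 - w) * traj[i, t0, ] + w * meet
            traj[j, t, ] <- (1 - w) * traj[j, t0, ] + w * meet
          }
          active[j, f:motion$frames] <- FALSE
          fates[j] <- "merged"
        } else if (ev$type == "split") {
          i <- ev$ids[1]
          next_id <- next_id + 1L
          dirv <- c(cos(runif(1, 0, 2 * pi)), sin(runif(1, 0, 2 * pi)))
          for (t in f:motion$frames) {
            traj[next_id, t, ] <- traj[i, f, ] + (t - f) * 0.8 * dirv
            active[next_id, t] <- TRUE
          }
          fates[next_id] <- "persisted"
        } else if (ev$type == "absorb") {
          i <- ev$ids[1]
          tgt <- absorb_target(truth, traj[i, 1, ])
          L <- min(6L, f - 1L); t0 <- f - L
          for (t in t0:f) {
            w <- (t - t0) / L
            traj[i, t, ] <- (1 - w) * traj[i, t0, ] + w * tgt
          }
          active[i, (f):motion$frames] <- FALSE
          fates[i] <- "absorbed"
        }
      }
    }

    # ---- render frames --------------------------------------------------
    frames <- vector("list", motion$frames)
    frames[[1]] <- add_puncta(base$image$frames[[1]], traj, active, 1L,
                              motion, spec)
    static_net <- !any(mobile)
    clean_static <- NULL
    for (t in seq_len(motion$frames)[-1]) {
      if (static_net) {
        if (is.null(clean_static)) clean_static <- truth$clean
        clean <- clean_static
      } else {
        verts_t <- graph$vertices + D[[t]]
        tub <- fill_small_holes(rasterize_segments(verts_t, graph$edges,
                                                   spec$tubule_width_px,
                                                   H, W) & (roi > 0)) == 1L
        cis <- matrix(FALSE, H, W)
        if (length(truth$cisterna_anchors) > 0) {
          ctr <- graph$vertices[truth$cisterna_anchors, , drop = FALSE] +
            D[[t]][truth$cisterna_anchors, , drop = FALSE]
          cis <- rasterize_disks(ctr, truth$cisterna_radii, H, W) & (roi > 0)
        }
        clean <- matrix(spec$bg_level, H, W)
        clean[tub] <- spec$tubule_level
        clean[cis] <- spec$cisterna_level
        clean[truth$distractor_mask > 0] <- spec$distractor_level
      }
      img <- apply_optics(clean, spec)
      frames[[t]] <- add_puncta(img, traj, active, t, motion, spec)
    }

    tracks <- NULL
    if (!is.null(traj)) {
      tracks <- do.call(rbind, lapply(seq_len(n_tracks), function(i) {
        data.frame(track_id = i, frame = seq_len(motion$frames),
                   x = traj[i, , 1], y = traj[i, , 2],
                   active = active[i, ])
      }))
    }
    events_df <- if (length(motion$events))
      do.call(rbind, lapply(motion$events, function(e)
        data.frame(frame = e$frame, type = e$type, id1 = e$ids[1],
                   id2 = if (length(e$ids) > 1) e$ids[2] else NA_integer_)))
    else data.frame(frame = integer(0), type = character(0),
                    id1 = integer(0), id2 = integer(0))
    truth$tracks <- tracks
    truth$events <- events_df
    truth$fates <- fates
    truth$mobile_vertices <- which(mobile)
    truth$vertex_displacement <- D
    list(stack = image_stack(frames, spec$pixel_size_um,
                             motion$frame_interval_s),
         truth = truth)
  })
}

absorb_target <- function(truth, from_xy) {
  if (length(truth$cisterna_anchors) == 0L) return(from_xy)
  ctr <- truth$graph$vertices[truth$cisterna_anchors, , drop = FALSE]
  d2 <- (ctr[, 1] - from_xy[1])^2 + (ctr[, 2] - from_xy[2])^2
  ctr[which.min(d2), ]
}

add_puncta <- function(img, traj, active, t, motion, spec) {
  if (is.null(traj)) return(img)
  idx <- which(active[, t])
  if (length(idx) == 0L) return(img)
  ctr <- matrix(traj[idx, t, ], ncol = 2)
  m <- rasterize_disks(ctr, rep(motion$puncta_radius_px, length(idx)),
                       spec$height, spec$width)
  img[m] <- spec$distractor_level
  img
}
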