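# Shared fixtures: phantoms are generated in code, cached per session.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- builder()
  .fixture_env[[key]]
}

noiseless_spec <- function(seed, n_seeds = 90, cisternae_fraction = 0,
                           size = 256, tubule_width_px = 3) {
  phantom_spec(width = size, height = size, n_seeds = n_seeds,
               cisternae_fraction = cisternae_fraction,
               tubule_width_px = tubule_width_px,
               psf_sigma_px = 0, peak_photons = Inf, read_noise_sd = 0,
               seed = seed)
}

noisy_spec <- function(seed, peak_photons = 50, n_seeds = 90,
                       cisternae_fraction = 0.10, size = 256,
                       tubule_width_px = 2, n_distractors = 0) {
  phantom_spec(width = size, height = size, n_seeds = n_seeds,
               cisternae_fraction = cisternae_fraction,
               tubule_width_px = tubule_width_px, n_distractors = n_distractors,
               psf_sigma_px = 1, peak_photons = peak_photons,
               read_noise_sd = 0.01, seed = seed)
}

jaccard <- function(a, b) sum(a == 1L & b == 1L) / sum(a == 1L | b == 1L)

# a moderately noisy phantom with distractors plus a classifier trained on
# half of its truth labels; reused across segmentation tests
classifier_fixture <- function() {
  cached("classifier", function() {
    spec <- noisy_spec(21, peak_photons = 50, cisternae_fraction = 0.08,
                       n_distractors = 6, tubule_width_px = 3)
    ph <- render_phantom(generate_network_graph(spec))
    frame <- ph$image$frames[[1]]
    labels <- matrix(0L, spec$height, spec$width)
    labels[ph$truth$er_mask == 1L] <- 1L
    labels[ph$truth$er_mask == 0L & ph$truth$distractor_mask == 0L] <- 2L
    labels[ph$truth$distractor_mask == 1L] <- 3L
    train <- labels
    set.seed(99)
    train[sample(length(train), length(train) / 2)] <- 0L
    fs <- extract_pixel_features(frame)
    clf <- train_pixel_classifier(fs, train, seed = 5)
    list(spec = spec, phantom = ph, frame = frame, labels = labels,
         classifier = clf)
  })
}

# Greedy one-to-one matching of detected tracks to truth tracks: a truth
# track is recovered when a distinct detected track follows it with mean
# distance <= tol_px over >= min_overlap of its active frames.
match_tracks <- function(truth_tracks, detected_tracks, tol_px = 3,
                         min_overlap = 0.8) {
  t_ids <- unique(truth_tracks$track_id)
  d_ids <- unique(detected_tracks$track_id)
  pairs <- NULL
  for (id in t_ids) {
    tt <- truth_tracks[truth_tracks$track_id == id & truth_tracks$active, ]
    for (did in d_ids) {
      dt <- detected_tracks[detected_tracks$track_id == did, ]
      mf <- intersect(tt$frame, dt$frame)
      if (length(mf) < min_overlap * nrow(tt)) next
      d <- mean(sqrt((tt$x[match(mf, tt$frame)] - dt$x[match(mf, dt$frame)])^2 +
                     (tt$y[match(mf, tt$frame)] - dt$y[match(mf, dt$frame)])^2))
      if (d <= tol_px) pairs <- rbind(pairs, c(id, did, d))
    }
  }
  n_matched <- 0L
  if (!is.null(pairs)) {
    used_t <- used_d <- numeric(0)
    for (k in order(pairs[, 3])) {
      if (pairs[k, 1] %in% used_t || pairs[k, 2] %in% used_d) next
      used_t <- c(used_t, pairs[k, 1])
      used_d <- c(used_d, pairs[k, 2])
      n_matched <- n_matched + 1L
    }
  }
  list(n_truth = length(t_ids), n_matched = n_matched,
       rate = n_matched / length(t_ids))
}
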