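# Trainable three-class pixel segmentation of ER micrographs:
# {ER, background, rejected} as in interactive Weka-style workflows, but
# headless and reproducible. A global-threshold fallback covers clean images.

ER_CLASSES <- c("er", "background", "rejected")

#' Enhance image contrast
#'
#' Optional small-sigma Gaussian smoothing followed by a monotone linear
#' rescaling to `[0, 1]` that saturates the stated fraction of extreme
#' pixels (half at each end), mirroring ImageJ's enhance-contrast step.
#'
#' @param frame numeric matrix.
#' @param saturation_fraction total fraction of pixels clipped, in `[0, 0.5)`.
#' @param smooth_sigma_px pre-smoothing sigma in px; 0 disables.
#' @return numeric matrix in `[0, 1]`.
#' @export
enhance_contrast <- function(frame, saturation_fraction = 0.003,
                             smooth_sigma_px = 0) {
  if (!is.matrix(frame) || length(frame) == 0L)
    stop_ernet("frame must be a non-empty matrix")
  if (saturation_fraction < 0 || saturation_fraction >= 0.5)
    stop_ernet("saturation_fraction must lie in [0, 0.5)")
  f <- if (smooth_sigma_px > 0) gauss_smooth(frame, smooth_sigma_px) else frame
  qs <- quantile(f, c(saturation_fraction / 2, 1 - saturation_fraction / 2),
                 names = FALSE)
  lo <- qs[1]; hi <- qs[2]
  if (hi - lo < .Machine$double.eps) return(matrix(0, nrow(f), ncol(f)))
  pmin(pmax((f - lo) / (hi - lo), 0), 1)
}

#' Extract a multi-scale per-pixel feature stack
#'
#' For each scale sigma: Gaussian-smoothed intensity, gradient magnitude of
#' the smoothed image (central differences), Laplacian (ridge/edge response)
#' and difference of Gaussians (sigma vs 1.6 sigma). Boundaries are handled
#' by reflection, so features are exactly zero-derivative on constant input.
#'
#' @param frame numeric matrix.
#' @param scales vector of positive smoothing scales (px).
#' @return A `feature_stack`: list with `features` (H x W x (4 * n_scales)
#'   array), `scales` and `feature_names`.
#' @export
extract_pixel_features <- function(frame, scales = c(1, 2, 4)) {
  if (!is.matrix(frame)) stop_ernet("frame must be a matrix")
  if (length(scales) == 0L || any(scales <= 0))
    stop_ernet("scales must be non-empty and positive")
  H <- nrow(frame); W <- ncol(frame)
  feats <- array(0, c(H, W, 4L * length(scales)))
  nms <- character(4L * length(scales))
  k <- 0L
  for (s in scales) {
    sm <- gauss_smooth(frame, s)
    gx <- matrix(0, H, W); gy <- matrix(0, H, W)
    gx[, 2:(W - 1)] <- (sm[, 3:W] - sm[, 1:(W - 2)]) / 2
    gy[2:(H - 1), ] <- (sm[3:H, ] - sm[1:(H - 2), ]) / 2
    lap <- matrix(0, H, W)
    lap[2:(H - 1), 2:(W - 1)] <-
      sm[1:(H - 2), 2:(W - 1)] + sm[3:H, 2:(W - 1)] +
      sm[2:(H - 1), 1:(W - 2)] + sm[2:(H - 1), 3:W] -
      4 * sm[2:(H - 1), 2:(W - 1)]
    dog <- sm - gauss_smooth(frame, 1.6 * s)
    feats[, , k + 1L] <- sm
    feats[, , k + 2L] <- sqrt(gx^2 + gy^2)
    feats[, , k + 3L] <- lap
    feats[, , k + 4L] <- dog
    nms[k + 1:4] <- paste0(c("gauss", "gradmag", "laplacian", "dog"),
                           "_s", s)
    k <- k + 4L
  }
  structure(list(features = feats, scales = scales, feature_names = nms),
            class = "feature_stack")
}

feature_matrix <- function(fs, idx = NULL) {
  d <- dim(fs$features)
  m <- matrix(fs$features, d[1] * d[2], d[3])
  colnames(m) <- fs$feature_names
  if (!is.null(idx)) m <- m[idx, , drop = FALSE]
  m
}

#' Train the three-class pixel classifier
#'
#' Fits a seeded random forest (decision-tree ensemble) on labelled pixels.
#' Labels use 1 = ER, 2 = background, 3 = rejected (e.g. mitochondria);
#' 0 = unlabelled. Each class needs at least 50 labelled pixels; a balanced
#' subsample (up to `max_per_class` per class) keeps training fast.
#'
#' @param features a `feature_stack` from [extract_pixel_features()].
#' @param label_mask integer matrix of the same H x W with values 0..3.
#' @param n_trees number of trees.
#' @param max_per_class training pixels sampled per class.
#' @param seed integer seed; training and prediction are reproducible.
#' @return A `pixel_classifier`: the fitted ensemble, the scales used, class
#'   labels, and per-class training recall.
#' @export
train_pixel_classifier <- function(features, label_mask, n_trees = 100,
                                   max_per_class = 2000, seed = 1) {
  stopifnot(inherits(features, "feature_stack"))
  d <- dim(features$features)
  if (!is.matrix(label_mask) || nrow(label_mask) != d[1] ||
      ncol(label_mask) != d[2])
    stop_ernet("label_mask must match the feature stack dimensions")
  counts <- vapply(1:3, function(k) sum(label_mask == k), 0L)
  for (k in 1:3)
    if (counts[k] < 50L)
      stop_ernet("class '", ER_CLASSES[k], "' has only ", counts[k],
                 " labelled pixels (need >= 50)")
  with_seed(seed, {
    idx <- unlist(lapply(1:3, function(k) {
      w <- which(label_mask == k)
      if (length(w) > max_per_class) sample(w, max_per_class) else w
    }))
    X <- feature_matrix(features, idx)
    y <- factor(ER_CLASSES[label_mask[idx]], levels = ER_CLASSES)
    df <- data.frame(X, y = y, check.names = FALSE)
    fit <- ranger::ranger(y ~ ., data = df, num.trees = n_trees,
                          seed = seed, num.threads = 1L,
                          respect.unordered.factors = "order")
    pred <- predict(fit, data = df, num.threads = 1L)$predictions
    recall <- vapply(ER_CLASSES, function(cl)
      mean(pred[y == cl] == cl), 0)
    structure(list(model = fit, scales = features$scales,
                   classes = ER_CLASSES, training_recall = recall,
                   seed = seed, n_trees = n_trees),
              class = "pixel_classifier")
  })
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat(sprintf("pixel_classifier: %d trees, scales {%s}; training recall er %.3f / bg %.3f / rejected %.3f\n",
              x$n_trees, paste(x$scales, collapse = ", "),
              x$training_recall[1], x$training_recall[2],
              x$training_recall[3]))
  invisible(x)
}

#' Predict the class map for a frame
#' @param classifier a [train_pixel_classifier()] fit.
#' @param frame numeric matrix.
#' @return integer matrix with values 1 (ER), 2 (background), 3 (rejected).
#' @export
predict_class_map <- function(classifier, frame) {
  stopifnot(inherits(classifier, "pixel_classifier"))
  fs <- extract_pixel_features(frame, classifier$scales)
  X <- data.frame(feature_matrix(fs), check.names = FALSE)
  pred <- predict(classifier$model, data = X, num.threads = 1L)$predictions
  matrix(match(as.character(pred), ER_CLASSES), nrow(frame), ncol(frame))
}

#' Segment one frame into ER / background / rejected
#'
#' Either applies a trained [train_pixel_classifier()] model, or falls back
#' to a global threshold (Otsu's between-class-variance criterion when
#' `threshold = NULL`). Rejected (distractor) pixels are excluded from the
#' binary ER mask by construction.
#'
#' @param frame numeric matrix. In threshold mode intensities are
#'   contrast-normalized to `[0, 1]` first; in classifier mode features are
#'   computed on the raw frame, matching the training convention.
#' @param classifier optional `pixel_classifier`; when `NULL`, threshold
#'   mode is used.
#' @param threshold optional global threshold in (0, 1) on the normalized
#'   frame.
#' @param saturation_fraction passed to [enhance_contrast()].
#' @param smooth_sigma_px optional noise-reduction smoothing before
#'   thresholding (as applied to noisy confocal images); 0 disables.
#' @return A `segmentation_mask`: `class_map` (1/2/3), `er_mask` (0/1),
#'   and `provenance` (classifier or the threshold used).
#' @export
segment_image <- function(frame, classifier = NULL, threshold = NULL,
                          saturation_fraction = 0.003,
                          smooth_sigma_px = 0) {
  if (!is.matrix(frame)) stop_ernet("frame must be a matrix")
  norm <- enhance_contrast(frame, saturation_fraction, smooth_sigma_px)
  if (!is.null(classifier)) {
    cm <- predict_class_map(classifier, frame)
    prov <- sprintf("classifier(trees=%d, seed=%d)", classifier$n_trees,
                    classifier$seed)
  } else {
    if (is.null(threshold)) {
      threshold <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
    } else if (threshold <= 0 || threshold >= 1) {
      stop_ernet("threshold must lie in (0, 1)")
    }
    cm <- matrix(2L, nrow(frame), ncol(frame))
    cm[norm > threshold] <- 1L
    prov <- sprintf("threshold(%.4f)", threshold)
  }
  structure(list(class_map = cm, er_mask = check_mask(cm == 1L),
                 provenance = prov), class = "segmentation_mask")
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat(sprintf("segmentation_mask: %d ER px, %d rejected px [%s]\n",
              sum(x$class_map == 1L), sum(x$class_map == 3L), x$provenance))
  invisible(x)
}

#' Morphological closing of a binary mask
#'
#' Dilation followed by erosion with a disc element, iterated; seals small
#' gaps to restore network connectivity after segmentation. Closing is
#' extensive (never removes foreground) and idempotent beyond the first
#' iteration.
#'
#' @param mask binary matrix.
#' @param radius_px disc radius in px (>= 1).
#' @param iterations number of closing passes (>= 1).
#' @return 0/1 integer matrix.
#' @export
close_mask <- function(mask, radius_px = 2, iterations = 1) {
  mask <- check_mask(mask)
  if (radius_px < 1) stop_ernet("radius_px must be >= 1")
  if (iterations < 1) stop_ernet("iterations must be >= 1")
  kern <- disc_brush(radius_px)
  H <- nrow(mask); W <- ncol(mask)
  pad <- radius_px + 1L
  out <- mask
  for (i in seq_len(iterations)) {
    # pad so border foreground is not eaten by the erosion half-step
    p <- matrix(0L, H + 2L * pad, W + 2L * pad)
    p[(pad + 1):(pad + H), (pad + 1):(pad + W)] <- out
    p <- EBImage::closing(p, kern)
    out <- check_mask(p[(pad + 1):(pad + H), (pad + 1):(pad + W)] > 0)
  }
  check_mask(out == 1L | mask == 1L)
}
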