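# Group comparisons for ER morphometrics: Wilcoxon rank-sum (exact by
# enumeration with midrank ties, or tie-corrected normal approximation with
# continuity correction) and Welch's unequal-variance t test.

#' Wilcoxon rank-sum test
#'
#' Rank-sum test with midrank handling of ties. In exact mode the null
#' distribution of the rank-sum of `a` is enumerated over all
#' `choose(n_a + n_b, n_a)` assignments of the (mid)ranks, which stays
#' valid under ties; otherwise a normal approximation with tie-corrected
#' variance and continuity correction is used.
#'
#' @param a,b numeric samples (each >= 1 value).
#' @param alternative `"two.sided"`, `"greater"` (a shifted above b) or
#'   `"less"`.
#' @param mode `"auto"` (exact when `n_a + n_b <= 20`), `"exact"` or
#'   `"normal"`.
#' @return A `group_comparison` list: `test`, `statistic` (rank-sum W of
#'   `a`), `p_value`, `n`, `alternative`, `mode`.
#' @export
wilcoxon_rank_sum <- function(a, b,
                              alternative = c("two.sided", "greater", "less"),
                              mode = c("auto", "exact", "normal")) {
  alternative <- match.arg(alternative)
  mode <- match.arg(mode)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 1L || length(b) < 1L)
    stop_ernet("each sample needs at least one value")
  na <- as.numeric(length(a)); nb <- as.numeric(length(b)); n <- na + nb
  if (mode == "auto") mode <- if (n <= 20L) "exact" else "normal"
  if (mode == "exact" && n > 20L)
    stop_ernet("exact mode is limited to n_a + n_b <= 20")
  r <- rank(c(a, b))            # midranks
  W <- sum(r[seq_len(na)])
  mu <- na * (n + 1) / 2
  if (length(unique(c(a, b))) == 1L) {
    warning("all values identical in both samples: p = 1", call. = FALSE)
    return(new_group_comparison("wilcoxon", W, 1, c(na, nb), alternative,
                                mode))
  }
  if (mode == "exact") {
    sums <- combn_rank_sums(r, na)
    tol <- 1e-9
    p <- switch(alternative,
      two.sided = mean(abs(sums - mu) >= abs(W - mu) - tol),
      greater   = mean(sums >= W - tol),
      less      = mean(sums <= W + tol))
  } else {
    ties <- table(r)
    tie_corr <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tie_corr)
    sigma <- sqrt(sigma2)
    z_cc <- function(dev) (dev - 0.5 * sign(dev)) / sigma
    p <- switch(alternative,
      two.sided = 2 * pnorm(abs(z_cc(W - mu)), lower.tail = FALSE),
      greater   = pnorm(z_cc(W - mu), lower.tail = FALSE),
      less      = pnorm(z_cc(W - mu)))
    p <- min(1, p)
  }
  new_group_comparison("wilcoxon", W, p, c(na, nb), alternative, mode)
}

# rank-sums of every choose(n, na)-subset of the (mid)rank vector
combn_rank_sums <- function(r, na) {
  combn(length(r), na, FUN = function(i) sum(r[i]))
}

#' Welch's unequal-variance t test
#'
#' Two-sample t test with Welch-Satterthwaite degrees of freedom.
#'
#' @param a,b numeric samples (each >= 2 values).
#' @param alternative as in [wilcoxon_rank_sum()].
#' @return A `group_comparison` list with `statistic` (t), `p_value`, `df`.
#' @export
welch_t <- function(a, b,
                    alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop_ernet("each sample needs at least two values")
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b)) {
      warning("zero variance and equal means: p = 1", call. = FALSE)
      return(new_group_comparison("welch", 0, 1,
                                  c(length(a), length(b)), alternative,
                                  "welch", df = NA_real_))
    }
    stop_ernet("zero variance in both samples with unequal means")
  }
  ht <- t.test(a, b, alternative = alternative, var.equal = FALSE)
  new_group_comparison("welch", unname(ht$statistic), ht$p.value,
                       c(length(a), length(b)), alternative, "welch",
                       df = unname(ht$parameter))
}

new_group_comparison <- function(test, statistic, p, n, alternative, mode,
                                 df = NULL) {
  structure(list(test = test, statistic = statistic, p_value = p,
                 n = n, alternative = alternative, mode = mode, df = df),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s test (%s, %s): statistic %.4g, p = %.4g (n = %s)\n",
              x$test, x$mode, x$alternative, x$statistic, x$p_value,
              paste(x$n, collapse = "/")))
  invisible(x)
}

# box-plot statistics with linear-interpolation quartiles (type 7)
box_stats <- function(x) {
  q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lw <- min(x[x >= q[1] - 1.5 * iqr])
  uw <- max(x[x <= q[3] + 1.5 * iqr])
  c(q1 = q[1], median = q[2], q3 = q[3], whisker_low = lw,
    whisker_high = uw, n_outliers = sum(x < lw | x > uw))
}

#' Compare two groups of per-cell morphometric summaries
#'
#' Applies the configured test to one of the three headline ER metrics.
#' Polygon areas are pooled across the images of each group (each enclosed
#' polygon contributes one value, matching how per-cell polygon
#' distributions are reported); cisternae percentage and junction density
#' contribute one value per image. Box-plot statistics (median, quartiles
#' by linear interpolation, 1.5 IQR whiskers) are reported per group.
#'
#' @param summaries_a,summaries_b lists of `morphometric_summary` objects
#'   (or data.frames from [summary_row()] for the per-image metrics).
#' @param metric `"polygon_area_um2"`, `"cisternae_pct"` or
#'   `"junction_density_per_um2"`.
#' @param test `"wilcoxon"` (default for polygon areas) or `"welch"`.
#' @param alternative passed to the test.
#' @return A `group_comparison` augmented with per-group `values`,
#'   `box_stats` and the metric name.
#' @export
compare_groups <- function(summaries_a, summaries_b,
                           metric = c("polygon_area_um2", "cisternae_pct",
                                      "junction_density_per_um2"),
                           test = c("wilcoxon", "welch"),
                           alternative = "two.sided") {
  metric <- match.arg(metric)
  test <- match.arg(test)
  va <- metric_values(summaries_a, metric)
  vb <- metric_values(summaries_b, metric)
  if (length(va) < 2L || length(vb) < 2L)
    stop_ernet("need >= 2 values per group for metric ", metric)
  cmp <- if (test == "wilcoxon")
    wilcoxon_rank_sum(va, vb, alternative = alternative, mode = "auto")
  else welch_t(va, vb, alternative = alternative)
  cmp$metric <- metric
  cmp$values <- list(a = va, b = vb)
  cmp$box_stats <- list(a = box_stats(va), b = box_stats(vb))
  cmp
}

metric_values <- function(summaries, metric) {
  if (is.data.frame(summaries)) {
    if (metric == "polygon_area_um2")
      stop_ernet("polygon areas need full summaries, not summary rows")
    if (!metric %in% names(summaries))
      stop_ernet("metric '", metric, "' not found in summary table")
    return(summaries[[metric]])
  }
  stopifnot(is.list(summaries))
  if (metric == "polygon_area_um2") {
    unlist(lapply(summaries, function(s) {
      stopifnot(inherits(s, "morphometric_summary"))
      s$polygon_areas_um2
    }))
  } else {
    vapply(summaries, function(s) {
      stopifnot(inherits(s, "morphometric_summary"))
      v <- s[[metric]]
      if (is.null(v)) stop_ernet("metric '", metric, "' missing")
      v
    }, 0)
  }
}
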