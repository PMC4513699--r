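#' Nearest-rank percentile
#'
#' The q-th percentile of a sample is its k-th smallest value with
#' `k = ceiling(q/100 * n)` (and `k >= 1`, so `q = 0` returns the minimum).
#' This convention is exactly reproducible on any sample size and makes the
#' filtered set of [filtered_mean] never empty: at q = 89 at least the top
#' 11% of samples lie at or above the threshold.
#'
#' @param values non-empty numeric vector, all finite.
#' @param q percentile in `[0, 100)`.
#' @return the nearest-rank percentile value.
#' @export
percentile <- function(values, q) {
  n <- length(values)
  if (n == 0L) stop("`values` must be non-empty")
  if (!all(is.finite(values))) stop("`values` must be finite")
  if (!is.numeric(q) || length(q) != 1L || q < 0 || q >= 100)
    stop("`q` must be a single value in [0, 100)")
  k <- max(1L, as.integer(ceiling(q / 100 * n)))
  sort(values, partial = k)[k]
}

#' Segment summary: raw and percentile-filtered means
#'
#' Retains every value at or above the q-th nearest-rank percentile (ties at
#' the threshold are all kept) and averages them. This is the dark-object
#' filter of the method: near-zero pixels from nuclei or glycogen-rich
#' cytoplasm fall below the threshold and are excluded, so the filtered mean
#' tracks the bright cytoplasmic plateau of the segment.
#'
#' @param values non-empty numeric vector of segment intensities.
#' @param q percentile threshold in `[0, 100)`; default 89 keeps the top
#'   decile (and a little more on small samples).
#' @return an object of class `segment_summary`: list with `raw_mean`,
#'   `filtered_mean`, `q`, `threshold`, `n`, `n_kept`. `filtered_mean >=
#'   raw_mean` always.
#' @export
filtered_mean <- function(values, q = 89) {
  thr <- percentile(values, q)
  kept <- values[values >= thr]
  structure(list(raw_mean = mean(values), filtered_mean = mean(kept),
                 q = q, threshold = thr,
                 n = length(values), n_kept = length(kept)),
            class = "segment_summary")
}

#' Ordinary least-squares slope through segment means
#'
#' Fits `y ~ x` by OLS. With the default abscissa of segment indices
#' `x = (1, 2, 3)`, the slope reduces exactly to `(m3 - m1) / 2`.
#'
#' @param y numeric response (segment means).
#' @param x strictly increasing numeric abscissa, same length as `y`.
#' @return list with `slope` and `intercept`.
#' @export
fit_slope <- function(y, x = c(1, 2, 3)) {
  if (length(x) != length(y) || length(y) < 2L)
    stop("`x` and `y` must have equal length >= 2")
  if (any(diff(x) <= 0)) stop("`x` must be strictly increasing")
  ols_line(y, x)
}

# plain OLS line; used directly when x carries ties (per-sample regression)
ols_line <- function(y, x) {
  xc <- x - mean(x)
  if (all(xc == 0)) stop("`x` must vary")
  slope <- sum(xc * (y - mean(y))) / sum(xc^2)
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}

#' Normalize segment means to the basal segment
#'
#' Divides all segment means by the basal (first) mean so the basal value is
#' exactly 1. This internal control removes multiplicative variation from
#' staining intensity, exposure time, illumination and section thickness,
#' making slopes comparable across samples and institutions.
#'
#' @param means numeric vector of segment means; `means[1]` must be `> 0`.
#' @return `means / means[1]`, first element exactly 1.
#' @export
normalize_to_basal <- function(means) {
  if (!all(is.finite(means))) stop("segment means must be finite")
  if (means[1] <= 0)
    stop("basal segment mean must be > 0 for normalization")
  means / means[1]
}

#' Score one intensity profile
#'
#' The per-line statistic of the method: the profile is split into three
#' equidistant segments, each segment is reduced to its percentile-filtered
#' mean (default q = 89, the top decile), an OLS slope is fitted through the
#' three filtered means against segment indices (1, 2, 3), and the means are
#' normalized to the basal segment. With the segment-index abscissa the
#' normalized slope equals `raw_slope / basal filtered mean`, so it is
#' invariant to any positive rescaling of the image.
#'
#' @param profile an [intensity_profile] or numeric vector of ordered
#'   basal-to-surface intensities.
#' @param q percentile threshold in `[0, 100)`; default 89.
#' @param x_convention `"segment_index"` (x = 1, 2, 3; default) or
#'   `"pixel_midpoint"` (x = mean 0-based sample index of each segment, in
#'   pixels, times the sampling step).
#' @param regression_mode `"segment_means"` (fit the three filtered means;
#'   default) or `"all_samples"` (fit every retained sample against its
#'   segment abscissa; sensitivity analysis).
#' @return an object of class `slope_result`: list with `raw_slope`,
#'   `intercept`, `filtered_means`, `raw_means`, `normalized_means`
#'   (first element exactly 1 when valid), `normalized_slope`, `q`, `valid`.
#'   A line whose basal filtered mean is not positive is flagged
#'   `valid = FALSE` (normalized quantities `NA`) so aggregation can exclude
#'   and count it.
#' @export
score_line <- function(profile, q = 89,
                       x_convention = c("segment_index", "pixel_midpoint"),
                       regression_mode = c("segment_means", "all_samples")) {
  x_convention <- match.arg(x_convention)
  regression_mode <- match.arg(regression_mode)
  values <- if (inherits(profile, "intensity_profile")) profile$values
            else as.numeric(profile)
  step <- if (inherits(profile, "intensity_profile")) profile$step else 1
  seg <- split_into_segments(values)
  segs <- list(seg$lower, seg$middle, seg$upper)
  summaries <- lapply(segs, filtered_mean, q = q)
  m <- vapply(summaries, `[[`, 0, "filtered_mean")
  raw_means <- vapply(summaries, `[[`, 0, "raw_mean")
  lens <- lengths(segs)
  x <- if (x_convention == "segment_index") c(1, 2, 3) else {
    ends <- cumsum(lens)
    starts <- c(0, ends[-3])
    (starts + ends - 1) / 2 * step  # mean 0-based sample index, in px
  }
  if (regression_mode == "segment_means") {
    fit <- fit_slope(m, x)
  } else {
    keep <- lapply(seq_len(3), function(k)
      segs[[k]][segs[[k]] >= summaries[[k]]$threshold])
    fit <- ols_line(unlist(keep), rep(x, lengths(keep)))
  }
  valid <- m[1] > 0
  norm_means <- if (valid) m / m[1] else rep(NA_real_, 3)
  norm_slope <- if (valid) fit_slope(norm_means, x)$slope else NA_real_
  structure(list(raw_slope = fit$slope, intercept = fit$intercept,
                 filtered_means = m, raw_means = raw_means,
                 normalized_means = norm_means,
                 normalized_slope = norm_slope,
                 q = q, x = x, valid = valid),
            class = "slope_result")
}

#' @export
print.slope_result <- function(x, ...) {
  cat(sprintf("slope_result: raw %.4g, normalized %.4g (q = %g, %s)\n",
              x$raw_slope, x$normalized_slope, x$q,
              if (x$valid) "valid" else "INVALID basal segment"))
  invisible(x)
}

#' Threshold sweep across percentile filters
#'
#' Recomputes per-group mean normalized slopes for every threshold on a 2%
#' grid from the bottom up, together with a separation score per threshold:
#' the minimum over group pairs of `|difference of group means| / pooled
#' SEM`. The separation score is a reporting aid for judging where class
#' signatures emerge (near the top decile); it is never used to change the
#' working threshold. A pooled SEM of zero with distinct means yields `Inf`.
#'
#' @param profiles_by_group named list: group label -> list of profiles
#'   (each an [intensity_profile] or numeric vector). At least 2 groups of
#'   at least 2 profiles.
#' @param q_grid increasing percentile grid; default `seq(0, 98, by = 2)`.
#' @param ... passed to [score_line].
#' @return an object of class `sweep_curve`: data frame with one row per
#'   threshold, columns `q`, `mean_<group>` per group, and `separation`.
#' @export
threshold_sweep <- function(profiles_by_group, q_grid = seq(0, 98, by = 2),
                            ...) {
  if (length(profiles_by_group) < 2L)
    stop("need at least 2 groups")
  if (any(lengths(profiles_by_group) < 2L))
    stop("each group needs at least 2 profiles")
  if (is.null(names(profiles_by_group)) ||
      any(!nzchar(names(profiles_by_group))))
    stop("`profiles_by_group` must be a named list")
  if (any(diff(q_grid) <= 0) || any(q_grid < 0 | q_grid >= 100))
    stop("`q_grid` must be strictly increasing within [0, 100)")
  groups <- names(profiles_by_group)
  rows <- lapply(q_grid, function(q) {
    stats_by_group <- lapply(profiles_by_group, function(pl) {
      s <- vapply(pl, function(p) score_line(p, q = q, ...)$normalized_slope,
                  0)
      s <- s[is.finite(s)]
      c(mean = mean(s), sem = stats::sd(s) / sqrt(length(s)), n = length(s))
    })
    mu <- vapply(stats_by_group, `[[`, 0, "mean")
    sem <- vapply(stats_by_group, `[[`, 0, "sem")
    pairs <- utils::combn(seq_along(groups), 2)
    sep <- apply(pairs, 2, function(ij) {
      d <- abs(mu[ij[1]] - mu[ij[2]])
      pooled <- sqrt(sem[ij[1]]^2 + sem[ij[2]]^2)
      if (pooled == 0) { if (d == 0) 0 else Inf } else d / pooled
    })
    c(q = q, mu, separation = min(sep))
  })
  df <- as.data.frame(do.call(rbind, rows))
  names(df) <- c("q", paste0("mean_", groups), "separation")
  class(df) <- c("sweep_curve", "data.frame")
  df
}
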