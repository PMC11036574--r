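# Gray-level quantization and first-order (intensity) features.

#' Quantize the VOI gray levels
#'
#' Equal-width binning of in-mask HU values between the in-mask minimum and
#' maximum into `n_bins` levels (1..n_bins). A constant-intensity VOI maps to
#' level 1 everywhere. Background voxels get level 0 and are excluded from all
#' texture counts.
#'
#' @param volume A [ct_volume()].
#' @param mask A congruent [roi_mask()].
#' @param n_bins Number of gray levels (>= 2).
#' @return List of class `quantized_voi`: `levels` (3D integer array, 0 =
#'   background), `n_bins`, `bin_edges` (length `n_bins + 1`, HU).
#' @export
quantize <- function(volume, mask, n_bins = 64L) {
  stopifnot(inherits(volume, "ct_volume"), inherits(mask, "roi_mask"))
  if (n_bins < 2L) stop("n_bins must be >= 2")
  fg <- mask$labels == 1L
  if (!any(fg)) stop("empty VOI")
  x <- volume$intensities[fg]
  lo <- min(x); hi <- max(x)
  lev <- array(0L, dim = dim(mask$labels))
  if (hi - lo <= .Machine$double.eps * max(1, abs(hi))) {
    lev[fg] <- 1L
    edges <- seq(lo - 0.5, lo + 0.5, length.out = n_bins + 1L)
  } else {
    l <- floor((x - lo) / (hi - lo) * n_bins) + 1L
    l[l > n_bins] <- n_bins                       # max HU lands in top bin
    lev[fg] <- as.integer(l)
    edges <- seq(lo, hi, length.out = n_bins + 1L)
  }
  structure(list(levels = lev, n_bins = as.integer(n_bins), bin_edges = edges),
            class = "quantized_voi")
}

#' First-order intensity features (24)
#'
#' Classical first-order statistics of the in-mask HU distribution. Variance,
#' sd, skewness and kurtosis use the population (1/n) convention; kurtosis is
#' excess kurtosis. `fo_entropy` and `fo_uniformity` are computed on the
#' quantized gray levels (`n_bins` equal-width bins, log base 2).
#' Degenerate limits: a constant VOI has skewness 0, kurtosis 0, entropy 0,
#' uniformity 1; `fo_cv` is 0 when the mean is 0.
#'
#' @param volume A [ct_volume()].
#' @param mask A congruent [roi_mask()].
#' @param n_bins Bins for the entropy/uniformity histogram.
#' @return Named numeric vector of 24 features, prefix `fo_`.
#' @export
intensity_features <- function(volume, mask, n_bins = 64L) {
  x <- volume$intensities[mask$labels == 1L]
  n <- length(x)
  if (n < 1L) stop("empty VOI")
  m <- mean(x)
  med <- stats::median(x)
  qs <- unname(stats::quantile(x, c(0.10, 0.25, 0.75, 0.90), type = 7))
  v <- sum((x - m)^2) / n                       # population variance
  s <- sqrt(v)
  skew <- if (s > 0) sum((x - m)^3) / n / s^3 else 0
  kurt <- if (s > 0) sum((x - m)^4) / n / v^2 - 3 else 0
  cellvol <- prod(volume$spacing_mm)
  energy <- sum(x^2)
  rx <- x[x >= qs[1L] & x <= qs[4L]]            # robust 10-90% subset
  q <- quantize(volume, mask, n_bins)
  pl <- tabulate(q$levels[q$levels > 0L], nbins = q$n_bins) / n
  pl <- pl[pl > 0]
  c(fo_mean = m,
    fo_median = med,
    fo_minimum = min(x),
    fo_maximum = max(x),
    fo_range = max(x) - min(x),
    fo_p10 = qs[1L],
    fo_p25 = qs[2L],
    fo_p75 = qs[3L],
    fo_p90 = qs[4L],
    fo_iqr = qs[3L] - qs[2L],
    fo_variance = v,
    fo_sd = s,
    fo_skewness = skew,
    fo_kurtosis = kurt,
    fo_energy = energy,
    fo_total_energy = energy * cellvol,
    fo_rms = sqrt(energy / n),
    fo_mad = mean(abs(x - m)),
    fo_robust_mad = mean(abs(rx - mean(rx))),
    fo_medad = mean(abs(x - med)),
    fo_entropy = -sum(pl * log2(pl)),
    fo_uniformity = sum(pl^2),
    fo_cv = if (abs(m) > .Machine$double.eps) s / m else 0,
    fo_sum = sum(x))
}
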