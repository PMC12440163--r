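# R-side surface of the feature engine: catalogue compilation to opcodes,
# single-series feature helpers grouped by family, and the window-set
# feature-matrix builder.

.op_table <- c(
  mean = 1, median = 2, maximum = 3, minimum = 4, absolute_maximum = 5,
  standard_deviation = 6, variance = 7, variation_coefficient = 8,
  root_mean_square = 9, sum_values = 10, abs_energy = 11,
  mean_abs_change = 12, absolute_sum_of_changes = 13, sample_entropy = 14,
  benford_correlation = 15, binned_entropy = 16, mean_n_absolute_max = 17,
  approximate_entropy = 18, permutation_entropy = 19, fourier_entropy = 20,
  cid_ce = 21, number_crossing_m = 22, number_peaks = 23, count_above = 24,
  count_below = 25, range_count = 26, quantile = 27, change_quantiles = 28,
  autocorrelation = 29, agg_autocorrelation = 30, c3 = 31,
  cwt_coefficients = 32, fft_coefficient = 33, fft_aggregated = 34,
  linear_trend = 35, agg_linear_trend = 36, max_langevin_fixed_point = 37
)

.agg_enum <- c(mean = 0, var = 1, median = 2, std = 3, max = 4, min = 5)
.lin_enum <- c(slope = 0, intercept = 1, rvalue = 2, pvalue = 3, stderr = 4)
.fft_enum <- c(real = 0, imag = 1, abs = 2, angle = 3)
.fftagg_enum <- c(centroid = 0, variance = 1, skew = 2, kurtosis = 3)

# compile a catalogue tibble into the integer/real vectors the C++ engine
# consumes
.compile_catalog <- function(catalog) {
  op <- unname(.op_table[catalog$feature_type])
  if (any(is.na(op))) {
    stop("unknown feature type: ",
         paste(unique(catalog$feature_type[is.na(op)]), collapse = ", "))
  }
  e1 <- integer(nrow(catalog))
  e2 <- integer(nrow(catalog))
  for (i in seq_len(nrow(catalog))) {
    ft <- catalog$feature_type[i]
    s1 <- catalog$s1[i]; s2 <- catalog$s2[i]
    e1[i] <- switch(ft,
      change_quantiles = .agg_enum[[s1]],
      agg_autocorrelation = .agg_enum[[s1]],
      fft_coefficient = .fft_enum[[s1]],
      fft_aggregated = .fftagg_enum[[s1]],
      linear_trend = .lin_enum[[s1]],
      agg_linear_trend = .lin_enum[[s1]],
      0L)
    e2[i] <- switch(ft, agg_linear_trend = .agg_enum[[s2]], 0L)
  }
  list(op = as.integer(op),
       p1 = ifelse(is.na(catalog$p1), 0, catalog$p1),
       p2 = ifelse(is.na(catalog$p2), 0, catalog$p2),
       p3 = ifelse(is.na(catalog$p3), 0, catalog$p3),
       e1 = e1, e2 = as.integer(e2))
}

# evaluate a catalogue on a single numeric series
.eval_series <- function(series, catalog) {
  stopifnot(is.numeric(series), length(series) >= 1)
  cc <- .compile_catalog(catalog)
  m <- compute_features_engine(list(matrix(series, ncol = 1)),
                               cc$op, cc$p1, cc$p2, cc$p3, cc$e1, cc$e2)
  stats::setNames(as.numeric(m[1, ]), catalog$name)
}

.cat_subset <- function(types) {
  cat <- feature_catalog("full")
  cat[cat$feature_type %in% types, , drop = FALSE]
}

#' Moment and amplitude statistics of a series
#'
#' Mean, median, extrema, absolute maximum, population standard deviation
#' and variance, variation coefficient (sd/mean, 0 when the mean is 0), root
#' mean square, sum, absolute energy (sum of squares) and the mean of the
#' `n` largest absolute values.
#'
#' @param series Numeric vector (length >= 1).
#' @param n_absolute_max `n` for `mean_n_absolute_max`.
#' @return Named numeric vector.
#' @export
moment_statistics <- function(series, n_absolute_max = 7) {
  if (length(series) < 1) stop("empty series")
  cat <- dplyr::bind_rows(
    .cat_subset(c("mean", "median", "maximum", "minimum", "absolute_maximum",
                  "standard_deviation", "variance", "variation_coefficient",
                  "root_mean_square", "sum_values", "abs_energy")),
    .cat_rows("mean_n_absolute_max",
              data.frame(number_of_maxima = n_absolute_max))
  )
  .eval_series(series, cat)
}

#' Change, crossing, peak and corridor statistics of a series
#'
#' @param series Numeric vector (length >= 2 for change-based features).
#' @param m Threshold for `number_crossing_m`. @param n Peak support for
#'   `number_peaks`. @param t Threshold for `count_above` / `count_below`.
#' @param range `c(lo, hi)` for `range_count` (half-open). @param q Quantile
#'   level. @param ql,qh,isabs,f_agg `change_quantiles` corridor parameters.
#' @return Named numeric vector.
#' @export
change_statistics <- function(series, m = 0, n = 3, t = 0, range = c(-1, 1),
                              q = 0.5, ql = 0, qh = 1, isabs = FALSE,
                              f_agg = "mean") {
  if (length(series) < 2) stop("series too short for change statistics")
  if (ql >= qh) stop("ql must be < qh")
  cat <- dplyr::bind_rows(
    .cat_subset(c("mean_abs_change", "absolute_sum_of_changes")),
    .cat_rows("cid_ce", data.frame(normalize = c(0, 1))),
    .cat_rows("number_crossing_m", data.frame(m = m)),
    .cat_rows("number_peaks", data.frame(n = n)),
    .cat_rows("count_above", data.frame(t = t)),
    .cat_rows("count_below", data.frame(t = t)),
    .cat_rows("range_count", data.frame(min = range[1], max = range[2])),
    .cat_rows("quantile", data.frame(q = q)),
    .cat_rows("change_quantiles",
              data.frame(ql = ql, qh = qh, isabs = as.numeric(isabs),
                         f_agg = f_agg))
  )
  .eval_series(series, cat)
}

#' Correlation, trend and nonlinearity statistics of a series
#'
#' Autocorrelation at a lag (`sum((x_t - mu)(x_{t+lag} - mu)) /
#' ((n - lag) sigma^2)`, 0 for constant series), aggregated autocorrelation,
#' least-squares linear trend against the sample index, chunk-aggregated
#' linear trend, the c3 nonlinearity statistic, the Benford first-digit
#' correlation and the largest fixed point of Langevin dynamics estimated by
#' a polynomial fit to bin-averaged conditional increments.
#'
#' @param series Numeric vector.
#' @param lag Autocorrelation / c3 lag. @param maxlag,f_agg Aggregated
#'   autocorrelation parameters. @param chunk_len Chunk length for
#'   `agg_linear_trend`. @param langevin_m,langevin_r Polynomial order and
#'   bin count of the Langevin fixed-point estimate.
#' @return Named numeric vector.
#' @export
correlation_trend <- function(series, lag = 1, maxlag = 40, f_agg = "mean",
                              chunk_len = 10, langevin_m = 3,
                              langevin_r = 30) {
  if (length(series) < 3) stop("series too short for trend statistics")
  if (length(series) <= 2 * lag) stop("series length must exceed 2*lag")
  cat <- dplyr::bind_rows(
    .cat_rows("autocorrelation", data.frame(lag = lag)),
    .cat_rows("agg_autocorrelation",
              data.frame(f_agg = f_agg, maxlag = maxlag)),
    .cat_rows("linear_trend",
              data.frame(attr = c("slope", "intercept", "rvalue", "pvalue",
                                  "stderr"))),
    .cat_rows("agg_linear_trend",
              expand.grid(attr = c("slope", "intercept", "rvalue", "stderr"),
                          f_agg = f_agg, chunk_len = chunk_len,
                          stringsAsFactors = FALSE)),
    .cat_rows("c3", data.frame(lag = lag)),
    .cat_subset("benford_correlation"),
    .cat_rows("max_langevin_fixed_point",
              data.frame(m = langevin_m, r = langevin_r))
  )
  if (langevin_m != 3) stop("max_langevin_fixed_point is pinned to m = 3")
  .eval_series(series, cat)
}

#' Entropy statistics of a series
#'
#' Binned entropy (equidistant bins over the value range), approximate
#' entropy (Chebyshev distance, tolerance r times the SD), sample entropy (m = 2,
#' tolerance 0.2 sd, `-ln(A/B)`), permutation entropy (Shannon entropy of
#' ordinal-pattern frequencies, natural log) and Fourier entropy (binned
#' entropy of the max-normalised single-segment Welch power spectrum).
#' Degenerate cases (constant series) return 0.
#'
#' @param series Numeric vector.
#' @param max_bins Bins for binned entropy. @param m,r Approximate-entropy
#'   parameters. @param dim,tau Permutation-entropy embedding.
#' @param fourier_bins Bins for Fourier entropy.
#' @return Named numeric vector.
#' @export
entropies <- function(series, max_bins = 10, m = 2, r = 0.3, dim = 3,
                      tau = 1, fourier_bins = 10) {
  if (length(series) < max(m + 2, dim * tau + 1)) {
    stop("series too short for the requested entropies")
  }
  cat <- dplyr::bind_rows(
    .cat_rows("binned_entropy", data.frame(max_bins = max_bins)),
    .cat_rows("approximate_entropy", data.frame(m = m, r = r)),
    .cat_subset("sample_entropy"),
    .cat_rows("permutation_entropy", data.frame(tau = tau, dimension = dim)),
    .cat_rows("fourier_entropy", data.frame(bins = fourier_bins))
  )
  .eval_series(series, cat)
}

#' Spectral statistics of a series
#'
#' Discrete Fourier coefficients of the real input (`real`, `imag`, `abs`,
#' `angle` in degrees), aggregated spectral moments (centroid, variance,
#' skew, kurtosis of the magnitude spectrum over frequency-bin index), and
#' continuous wavelet transform coefficients with the Ricker (Mexican hat)
#' wavelet.
#'
#' @param series Numeric vector.
#' @param k FFT coefficient index, `k <= floor(n/2)`.
#' @param width Ricker wavelet width. @param coeff CWT coefficient index.
#' @return Named numeric vector.
#' @export
spectral <- function(series, k = 1, width = 2, coeff = 0) {
  n <- length(series)
  if (k > floor(n / 2)) stop("k must be <= floor(n/2)")
  cat <- dplyr::bind_rows(
    .cat_rows("fft_coefficient",
              expand.grid(attr = c("real", "imag", "abs", "angle"),
                          coeff = k, stringsAsFactors = FALSE)),
    .cat_rows("fft_aggregated",
              data.frame(aggtype = c("centroid", "variance", "skew",
                                     "kurtosis"))),
    .cat_rows("cwt_coefficients", data.frame(coeff = coeff, width = width))
  )
  .eval_series(series, cat)
}

#' Compute the window-by-feature matrix
#'
#' Evaluates every catalogue entry on every keypoint-channel series (33
#' landmarks x 3 channels = 99 series) of every analysis window. Feature
#' columns are named `<landmark>_<channel>__<type>__<param=value>`; the
#' column order (channels in window-column order, catalogue order within
#' channel) is deterministic. Non-finite feature values are replaced by 0
#' and reported in a message.
#'
#' @param windows Window tibble from [segment_windows()].
#' @param catalog Catalogue tibble from [feature_catalog()].
#' @return Tibble: the window metadata columns followed by one numeric
#'   column per feature.
#' @export
compute_feature_matrix <- function(windows, catalog = feature_catalog()) {
  if (nrow(windows) == 0) stop("no windows supplied")
  mats <- windows$data
  dims <- vapply(mats, function(m) dim(m), integer(2))
  if (length(unique(dims[1, ])) != 1 || length(unique(dims[2, ])) != 1) {
    stop("window shape mismatch")
  }
  tlen <- dims[1, 1]
  bad <- catalog$feature_type == "fft_coefficient" &
    catalog$p1 > floor(tlen / 2)
  if (any(bad)) {
    stop("fft_coefficient index exceeds floor(window_length/2)")
  }
  cc <- .compile_catalog(catalog)
  m <- compute_features_engine(mats, cc$op, cc$p1, cc$p2, cc$p3, cc$e1,
                               cc$e2)
  nnf <- attr(m, "n_nonfinite")
  if (!is.null(nnf) && nnf > 0) {
    message("replaced ", nnf, " non-finite feature values with 0")
  }
  channels <- colnames(mats[[1]])
  colnames(m) <- as.vector(vapply(channels, function(ch) {
    paste0(ch, "__", catalog$name)
  }, character(nrow(catalog))))
  meta <- windows[, setdiff(names(windows), "data"), drop = FALSE]
  dplyr::bind_cols(meta, tibble::as_tibble(m))
}

#' Split a feature name into keypoint channel and feature descriptor
#'
#' @param feature Character vector of feature names
#'   (`<landmark>_<channel>__<type>__<params>`).
#' @return Tibble with columns `feature`, `channel` (e.g. `left_knee_x`),
#'   `landmark_name`, `axis` and `feature_type`.
#' @export
parse_feature_names <- function(feature) {
  parts <- strsplit(feature, "__", fixed = TRUE)
  channel <- vapply(parts, `[`, character(1), 1)
  type <- vapply(parts, `[`, character(1), 2)
  axis <- sub(".*_([xyz])$", "\\1", channel)
  lmk <- sub("_[xyz]$", "", channel)
  bad <- !(axis %in% c("x", "y", "z")) | !(lmk %in% pose_landmarks) |
    is.na(type)
  if (any(bad)) {
    stop("unparseable feature name: ", feature[which(bad)[1]])
  }
  tibble::tibble(feature = feature, channel = channel, landmark_name = lmk,
                 axis = axis, feature_type = type)
}
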