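# The time-series feature catalogue.
#
# Each catalogue entry is one (feature type, parameter set) pair, evaluated
# on every keypoint-channel series of every analysis window. Two pinned
# catalogues are provided: "full" mirrors the published per-channel
# catalogue size of 783 entries (so 33 landmarks x 3 channels x 783 =
# 77,517 candidate features per window set), "reduced" is the 71-entry
# default used for routine analyses and tests.

.fmt_num <- function(x) {
  vapply(x, function(v) format(v, trim = TRUE, scientific = FALSE),
         character(1))
}

.cat_rows <- function(type, grid = NULL, strings = character(0)) {
  if (is.null(grid)) {
    return(tibble::tibble(name = type, feature_type = type,
                          p1 = NA_real_, p2 = NA_real_, p3 = NA_real_,
                          s1 = NA_character_, s2 = NA_character_))
  }
  grid <- tibble::as_tibble(grid)
  pnames <- names(grid)
  parts <- lapply(seq_len(nrow(grid)), function(i) {
    vals <- grid[i, , drop = FALSE]
    paste0(pnames, "=", vapply(seq_along(pnames), function(j) {
      v <- vals[[j]]
      if (is.character(v)) v else .fmt_num(v)
    }, character(1)), collapse = "__")
  })
  num <- pnames[!vapply(grid, is.character, logical(1))]
  chr <- pnames[vapply(grid, is.character, logical(1))]
  out <- tibble::tibble(
    name = paste0(type, "__", unlist(parts)),
    feature_type = type,
    p1 = if (length(num) >= 1) as.numeric(grid[[num[1]]]) else NA_real_,
    p2 = if (length(num) >= 2) as.numeric(grid[[num[2]]]) else NA_real_,
    p3 = if (length(num) >= 3) as.numeric(grid[[num[3]]]) else NA_real_,
    s1 = if (length(chr) >= 1) grid[[chr[1]]] else NA_character_,
    s2 = if (length(chr) >= 2) grid[[chr[2]]] else NA_character_
  )
  out
}

#' Build the pinned feature catalogue
#'
#' @param mode `"reduced"` (71 entries per channel, the default for analyses
#'   and tests) or `"full"` (783 entries per channel, mirroring the published
#'   per-channel catalogue size).
#' @return Tibble with one row per (feature type, parameter set): columns
#'   `name` (the `type__param=value` suffix used in feature names),
#'   `feature_type`, numeric parameters `p1`..`p3` and string parameters
#'   `s1`, `s2`.
#' @export
feature_catalog <- function(mode = c("reduced", "full")) {
  mode <- match.arg(mode)
  singles <- c("mean", "median", "maximum", "minimum", "absolute_maximum",
               "standard_deviation", "variance", "variation_coefficient",
               "root_mean_square", "sum_values", "abs_energy",
               "mean_abs_change", "absolute_sum_of_changes",
               "sample_entropy", "benford_correlation")
  rows <- lapply(singles, .cat_rows)

  if (mode == "full") {
    qgrid <- expand.grid(ql = seq(0, 0.9, by = 0.1),
                         qh = seq(0.1, 1, by = 0.1))
    qgrid <- qgrid[qgrid$ql < qgrid$qh - 1e-9, ]
    cq <- expand.grid(f_agg = c("mean", "var", "median", "std"),
                      isabs = c(0, 1), i = seq_len(nrow(qgrid)),
                      stringsAsFactors = FALSE)
    cq <- data.frame(ql = qgrid$ql[cq$i], qh = qgrid$qh[cq$i],
                     isabs = cq$isabs, f_agg = cq$f_agg)
    rows <- c(rows, list(
      .cat_rows("binned_entropy", data.frame(max_bins = c(2, 5, 10, 20))),
      .cat_rows("mean_n_absolute_max",
                data.frame(number_of_maxima = c(3, 5, 7))),
      .cat_rows("approximate_entropy",
                data.frame(m = 2, r = seq(0.1, 0.9, by = 0.1))),
      .cat_rows("permutation_entropy",
                expand.grid(tau = 1:3, dimension = 3:7)),
      .cat_rows("fourier_entropy",
                data.frame(bins = c(2, 3, 5, 10, 30, 100))),
      .cat_rows("cid_ce", data.frame(normalize = c(0, 1))),
      .cat_rows("number_crossing_m", data.frame(m = c(-1, 0, 1))),
      .cat_rows("number_peaks", data.frame(n = c(1, 3, 5, 7, 10))),
      .cat_rows("count_above", data.frame(t = c(-1, -0.5, 0, 0.5, 1))),
      .cat_rows("count_below", data.frame(t = c(-1, -0.5, 0, 0.5, 1))),
      .cat_rows("range_count",
                data.frame(min = c(-1, -2, 0, -0.5, -2, 0),
                           max = c(1, 0, 2, 0.5, 2, 1))),
      .cat_rows("quantile",
                data.frame(q = c(0.1, 0.2, 0.3, 0.4, 0.6, 0.7, 0.8, 0.9))),
      .cat_rows("change_quantiles", cq),
      .cat_rows("autocorrelation", data.frame(lag = 0:15)),
      .cat_rows("agg_autocorrelation",
                expand.grid(f_agg = c("mean", "median", "var", "std"),
                            maxlag = c(10, 40), stringsAsFactors = FALSE)),
      .cat_rows("c3", data.frame(lag = 1:4)),
      .cat_rows("cwt_coefficients",
                expand.grid(coeff = 0:14, width = c(2, 4, 8, 14, 20))),
      .cat_rows("fft_coefficient",
                expand.grid(attr = c("real", "imag", "abs", "angle"),
                            coeff = 0:15, stringsAsFactors = FALSE)),
      .cat_rows("fft_aggregated",
                data.frame(aggtype = c("centroid", "variance", "skew",
                                       "kurtosis"))),
      .cat_rows("linear_trend",
                data.frame(attr = c("slope", "intercept", "rvalue",
                                    "pvalue", "stderr"))),
      .cat_rows("agg_linear_trend",
                expand.grid(attr = c("slope", "intercept", "rvalue",
                                     "stderr"),
                            f_agg = c("max", "min", "mean", "var"),
                            chunk_len = c(3, 5, 6, 10, 15),
                            stringsAsFactors = FALSE)),
      .cat_rows("max_langevin_fixed_point", data.frame(m = 3, r = 30))
    ))
  } else {
    cq <- expand.grid(f_agg = c("mean", "var"), isabs = c(0, 1),
                      i = 1:2, stringsAsFactors = FALSE)
    qgrid <- data.frame(ql = c(0, 0.6), qh = c(0.4, 1))
    cq <- data.frame(ql = qgrid$ql[cq$i], qh = qgrid$qh[cq$i],
                     isabs = cq$isabs, f_agg = cq$f_agg)
    rows <- c(rows, list(
      .cat_rows("binned_entropy", data.frame(max_bins = 10)),
      .cat_rows("mean_n_absolute_max", data.frame(number_of_maxima = 7)),
      .cat_rows("approximate_entropy", data.frame(m = 2, r = 0.3)),
      .cat_rows("permutation_entropy",
                expand.grid(tau = 1, dimension = c(3, 5))),
      .cat_rows("fourier_entropy", data.frame(bins = 10)),
      .cat_rows("cid_ce", data.frame(normalize = c(0, 1))),
      .cat_rows("number_crossing_m", data.frame(m = 0)),
      .cat_rows("number_peaks", data.frame(n = c(1, 3))),
      .cat_rows("count_above", data.frame(t = 0)),
      .cat_rows("count_below", data.frame(t = 0)),
      .cat_rows("range_count", data.frame(min = -1, max = 1)),
      .cat_rows("quantile", data.frame(q = c(0.1, 0.9))),
      .cat_rows("change_quantiles", cq),
      .cat_rows("autocorrelation", data.frame(lag = c(1, 2, 3, 5))),
      .cat_rows("agg_autocorrelation",
                expand.grid(f_agg = c("mean", "var"), maxlag = 40,
                            stringsAsFactors = FALSE)),
      .cat_rows("c3", data.frame(lag = 1:2)),
      .cat_rows("cwt_coefficients",
                expand.grid(coeff = c(3, 9), width = c(2, 8, 20))),
      .cat_rows("fft_coefficient",
                expand.grid(attr = c("abs", "angle"), coeff = 1:3,
                            stringsAsFactors = FALSE)),
      .cat_rows("fft_aggregated",
                data.frame(aggtype = c("centroid", "variance", "skew",
                                       "kurtosis"))),
      .cat_rows("linear_trend",
                data.frame(attr = c("slope", "intercept", "rvalue",
                                    "pvalue", "stderr"))),
      .cat_rows("agg_linear_trend",
                expand.grid(attr = c("slope", "rvalue"), f_agg = "mean",
                            chunk_len = 10, stringsAsFactors = FALSE)),
      .cat_rows("max_langevin_fixed_point", data.frame(m = 3, r = 30))
    ))
  }
  out <- dplyr::bind_rows(rows)
  if (any(out$feature_type == "change_quantiles")) {
    bad <- out$feature_type == "change_quantiles" & out$p1 >= out$p2
    if (any(bad)) stop("change_quantiles requires ql < qh")
  }
  if (anyDuplicated(out$name)) stop("catalogue names are not unique")
  out
}
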