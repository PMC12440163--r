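# Permutation feature importance with normal-approximation confidence
# intervals, aggregated to keypoint channels and top-k rankings.

#' Permutation feature importance
#'
#' For each feature column: repeat `n_repeats` times, permute that column,
#' rescore the model, and report `importance = baseline accuracy - mean
#' permuted accuracy` with a 95% normal-approximation CI over repeats.
#' Positive importance means performance dropped when the feature was
#' permuted (the feature is used by the model); negative means performance
#' increased; zero means no effect.
#'
#' @param model A fitted classifier from the evaluation pipeline (internal
#'   `gait_model`), or anything accepted by `predict_fun`.
#' @param x Feature matrix scored against (held-out data).
#' @param y True labels.
#' @param n_repeats Permutations per feature.
#' @param seed Integer seed.
#' @param predict_fun Function `(model, x) -> predicted labels`; defaults to
#'   the package's classifier surface.
#' @return Tibble: `feature`, `importance`, `ci_lo`, `ci_hi`, `n_repeats`.
#' @export
permutation_importance <- function(model, x, y, n_repeats = 10, seed = 1L,
                                   predict_fun = NULL) {
  x <- as.matrix(x)
  if (is.null(predict_fun)) {
    if (!inherits(model, "gait_model")) stop("model is not a fitted classifier")
    predict_fun <- function(m, xx) {
      p <- .predict_proba(m, xx)
      m$classes[max.col(p, ties.method = "first")]
    }
  }
  baseline <- mean(predict_fun(model, x) == y)
  n <- nrow(x)
  res <- vector("list", ncol(x))
  .with_seed(.hash_seed(seed, 523), {
    for (j in seq_len(ncol(x))) {
      drops <- vapply(seq_len(n_repeats), function(r) {
        xp <- x
        xp[, j] <- xp[sample.int(n), j]
        baseline - mean(predict_fun(model, xp) == y)
      }, numeric(1))
      se <- stats::sd(drops) / sqrt(n_repeats)
      res[[j]] <- tibble::tibble(
        feature = colnames(x)[j], importance = mean(drops),
        ci_lo = mean(drops) - 1.96 * se, ci_hi = mean(drops) + 1.96 * se,
        n_repeats = n_repeats)
    }
  })
  dplyr::bind_rows(res)
}

#' Permutation importance of a cross-validated pipeline
#'
#' Computes permutation importance on each outer fold's held-out subject
#' (using the fold's fitted model and selected features) and averages the
#' per-feature importances across folds. Features never selected in a fold
#' contribute importance 0 there.
#'
#' @param cv A [nested_loso_evaluate()] result run with
#'   `keep_models = TRUE`.
#' @param n_repeats Permutations per feature per fold.
#' @param seed Integer seed.
#' @param folds Number of outer folds to average over (defaults to all);
#'   fewer folds trade stability for runtime.
#' @return Tibble as in [permutation_importance()].
#' @export
cv_permutation_importance <- function(cv, n_repeats = 5, seed = 1L,
                                      folds = NULL) {
  stopifnot(inherits(cv, "gait_cv"))
  if (is.null(cv$fold_models)) {
    stop("run nested_loso_evaluate() with keep_models = TRUE")
  }
  use <- seq_along(cv$fold_models)
  if (!is.null(folds)) use <- use[seq_len(min(folds, length(use)))]
  per_fold <- lapply(use, function(i) {
    fm <- cv$fold_models[[i]]
    imp <- permutation_importance(fm$model, fm$x_test, fm$y_test,
                                  n_repeats = n_repeats,
                                  seed = .hash_seed(seed, i))
    imp$fold <- names(cv$fold_models)[i]
    imp
  })
  # features outside a fold's selected set (or never selected) have
  # importance exactly 0
  dplyr::bind_rows(per_fold) |>
    tidyr::complete(feature = cv$feature_names,
                    fold = names(cv$fold_models)[use],
                    fill = list(importance = 0, ci_lo = 0, ci_hi = 0,
                                n_repeats = n_repeats)) |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(
      importance = mean(.data$importance),
      ci_lo = mean(.data$ci_lo), ci_hi = mean(.data$ci_hi),
      n_repeats = dplyr::first(.data$n_repeats), .groups = "drop")
}

#' Aggregate feature importances to keypoint channels
#'
#' Sums signed importances of all features belonging to each keypoint
#' channel (`<landmark>_<axis>` prefix of the canonical feature name).
#'
#' @param records Importance tibble with `feature` and `importance`.
#' @return Tibble: `channel`, `landmark_name`, `axis`, `group` (anatomical
#'   group), `importance`, sorted by decreasing importance.
#' @export
keypoint_importance <- function(records) {
  parsed <- parse_feature_names(records$feature)
  dplyr::bind_cols(records["importance"], parsed) |>
    dplyr::group_by(.data$channel, .data$landmark_name, .data$axis) |>
    dplyr::summarise(importance = sum(.data$importance),
                     .groups = "drop") |>
    dplyr::mutate(group = landmark_group(.data$landmark_name)) |>
    dplyr::arrange(dplyr::desc(.data$importance), .data$channel)
}

#' Top-k channel x feature-type importance table
#'
#' Ranks keypoint channels and feature types by cumulative permutation
#' importance and returns the cross table of summed importances for the top
#' `k` of each (the structure usually rendered as a heatmap). Ties are
#' broken by name.
#'
#' @param records Importance tibble with `feature` and `importance`.
#' @param k Number of channels / feature types to keep.
#' @return Tibble: `channel`, `feature_type`, `importance`, with channels
#'   and feature types as ordered factors (rank order).
#' @export
top_k_heatmap_table <- function(records, k = 20) {
  stopifnot(k >= 1)
  parsed <- parse_feature_names(records$feature)
  long <- dplyr::bind_cols(records["importance"], parsed) |>
    dplyr::group_by(.data$channel, .data$feature_type) |>
    dplyr::summarise(importance = sum(.data$importance), .groups = "drop")
  rank_of <- function(tbl, col) {
    tbl |>
      dplyr::group_by(.data[[col]]) |>
      dplyr::summarise(total = sum(.data$importance), .groups = "drop") |>
      dplyr::arrange(dplyr::desc(.data$total), .data[[col]]) |>
      dplyr::slice_head(n = k)
  }
  chs <- rank_of(long, "channel")
  fts <- rank_of(long, "feature_type")
  out <- long |>
    dplyr::filter(.data$channel %in% chs$channel,
                  .data$feature_type %in% fts$feature_type) |>
    dplyr::mutate(
      channel = factor(.data$channel, levels = chs$channel),
      feature_type = factor(.data$feature_type, levels = fts$feature_type))
  dplyr::arrange(out, .data$channel, .data$feature_type)
}
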