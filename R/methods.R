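# broom-style accessors and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a cross-validation result
#'
#' @param x A `gait_cv` object.
#' @param ... Unused.
#' @return Long tibble: `trial`, `fold`, `level`, `metric`, `value`.
#' @export
tidy.gait_cv <- function(x, ...) {
  dplyr::relocate(x$scores, "trial", "fold", "level", "metric", "value")
}

#' One-row summary of a cross-validation result
#'
#' @param x A `gait_cv` object.
#' @param ... Unused.
#' @return One-row tibble with the fused/video/window accuracies (and CI
#'   half-widths), model family, view, trial and subject counts.
#' @export
glance.gait_cv <- function(x, ...) {
  s <- x$summary[x$summary$metric == "accuracy", ]
  g <- function(lv, col) {
    v <- s[s$level == lv, ][[col]]
    if (length(v)) v else NA_real_
  }
  tibble::tibble(
    family = x$family, view = x$view,
    n_subjects = x$n_subjects, trials = x$trials,
    window_accuracy = g("window", "mean"),
    video_accuracy = g("video", "mean"),
    fused_accuracy = g("fused", "mean"),
    fused_ci_halfwidth = 1.96 * g("fused", "se")
  )
}

#' Plot cross-validated accuracies with confidence intervals
#'
#' @param object A `gait_cv` object.
#' @param metric Metric to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gait_cv <- function(object, metric = "accuracy", ...) {
  s <- object$summary[object$summary$metric == metric, ]
  ggplot2::ggplot(s, ggplot2::aes(x = .data$level, y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo,
                                        ymax = .data$ci_hi), width = 0.2) +
    ggplot2::geom_hline(yintercept = 1 / 7, linetype = "dashed") +
    ggplot2::labs(x = "aggregation level", y = metric,
                  title = sprintf("%s, %s view(s): %s with 95%% CI",
                                  object$family, object$view, metric)) +
    ggplot2::ylim(0, 1)
}

#' Tidy a feature-selection result
#'
#' @param x A `fresh_selection` object.
#' @param ... Unused.
#' @return Tibble `feature`, `class`, `p`, `selected`.
#' @export
tidy.fresh_selection <- function(x, ...) x$pvalues

#' One-row summary of a feature-selection result
#'
#' @param x A `fresh_selection` object.
#' @param ... Unused.
#' @return One-row tibble: candidate/selected feature counts, surviving
#'   feature-type count, FDR level.
#' @export
glance.fresh_selection <- function(x, ...) {
  tibble::tibble(n_candidates = x$n_candidates,
                 n_selected = length(x$selected),
                 n_feature_types = nrow(x$survivors_by_type),
                 q = x$q)
}

#' Heatmap of top-k channel x feature-type permutation importances
#'
#' @param records Importance tibble (`feature`, `importance`).
#' @param k Channels / feature types to keep.
#' @return A ggplot object.
#' @export
plot_importance_heatmap <- function(records, k = 20) {
  tab <- top_k_heatmap_table(records, k)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$channel,
                                    y = .data$feature_type,
                                    fill = .data$importance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "red") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1)) +
    ggplot2::labs(x = "keypoint channel", y = "feature type",
                  fill = "importance")
}

#' Plot keypoint-channel importances
#'
#' @param records Importance tibble (`feature`, `importance`).
#' @param k Number of channels shown.
#' @return A ggplot object.
#' @export
plot_keypoint_importance <- function(records, k = 20) {
  kp <- keypoint_importance(records) |> dplyr::slice_head(n = k)
  kp$channel <- factor(kp$channel, levels = rev(kp$channel))
  ggplot2::ggplot(kp, ggplot2::aes(x = .data$importance, y = .data$channel,
                                   fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "summed permutation importance", y = NULL,
                  fill = "anatomical group")
}
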