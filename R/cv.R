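# User-independent nested leave-one-subject-out evaluation.
#
# Outer loop: every subject is held out once. Per fold: relevance selection
# (BY FDR) and SMOTE balancing are fitted on the outer-training windows
# only, hyperparameters are tuned by seeded random search in a
# subject-grouped inner cross-validation, and the tuned model predicts the
# held-out subject's windows. Window labels are aggregated to video labels
# by majority vote and to fused multi-view labels by pooling both views'
# window labels. Trials rerun the scheme under different seeds (inner fold
# assignment, sampler, SMOTE); outer LOSO folds are deterministic.

#' Multiclass classification metrics
#'
#' Accuracy plus weighted-average precision, recall and F1 (per-class
#' metrics weighted by true-class support; undefined per-class values count
#' as 0), with the confusion matrix (rows = true classes).
#'
#' @param true,predicted Equal-length label vectors.
#' @return List with `accuracy`, `precision`, `recall`, `f1`, `confusion`.
#' @export
compute_metrics <- function(true, predicted) {
  if (length(true) == 0) stop("empty input")
  if (length(true) != length(predicted)) stop("length mismatch")
  cls <- sort(unique(c(true, predicted)))
  cm <- table(factor(true, levels = cls), factor(predicted, levels = cls))
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  w <- rowSums(cm) / sum(cm)
  list(accuracy = sum(tp) / sum(cm),
       precision = sum(w * prec), recall = sum(w * rec), f1 = sum(w * f1),
       confusion = cm)
}

#' Per-class one-vs-rest report
#'
#' @inheritParams compute_metrics
#' @return Tibble with `class`, `precision`, `recall`, `f1`, `support`.
#'   A class never predicted gets precision 0 (flagged by `support`).
#' @export
per_class_report <- function(true, predicted) {
  if (length(true) == 0) stop("empty input")
  cls <- sort(unique(c(true, predicted)))
  cm <- table(factor(true, levels = cls), factor(predicted, levels = cls))
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  tibble::tibble(class = cls, precision = unname(prec),
                 recall = unname(rec), f1 = unname(f1),
                 support = unname(rowSums(cm)))
}

# majority vote over window labels with deterministic tie-breaking:
# highest vote count, then highest mean class score, then lexicographic
.vote <- function(labels, scores = NULL) {
  tab <- table(labels)
  top <- names(tab)[tab == max(tab)]
  if (length(top) == 1) return(top)
  if (!is.null(scores)) {
    ms <- colMeans(scores[, top, drop = FALSE])
    top <- top[ms == max(ms)]
  }
  sort(top)[1]
}

#' Video-level majority vote
#'
#' @param labels Window-level predicted labels of one video.
#' @param scores Optional window x class score matrix for tie-breaking.
#' @return The video label (modal window label; ties broken by highest mean
#'   class score, then lexicographic class code).
#' @export
video_majority_vote <- function(labels, scores = NULL) {
  if (length(labels) == 0) stop("no windows to vote over")
  .vote(labels, scores)
}

#' Fused multi-view vote
#'
#' Pools the window-level labels of the frontal and sagittal videos of one
#' subject x class x direction and applies the same majority vote (a view
#' contributing more windows carries proportionally more weight). A missing
#' view degrades to the single-view vote.
#'
#' @param labels_frontal,labels_sagittal Window labels per view (either may
#'   be empty).
#' @param scores_frontal,scores_sagittal Optional score matrices.
#' @return The fused label.
#' @export
fuse_views_vote <- function(labels_frontal, labels_sagittal,
                            scores_frontal = NULL, scores_sagittal = NULL) {
  labels <- c(labels_frontal, labels_sagittal)
  if (length(labels) == 0) stop("no windows to vote over")
  scores <- NULL
  if (!is.null(scores_frontal) || !is.null(scores_sagittal)) {
    scores <- rbind(scores_frontal, scores_sagittal)
  }
  .vote(labels, scores)
}

#' Tune hyperparameters by subject-grouped random search
#'
#' Seeded random search over the model's hyperparameter space; candidates
#' are scored by mean validation accuracy in a user-independent k-fold split
#' of the training subjects (5 folds, falling back to 3 with a warning when
#' fewer than 5 subjects are available). Folds split by subject, never by
#' window. Ties are broken by sampling order. With a budget of 1 the single
#' sampled configuration is returned without evaluation.
#'
#' @param x,y Training windows and labels.
#' @param groups Subject id per row.
#' @param spec A [model_spec()].
#' @param seed Integer seed (sampler and fold assignment).
#' @return List: `hp` (winning configuration), `scores` (per-candidate mean
#'   validation accuracy, `NA` when not evaluated).
#' @export
inner_tune <- function(x, y, groups, spec, seed = 1L) {
  x <- as.matrix(x)
  cand <- .sample_hparams(spec, spec$budget, seed)
  if (spec$budget == 1) {
    return(list(hp = cand[[1]], scores = NA_real_))
  }
  subj <- unique(groups)
  k <- if (length(subj) >= 5) 5 else {
    warning("fewer than 5 training subjects; using 3-fold inner CV")
    3
  }
  fold_of <- .with_seed(.hash_seed(seed, 331), {
    stats::setNames(rep_len(sample(k), length(subj)), sample(subj))
  })
  scores <- vapply(seq_along(cand), function(ci) {
    acc <- vapply(seq_len(k), function(fi) {
      val <- groups %in% names(fold_of)[fold_of == fi]
      if (!any(val) || length(unique(y[!val])) < 2) return(NA_real_)
      pred <- fit_predict_windows(spec$family, cand[[ci]],
                                  x[!val, , drop = FALSE], y[!val],
                                  x[val, , drop = FALSE],
                                  seed = .hash_seed(seed, ci, fi))
      mean(pred$label == y[val])
    }, numeric(1))
    mean(acc, na.rm = TRUE)
  }, numeric(1))
  best <- which.max(scores)   # first index on ties
  list(hp = cand[[best]], scores = scores)
}

.metric_row <- function(true, pred, level) {
  m <- compute_metrics(true, pred)
  tibble::tibble(level = level,
                 metric = c("accuracy", "precision", "recall", "f1"),
                 value = c(m$accuracy, m$precision, m$recall, m$f1))
}

#' Nested leave-one-subject-out evaluation
#'
#' @param features Feature tibble from [compute_feature_matrix()] with
#'   metadata columns `window_id`, `video_id`, `subject_id`, `view`,
#'   `direction`, `label`.
#' @param spec A [model_spec()].
#' @param view `"combined"` (both views, fused predictions), `"frontal"` or
#'   `"sagittal"`.
#' @param trials Number of repeated nested-CV trials (different seeds for
#'   inner folds, sampler and SMOTE; outer folds are fixed).
#' @param q FDR level of the per-fold feature selection.
#' @param smote_k SMOTE neighbour count.
#' @param seed Integer seed.
#' @param keep_models Keep each fold's fitted model and test-window features
#'   (needed for permutation importance downstream).
#' @return Object of class `gait_cv`: list with `scores` (tibble: trial,
#'   fold, level, metric, value), `summary` (mean +/- 1.96 SE per
#'   level/metric), `confusion` (pooled per level), `chosen_hp`,
#'   `predictions` (window-level), `selection_sizes`, and (optionally)
#'   `fold_models`.
#' @export
nested_loso_evaluate <- function(features, spec = model_spec("xgboost"),
                                 view = c("combined", "frontal", "sagittal"),
                                 trials = 10, q = 0.05, smote_k = 5,
                                 seed = 1L, keep_models = FALSE) {
  view <- match.arg(view)
  stopifnot(inherits(spec, "model_spec"))
  feats <- tibble::as_tibble(features)
  if (view != "combined") feats <- feats[feats$view == view, ]
  need <- c("window_id", "video_id", "subject_id", "view", "direction",
            "label")
  if (!all(need %in% names(feats))) stop("missing metadata columns")
  subjects <- sort(unique(feats$subject_id))
  if (length(subjects) < 6) stop("nested LOSO needs >= 6 subjects")
  fc <- .feature_cols(feats)
  xall <- as.matrix(as.data.frame(feats)[, fc, drop = FALSE])

  scores <- list(); preds <- list(); vpreds <- list(); fpreds <- list()
  hps <- list(); selsz <- list()
  fold_models <- list()
  cms <- list(window = NULL, video = NULL, fused = NULL)
  for (tr in seq_len(trials)) {
    for (si in seq_along(subjects)) {
      s <- subjects[si]
      tr_seed <- .hash_seed(seed, 7907, tr, si)
      is_test <- feats$subject_id == s
      stopifnot(!any(feats$subject_id[!is_test] == s))  # subject guard
      ytr <- feats$label[!is_test]
      sel <- suppressWarnings(
        fresh_select(xall[!is_test, , drop = FALSE], y = ytr, q = q))
      keep <- sel$selected
      bal <- smote_oversample(xall[!is_test, keep, drop = FALSE], ytr,
                              k = smote_k, seed = tr_seed,
                              groups = feats$subject_id[!is_test])
      tuned <- inner_tune(bal$x, bal$y, bal$groups, spec, seed = tr_seed)
      model <- .fit_model(spec$family, tuned$hp, as.matrix(bal$x), bal$y,
                          seed = tr_seed)
      xte <- xall[is_test, keep, drop = FALSE]
      p <- .predict_proba(model, xte)
      wlab <- model$classes[max.col(p, ties.method = "first")]
      te <- feats[is_test, need]
      te$pred <- wlab
      te$trial <- tr

      # video-level votes
      vid <- dplyr::distinct(te, .data$video_id, .data$subject_id,
                             .data$view, .data$direction, .data$label)
      vid$pred <- vapply(seq_len(nrow(vid)), function(i) {
        rows <- te$video_id == vid$video_id[i]
        .vote(te$pred[rows], p[rows, , drop = FALSE])
      }, character(1))

      # fused multi-view votes per class x direction
      fus <- te |>
        dplyr::group_by(.data$subject_id, .data$label, .data$direction) |>
        dplyr::summarise(.groups = "drop")
      fus$pred <- vapply(seq_len(nrow(fus)), function(i) {
        rows <- te$label == fus$label[i] & te$direction == fus$direction[i]
        .vote(te$pred[rows], p[rows, , drop = FALSE])
      }, character(1))

      fold_scores <- dplyr::bind_rows(
        .metric_row(te$label, te$pred, "window"),
        .metric_row(vid$label, vid$pred, "video"),
        .metric_row(fus$label, fus$pred, "fused")
      )
      fold_scores$trial <- tr
      fold_scores$fold <- s
      scores[[length(scores) + 1]] <- fold_scores
      preds[[length(preds) + 1]] <- te
      vid$trial <- tr
      fus$trial <- tr
      vpreds[[length(vpreds) + 1]] <- vid
      fpreds[[length(fpreds) + 1]] <- fus
      hps[[length(hps) + 1]] <- tibble::tibble(
        trial = tr, fold = s,
        hp = list(tuned$hp))
      selsz[[length(selsz) + 1]] <- tibble::tibble(
        trial = tr, fold = s, n_selected = length(keep),
        n_types = nrow(sel$survivors_by_type))
      for (lv in c("window", "video", "fused")) {
        tt <- switch(lv, window = te, video = vid, fused = fus)
        cm <- table(factor(tt$label, levels = gait_classes),
                    factor(tt$pred, levels = gait_classes))
        cms[[lv]] <- if (is.null(cms[[lv]])) cm else cms[[lv]] + cm
      }
      if (keep_models && tr == 1) {
        fold_models[[s]] <- list(model = model, x_test = xte,
                                 y_test = te$label, meta = te)
      }
    }
  }
  scores <- dplyr::bind_rows(scores)
  summary <- scores |>
    dplyr::group_by(.data$level, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value),
      se = stats::sd(.data$value) / sqrt(dplyr::n()),
      ci_lo = .data$mean - 1.96 * .data$se,
      ci_hi = .data$mean + 1.96 * .data$se,
      n_scores = dplyr::n(), .groups = "drop")
  structure(list(
    scores = scores, summary = summary, confusion = cms,
    chosen_hp = dplyr::bind_rows(hps),
    predictions = dplyr::bind_rows(preds),
    video_predictions = dplyr::bind_rows(vpreds),
    fused_predictions = dplyr::bind_rows(fpreds),
    selection_sizes = dplyr::bind_rows(selsz),
    fold_models = if (keep_models) fold_models else NULL,
    feature_names = fc,
    view = view, family = spec$family, trials = trials,
    n_subjects = length(subjects), seed = seed
  ), class = "gait_cv")
}

#' Video-level accuracy split by camera view
#'
#' Computes, from a (typically combined-view) cross-validation result, the
#' video-level accuracy restricted to each camera view — the single-view
#' performance that fused multi-view voting is compared against.
#'
#' @param cv A `gait_cv` object.
#' @return Tibble: `view`, `accuracy`, `n_videos` (pooled over trials).
#' @export
video_accuracy_by_view <- function(cv) {
  stopifnot(inherits(cv, "gait_cv"))
  cv$video_predictions |>
    dplyr::group_by(.data$view) |>
    dplyr::summarise(accuracy = mean(.data$pred == .data$label),
                     n_videos = dplyr::n(), .groups = "drop")
}

#' @export
print.gait_cv <- function(x, ...) {
  cat("<gait_cv> ", x$family, "model,", x$view, "view(s),",
      x$n_subjects, "subjects x", x$trials, "trial(s)\n")
  s <- x$summary[x$summary$metric == "accuracy", ]
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-6s accuracy %.3f (95%% CI %.3f-%.3f)\n",
                s$level[i], s$mean[i], s$ci_lo[i], s$ci_hi[i]))
  }
  invisible(x)
}
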