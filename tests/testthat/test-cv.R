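# Metrics, votes, tuning, and the nested LOSO driver (on a fast synthetic
# feature table).

test_that("multiclass metrics match hand computation", {
  m <- compute_metrics(c("a", "a", "b", "b"), c("a", "a", "a", "b"))
  # confusion [[2,0],[1,1]]: class-a precision 2/3, recall 1, F1 0.8
  expect_equal(m$confusion["a", "a"], 2)
  expect_equal(m$accuracy, 3 / 4)
  expect_equal(sum(diag(m$confusion)) / sum(m$confusion), m$accuracy)
  pc <- per_class_report(c("a", "a", "b", "b"), c("a", "a", "a", "b"))
  expect_equal(pc$precision[pc$class == "a"], 2 / 3)
  expect_equal(pc$recall[pc$class == "a"], 1)
  expect_equal(pc$f1[pc$class == "a"], 0.8)
  # weighted average consistency
  expect_equal(m$f1, sum(pc$f1 * pc$support / sum(pc$support)))
  # perfect predictions
  mp <- compute_metrics(c("x", "y"), c("x", "y"))
  expect_true(all(unlist(mp[c("accuracy", "precision", "recall", "f1")]) == 1))
  expect_error(compute_metrics(character(0), character(0)), "empty")
  expect_error(compute_metrics("a", c("a", "b")), "mismatch")
})

test_that("per-class report equals direct binary one-vs-rest reduction", {
  set.seed(1)
  true <- sample(c("A", "B", "C"), 60, replace = TRUE)
  pred <- sample(c("A", "B", "C"), 60, replace = TRUE)
  pc <- per_class_report(true, pred)
  for (cl in c("A", "B", "C")) {
    tp <- sum(true == cl & pred == cl)
    fp <- sum(true != cl & pred == cl)
    fn <- sum(true == cl & pred != cl)
    expect_equal(pc$precision[pc$class == cl],
                 if (tp + fp > 0) tp / (tp + fp) else 0)
    expect_equal(pc$recall[pc$class == cl], tp / (tp + fn))
  }
  # class absent from predictions: precision 0 by convention
  pc0 <- per_class_report(c("A", "B"), c("A", "A"))
  expect_equal(pc0$precision[pc0$class == "B"], 0)
})

test_that("majority votes and tie rules are deterministic", {
  expect_equal(video_majority_vote(c("CIR", "CIR", "NOR")), "CIR")
  expect_equal(video_majority_vote("PAR"), "PAR")
  sc <- matrix(c(0.6, 0.4, 0.4, 0.6), 2, 2,
               dimnames = list(NULL, c("CIR", "NOR")))
  expect_equal(video_majority_vote(c("CIR", "NOR"), sc[c(1, 1), ]), "CIR")
  # lexicographic fallback without scores
  expect_equal(video_majority_vote(c("NOR", "CIR")), "CIR")
  expect_error(video_majority_vote(character(0)), "no windows")
})

test_that("fused votes pool windows across views; missing view degrades", {
  expect_equal(fuse_views_vote(c("CIR", "CIR"), c("CIR")), "CIR")
  expect_equal(fuse_views_vote(c("NOR", "NOR"), c("PAR", "PAR", "PAR")),
               "PAR")                               # pooled 3-2
  expect_equal(fuse_views_vote(c("TRE", "TRE", "NOR"), character(0)),
               video_majority_vote(c("TRE", "TRE", "NOR")))
})

test_that("inner tuning is seeded, grouped, and tie-broken by draw order", {
  toy <- toy_feature_set(n_subjects = 6, n_windows = 4, effect = 5,
                         views = "sagittal")
  fc <- setdiff(names(toy), c("window_id", "video_id", "subject_id", "view",
                              "direction", "label", "start_frame"))
  x <- as.matrix(as.data.frame(toy)[, fc])
  spec <- model_spec("random_forest", budget = 3)
  t1 <- inner_tune(x, toy$label, toy$subject_id, spec, seed = 11)
  t2 <- inner_tune(x, toy$label, toy$subject_id, spec, seed = 11)
  expect_identical(t1, t2)
  expect_equal(length(t1$scores), 3)
  # easily separable: every candidate near-perfect, winner = first best
  expect_equal(which.max(t1$scores),
               which(t1$scores == max(t1$scores))[1])
  # budget 1 returns the single sampled configuration without evaluation
  b1 <- inner_tune(x, toy$label, toy$subject_id,
                   model_spec("random_forest", budget = 1), seed = 11)
  expect_identical(b1$hp, gaitwise:::.sample_hparams(
    model_spec("random_forest", budget = 1), 1, 11)[[1]])
  # < 5 subjects: 3-fold fallback with warning
  small <- toy$subject_id %in% c("S01", "S02", "S03", "S04")
  expect_warning(
    inner_tune(x[small, ], toy$label[small], toy$subject_id[small],
               model_spec("random_forest", budget = 2), seed = 1),
    "3-fold")
})

test_that("fit_predict_windows memorises separable data and checks columns", {
  toy <- toy_feature_set(n_subjects = 6, n_windows = 2, effect = 6,
                         views = "sagittal")
  fc <- setdiff(names(toy), c("window_id", "video_id", "subject_id", "view",
                              "direction", "label", "start_frame"))
  x <- as.matrix(as.data.frame(toy)[, fc])
  hp <- list(n_estimators = 100, max_depth = 10, min_samples_split = 2,
             min_samples_leaf = 1, max_features = 0.5)
  pred <- fit_predict_windows("random_forest", hp, x, toy$label, x)
  expect_gt(mean(pred$label == toy$label), 0.95)
  probs <- as.matrix(pred[, gait_classes])
  expect_equal(rowSums(probs), rep(1, nrow(probs)), tolerance = 1e-9)
  x2 <- x[, rev(seq_len(ncol(x)))]
  expect_error(fit_predict_windows("random_forest", hp, x, toy$label, x2),
               "do not match")
})

test_that("nested LOSO: structure, determinism, subject independence", {
  toy <- toy_feature_set(n_subjects = 6, n_windows = 3, effect = 3, seed = 2)
  spec <- model_spec("random_forest", budget = 1)
  cv <- nested_loso_evaluate(toy, spec, view = "combined", trials = 2,
                             seed = 5)
  expect_equal(sort(unique(cv$scores$fold)), sprintf("S%02d", 1:6))
  expect_equal(nrow(cv$scores), 2 * 6 * 3 * 4)   # trials x folds x lvl x mtr
  # no test subject's windows reach training: predictions cover each subject
  # exactly once per trial
  tab <- table(cv$predictions$subject_id, cv$predictions$trial)
  expect_true(all(tab == nrow(toy) / 6))
  cv2 <- nested_loso_evaluate(toy, spec, view = "combined", trials = 2,
                              seed = 5)
  expect_equal(cv$scores, cv2$scores)
  expect_error(nested_loso_evaluate(toy[toy$subject_id %in%
                                          sprintf("S%02d", 1:5), ], spec),
               ">= 6 subjects")
  # voting denoises: video accuracy >= window accuracy (sampling slack)
  acc <- function(lv) mean(cv$scores$value[cv$scores$level == lv &
                                             cv$scores$metric == "accuracy"])
  expect_gte(acc("video"), acc("window") - 0.05)
  expect_gte(acc("fused"), acc("video") - 0.05)
  g <- glance(cv)
  expect_equal(g$trials, 2)
  expect_true(is.finite(g$fused_accuracy))
  td <- tidy(cv)
  expect_named(td, c("trial", "fold", "level", "metric", "value"))
})

test_that("confidence intervals tighten roughly as 1/sqrt(trials)", {
  toy <- toy_feature_set(n_subjects = 6, n_windows = 2, effect = 1.2,
                         seed = 3, views = "sagittal")
  spec <- model_spec("random_forest", budget = 1)
  w2 <- glance(nested_loso_evaluate(toy, spec, view = "sagittal",
                                    trials = 2, seed = 1))$fused_ci_halfwidth
  w10 <- glance(nested_loso_evaluate(toy, spec, view = "sagittal",
                                     trials = 10, seed = 1))$fused_ci_halfwidth
  expect_lt(w10, w2)
  expect_lt(w10 / w2, 0.9)      # expected ~ sqrt(2/10) = 0.45, with noise
})

test_that("label permutation drives video accuracy to chance", {
  set.seed(9)
  toy <- toy_feature_set(n_subjects = 6, n_windows = 3, effect = 3, seed = 4)
  # permute the class labels within each subject, consistently across
  # views/directions/windows (preserves structure, breaks the signal)
  for (s in unique(toy$subject_id)) {
    perm <- setNames(sample(gait_classes), gait_classes)
    rows <- toy$subject_id == s
    toy$label[rows] <- perm[toy$label[rows]]
  }
  cv <- nested_loso_evaluate(toy, model_spec("random_forest", budget = 1),
                             view = "combined", trials = 1, seed = 2)
  s <- cv$summary[cv$summary$level == "video" &
                    cv$summary$metric == "accuracy", ]
  # CI covers chance (1/7) within 3 SE
  expect_lt(abs(s$mean - 1 / 7), 3 * s$se + 0.05)
})
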