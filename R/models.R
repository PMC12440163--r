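# Classifier families and their hyperparameter spaces.
#
# Three families mirror common practice in pose-based gait classification:
# kernel SVM, random forest, and gradient-boosted trees. Hyperparameter
# names follow the conventional tuning surface of each family; numeric
# ranges are pinned here. Tuning is by seeded random search.

.default_space <- function(family) {
  switch(family,
    svm = list(
      C = list(type = "logunif", lo = 1e-1, hi = 1e2),
      gamma = list(type = "logunif", lo = 1e-4, hi = 1),
      kernel = list(type = "choice", values = c("linear", "rbf"))
    ),
    random_forest = list(
      n_estimators = list(type = "int", lo = 100, hi = 300),
      max_depth = list(type = "int", lo = 4, hi = 16),
      min_samples_split = list(type = "int", lo = 2, hi = 10),
      min_samples_leaf = list(type = "int", lo = 1, hi = 5),
      max_features = list(type = "unif", lo = 0.05, hi = 0.5)
    ),
    xgboost = list(
      max_depth = list(type = "int", lo = 2, hi = 5),
      learning_rate = list(type = "logunif", lo = 0.1, hi = 0.4),
      n_estimators = list(type = "int", lo = 30, hi = 80),
      min_child_weight = list(type = "int", lo = 1, hi = 8),
      subsample = list(type = "unif", lo = 0.6, hi = 1),
      # feature matrices here are wide (thousands of columns); strong
      # per-tree column subsampling keeps trees decorrelated and fast
      colsample_bytree = list(type = "unif", lo = 0.1, hi = 0.5)
    ),
    stop("unknown model family: ", family)
  )
}

#' Classifier specification
#'
#' @param family `"xgboost"` (gradient-boosted trees), `"random_forest"` or
#'   `"svm"`.
#' @param budget Number of random-search draws in the inner tuning loop.
#' @param space Hyperparameter space; defaults to the pinned space of the
#'   family. Each entry is `list(type, lo, hi)` or `list(type = "choice",
#'   values)`.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(family = c("xgboost", "random_forest", "svm"),
                       budget = 25, space = NULL) {
  family <- match.arg(family)
  if (budget < 1) stop("budget must be >= 1")
  space <- space %||% .default_space(family)
  for (nm in names(space)) {
    sp <- space[[nm]]
    if (sp$type != "choice" &&
        (!is.finite(sp$lo) || !is.finite(sp$hi) || sp$lo > sp$hi)) {
      stop("hyperparameter bounds must be finite and ordered: ", nm)
    }
  }
  structure(list(family = family, budget = as.integer(budget),
                 space = space), class = "model_spec")
}

# seeded random draws from the space; returns a list of named configs
.sample_hparams <- function(spec, n, seed) {
  .with_seed(.hash_seed(seed, 9973), {
    lapply(seq_len(n), function(i) {
      cfg <- lapply(spec$space, function(sp) {
        switch(sp$type,
          unif = stats::runif(1, sp$lo, sp$hi),
          logunif = exp(stats::runif(1, log(sp$lo), log(sp$hi))),
          int = sample(seq(sp$lo, sp$hi), 1),
          choice = sp$values[[sample.int(length(sp$values), 1)]]
        )
      })
      cfg
    })
  })
}

# fit one model; x matrix, y character labels. Returns a classifier object
# with a uniform predict surface.
.fit_model <- function(family, hp, x, y, seed = 1L) {
  classes <- sort(unique(y))
  yf <- factor(y, levels = classes)
  fit <- switch(family,
    svm = .with_seed(.hash_seed(seed, 11), {
      e1071::svm(x = x, y = yf,
                 kernel = if (hp$kernel == "rbf") "radial" else "linear",
                 cost = hp$C, gamma = hp$gamma, probability = TRUE,
                 scale = FALSE)
    }),
    random_forest = ranger::ranger(
      x = as.data.frame(x), y = yf,
      num.trees = hp$n_estimators, max.depth = hp$max_depth,
      min.node.size = max(hp$min_samples_leaf,
                          ceiling(hp$min_samples_split / 2)),
      mtry = max(1, floor(hp$max_features * ncol(x))),
      probability = TRUE, num.threads = 1,
      seed = .hash_seed(seed, 13)),
    xgboost = {
      dtrain <- xgboost::xgb.DMatrix(data = x,
                                     label = as.integer(yf) - 1L)
      xgboost::xgb.train(
        params = list(objective = "multi:softprob",
                      num_class = length(classes),
                      max_depth = hp$max_depth, eta = hp$learning_rate,
                      min_child_weight = hp$min_child_weight,
                      subsample = hp$subsample,
                      colsample_bytree = hp$colsample_bytree,
                      tree_method = "hist", max_bin = 64, nthread = 1,
                      seed = .hash_seed(seed, 17)),
        data = dtrain, nrounds = hp$n_estimators, verbose = 0)
    }
  )
  structure(list(family = family, fit = fit, classes = classes,
                 features = colnames(x)), class = "gait_model")
}

# class-probability matrix (rows = samples, columns = model classes)
.predict_proba <- function(model, x) {
  if (!is.null(model$features) &&
      !identical(colnames(x), model$features)) {
    stop("feature columns of test data do not match the fitted model")
  }
  p <- switch(model$family,
    svm = {
      pr <- stats::predict(model$fit, x, probability = TRUE)
      attr(pr, "probabilities")[, model$classes, drop = FALSE]
    },
    random_forest = {
      stats::predict(model$fit, data = as.data.frame(x),
                     num.threads = 1)$predictions[, model$classes,
                                                  drop = FALSE]
    },
    xgboost = {
      pr <- stats::predict(model$fit, xgboost::xgb.DMatrix(data = x))
      if (!is.matrix(pr)) {
        pr <- matrix(pr, ncol = length(model$classes), byrow = TRUE)
      }
      dimnames(pr) <- list(NULL, model$classes)
      pr
    }
  )
  p
}

#' Fit a window-level classifier and predict held-out windows
#'
#' @param family Model family (see [model_spec()]).
#' @param hp Named list of hyperparameters.
#' @param x_train,y_train Training windows (matrix, labels).
#' @param x_test Test windows; must have exactly the training columns.
#' @param seed Integer seed.
#' @return Tibble with `label` (predicted) and one probability column per
#'   class (probabilities sum to 1 per window).
#' @export
fit_predict_windows <- function(family, hp, x_train, y_train, x_test,
                                seed = 1L) {
  model <- .fit_model(family, hp, as.matrix(x_train), y_train, seed)
  p <- .predict_proba(model, as.matrix(x_test))
  lab <- model$classes[max.col(p, ties.method = "first")]
  dplyr::bind_cols(tibble::tibble(label = lab),
                   tibble::as_tibble(p))
}
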