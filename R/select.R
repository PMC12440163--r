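# Relevance filtering (one-vs-rest Mann-Whitney tests under
# Benjamini-Yekutieli FDR control) and SMOTE class balancing. Both are
# fitted on training folds only; the cross-validation driver enforces this.

.meta_cols <- c("window_id", "video_id", "subject_id", "view", "direction",
                "label", "start_frame")

.feature_cols <- function(tbl) {
  setdiff(names(tbl), .meta_cols)
}

#' One-vs-rest Mann-Whitney relevance p-values
#'
#' For every feature and every class, a two-sided Mann-Whitney U test of the
#' feature values in that class against all other classes. Exact p-values
#' (via the null U distribution) are used for small tie-free samples
#' (n <= 50); otherwise the normal approximation with tie and continuity
#' correction. Constant features get p = 1.
#'
#' @param x Numeric matrix or data frame of features (rows = windows).
#' @param y Class labels (>= 2 classes, >= 2 samples per class).
#' @return Tibble with columns `feature`, `class`, `p`.
#' @export
relevance_pvalues <- function(x, y) {
  x <- as.matrix(x)
  y <- as.character(y)
  cls <- sort(unique(y))
  if (length(cls) < 2) stop("y must contain at least 2 classes")
  if (any(table(y) < 2)) stop("every class needs >= 2 samples")
  n <- nrow(x)
  rk <- col_midranks(x)                # midranks + tie bookkeeping (C++)
  tie_term <- attr(rk, "tie_term")
  is_const <- attr(rk, "is_const")
  has_ties <- tie_term > 0
  out <- vector("list", length(cls))
  for (ci in seq_along(cls)) {
    g <- y == cls[ci]
    n1 <- sum(g); n2 <- n - n1
    r1 <- colSums(rk[g, , drop = FALSE])
    u1 <- r1 - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    sig <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1))))
    zadj <- pmax(abs(u1 - mu) - 0.5, 0)
    p <- ifelse(sig > 0, 2 * stats::pnorm(-zadj / sig), 1)
    exact <- !has_ties & n <= 50
    if (any(exact)) {
      pe <- vapply(which(exact), function(j) {
        u <- u1[j]
        if (u > n1 * n2 / 2) {
          pp <- 2 * stats::pwilcox(n1 * n2 - u, n1, n2)
        } else {
          pp <- 2 * stats::pwilcox(u, n1, n2)
        }
        min(pp, 1)
      }, numeric(1))
      p[exact] <- pe
    }
    p[is_const] <- 1
    p <- pmin(p, 1)
    out[[ci]] <- tibble::tibble(feature = colnames(x) %||%
                                  paste0("V", seq_len(ncol(x))),
                                class = cls[ci], p = unname(p))
  }
  dplyr::bind_rows(out)
}

#' Benjamini-Yekutieli step-up rejection mask
#'
#' Step-up FDR procedure valid under arbitrary dependence: with `m` sorted
#' p-values, the k-th threshold is `k * q / (m * c(m))` with
#' `c(m) = sum_{i=1..m} 1/i`; all p-values up to the largest admissible k
#' are rejected.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @param q Target false discovery rate in `(0, 1)`.
#' @return Logical rejection mask, aligned with `pvals`.
#' @export
benjamini_yekutieli <- function(pvals, q = 0.05) {
  stopifnot(all(pvals >= 0 & pvals <= 1), q > 0, q < 1)
  m <- length(pvals)
  if (m == 0) return(logical(0))
  cm <- sum(1 / seq_len(m))
  o <- order(pvals)
  thr <- seq_len(m) * q / (m * cm)
  ok <- pvals[o] <= thr
  k <- if (any(ok)) max(which(ok)) else 0
  mask <- logical(m)
  if (k > 0) mask[o[seq_len(k)]] <- TRUE
  mask
}

#' Relevance-based feature selection with BY FDR control
#'
#' Computes one-vs-rest Mann-Whitney p-values for every feature x class
#' combination, applies Benjamini-Yekutieli jointly across the full
#' feature-class p-matrix, and keeps a feature if it is rejected
#' (significant) for at least one class. An empty selection falls back to
#' the full feature set with a warning.
#'
#' @param features Feature tibble ([compute_feature_matrix()] output) or a
#'   plain numeric matrix/data frame.
#' @param y Labels; defaults to the tibble's `label` column.
#' @param q FDR level.
#' @return Object of class `fresh_selection`: list with `pvalues` (tibble
#'   `feature`, `class`, `p`, `selected`), `selected` (character vector),
#'   `survivors_by_type` (tibble), `q`, `n_candidates`.
#' @export
fresh_select <- function(features, y = NULL, q = 0.05) {
  fc <- .feature_cols(tibble::as_tibble(as.data.frame(features)))
  if (is.null(y)) {
    if (!"label" %in% names(features)) stop("y missing and no label column")
    y <- features$label
  }
  x <- as.matrix(as.data.frame(features)[, fc, drop = FALSE])
  pv <- relevance_pvalues(x, y)
  mask <- benjamini_yekutieli(pv$p, q)
  pv$selected <- mask
  sel <- pv |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(keep = any(.data$selected)) |>
    dplyr::filter(.data$keep)
  selected <- sel$feature
  if (length(selected) == 0) {
    warning("BY selection rejected nothing; keeping the full feature set")
    selected <- colnames(x)
  }
  surv <- tryCatch({
    parsed <- parse_feature_names(selected)
    dplyr::count(parsed, .data$feature_type, name = "n_features")
  }, error = function(e) {
    tibble::tibble(feature_type = character(), n_features = integer())
  })
  structure(list(pvalues = pv, selected = selected,
                 survivors_by_type = surv, q = q,
                 n_candidates = ncol(x)),
            class = "fresh_selection")
}

#' @export
print.fresh_selection <- function(x, ...) {
  cat("<fresh_selection> ", length(x$selected), "of", x$n_candidates,
      "features kept at BY FDR q =", x$q, "\n")
  cat("  feature types surviving:", nrow(x$survivors_by_type), "\n")
  invisible(x)
}

#' SMOTE oversampling to the majority class
#'
#' Every minority class is upsampled to the majority-class count by
#' interpolating between a random class member `x` and one of its `k`
#' nearest same-class neighbours `nn` (Euclidean): `x + lambda * (nn - x)`
#' with `lambda ~ U(0, 1)`. `k` is reduced to `n_class - 1` where necessary;
#' singleton classes are duplicated. Original rows are preserved verbatim.
#'
#' @param x Numeric matrix or data frame of features.
#' @param y Class labels (every class non-empty).
#' @param k Number of nearest neighbours.
#' @param seed Integer seed for the interpolation draws.
#' @param groups Optional grouping vector (e.g. subject ids); a synthetic
#'   sample inherits the group of its base sample, so grouped
#'   cross-validation downstream stays subject-independent.
#' @return List with elements `x` (tibble), `y` (character vector) and
#'   `groups` (or `NULL`); attribute `n_synthetic` gives the number of
#'   generated rows.
#' @export
smote_oversample <- function(x, y, k = 5, seed = 1L, groups = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  y <- as.character(y)
  if (anyNA(y)) stop("labels must not be missing")
  if (nrow(x) != length(y)) stop("x and y sizes differ")
  if (!is.null(groups) && length(groups) != length(y)) {
    stop("groups and y sizes differ")
  }
  tab <- table(y)
  if (any(tab == 0)) stop("empty class")
  target <- max(tab)
  new_x <- list(); new_y <- character(0); new_g <- list()
  .with_seed(.hash_seed(seed, 7177), {
    for (cl in names(tab)) {
      need <- target - tab[[cl]]
      if (need == 0) next
      rows <- which(y == cl)
      xc <- x[rows, , drop = FALSE]
      nc <- nrow(xc)
      if (nc == 1) {
        syn <- xc[rep(1, need), , drop = FALSE]
        base <- rep(1L, need)
      } else {
        kk <- min(k, nc - 1)
        # squared Euclidean distances via the Gram matrix (BLAS)
        sq <- rowSums(xc^2)
        d <- outer(sq, sq, `+`) - 2 * tcrossprod(xc)
        diag(d) <- Inf
        nn_idx <- apply(d, 1, function(r) order(r)[seq_len(kk)])
        nn_idx <- matrix(nn_idx, nrow = kk)    # kk x nc
        base <- sample.int(nc, need, replace = TRUE)
        pick <- vapply(base, function(b) {
          nn_idx[sample.int(kk, 1), b]
        }, integer(1))
        lam <- stats::runif(need)
        syn <- xc[base, , drop = FALSE] +
          lam * (xc[pick, , drop = FALSE] - xc[base, , drop = FALSE])
      }
      new_x[[cl]] <- syn
      new_y <- c(new_y, rep(cl, need))
      if (!is.null(groups)) new_g[[cl]] <- groups[rows][base]
    }
  })
  xa <- rbind(x, do.call(rbind, new_x))
  rownames(xa) <- NULL
  out <- list(x = tibble::as_tibble(xa), y = c(y, new_y),
              groups = if (is.null(groups)) NULL
                       else c(groups, unlist(new_g, use.names = FALSE)))
  attr(out, "n_synthetic") <- length(new_y)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
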