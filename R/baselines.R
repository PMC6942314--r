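# Comparison baselines: static single-aspect / average / maximum scores
# with training-set threshold selection, the exhaustive weighted-average
# grid search, and a CART decision tree.

#' Static combination of aspect scores
#'
#' The five static baselines: each single aspect score, their arithmetic
#' mean (`Avg`), or their maximum (`Max`). Aspect kinds are matched
#' against the column order `BP`, `CC`, `MF` (or positionally via
#' `aspects`).
#'
#' @param features numeric vector of aspect scores or an n x n_aspects
#'   matrix.
#' @param kind one of the aspect names, `"Avg"`, or `"Max"`.
#' @param aspects aspect names in column order (default BP, CC, MF).
#' @return a numeric scalar or vector of combined scores.
#' @export
combine_static <- function(features, kind, aspects = c("BP", "CC", "MF")) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  out <- if (kind == "Avg") {
    rowMeans(features)
  } else if (kind == "Max") {
    do.call(pmax, lapply(seq_len(ncol(features)), function(j) features[, j]))
  } else {
    j <- match(kind, aspects)
    if (is.na(j) || j > ncol(features)) stop("unknown static kind: ", kind, call. = FALSE)
    features[, j]
  }
  if (length(out) == 1L) as.numeric(out) else out
}

#' Select the classification threshold on training scores
#'
#' Scans thresholds from 0 to 1 in steps of `step` (default 0.01) with
#' the rule `score > threshold -> class 1`, and returns the threshold
#' maximizing the training WAF; ties go to the smallest threshold. This
#' emulates the best cutoff a practitioner could have picked on the
#' training set.
#'
#' @param scores numeric vector of combined similarity scores.
#' @param labels 0/1 labels; both classes must be present.
#' @param step scan granularity.
#' @return list with `threshold` and `train_waf`.
#' @export
fit_threshold <- function(scores, labels, step = 0.01) {
  if (length(unique(labels)) < 2L) {
    stop("threshold selection needs both classes in the labels", call. = FALSE)
  }
  thresholds <- seq(0, 1, by = step)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  pos_scores <- scores[labels == 1L]
  neg_scores <- scores[labels == 0L]
  tp <- vapply(thresholds, function(th) sum(pos_scores > th), numeric(1L))
  fp <- vapply(thresholds, function(th) sum(neg_scores > th), numeric(1L))
  wafs <- waf_from_counts(tp, fp, n_pos - tp, n_pos, n_neg)
  best <- which.max(wafs)  # which.max takes the first (smallest) on ties
  list(threshold = thresholds[[best]], train_waf = wafs[[best]])
}

#' Exhaustive grid search over weighted-average combinations
#'
#' Enumerates every weight triple on the `[0, 1]` grid with step
#' `weight_step` (excluding the all-zero triple) and every threshold on
#' the `[0, 1]` grid with step `threshold_step`; the candidate score is
#' the weighted average of the aspect scores and the rule is
#' `score > threshold -> class 1`. Returns the candidate maximizing
#' training WAF, taking the first in lexicographic
#' `(w_1, w_2, w_3, threshold)` order on ties.
#'
#' @param train a labeled `feature_table`.
#' @param weight_step weight grid step (default 0.1, giving 11^3 - 1 =
#'   1330 triples).
#' @param threshold_step threshold grid step (default 0.05, giving 21
#'   values).
#' @return list with `weights` (length-3 numeric), `threshold`, and
#'   `train_waf`.
#' @export
grid_search <- function(train, weight_step = 0.1, threshold_step = 0.05) {
  stopifnot(inherits(train, "feature_table"))
  if (nrow(train) == 0L) stop("empty training table", call. = FALSE)
  y <- train$label
  if (is.null(y)) stop("training table has no labels", call. = FALSE)
  S <- feature_matrix(train)
  vals <- seq(0, 1, by = weight_step)
  W <- as.matrix(expand.grid(w3 = vals, w2 = vals, w1 = vals))[, 3:1]
  W <- W[rowSums(W) > 0, , drop = FALSE]
  # expand.grid varies its first factor fastest; after the column flip the
  # rows ascend in lexicographic (w1, w2, w3) order.
  scores <- S %*% t(W)
  scores <- sweep(scores, 2L, rowSums(W), "/")
  thresholds <- seq(0, 1, by = threshold_step)
  n_pos <- sum(y == 1L)
  n_neg <- sum(y == 0L)
  pos <- y == 1L
  # waf_mat[j, i]: threshold j, weight triple i. Column-major traversal of
  # this matrix visits candidates in lexicographic (w1, w2, w3, threshold)
  # order, so which.max's first-maximum rule is the tie-break.
  waf_mat <- matrix(NA_real_, length(thresholds), nrow(W))
  for (j in seq_along(thresholds)) {
    pred <- scores > thresholds[[j]]
    tp <- colSums(pred[pos, , drop = FALSE])
    fp <- colSums(pred[!pos, , drop = FALSE])
    waf_mat[j, ] <- waf_from_counts(tp, fp, n_pos - tp, n_pos, n_neg)
  }
  idx <- which.max(waf_mat)
  j <- (idx - 1L) %% length(thresholds) + 1L
  i <- (idx - 1L) %/% length(thresholds) + 1L
  list(weights = unname(W[i, ]), threshold = thresholds[[j]],
       train_waf = waf_mat[[idx]])
}

#' Fit the decision-tree reference classifier
#'
#' Thin adapter over CART (`rpart`) with its default parameters, using
#' the three aspect scores as features. The internal cross-validation of
#' the tree routine consumes random numbers, so a seed makes the fit
#' reproducible.
#'
#' @param train a labeled `feature_table` containing both classes.
#' @param seed integer seed.
#' @return a fitted classifier handle.
#' @export
fit_decision_tree <- function(train, seed = 1L) {
  stopifnot(inherits(train, "feature_table"))
  if (length(unique(train$label)) < 2L) {
    stop("decision tree needs both classes in the training labels", call. = FALSE)
  }
  df <- as.data.frame(feature_matrix(train))
  df$label <- factor(train$label, levels = c(0L, 1L))
  fit <- with_seed(seed, rpart::rpart(label ~ ., data = df, method = "class"))
  structure(list(fit = fit, features = colnames(feature_matrix(train))),
            class = "kgsim_tree")
}

#' Predict with the decision-tree baseline
#' @param handle a handle from [fit_decision_tree()].
#' @param features a `feature_table` or score matrix.
#' @return integer vector of 0/1 labels.
#' @export
predict_decision_tree <- function(handle, features) {
  stopifnot(inherits(handle, "kgsim_tree"))
  if (inherits(features, "feature_table")) features <- feature_matrix(features)
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L,
                                                 dimnames = list(NULL, handle$features))
  df <- as.data.frame(features)
  colnames(df) <- handle$features
  as.integer(as.character(predict(handle$fit, df, type = "class")))
}
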