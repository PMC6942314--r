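# Evaluation harness: pair datasets, annotation filtering, the weighted
# average of per-class F-measures, stratified cross-validation,
# cross-dataset deduplication, protocol runners and method comparison.

canonical_pair_key <- function(e1, e2) {
  paste(pmin(e1, e2), pmax(e1, e2), sep = "\r")
}

#' Construct a labeled pair dataset
#'
#' Pairs are unordered: each row is stored with its two entity ids in
#' canonical (sorted) order, and exact duplicate (unordered pair, label)
#' rows are removed with a reported count.
#'
#' @param pairs data frame with columns `entity1`, `entity2`, `label`
#'   (0/1).
#' @param name dataset label.
#' @param species optional species tag.
#' @return an object of class `pair_dataset`.
#' @export
pair_dataset <- function(pairs, name = "dataset", species = NA_character_) {
  stopifnot(all(c("entity1", "entity2", "label") %in% names(pairs)))
  if (!all(pairs$label %in% c(0L, 1L))) stop("labels must be 0 or 1", call. = FALSE)
  e1 <- pmin(pairs$entity1, pairs$entity2)
  e2 <- pmax(pairs$entity1, pairs$entity2)
  df <- data.frame(entity1 = e1, entity2 = e2, label = as.integer(pairs$label),
                   stringsAsFactors = FALSE)
  key <- paste(df$entity1, df$entity2, df$label, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    message("pair_dataset: removed ", sum(dup), " duplicate (pair, label) row(s)")
    df <- df[!dup, , drop = FALSE]
    rownames(df) <- NULL
  }
  structure(list(pairs = df, name = name, species = species),
            class = "pair_dataset")
}

#' @export
print.pair_dataset <- function(x, ...) {
  cat("<pair_dataset> '", x$name, "': ", nrow(x$pairs), " pairs (",
      sum(x$pairs$label == 1L), " positive)\n", sep = "")
  invisible(x)
}

#' Read a pair dataset from TSV
#'
#' Format: `entity1 TAB entity2 TAB label`, `#`-comment lines allowed, no
#' header required (a `entity1`-headed first line is accepted).
#'
#' @param path TSV path.
#' @param name dataset label (default: file base name).
#' @return a `pair_dataset`.
#' @export
read_pairs <- function(path, name = NULL) {
  if (!file.exists(path)) stop("pair file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  has_header <- grepl("^entity1\\b", first)
  df <- utils::read.table(path, sep = "\t", header = has_header,
                          comment.char = "#", stringsAsFactors = FALSE,
                          col.names = c("entity1", "entity2", "label"))
  pair_dataset(df, name = name %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Write a pair dataset as TSV
#' @param dataset a `pair_dataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(dataset, path) {
  stopifnot(inherits(dataset, "pair_dataset"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# pair dataset: ", dataset$name), con)
  utils::write.table(dataset$pairs, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Keep only pairs whose entities are both annotated somewhere
#'
#' A pair survives iff each of its two entities has at least one direct
#' annotation in at least one semantic aspect; the number of removed
#' pairs is reported.
#'
#' @param dataset a `pair_dataset`.
#' @param store an `annotation_store`.
#' @return the filtered `pair_dataset`.
#' @export
filter_pairs <- function(dataset, store) {
  stopifnot(inherits(dataset, "pair_dataset"), inherits(store, "annotation_store"))
  ents <- unique(c(dataset$pairs$entity1, dataset$pairs$entity2))
  ok <- stats::setNames(vapply(ents, function(e) has_any_annotation(store, e),
                               logical(1L)), ents)
  keep <- ok[dataset$pairs$entity1] & ok[dataset$pairs$entity2]
  removed <- sum(!keep)
  if (removed > 0L) message("filter_pairs: removed ", removed, " pair(s)")
  out <- dataset
  out$pairs <- dataset$pairs[keep, , drop = FALSE]
  rownames(out$pairs) <- NULL
  out
}

#' Weighted average of per-class F-measures
#'
#' For each class occurring in `y_true`, precision, recall and F-measure
#' are computed (a zero denominator yields 0), and the F-measures are
#' averaged weighted by class support.
#'
#' @param y_true,y_pred equal-length label vectors.
#' @return a real in `[0, 1]`.
#' @export
waf <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred have different lengths", call. = FALSE)
  }
  if (length(y_true) == 0L) stop("empty label vectors", call. = FALSE)
  classes <- sort(unique(y_true))
  total <- 0
  for (cl in classes) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    total <- total + f * sum(y_true == cl)
  }
  total / length(y_true)
}

# Vectorized binary WAF from confusion counts; entries are candidate
# classifiers over the same labels. Mirrors waf()'s precision/recall
# arithmetic operation for operation, so a scan over candidates and a
# naive per-candidate waf() call agree bitwise.
waf_from_counts <- function(tp, fp, fn, n_pos, n_neg) {
  tn <- n_neg - fp
  prec_p <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec_p <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f_pos <- ifelse(prec_p + rec_p > 0, 2 * prec_p * rec_p / (prec_p + rec_p), 0)
  prec_n <- ifelse(tn + fn > 0, tn / (tn + fn), 0)
  rec_n <- ifelse(tn + fp > 0, tn / (tn + fp), 0)
  f_neg <- ifelse(prec_n + rec_n > 0, 2 * prec_n * rec_n / (prec_n + rec_n), 0)
  (f_neg * n_neg + f_pos * n_pos) / (n_pos + n_neg)
}

#' Stratified k-fold assignment
#'
#' Within each class, indices are shuffled and dealt round-robin, so the
#' per-fold class counts deviate from exact proportionality by at most
#' one. The folds are a deterministic function of the seed; pinning the
#' seed reuses the same folds across all experiments.
#'
#' @param labels 0/1 label vector (or a `pair_dataset`).
#' @param k number of folds.
#' @param seed integer seed.
#' @return list of `k` lists with integer `train` and `test` index
#'   vectors partitioning `seq_along(labels)`.
#' @export
stratified_kfold <- function(labels, k = 10L, seed = 1L) {
  if (inherits(labels, "pair_dataset")) labels <- labels$pairs$label
  n <- length(labels)
  if (n < k) stop("fewer observations than folds", call. = FALSE)
  tab <- table(labels)
  if (length(tab) < 2L) stop("labels contain a single class", call. = FALSE)
  fold_of <- integer(n)
  with_seed(seed, {
    # dealing continues around the fold ring across classes, so per-class
    # counts stay proportional (+-1) while total fold sizes stay even
    cursor <- 0L
    for (cl in names(tab)) {
      idx <- sample(which(labels == cl))
      fold_of[idx] <- (cursor + seq_along(idx) - 1L) %% k + 1L
      cursor <- (cursor + length(idx)) %% k
    }
  })
  lapply(seq_len(k), function(f) {
    list(train = which(fold_of != f), test = which(fold_of == f))
  })
}

#' Remove unordered-pair overlap between two datasets
#'
#' A pair present (in either entity order) in both datasets is removed
#' from one of them, so that training and test sets never share a pair.
#'
#' @param train,test `pair_dataset` objects.
#' @param remove_from which side loses the overlapping pairs; default
#'   `"train"`, preserving the integrity of the reported test set.
#' @return list with the two (possibly reduced) datasets, `$train` and
#'   `$test`.
#' @export
dedup_across <- function(train, test, remove_from = c("train", "test")) {
  remove_from <- match.arg(remove_from)
  stopifnot(inherits(train, "pair_dataset"), inherits(test, "pair_dataset"))
  key_tr <- canonical_pair_key(train$pairs$entity1, train$pairs$entity2)
  key_te <- canonical_pair_key(test$pairs$entity1, test$pairs$entity2)
  overlap <- intersect(key_tr, key_te)
  if (length(overlap)) {
    message("dedup_across: ", length(overlap), " overlapping pair(s) removed from ",
            remove_from)
    if (remove_from == "train") {
      train$pairs <- train$pairs[!(key_tr %in% overlap), , drop = FALSE]
      rownames(train$pairs) <- NULL
    } else {
      test$pairs <- test$pairs[!(key_te %in% overlap), , drop = FALSE]
      rownames(test$pairs) <- NULL
    }
  }
  list(train = train, test = test)
}

#' Construct an evaluation report
#' @param method method label (e.g. `"gp"`, `"static:Max"`).
#' @param scores per-fold or per-run test WAF values.
#' @param protocol `"cv"` or `"cross"`.
#' @param details optional per-fold detail list (models, thresholds...).
#' @param seeds the seeds used.
#' @return list of class `evaluation_report` with `median_waf` filled.
#' @export
evaluation_report <- function(method, scores, protocol, details = NULL, seeds = NULL) {
  structure(list(method = method, protocol = protocol,
                 scores = as.numeric(scores),
                 median_waf = stats::median(as.numeric(scores)),
                 details = details, seeds = seeds),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> ", x$method, " [", x$protocol, "]: median WAF ",
      format(round(x$median_waf, 4)), " over ", length(x$scores), " score(s)\n",
      sep = "")
  invisible(x)
}

#' Write an evaluation report as JSON
#' @param report an `evaluation_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read an evaluation report written by [write_report()]
#' @param path JSON path.
#' @return an `evaluation_report`.
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  evaluation_report(x$method, x$scores, x$protocol, details = x$details,
                    seeds = x$seeds)
}

# Fit the requested method on a training feature table; returns a
# prediction closure over feature tables plus a detail record.
fit_method <- function(method, train_ft, seed = 1L, gp = gp_params()) {
  if (startsWith(method, "static:")) {
    kind <- sub("^static:", "", method)
    sc <- combine_static(feature_matrix(train_ft), kind)
    th <- fit_threshold(sc, train_ft$label)
    list(predict = function(ft) as.integer(combine_static(feature_matrix(ft), kind) > th$threshold),
         detail = list(kind = kind, threshold = th$threshold, train_waf = th$train_waf),
         stochastic = FALSE)
  } else if (method == "grid") {
    sol <- grid_search(train_ft)
    list(predict = function(ft) {
      s <- feature_matrix(ft) %*% sol$weights / sum(sol$weights)
      as.integer(s > sol$threshold)
    },
    detail = list(weights = sol$weights, threshold = sol$threshold,
                  train_waf = sol$train_waf),
    stochastic = FALSE)
  } else if (method == "tree") {
    fitd <- fit_decision_tree(train_ft, seed = seed)
    list(predict = function(ft) predict_decision_tree(fitd, ft),
         detail = list(), stochastic = TRUE)
  } else if (method == "gp") {
    model <- evolve(train_ft, gp, seed = seed)
    simp <- simplify_model(model)
    st <- model_stats(simp, n_vars = gp$n_variables)
    list(predict = function(ft) predict(model, ft),
         detail = list(model = model_to_string(simp),
                       length = st$length,
                       variable_frequency = as.list(st$variable_frequency),
                       train_rmse = model$fitness),
         stochastic = TRUE)
  } else {
    stop("unknown method: ", method, call. = FALSE)
  }
}

#' Run an evaluation protocol for one method
#'
#' Two protocols are supported. `"cv"` performs stratified k-fold
#' cross-validation on one feature table: each fold's training rows fit
#' the method, and WAF is measured on the held-out rows. `"cross"` takes
#' separate train and test feature tables (deduplicated with
#' [dedup_across()] semantics: overlapping unordered pairs are removed
#' from the training side), fits on the full training table and scores
#' the test table; stochastic methods are repeated over `n_runs` seeds,
#' deterministic ones produce a single score.
#'
#' @param features a labeled `feature_table` (the training/CV table).
#' @param method `"gp"`, `"static:<BP|CC|MF|Avg|Max>"` (aspect kinds
#'   follow the table's aspect names), `"grid"`, or `"tree"`.
#' @param protocol `"cv"` or `"cross"`.
#' @param test_features test `feature_table` for the cross protocol.
#' @param k folds for cv.
#' @param seed base seed; fold assignment uses it directly and run
#'   `i` uses `seed + i - 1`.
#' @param n_runs independent runs for stochastic methods under cross.
#' @param gp a [gp_params()] object for the GP method.
#' @return an [evaluation_report()].
#' @export
run_protocol <- function(features, method, protocol = c("cv", "cross"),
                         test_features = NULL, k = 10L, seed = 1L,
                         n_runs = 10L, gp = gp_params()) {
  protocol <- match.arg(protocol)
  stopifnot(inherits(features, "feature_table"))
  if (is.null(features$label)) stop("feature table has no labels", call. = FALSE)

  if (protocol == "cv") {
    folds <- stratified_kfold(features$label, k = k, seed = seed)
    scores <- numeric(k)
    details <- vector("list", k)
    for (f in seq_len(k)) {
      tr <- features[folds[[f]]$train, , drop = FALSE]
      te <- features[folds[[f]]$test, , drop = FALSE]
      fitted <- fit_method(method, tr, seed = seed + f - 1L, gp = gp)
      scores[[f]] <- waf(te$label, fitted$predict(te))
      details[[f]] <- fitted$detail
    }
    evaluation_report(method, scores, "cv", details = details,
                      seeds = seed + seq_len(k) - 1L)
  } else {
    if (is.null(test_features)) stop("cross protocol needs `test_features`", call. = FALSE)
    # drop unordered-pair overlap from the training table
    key_tr <- canonical_pair_key(features$entity1, features$entity2)
    key_te <- canonical_pair_key(test_features$entity1, test_features$entity2)
    overlap <- key_tr %in% key_te
    if (any(overlap)) {
      message("run_protocol: ", sum(overlap),
              " overlapping pair(s) removed from the training table")
      features <- features[!overlap, , drop = FALSE]
    }
    probe <- fit_method(method, features, seed = seed, gp = gp)
    seeds <- if (probe$stochastic) seed + seq_len(n_runs) - 1L else seed
    scores <- numeric(length(seeds))
    details <- vector("list", length(seeds))
    scores[[1L]] <- waf(test_features$label, probe$predict(test_features))
    details[[1L]] <- probe$detail
    if (length(seeds) > 1L) {
      for (i in seq_along(seeds)[-1L]) {
        fitted <- fit_method(method, features, seed = seeds[[i]], gp = gp)
        scores[[i]] <- waf(test_features$label, fitted$predict(test_features))
        details[[i]] <- fitted$detail
      }
    }
    evaluation_report(method, scores, "cross", details = details, seeds = seeds)
  }
}

#' Compare two evaluation reports
#'
#' Two-sample Kruskal-Wallis rank test on the per-fold/per-run WAF
#' scores, significant when p falls below `alpha`.
#'
#' @param report_a,report_b `evaluation_report` objects with at least two
#'   scores each.
#' @param alpha significance level (default 0.01).
#' @return list with `statistic`, `p_value` and `significant`.
#' @export
compare_methods <- function(report_a, report_b, alpha = 0.01) {
  stopifnot(inherits(report_a, "evaluation_report"),
            inherits(report_b, "evaluation_report"))
  if (length(report_a$scores) < 2L || length(report_b$scores) < 2L) {
    stop("each report needs at least 2 scores", call. = FALSE)
  }
  kt <- stats::kruskal.test(list(report_a$scores, report_b$scores))
  stat <- unname(kt$statistic)
  p <- kt$p.value
  if (is.nan(stat)) { stat <- 0; p <- 1 }  # identical constant samples
  list(statistic = stat, p_value = p, significant = is.finite(p) && p < alpha)
}
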