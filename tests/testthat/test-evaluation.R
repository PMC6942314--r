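# WAF, filtering, folds, deduplication, protocols, and method comparison.

test_that("WAF matches the worked example and edge cases", {
  expect_equal(waf(c(1, 1, 1, 1, 0, 0), c(1, 1, 1, 0, 0, 1)),
               (0.75 * 4 + 0.5 * 2) / 6)
  expect_equal(waf(c(1, 0, 1), c(1, 0, 1)), 1)
  expect_equal(waf(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0)
  expect_error(waf(c(1, 0), c(1)), "different lengths")
  expect_error(waf(integer(0), integer(0)), "empty")
})

test_that("WAF equals the per-class precision/recall oracle on small tables", {
  for (tp in 0:3) for (fp in 0:3) for (fn in 0:3) for (tn in 0:3) {
    n <- tp + fp + fn + tn
    if (n == 0) next
    y_true <- c(rep(1L, tp), rep(0L, fp), rep(1L, fn), rep(0L, tn))
    y_pred <- c(rep(1L, tp), rep(1L, fp), rep(0L, fn), rep(0L, tn))
    expect_equal(waf(y_true, y_pred), oracle_waf(y_true, y_pred), tolerance = 1e-14)
  }
})

test_that("pair datasets canonicalize order and drop duplicate rows", {
  df <- data.frame(entity1 = c("B", "A", "A", "C"),
                   entity2 = c("A", "B", "B", "D"),
                   label = c(1L, 1L, 0L, 0L))
  expect_message(ds <- pair_dataset(df), "removed 1 duplicate")
  # (B,A,1) and (A,B,1) are the same unordered pair
  expect_equal(nrow(ds$pairs), 3L)
  expect_true(all(ds$pairs$entity1 <= ds$pairs$entity2))
  expect_error(pair_dataset(data.frame(entity1 = "a", entity2 = "b", label = 2L)),
               "labels")
})

test_that("pair TSV round-trips", {
  df <- data.frame(entity1 = c("A", "C"), entity2 = c("B", "D"), label = c(1L, 0L))
  ds <- pair_dataset(df, name = "toy")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pairs(ds, path)
  ds2 <- read_pairs(path)
  expect_equal(ds2$pairs, ds$pairs)
})

test_that("the annotation filter keeps pairs iff both entities are annotated somewhere", {
  g <- toy_graph()
  store <- annotation_store(g, list(p1 = list(R = "C"), p2 = list(R = "B")))
  ds <- pair_dataset(data.frame(entity1 = c("p1", "p1", "p2"),
                                entity2 = c("p2", "px", "py"),
                                label = c(1L, 1L, 0L)))
  expect_message(kept <- filter_pairs(ds, store), "removed 2")
  expect_equal(nrow(kept$pairs), 1L)
  empty_store <- annotation_store(g, list())
  all_gone <- suppressMessages(filter_pairs(ds, empty_store))
  expect_equal(nrow(all_gone$pairs), 0L)
})

test_that("stratified folds partition the data with near-proportional classes", {
  labels <- c(rep(1L, 12), rep(0L, 8))
  folds <- stratified_kfold(labels, k = 10L, seed = 42)
  test_idx <- lapply(folds, `[[`, "test")
  expect_setequal(unlist(test_idx), seq_along(labels))
  expect_equal(sum(lengths(test_idx)), 20L)
  for (f in folds) {
    expect_equal(sort(c(f$train, f$test)), seq_along(labels))
    expect_equal(length(f$test), 2L)
    n_pos <- sum(labels[f$test] == 1L)
    expect_true(n_pos %in% c(1L, 2L))
  }
  expect_identical(stratified_kfold(labels, 10L, seed = 42), folds)
  expect_error(stratified_kfold(c(1L, 0L), k = 3L), "fewer observations")
  expect_error(stratified_kfold(rep(1L, 10), k = 2L), "single class")
})

test_that("cross-dataset dedup removes unordered overlap from the chosen side", {
  train <- pair_dataset(data.frame(entity1 = c("A", "C", "E"),
                                   entity2 = c("B", "D", "F"),
                                   label = c(1L, 0L, 1L)))
  test <- pair_dataset(data.frame(entity1 = c("B", "G"),
                                  entity2 = c("A", "H"),
                                  label = c(1L, 0L)))
  out <- suppressMessages(dedup_across(train, test))
  expect_equal(nrow(out$train$pairs), 2L)  # (A,B) left the training side
  expect_equal(nrow(out$test$pairs), 2L)
  k_tr <- paste(out$train$pairs$entity1, out$train$pairs$entity2)
  k_te <- paste(out$test$pairs$entity1, out$test$pairs$entity2)
  expect_length(intersect(k_tr, k_te), 0L)
  out2 <- suppressMessages(dedup_across(train, test, remove_from = "test"))
  expect_equal(nrow(out2$train$pairs), 3L)
  expect_equal(nrow(out2$test$pairs), 1L)
  disjoint <- dedup_across(out$train, out$test)
  expect_equal(disjoint$train$pairs, out$train$pairs)
})

test_that("cross-validation protocol reports one score per fold and the median", {
  df <- random_feature_df(80, seed = 31)
  df$label <- as.integer(df$ss_CC > 0.5)
  ft <- feature_table(df)
  rep1 <- run_protocol(ft, "static:CC", protocol = "cv", k = 10L, seed = 7)
  expect_length(rep1$scores, 10L)
  expect_equal(rep1$median_waf, median(rep1$scores))
  expect_gte(rep1$median_waf, 0.95)
  rep2 <- run_protocol(ft, "static:CC", protocol = "cv", k = 10L, seed = 7)
  expect_identical(rep1$scores, rep2$scores)
})

test_that("cross protocol dedups pairs and repeats only stochastic methods", {
  df_tr <- random_feature_df(60, seed = 1)
  df_tr$label <- as.integer(df_tr$ss_BP > 0.5)
  df_te <- random_feature_df(30, seed = 2)
  df_te$label <- as.integer(df_te$ss_BP > 0.5)
  # inject an overlapping pair in reversed order
  df_te$entity1[1] <- df_tr$entity2[5]
  df_te$entity2[1] <- df_tr$entity1[5]
  ft_tr <- feature_table(df_tr); ft_te <- feature_table(df_te)
  expect_message(
    rep_static <- run_protocol(ft_tr, "static:BP", protocol = "cross",
                               test_features = ft_te, seed = 3),
    "overlapping")
  expect_length(rep_static$scores, 1L)   # deterministic method: single run
  rep_gp <- suppressMessages(run_protocol(
    ft_tr, "gp", protocol = "cross", test_features = ft_te, seed = 3,
    n_runs = 3L, gp = gp_params(population_size = 30L, generations = 3L)))
  expect_length(rep_gp$scores, 3L)
})

test_that("reports serialize to JSON and reload", {
  rep1 <- evaluation_report("static:Max", c(0.8, 0.9, 0.7), "cv")
  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep1, path)
  rep2 <- read_report(path)
  expect_equal(rep2$scores, rep1$scores)
  expect_equal(rep2$median_waf, 0.8)
  expect_equal(rep2$method, "static:Max")
})

test_that("method comparison honors alpha and handles identical samples", {
  a <- evaluation_report("m1", rep(0.9, 10), "cv")
  b <- evaluation_report("m2", rep(0.5, 10), "cv")
  cmp <- compare_methods(a, b, alpha = 0.01)
  expect_true(cmp$significant)
  expect_lt(cmp$p_value, 0.01)
  same <- compare_methods(a, a)
  expect_false(same$significant)
  expect_equal(same$statistic, 0)
  # cross-check against the base Kruskal-Wallis routine on mixed data
  x <- c(0.81, 0.83, 0.85, 0.9, 0.7)
  y <- c(0.5, 0.55, 0.62, 0.58, 0.66)
  cmp2 <- compare_methods(evaluation_report("a", x, "cv"),
                          evaluation_report("b", y, "cv"))
  ref <- kruskal.test(list(x, y))
  expect_equal(cmp2$p_value, ref$p.value)
  expect_error(compare_methods(evaluation_report("a", 0.5, "cv"), a), "at least 2")
})
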