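# Synthetic study generator: structure, determinism, sampling, round trips.

test_that("generated ontologies satisfy the graph invariants", {
  spec <- synthetic_spec(n_terms_per_aspect = c(BP = 50L, CC = 50L, MF = 50L),
                         aspect_annotation_prob = c(BP = 1, CC = 1, MF = 1))
  g <- generate_ontology(spec, seed = 2)
  expect_equal(length(g$terms), 150L)
  expect_length(g$roots, 3L)
  expect_true(all(g$ic >= 0 & g$ic <= 1))
  g2 <- generate_ontology(spec, seed = 2)
  expect_identical(g2$parents, g$parents)
  # max_parents = 1 gives a tree per aspect
  spec_tree <- synthetic_spec(n_terms_per_aspect = c(A = 30L, B = 10L),
                              aspect_annotation_prob = c(A = 1, B = 1),
                              max_parents = 1L)
  gt <- generate_ontology(spec_tree, seed = 3)
  expect_equal(sum(lengths(gt$parents)), 40L - 2L)
})

test_that("annotation generation respects sparsity and the coverage invariant", {
  spec <- synthetic_spec(n_entities = 300L,
                         aspect_annotation_prob = c(BP = 0.3, CC = 1, MF = 1),
                         direct_terms_per_aspect = c(2L, 2L))
  g <- generate_ontology(spec, seed = 1)
  store <- generate_annotations(g, spec, seed = 4)
  expect_length(store$direct, 300L)
  has_bp <- vapply(store$direct, function(b) length(b[["BP"]]) > 0, logical(1L))
  expect_gt(mean(has_bp), 0.3 - 3 * sqrt(0.3 * 0.7 / 300))
  expect_lt(mean(has_bp), 0.3 + 3 * sqrt(0.3 * 0.7 / 300))
  n_cc <- vapply(store$direct, function(b) length(b[["CC"]]), integer(1L))
  expect_true(all(n_cc == 2L))
  covered <- vapply(names(store$direct), function(e) {
    length(annotations(store, e, "BP")) + length(annotations(store, e, "CC")) +
      length(annotations(store, e, "MF")) > 0
  }, logical(1L))
  expect_true(all(covered))
})

test_that("labeled pairs follow the truth rule and the noise level", {
  spec <- synthetic_spec(n_pairs = 400L, n_entities = 80L, label_noise = 0,
                         truth_model = "max(BP, CC)", truth_threshold = 0.5)
  g <- generate_ontology(spec)
  store <- generate_annotations(g, spec)
  gen <- generate_labeled_pairs(g, store, spec, measure = "SimGIC", seed = 9)
  ft <- gen$features
  truth <- as.integer(pmax(ft$ss_BP, ft$ss_CC) > 0.5)
  expect_equal(ft$label, truth)   # zero noise: labels deterministic
  expect_equal(nrow(gen$dataset$pairs), 400L)
  # with noise, the flipped fraction sits in the binomial window
  spec_noisy <- synthetic_spec(n_pairs = 1000L, n_entities = 80L,
                               label_noise = 0.05)
  gen2 <- generate_labeled_pairs(g, store, spec_noisy, measure = "SimGIC", seed = 10)
  ft2 <- gen2$features
  truth2 <- as.integer(pmax(ft2$ss_BP, ft2$ss_CC) > 0.5)
  flipped <- mean(ft2$label != truth2)
  expect_gt(flipped, 0.05 - 3 * sqrt(0.05 * 0.95 / 1000))
  expect_lt(flipped, 0.05 + 3 * sqrt(0.05 * 0.95 / 1000))
  gen_same <- generate_labeled_pairs(g, store, spec, measure = "SimGIC", seed = 9)
  expect_identical(gen_same$features$label, gen$features$label)
})

test_that("balanced sampling tracks per-entity positive counts better than uniform", {
  count_dev <- function(sampling) {
    spec <- synthetic_spec(n_pairs = 300L, n_entities = 60L, label_noise = 0,
                           sampling = sampling, truth_threshold = 0.25)
    g <- generate_ontology(spec)
    store <- generate_annotations(g, spec)
    gen <- generate_labeled_pairs(g, store, spec, measure = "SimGIC", seed = 5)
    pr <- gen$dataset$pairs
    pos <- pr[pr$label == 1L, ]; neg <- pr[pr$label == 0L, ]
    ents <- unique(c(pr$entity1, pr$entity2))
    pc <- table(factor(c(pos$entity1, pos$entity2), levels = ents))
    nc <- table(factor(c(neg$entity1, neg$entity2), levels = ents))
    sum(abs(as.integer(nc) - as.integer(pc)))
  }
  expect_lt(count_dev("balanced"), count_dev("unbalanced"))
})

test_that("uniform-feature tables label by the truth rule with noise", {
  ft <- synthetic_feature_table(2000, "max(BP, CC)", 0.6, 0, seed = 1)
  expect_equal(ft$label, as.integer(pmax(ft$ss_BP, ft$ss_CC) > 0.6))
  ft2 <- synthetic_feature_table(2000, "max(BP, CC)", 0.6, 0.05, seed = 1)
  expect_gt(mean(ft2$label != ft$label), 0.02)
  expect_lt(mean(ft2$label != ft$label), 0.08)
})

test_that("fixtures round-trip through the OBO/GAF/TSV parsers", {
  spec <- synthetic_spec(n_terms_per_aspect = c(BP = 25L, CC = 20L, MF = 15L),
                         n_entities = 30L, n_pairs = 50L)
  g <- generate_ontology(spec)
  store <- generate_annotations(g, spec)
  gen <- generate_labeled_pairs(g, store, spec, measure = "SimGIC")
  dir <- withr::local_tempdir()
  paths <- write_fixture(g, store, gen$dataset, dir)
  g2 <- parse_obo(paths[["obo"]])
  expect_setequal(g2$terms, g$terms)
  expect_equal(graph_checksum(g2), graph_checksum(g))
  store2 <- parse_gaf(paths[["gaf"]], compute_ic(g2))
  expect_setequal(names(store2$direct), names(store$direct))
  for (e in names(store$direct)) {
    for (a in names(store$direct[[e]])) {
      expect_setequal(store2$direct[[e]][[a]], store$direct[[e]][[a]])
    }
  }
  ds2 <- read_pairs(paths[["pairs"]])
  expect_equal(ds2$pairs, gen$dataset$pairs)
})

test_that("the pipeline is self-consistent: a noise-free single-aspect rule is recovered", {
  spec <- synthetic_spec(n_pairs = 1000L, n_entities = 120L, label_noise = 0,
                         truth_model = "BP", truth_threshold = 0.5)
  g <- generate_ontology(spec)
  store <- generate_annotations(g, spec)
  gen <- generate_labeled_pairs(g, store, spec, measure = "SimGIC", seed = 3)
  ft <- gen$features
  folds <- stratified_kfold(ft$label, k = 5L, seed = 1)
  scores <- vapply(folds, function(f) {
    tr <- ft[f$train, ]; te <- ft[f$test, ]
    th <- fit_threshold(tr$ss_BP, tr$label)
    waf(te$label, as.integer(te$ss_BP > th$threshold))
  }, numeric(1L))
  expect_gte(median(scores), 0.99)
})

test_that("starving one aspect of annotations degrades that aspect's baseline", {
  waf_for_bp_prob <- function(prob, seed) {
    spec <- synthetic_spec(
      n_pairs = 300L, n_entities = 80L, label_noise = 0,
      aspect_annotation_prob = c(BP = prob, CC = 0.9, MF = 0.8),
      truth_model = "max(BP, CC)", truth_threshold = 0.4
    )
    g <- generate_ontology(spec, seed)
    store <- generate_annotations(g, spec, seed + 1L)
    gen <- generate_labeled_pairs(g, store, spec, measure = "SimGIC", seed + 2L)
    ft <- gen$features
    rep <- run_protocol(ft, "static:BP", protocol = "cv", k = 5L, seed = 1)
    rep$median_waf
  }
  rich <- median(vapply(1:2, function(s) waf_for_bp_prob(0.95, s * 100L), numeric(1L)))
  poor <- median(vapply(1:2, function(s) waf_for_bp_prob(0.25, s * 100L), numeric(1L)))
  expect_lt(poor, rich)
})
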