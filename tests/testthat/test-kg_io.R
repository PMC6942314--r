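# Ontology parsing, ancestor closure, and intrinsic IC.

obo_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".obo", .local_envir = parent.frame())
  writeLines(c("format-version: 1.2", "", lines), path)
  path
}

test_that("parse_obo reads terms, is-a edges and detects the root", {
  path <- obo_fixture(c(
    "[Term]", "id: R", "name: root", "",
    "[Term]", "id: A", "name: a", "is_a: R ! root", "",
    "[Term]", "id: B", "name: b", "is_a: R", "",
    "[Term]", "id: C", "name: c", "is_a: A", ""
  ))
  g <- parse_obo(path)
  expect_setequal(g$terms, c("R", "A", "B", "C"))
  expect_equal(sum(lengths(g$parents)), 3L)
  expect_equal(unname(g$roots), "R")
  expect_setequal(ancestors(g, "C"), c("C", "A", "R"))
})

test_that("non-requested relations are dropped and obsolete terms vanish", {
  path <- obo_fixture(c(
    "[Term]", "id: R", "",
    "[Term]", "id: A", "is_a: R", "relationship: part_of R", "",
    "[Term]", "id: B", "is_a: R", "",
    "[Term]", "id: OLD", "is_a: R", "is_obsolete: true", ""
  ))
  g <- parse_obo(path)
  expect_false("OLD" %in% g$terms)
  # A keeps only its is_a edge; the part_of relationship is not an edge
  expect_equal(g$parents[["A"]], "R")
  g2 <- parse_obo(path, relations = c("is_a", "part_of"))
  expect_setequal(g2$parents[["A"]], "R")
})

test_that("alt_id maps a superseded id to the canonical term", {
  path <- obo_fixture(c(
    "[Term]", "id: R", "",
    "[Term]", "id: A", "alt_id: A_OLD", "is_a: R", ""
  ))
  g <- parse_obo(path)
  expect_equal(ancestors(g, "A_OLD"), ancestors(g, "A"))
})

test_that("a cyclic is-a relation is rejected with the offending term named", {
  path <- obo_fixture(c(
    "[Term]", "id: R", "",
    "[Term]", "id: A", "is_a: C", "",
    "[Term]", "id: C", "is_a: A", ""
  ))
  expect_error(parse_obo(path), "cycle")
})

test_that("a term reaching two roots is a structural error", {
  expect_error(
    ontology_graph(c("R1", "R2", "X"), rbind(c("X", "R1"), c("X", "R2"))),
    "2 aspect roots"
  )
})

test_that("ancestors is reflexive, aspect-pure and idempotent on unions", {
  g <- toy_graph()
  expect_setequal(ancestors(g, "C"), c("C", "A", "R"))
  expect_equal(ancestors(g, "R"), "R")
  # diamond
  gd <- ontology_graph(c("R", "A", "B", "D"),
                       rbind(c("A", "R"), c("B", "R"), c("D", "A"), c("D", "B")))
  expect_setequal(ancestors(gd, "D"), c("D", "A", "B", "R"))
  expect_error(ancestors(g, "nope"), "unknown term")
  study <- random_study(11L)
  for (t in sample(study$graph$terms, 10L)) {
    anc <- ancestors(study$graph, t)
    expect_gte(length(anc), 1L)
    closure <- unique(unlist(lapply(anc, function(a) ancestors(study$graph, a))))
    expect_setequal(closure, anc)
    expect_true(all(study$graph$aspect[anc] == study$graph$aspect[[t]]))
  }
})

test_that("compute_ic matches the hand-worked toy values and clamps the root", {
  g <- toy_graph()
  expect_equal(g$ic[["B"]], 0.5)
  expect_equal(g$ic[["C"]], 0.5)
  expect_equal(g$ic[["A"]], 1 - log(3) / log(4))
  expect_equal(g$ic[["R"]], 0)
  g_raw <- toy_graph(clamp = FALSE)
  expect_equal(g_raw$ic[["R"]], 1 - log(5) / log(4))
  expect_lt(g_raw$ic[["R"]], 0)
})

test_that("IC decreases from leaf to root along any path and leaves peak", {
  study <- random_study(5L)
  g <- study$graph
  for (t in g$terms) {
    for (p in g$parents[[t]]) expect_lte(g$ic[[p]], g$ic[[t]])
  }
  for (a in names(g$roots)) {
    in_aspect <- g$terms[g$aspect == a]
    leaves <- in_aspect[!in_aspect %in% unlist(g$parents[in_aspect])]
    expect_equal(max(g$ic[in_aspect]), max(g$ic[leaves]))
  }
})

test_that("IC agrees with the naive descendant-count oracle", {
  study <- random_study(7L, n_terms = c(BP = 20L, CC = 15L, MF = 12L))
  g <- study$graph
  edges <- graph_edges_df(g)
  oracle <- oracle_ic_table(g$terms, edges)
  expect_equal(g$ic[g$terms], oracle$ic[g$terms], tolerance = 1e-14)
})

test_that("single-term aspects and global maxnodes are handled", {
  expect_error(compute_ic(ontology_graph(c("R1", "R2", "X"), rbind(c("X", "R1")))),
               "fewer than 2 terms")
  study <- random_study(3L)
  g_global <- compute_ic(study$graph, per_aspect = FALSE)
  # global maxnodes inflates the denominator, never decreasing IC
  expect_true(all(g_global$ic >= study$graph$ic - 1e-12))
})

test_that("OBO writing round-trips term, edge and aspect sets", {
  study <- random_study(9L)
  path <- withr::local_tempfile(fileext = ".obo")
  write_obo(study$graph, path)
  g2 <- parse_obo(path)
  expect_setequal(g2$terms, study$graph$terms)
  expect_equal(lapply(g2$parents[sort(names(g2$parents))], sort),
               lapply(study$graph$parents[sort(names(study$graph$parents))], sort))
  expect_equal(sort(names(g2$roots)), sort(names(study$graph$roots)))
})

test_that("parse_gaf applies NOT/unknown-term rules and assigns aspects from the graph", {
  g <- toy_graph()
  path <- withr::local_tempfile(fileext = ".gaf")
  rec <- function(entity, term, qualifier = "") {
    paste("DB", entity, entity, qualifier, term, "REF", "IEA", "", "P", "",
          "", "protein", "taxon:0", "20260101", "DB", "", "", sep = "\t")
  }
  writeLines(c("!gaf-version: 2.1",
               rec("P1", "C"),
               rec("P2", "B", qualifier = "NOT"),
               rec("P3", "UNKNOWN"),
               "badline"), path)
  expect_warning(
    expect_message(store <- parse_gaf(path, g), "dropped 1"),
    "malformed")
  expect_equal(annotations(store, "P1", "R", "direct"), "C")
  expect_length(store$direct[["P2"]], 0L)   # NOT-qualified record excluded
  expect_false("P3" %in% names(store$direct))
  # empty result is an error
  path2 <- withr::local_tempfile(fileext = ".gaf")
  writeLines(c("!gaf-version: 2.1", rec("P2", "B", qualifier = "NOT")), path2)
  expect_error(suppressWarnings(parse_gaf(path2, g)), "no usable")
})

test_that("annotation modes: extended closes under ancestors, unknown entity is empty", {
  g <- toy_graph()
  store <- toy_store(g)
  expect_equal(annotations(store, "p1", "R", "direct"), "C")
  expect_setequal(annotations(store, "p1", "R", "extended"), c("C", "A", "R"))
  ext <- annotations(store, "p4", "R", "extended")
  closure <- unique(unlist(lapply(ext, function(t) ancestors(g, t))))
  expect_setequal(closure, ext)
  expect_equal(annotations(store, "ghost", "R", "direct"), character(0L))
})

test_that("annotation_store validates term existence and aspect buckets", {
  g <- toy_graph()
  expect_error(annotation_store(g, list(p = list(R = "nope"))), "not in the referenced graph")
  g2 <- ontology_graph(c("R1", "R2", "X"), rbind(c("X", "R1")))
  expect_error(annotation_store(g2, list(p = list(R2 = "X"))), "belongs to")
})
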