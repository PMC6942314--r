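# Shared fixtures: the hand-checked toy DAG and small builders.

# Toy single-aspect DAG: root R with children A and B, C under A.
# Hand-computed Seco IC with maxnodes = 4:
#   hypo: R=4, A=2, B=1, C=1
#   IC(B) = IC(C) = 1 - log(2)/log(4) = 0.5
#   IC(A) = 1 - log(3)/log(4)
#   IC(R) = 1 - log(5)/log(4) < 0, clamped to 0
toy_graph <- function(clamp = TRUE) {
  g <- ontology_graph(c("R", "A", "B", "C"),
                      rbind(c("A", "R"), c("B", "R"), c("C", "A")))
  compute_ic(g, clamp = clamp)
}

toy_store <- function(g = toy_graph()) {
  annotation_store(g, list(
    p1 = list(R = "C"),
    p2 = list(R = "B"),
    p3 = list(R = "A"),
    p4 = list(R = c("C", "B"))
  ))
}

# Random study small enough for brute-force cross-checks.
random_study <- function(seed, n_terms = c(BP = 40L, CC = 30L, MF = 25L),
                         n_entities = 15L, n_pairs = 40L) {
  spec <- synthetic_spec(
    n_terms_per_aspect = n_terms,
    n_entities = n_entities,
    direct_terms_per_aspect = c(1L, 3L),
    n_pairs = n_pairs,
    seed = seed
  )
  graph <- generate_ontology(spec, seed)
  store <- generate_annotations(graph, spec, seed + 1L)
  list(spec = spec, graph = graph, store = store)
}

random_feature_df <- function(n, seed) {
  set.seed(seed)
  data.frame(
    entity1 = sprintf("a%03d", seq_len(n)),
    entity2 = sprintf("b%03d", seq_len(n)),
    label = sample(0:1, n, replace = TRUE),
    ss_BP = runif(n), ss_CC = runif(n), ss_MF = runif(n),
    stringsAsFactors = FALSE
  )
}
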