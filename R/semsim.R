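# Semantic similarity: term-level MICA similarity and three entity-level
# measures computed independently per aspect.

#' Term-level similarity (most informative common ancestor)
#'
#' The similarity of two terms is the maximal information content over
#' their common ancestors. Ancestor sets are reflexive, so
#' `term_similarity(g, t, t)` equals `IC(t)`.
#'
#' @param graph an `ontology_graph` with IC computed.
#' @param t1,t2 term ids from the same aspect.
#' @return a real in `[0, 1]`.
#' @export
term_similarity <- function(graph, t1, t2) {
  stopifnot(inherits(graph, "ontology_graph"))
  t1 <- canonical_term(graph, t1); t2 <- canonical_term(graph, t2)
  if (!t1 %in% graph$terms) stop("unknown term: ", t1, call. = FALSE)
  if (!t2 %in% graph$terms) stop("unknown term: ", t2, call. = FALSE)
  if (graph$aspect[[t1]] != graph$aspect[[t2]]) {
    stop("terms '", t1, "' and '", t2, "' belong to different aspects", call. = FALSE)
  }
  common <- intersect(graph$anc[[t1]], graph$anc[[t2]])
  max(graph$ic[common])
}

# All-pairs MICA similarity between two direct term sets of one aspect;
# returns a |ts1| x |ts2| matrix. Shared workhorse of the Resnik variants.
term_sim_matrix <- function(graph, ts1, ts2) {
  m <- matrix(0, length(ts1), length(ts2), dimnames = list(ts1, ts2))
  for (i in seq_along(ts1)) {
    a1 <- graph$anc[[ts1[[i]]]]
    for (j in seq_along(ts2)) {
      common <- intersect(a1, graph$anc[[ts2[[j]]]])
      m[i, j] <- max(graph$ic[common])
    }
  }
  m
}

#' IC-weighted Jaccard similarity of two entities (SimGIC)
#'
#' Ratio of summed IC over the intersection to summed IC over the union of
#' the two entities' extended (direct plus inherited) annotation sets in
#' one aspect. An entity with no annotation in the aspect scores 0, as
#' does a pair whose union carries zero total IC.
#'
#' @param graph an `ontology_graph` with IC computed.
#' @param store an `annotation_store`.
#' @param p1,p2 entity ids.
#' @param aspect aspect label.
#' @param mode annotation mode; extended is the measure's definition.
#' @return a real in `[0, 1]`.
#' @export
sim_gic <- function(graph, store, p1, p2, aspect, mode = "extended") {
  s1 <- annotations(store, p1, aspect, mode)
  s2 <- annotations(store, p2, aspect, mode)
  if (length(s1) == 0L || length(s2) == 0L) return(0)
  num <- sum(graph$ic[intersect(s1, s2)])
  den <- sum(graph$ic[union(s1, s2)])
  if (den == 0) return(0)
  num / den
}

#' Resnik entity similarity, maximum variant
#'
#' Maximum MICA similarity over the cross product of the two entities'
#' direct annotation sets in one aspect; 0 if either set is empty.
#'
#' @inheritParams sim_gic
#' @param mode annotation mode; the pairwise variants use direct sets.
#' @return a real in `[0, 1]`.
#' @export
resnik_max <- function(graph, store, p1, p2, aspect, mode = "direct") {
  s1 <- annotations(store, p1, aspect, mode)
  s2 <- annotations(store, p2, aspect, mode)
  if (length(s1) == 0L || length(s2) == 0L) return(0)
  max(term_sim_matrix(graph, s1, s2))
}

#' Resnik entity similarity, best-match-average variant
#'
#' Each term of one entity is matched to its best counterpart on the other
#' side; the two directional sums of best matches are each normalised by
#' twice the corresponding set size and added:
#' \deqn{\sum_i \max_j sim(t_i, t_j) / (2|S_1|) + \sum_j \max_i sim(t_i, t_j) / (2|S_2|).}
#' 0 if either direct set is empty.
#'
#' @inheritParams resnik_max
#' @return a real in `[0, 1]`.
#' @export
resnik_bma <- function(graph, store, p1, p2, aspect, mode = "direct") {
  s1 <- annotations(store, p1, aspect, mode)
  s2 <- annotations(store, p2, aspect, mode)
  if (length(s1) == 0L || length(s2) == 0L) return(0)
  m <- term_sim_matrix(graph, s1, s2)
  sum(apply(m, 1L, max)) / (2 * length(s1)) + sum(apply(m, 2L, max)) / (2 * length(s2))
}

ssm_measures <- c("SimGIC", "ResnikMax", "ResnikBMA")

entity_similarity <- function(graph, store, p1, p2, aspect, measure) {
  switch(measure,
    SimGIC    = sim_gic(graph, store, p1, p2, aspect),
    ResnikMax = resnik_max(graph, store, p1, p2, aspect),
    ResnikBMA = resnik_bma(graph, store, p1, p2, aspect),
    stop("unknown measure: ", measure, call. = FALSE)
  )
}

#' Per-pair, per-aspect similarity feature table
#'
#' For every entity pair, computes the chosen similarity in each aspect of
#' the graph. Pairs are expected to have passed [filter_pairs()]: an
#' entity with no annotation in any aspect is a contract violation here.
#'
#' @param graph an `ontology_graph` with IC computed.
#' @param store an `annotation_store`.
#' @param pairs data frame with columns `entity1`, `entity2` and
#'   optionally `label` (0/1), or a `pair_dataset`.
#' @param measure one of `"SimGIC"`, `"ResnikMax"`, `"ResnikBMA"`.
#' @return a `feature_table`: a data frame with the pair columns, `label`
#'   if given, and one `ss_<aspect>` column per aspect; the measure and
#'   graph checksum are carried as attributes.
#' @export
compute_features <- function(graph, store, pairs, measure = ssm_measures) {
  measure <- match.arg(measure)
  if (inherits(pairs, "pair_dataset")) pairs <- pairs$pairs
  stopifnot(all(c("entity1", "entity2") %in% names(pairs)))
  ents <- unique(c(pairs$entity1, pairs$entity2))
  bad <- ents[!vapply(ents, function(e) has_any_annotation(store, e), logical(1L))]
  if (length(bad)) {
    stop("entity '", bad[[1L]], "' has no annotation in any aspect; ",
         "apply filter_pairs() before computing features", call. = FALSE)
  }
  aspects <- names(graph$roots)
  out <- data.frame(entity1 = pairs$entity1, entity2 = pairs$entity2,
                    stringsAsFactors = FALSE)
  if ("label" %in% names(pairs)) out$label <- as.integer(pairs$label)
  for (a in aspects) {
    out[[paste0("ss_", a)]] <- mapply(function(p1, p2) {
      entity_similarity(graph, store, p1, p2, a, measure)
    }, pairs$entity1, pairs$entity2, USE.NAMES = FALSE)
  }
  feature_table(out, measure = measure, aspects = aspects,
                checksum = graph_checksum(graph))
}

#' Construct a feature table from a plain data frame
#'
#' @param df data frame with `entity1`, `entity2`, optional `label`, and
#'   `ss_<aspect>` score columns in `[0, 1]`.
#' @param measure similarity measure label.
#' @param aspects aspect labels in column order; inferred from the
#'   `ss_` columns when omitted.
#' @param checksum provenance checksum of the producing graph.
#' @return a data frame of class `feature_table`.
#' @export
feature_table <- function(df, measure = "unknown", aspects = NULL, checksum = NA_character_) {
  ss_cols <- grep("^ss_", names(df), value = TRUE)
  if (length(ss_cols) == 0L) stop("no ss_<aspect> score columns", call. = FALSE)
  if (is.null(aspects)) aspects <- sub("^ss_", "", ss_cols)
  scores <- as.matrix(df[ss_cols])
  if (any(!is.finite(scores)) || any(scores < -1e-12) || any(scores > 1 + 1e-12)) {
    stop("similarity scores must lie in [0, 1]", call. = FALSE)
  }
  structure(df, class = c("feature_table", "data.frame"),
            measure = measure, aspects = aspects, checksum = checksum)
}

#' Extract the per-aspect score matrix of a feature table
#' @param ft a `feature_table`.
#' @return numeric matrix, one column per aspect in table order.
#' @export
feature_matrix <- function(ft) {
  as.matrix(ft[paste0("ss_", attr(ft, "aspects"))])
}

#' Write a feature table as TSV with a provenance header
#'
#' @param ft a `feature_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(ft, path) {
  stopifnot(inherits(ft, "feature_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# measure=%s graph=%s aspects=%s",
                     attr(ft, "measure"), attr(ft, "checksum"),
                     paste(attr(ft, "aspects"), collapse = ",")), con)
  utils::write.table(as.data.frame(ft), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_features()]
#' @param path TSV path.
#' @return a `feature_table`.
#' @export
read_features <- function(path) {
  header <- readLines(path, n = 1L)
  measure <- sub(".*measure=(\\S+).*", "\\1", header)
  checksum <- sub(".*graph=(\\S+).*", "\\1", header)
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  feature_table(df, measure = measure, checksum = checksum)
}
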