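# Ontology container: a multi-rooted is-a DAG partitioned into semantic
# aspects (in the Gene Ontology: biological process, cellular component,
# molecular function), with intrinsic information content per term.

#' Construct an ontology graph from term and edge sets
#'
#' Builds the package's central container: a directed acyclic graph of terms
#' linked by is-a edges, partitioned into aspects. Each aspect is an
#' independent rooted sub-DAG; a root is a term with no parents. Every term
#' must reach exactly one root, and the aspect of a term is the aspect of
#' that root.
#'
#' @param terms character vector of term identifiers.
#' @param edges two-column character matrix or data frame of (child, parent)
#'   is-a edges.
#' @param namespaces optional named character vector mapping term id to a
#'   namespace label; when the namespace of a root is known it is used as
#'   the aspect label, otherwise the root id itself labels the aspect.
#' @param alt_ids optional named character vector mapping alternative ids to
#'   canonical term ids.
#' @return an object of class `ontology_graph` with fields `terms`,
#'   `parents`, `children`, `aspect`, `roots`, `anc` (reflexive ancestor
#'   closure) and `ic` (NA until [compute_ic()] is called).
#' @export
ontology_graph <- function(terms, edges, namespaces = NULL, alt_ids = NULL) {
  terms <- unique(as.character(terms))
  if (length(terms) == 0L) stop("ontology has no terms", call. = FALSE)
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(character(), ncol = 2L)
  }
  storage.mode(edges) <- "character"
  if (ncol(edges) != 2L) stop("`edges` must have two columns (child, parent)", call. = FALSE)
  unknown <- setdiff(c(edges), terms)
  if (length(unknown)) {
    stop("edge references unknown term(s): ", paste(utils::head(unknown, 3L), collapse = ", "),
         call. = FALSE)
  }

  parents <- split(edges[, 2L], factor(edges[, 1L], levels = terms))
  parents <- lapply(parents, unique)
  children <- split(edges[, 1L], factor(edges[, 2L], levels = terms))
  children <- lapply(children, unique)

  # Kahn topological sort; doubles as the cycle check.
  indeg <- vapply(parents, length, integer(1L))
  queue <- terms[indeg == 0L]
  topo <- character(0L)
  indeg_w <- indeg
  while (length(queue)) {
    t <- queue[[1L]]; queue <- queue[-1L]
    topo <- c(topo, t)
    for (ch in children[[t]]) {
      indeg_w[[ch]] <- indeg_w[[ch]] - 1L
      if (indeg_w[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(topo) != length(terms)) {
    bad <- setdiff(terms, topo)
    stop("cycle detected in is-a relation involving term '", bad[[1L]], "'", call. = FALSE)
  }

  root_terms <- terms[indeg == 0L]
  # Reflexive-transitive ancestor closure, filled parents-first.
  anc <- vector("list", length(terms))
  names(anc) <- terms
  for (t in topo) {
    up <- parents[[t]]
    anc[[t]] <- if (length(up)) unique(c(t, unlist(anc[up], use.names = FALSE))) else t
  }

  aspect <- character(length(terms))
  names(aspect) <- terms
  root_label <- vapply(root_terms, function(r) {
    ns <- if (!is.null(namespaces)) namespaces[[r]] else NULL
    if (is.null(ns) || is.na(ns) || !nzchar(ns)) r else ns
  }, character(1L))
  if (anyDuplicated(root_label)) {
    stop("two aspect roots share the namespace label '",
         root_label[duplicated(root_label)][[1L]], "'", call. = FALSE)
  }
  for (t in terms) {
    r <- intersect(anc[[t]], root_terms)
    if (length(r) != 1L) {
      stop("term '", t, "' reaches ", length(r), " aspect roots; expected exactly 1",
           call. = FALSE)
    }
    aspect[[t]] <- root_label[[r]]
  }
  roots <- stats::setNames(root_terms, root_label)

  structure(
    list(terms = terms, parents = parents, children = children,
         aspect = aspect, roots = roots, anc = anc,
         ic = stats::setNames(rep(NA_real_, length(terms)), terms),
         alt_ids = alt_ids %||% stats::setNames(character(0L), character(0L))),
    class = "ontology_graph"
  )
}

#' @export
print.ontology_graph <- function(x, ...) {
  n_edges <- sum(vapply(x$parents, length, integer(1L)))
  cat("<ontology_graph> ", length(x$terms), " terms, ", n_edges, " is-a edges, ",
      length(x$roots), " aspect(s): ", paste(names(x$roots), collapse = ", "),
      if (all(is.na(x$ic))) " (IC not computed)" else "", "\n", sep = "")
  invisible(x)
}

#' Parse an ontology from an OBO flat file
#'
#' Reads `[Term]` stanzas from an OBO 1.2/1.4 file, keeping only the
#' requested relation types (by default only is-a, so part-of and other
#' relationship lines are discarded). Obsolete terms are dropped, and
#' `alt_id` lines are recorded so that annotations using a superseded id
#' can be mapped to the canonical term.
#'
#' @param path path to an OBO file.
#' @param relations character vector of relation names to keep; `"is_a"`
#'   covers the native `is_a:` tag, any other name is matched against
#'   `relationship:` lines.
#' @return an [ontology_graph()].
#' @export
parse_obo <- function(path, relations = "is_a") {
  if (!file.exists(path)) stop("OBO file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  in_term <- FALSE
  cur <- NULL
  terms <- list()
  flush <- function(cur, terms) {
    if (!is.null(cur) && !isTRUE(cur$obsolete) && !is.null(cur$id)) {
      terms[[cur$id]] <- cur
    }
    terms
  }
  for (ln in lines) {
    ln <- sub("\\s*!.*$", "", ln)  # trailing comments
    ln <- trimws(ln)
    if (ln == "[Term]") {
      terms <- flush(cur, terms)
      cur <- list(parents = character(0L), alt = character(0L), obsolete = FALSE)
      in_term <- TRUE
      next
    }
    if (grepl("^\\[", ln)) {  # [Typedef] or other stanza
      terms <- flush(cur, terms)
      cur <- NULL
      in_term <- FALSE
      next
    }
    if (!in_term || !nzchar(ln)) next
    if (grepl("^id:", ln)) {
      cur$id <- trimws(sub("^id:", "", ln))
    } else if (grepl("^name:", ln)) {
      cur$name <- trimws(sub("^name:", "", ln))
    } else if (grepl("^namespace:", ln)) {
      cur$namespace <- trimws(sub("^namespace:", "", ln))
    } else if (grepl("^alt_id:", ln)) {
      cur$alt <- c(cur$alt, trimws(sub("^alt_id:", "", ln)))
    } else if (grepl("^is_obsolete:\\s*true", ln)) {
      cur$obsolete <- TRUE
    } else if (grepl("^is_a:", ln) && "is_a" %in% relations) {
      cur$parents <- c(cur$parents, trimws(sub("^is_a:", "", ln)))
    } else if (grepl("^relationship:", ln)) {
      body <- trimws(sub("^relationship:", "", ln))
      parts <- strsplit(body, "\\s+")[[1L]]
      if (length(parts) >= 2L && parts[[1L]] %in% relations) {
        cur$parents <- c(cur$parents, parts[[2L]])
      }
    }
  }
  terms <- flush(cur, terms)
  if (length(terms) == 0L) stop("no usable [Term] stanzas in ", path, call. = FALSE)

  ids <- names(terms)
  edges <- do.call(rbind, lapply(terms, function(tm) {
    keep <- intersect(tm$parents, ids)  # parents pointing at obsolete terms vanish with them
    if (length(keep)) cbind(tm$id, keep) else NULL
  }))
  if (is.null(edges)) edges <- matrix(character(), ncol = 2L)
  namespaces <- stats::setNames(
    vapply(terms, function(tm) tm$namespace %||% NA_character_, character(1L)), ids)
  alt_pairs <- do.call(rbind, lapply(terms, function(tm) {
    if (length(tm$alt)) cbind(tm$alt, tm$id) else NULL
  }))
  alt_ids <- if (is.null(alt_pairs)) {
    stats::setNames(character(0L), character(0L))
  } else {
    stats::setNames(alt_pairs[, 2L], alt_pairs[, 1L])
  }
  ontology_graph(ids, edges, namespaces = namespaces, alt_ids = alt_ids)
}

#' Write an ontology graph as an OBO flat file
#'
#' Inverse of [parse_obo()] for is-a-only graphs; term and edge sets
#' round-trip exactly.
#'
#' @param graph an `ontology_graph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(graph, path) {
  stopifnot(inherits(graph, "ontology_graph"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (t in graph$terms) {
    writeLines(c(
      "[Term]",
      paste0("id: ", t),
      paste0("name: ", t),
      paste0("namespace: ", graph$aspect[[t]]),
      paste0("is_a: ", graph$parents[[t]]),
      ""
    ), con)
  }
  invisible(path)
}

#' Canonicalize a term id through the graph's alt_id table
#' @keywords internal
#' @noRd
canonical_term <- function(graph, t) {
  if (length(graph$alt_ids) && t %in% names(graph$alt_ids)) graph$alt_ids[[t]] else t
}

#' Ancestors of a term
#'
#' Reflexive-transitive closure over is-a edges: the result contains the
#' term itself, so the most-informative-common-ancestor similarity of a
#' term with itself equals its own information content.
#'
#' @param graph an `ontology_graph`.
#' @param t a term id present in the graph.
#' @return character vector of ancestor term ids (including `t`).
#' @export
ancestors <- function(graph, t) {
  stopifnot(inherits(graph, "ontology_graph"))
  t <- canonical_term(graph, t)
  if (!t %in% graph$terms) stop("unknown term: ", t, call. = FALSE)
  graph$anc[[t]]
}

#' Compute intrinsic information content for every term
#'
#' Seco-style structural IC: with `hypo(t)` the number of descendants of
#' `t` including `t` itself and `maxnodes` the number of terms in the
#' relevant (sub-)ontology,
#' \deqn{IC(t) = 1 - \log(hypo(t) + 1) / \log(maxnodes).}
#' Because `hypo(root) + 1` exceeds `maxnodes`, the root's raw value is
#' slightly negative; it is clamped to 0 by default so the stated [0, 1]
#' range (and hence the SimGIC bounds) holds.
#'
#' @param graph an `ontology_graph`.
#' @param per_aspect if `TRUE` (default), `maxnodes` is the term count of
#'   the term's own aspect sub-ontology; if `FALSE`, the whole graph.
#' @param clamp clamp negative raw values to 0 (default `TRUE`).
#' @return the graph with its `ic` field filled.
#' @export
compute_ic <- function(graph, per_aspect = TRUE, clamp = TRUE) {
  stopifnot(inherits(graph, "ontology_graph"))
  aspect_sizes <- table(graph$aspect)
  if (any(aspect_sizes < 2L)) {
    bad <- names(aspect_sizes)[aspect_sizes < 2L][[1L]]
    stop("aspect '", bad, "' has fewer than 2 terms; IC denominator log(maxnodes) is 0",
         call. = FALSE)
  }
  # hypo(t) = number of terms whose ancestor closure contains t
  # (the closure is reflexive, so every term counts itself).
  hypo <- table(factor(unlist(graph$anc, use.names = FALSE), levels = graph$terms))
  hypo <- stats::setNames(as.integer(hypo), graph$terms)
  maxnodes <- if (per_aspect) {
    as.numeric(aspect_sizes[graph$aspect])
  } else {
    rep(length(graph$terms), length(graph$terms))
  }
  ic <- 1 - log(hypo + 1) / log(maxnodes)
  if (clamp) ic <- pmax(ic, 0)
  graph$ic <- stats::setNames(as.numeric(ic), graph$terms)
  graph
}
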