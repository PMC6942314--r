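# Independent brute-force oracles. These work from the raw term/edge/
# annotation data only, recomputing ancestor sets by naive upward walks on
# every call (no caching, no reuse of the package's closure), so they are
# a genuinely separate route to every similarity value.

# edges as a data.frame(child, parent)
graph_edges_df <- function(graph) {
  rows <- lapply(names(graph$parents), function(t) {
    ps <- graph$parents[[t]]
    if (length(ps)) data.frame(child = t, parent = ps, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) data.frame(child = character(), parent = character()) else out
}

oracle_ancestors <- function(edges, t) {
  res <- t
  frontier <- t
  repeat {
    up <- unique(edges$parent[edges$child %in% frontier])
    new <- setdiff(up, res)
    if (length(new) == 0L) return(res)
    res <- c(res, new)
    frontier <- new
  }
}

# Seco IC table recomputed from scratch: descendant counts by testing, for
# every term, which other terms reach it.
oracle_ic_table <- function(terms, edges, clamp = TRUE) {
  anc_of <- lapply(terms, function(x) oracle_ancestors(edges, x))
  roots <- terms[!terms %in% edges$child]
  aspect <- vapply(seq_along(terms), function(k) {
    intersect(anc_of[[k]], roots)[[1L]]
  }, character(1L))
  names(aspect) <- terms
  ic <- vapply(seq_along(terms), function(k) {
    t <- terms[[k]]
    hypo <- sum(vapply(anc_of, function(a) t %in% a, logical(1L)))
    maxnodes <- sum(aspect == aspect[[t]])
    val <- 1 - log(hypo + 1) / log(maxnodes)
    if (clamp) max(val, 0) else val
  }, numeric(1L))
  names(ic) <- terms
  list(ic = ic, aspect = aspect)
}

oracle_term_sim <- function(edges, ic, t1, t2) {
  common <- intersect(oracle_ancestors(edges, t1), oracle_ancestors(edges, t2))
  max(ic[common])
}

oracle_simgic <- function(edges, ic, set1, set2) {
  if (length(set1) == 0L || length(set2) == 0L) return(0)
  e1 <- unique(unlist(lapply(set1, function(t) oracle_ancestors(edges, t))))
  e2 <- unique(unlist(lapply(set2, function(t) oracle_ancestors(edges, t))))
  den <- sum(ic[union(e1, e2)])
  if (den == 0) return(0)
  sum(ic[intersect(e1, e2)]) / den
}

oracle_resnik_max <- function(edges, ic, set1, set2) {
  if (length(set1) == 0L || length(set2) == 0L) return(0)
  best <- 0
  for (t1 in set1) for (t2 in set2) {
    best <- max(best, oracle_term_sim(edges, ic, t1, t2))
  }
  best
}

oracle_resnik_bma <- function(edges, ic, set1, set2) {
  if (length(set1) == 0L || length(set2) == 0L) return(0)
  best1 <- vapply(set1, function(t1) {
    max(vapply(set2, function(t2) oracle_term_sim(edges, ic, t1, t2), numeric(1L)))
  }, numeric(1L))
  best2 <- vapply(set2, function(t2) {
    max(vapply(set1, function(t1) oracle_term_sim(edges, ic, t1, t2), numeric(1L)))
  }, numeric(1L))
  sum(best1) / (2 * length(set1)) + sum(best2) / (2 * length(set2))
}

# WAF by explicit per-class precision/recall bookkeeping, written as the
# textbook formula rather than the package's count-based scan.
oracle_waf <- function(y_true, y_pred) {
  classes <- sort(unique(y_true))
  fs <- numeric(length(classes))
  support <- numeric(length(classes))
  for (k in seq_along(classes)) {
    cl <- classes[[k]]
    tp <- sum(y_pred == cl & y_true == cl)
    predicted <- sum(y_pred == cl)
    actual <- sum(y_true == cl)
    precision <- if (predicted == 0) 0 else tp / predicted
    recall <- if (actual == 0) 0 else tp / actual
    fs[[k]] <- if (precision + recall == 0) 0 else
      2 * precision * recall / (precision + recall)
    support[[k]] <- actual
  }
  sum(fs * support) / sum(support)
}

# Full enumeration of the weighted-average grid, coded as plain loops over
# triples and thresholds with per-candidate oracle_waf calls.
oracle_grid_search <- function(scores, labels, weight_step = 0.1,
                               threshold_step = 0.05) {
  vals <- seq(0, 1, by = weight_step)
  thresholds <- seq(0, 1, by = threshold_step)
  best <- NULL
  for (w1 in vals) for (w2 in vals) for (w3 in vals) {
    if (w1 + w2 + w3 == 0) next
    s <- (scores[, 1L] * w1 + scores[, 2L] * w2 + scores[, 3L] * w3) / (w1 + w2 + w3)
    for (th in thresholds) {
      v <- oracle_waf(labels, as.integer(s > th))
      if (is.null(best) || v > best$train_waf) {
        best <- list(weights = c(w1, w2, w3), threshold = th, train_waf = v)
      }
    }
  }
  best
}
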