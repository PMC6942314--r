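# Synthetic study generator: multi-aspect ontologies, sparse per-aspect
# annotation sets, and labeled entity pairs driven by a known ground-truth
# combination rule. Everything takes an explicit seed; no global state.

#' Specification of a synthetic study
#'
#' The defaults describe the study conditions the package's experiments
#' use: three GO-like aspects with the process aspect largest, a sparse-ish
#' DAG (each term attaching to up to 3 earlier terms), entities annotated
#' in most aspects with 1-5 direct leaf-biased terms, a positive class
#' defined by the maximum of the BP and CC similarities crossing 0.5, and
#' 5% label noise.
#'
#' @param n_terms_per_aspect named integer vector of terms per aspect
#'   (names are the aspect labels, each at least 2).
#' @param max_parents maximum is-a out-degree of a new term.
#' @param n_entities number of annotated entities.
#' @param direct_terms_per_aspect length-2 integer range of direct terms
#'   drawn per annotated aspect.
#' @param aspect_annotation_prob per-aspect probability that an entity is
#'   annotated in that aspect at all (controls sparsity; lowering one
#'   aspect's value emulates a corpus poor in that aspect's annotations).
#' @param truth_model ground-truth combination rule over the aspect
#'   scores, in the expression language of [parse_model()].
#' @param truth_threshold positive labels are pairs whose truth-model
#'   score strictly exceeds this.
#' @param label_noise probability of flipping each label.
#' @param sampling `"unbalanced"` (negatives drawn uniformly) or
#'   `"balanced"` (per-entity negative occurrence counts greedily matched
#'   to the positive counts).
#' @param n_pairs number of labeled pairs.
#' @param seed default seed for the generators.
#' @return a list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_terms_per_aspect = c(BP = 100L, CC = 80L, MF = 60L),
                           max_parents = 3L,
                           n_entities = 100L,
                           direct_terms_per_aspect = c(1L, 5L),
                           aspect_annotation_prob = c(BP = 0.9, CC = 0.9, MF = 0.8),
                           truth_model = "max(BP, CC)",
                           truth_threshold = 0.5,
                           label_noise = 0.05,
                           sampling = c("unbalanced", "balanced"),
                           n_pairs = 1000L,
                           seed = 1L) {
  sampling <- match.arg(sampling)
  stopifnot(all(n_terms_per_aspect >= 2L), !is.null(names(n_terms_per_aspect)),
            max_parents >= 1L, n_entities >= 2L,
            length(direct_terms_per_aspect) == 2L,
            direct_terms_per_aspect[[1L]] >= 1L,
            direct_terms_per_aspect[[2L]] >= direct_terms_per_aspect[[1L]],
            all(aspect_annotation_prob >= 0), all(aspect_annotation_prob <= 1),
            label_noise >= 0, label_noise <= 1, n_pairs >= 1L)
  if (!identical(sort(names(n_terms_per_aspect)), sort(names(aspect_annotation_prob)))) {
    stop("aspect names of `n_terms_per_aspect` and `aspect_annotation_prob` differ",
         call. = FALSE)
  }
  structure(list(
    n_terms_per_aspect = n_terms_per_aspect,
    max_parents = as.integer(max_parents),
    n_entities = as.integer(n_entities),
    direct_terms_per_aspect = as.integer(direct_terms_per_aspect),
    aspect_annotation_prob = aspect_annotation_prob,
    truth_model = truth_model,
    truth_threshold = truth_threshold,
    label_noise = label_noise,
    sampling = sampling,
    n_pairs = as.integer(n_pairs),
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

#' Generate a multi-aspect random ontology
#'
#' Per aspect, builds a rooted DAG by attaching each new term to 1 to
#' `max_parents` uniformly chosen earlier terms of the same aspect
#' (acyclic by construction). Term ids look like `BP:0000017`.
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer seed (default: the spec's).
#' @return an [ontology_graph()] with IC computed.
#' @export
generate_ontology <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(seed, {
    terms <- character(0L)
    edges <- list()
    namespaces <- character(0L)
    for (a in names(spec$n_terms_per_aspect)) {
      n <- spec$n_terms_per_aspect[[a]]
      ids <- sprintf("%s:%07d", a, seq_len(n))
      for (i in seq_len(n)[-1L]) {
        k <- sample.int(min(spec$max_parents, i - 1L), 1L)
        ps <- if (i == 2L) ids[[1L]] else ids[sample.int(i - 1L, k)]
        edges[[length(edges) + 1L]] <- cbind(ids[[i]], ps)
      }
      terms <- c(terms, ids)
      namespaces <- c(namespaces, stats::setNames(rep(a, n), ids))
    }
    g <- ontology_graph(terms, do.call(rbind, edges), namespaces = namespaces)
    compute_ic(g)
  })
}

#' Generate sparse per-aspect annotation sets
#'
#' Each entity is annotated in each aspect with that aspect's
#' probability; an annotated aspect receives a number of direct terms
#' drawn from the configured range, sampled without replacement with
#' weight proportional to term IC (leaf-biased, so entity similarities
#' spread over \[0, 1\] instead of clustering near 0). Entities that end
#' up with no annotation at all are redrawn.
#'
#' @param graph an `ontology_graph` from [generate_ontology()] (IC
#'   computed).
#' @param spec a [synthetic_spec()].
#' @param seed integer seed.
#' @return an [annotation_store()] over entities `E0001`, `E0002`, ...
#' @export
generate_annotations <- function(graph, spec, seed = spec$seed) {
  stopifnot(inherits(graph, "ontology_graph"), inherits(spec, "synthetic_spec"))
  if (all(is.na(graph$ic))) graph <- compute_ic(graph)
  aspects <- names(spec$n_terms_per_aspect)
  by_aspect <- split(graph$terms, graph$aspect[graph$terms])
  with_seed(seed, {
    draw_entity <- function() {
      buckets <- list()
      for (a in aspects) {
        if (stats::runif(1L) <= spec$aspect_annotation_prob[[a]]) {
          pool <- by_aspect[[a]]
          k <- sample_range(spec$direct_terms_per_aspect[[1L]],
                            spec$direct_terms_per_aspect[[2L]])
          k <- min(k, length(pool))
          w <- graph$ic[pool] + 0.01  # root weight stays positive
          buckets[[a]] <- sample(pool, k, prob = w)
        }
      }
      buckets
    }
    direct <- vector("list", spec$n_entities)
    names(direct) <- sprintf("E%04d", seq_len(spec$n_entities))
    for (i in seq_len(spec$n_entities)) {
      repeat {
        b <- draw_entity()
        if (length(b) > 0L) break
      }
      direct[[i]] <- b
    }
    annotation_store(graph, direct)
  })
}

# Greedy balanced negative sampler: picks negatives so that each entity's
# negative-occurrence count tracks its positive count, preferring pairs
# where both entities still have a deficit, then one, then any.
balanced_negatives <- function(cand, pos_counts, n_needed) {
  deficit <- pos_counts
  chosen <- integer(0L)
  remaining <- seq_len(nrow(cand))
  for (pass in c(2L, 1L, 0L)) {
    if (length(chosen) >= n_needed) break
    for (r in remaining) {
      if (length(chosen) >= n_needed) break
      d1 <- deficit[cand$entity1[[r]]] %||% 0L
      d1 <- if (is.na(d1)) 0L else d1
      d2 <- deficit[cand$entity2[[r]]] %||% 0L
      d2 <- if (is.na(d2)) 0L else d2
      if (sum(c(d1 > 0L, d2 > 0L)) >= pass) {
        chosen <- c(chosen, r)
        if (!is.na(deficit[cand$entity1[[r]]])) {
          deficit[cand$entity1[[r]]] <- deficit[cand$entity1[[r]]] - 1L
        }
        if (!is.na(deficit[cand$entity2[[r]]])) {
          deficit[cand$entity2[[r]]] <- deficit[cand$entity2[[r]]] - 1L
        }
      }
    }
    remaining <- setdiff(remaining, chosen)
  }
  chosen
}

#' Generate labeled pairs from a ground-truth combination rule
#'
#' Samples distinct unordered entity pairs, computes their per-aspect
#' similarities with the chosen measure, labels each pair by whether the
#' truth model's score exceeds the truth threshold, then flips each label
#' with probability `label_noise`. Unbalanced sampling draws negatives
#' uniformly; balanced sampling greedily matches each entity's negative
#' occurrence count to its positive count (emulating degree-balanced
#' negative sets). The returned feature table carries the noisy labels.
#'
#' @param graph an `ontology_graph` with IC computed.
#' @param store an `annotation_store`.
#' @param spec a [synthetic_spec()].
#' @param measure similarity measure for the features.
#' @param seed integer seed.
#' @return list with `dataset` (a `pair_dataset`) and `features` (the
#'   matching `feature_table`).
#' @export
generate_labeled_pairs <- function(graph, store, spec, measure = "SimGIC",
                                   seed = spec$seed) {
  stopifnot(inherits(graph, "ontology_graph"), inherits(store, "annotation_store"),
            inherits(spec, "synthetic_spec"))
  truth <- parse_model(spec$truth_model,
                       var_names = names(spec$n_terms_per_aspect))
  ents <- names(store$direct)
  with_seed(seed, {
    n_ent <- length(ents)
    n_all <- n_ent * (n_ent - 1) / 2
    n_cand <- min(n_all, max(4L * spec$n_pairs, 200L))
    if (n_all <= 5e6) {
      # enumerate the upper triangle and sample rows
      i_all <- rep.int(seq_len(n_ent - 1L), (n_ent - 1L):1L)
      j_all <- unlist(lapply(seq_len(n_ent - 1L), function(k) (k + 1L):n_ent))
      pick <- sample.int(n_all, n_cand)
      i <- i_all[pick]; j <- j_all[pick]
    } else {
      # rejection sampling of distinct unordered pairs
      seen <- character(0L)
      i <- integer(0L); j <- integer(0L)
      while (length(i) < n_cand) {
        a <- sample.int(n_ent, n_cand)
        b <- sample.int(n_ent, n_cand)
        lo <- pmin(a, b); hi <- pmax(a, b)
        ok <- lo < hi
        key <- paste(lo[ok], hi[ok])
        new <- !duplicated(key) & !(key %in% seen)
        i <- c(i, lo[ok][new]); j <- c(j, hi[ok][new])
        seen <- c(seen, key[new])
      }
      i <- i[seq_len(n_cand)]; j <- j[seq_len(n_cand)]
    }
    cand <- data.frame(entity1 = ents[i], entity2 = ents[j],
                       stringsAsFactors = FALSE)
    ft <- compute_features(graph, store, cand, measure)
    raw <- evaluate_model(truth, ft)
    truth_label <- as.integer(raw > spec$truth_threshold)

    pos_idx <- which(truth_label == 1L)
    neg_idx <- which(truth_label == 0L)
    n_pos_want <- min(length(pos_idx), ceiling(spec$n_pairs / 2))
    n_neg_want <- spec$n_pairs - n_pos_want
    if (length(neg_idx) < n_neg_want) {
      stop("candidate pool has too few truth-negative pairs (", length(neg_idx),
           " < ", n_neg_want, "); loosen the truth rule or enlarge the pool",
           call. = FALSE)
    }
    if (n_pos_want < 1L) {
      stop("candidate pool has no truth-positive pairs; the truth threshold is too strict",
           call. = FALSE)
    }
    take_pos <- sample(pos_idx, n_pos_want)
    if (spec$sampling == "unbalanced") {
      take_neg <- sample(neg_idx, n_neg_want)
    } else {
      pos_counts <- table(c(cand$entity1[take_pos], cand$entity2[take_pos]))
      pos_counts <- stats::setNames(as.integer(pos_counts), names(pos_counts))
      negs <- cand[neg_idx, , drop = FALSE]
      shuffled <- sample(seq_along(neg_idx))
      sel <- balanced_negatives(negs[shuffled, , drop = FALSE], pos_counts, n_neg_want)
      take_neg <- neg_idx[shuffled[sel]]
    }
    keep <- c(take_pos, take_neg)
    label <- truth_label[keep]
    flip <- stats::runif(length(keep)) < spec$label_noise
    label[flip] <- 1L - label[flip]

    df <- data.frame(entity1 = cand$entity1[keep], entity2 = cand$entity2[keep],
                     label = label, stringsAsFactors = FALSE)
    dataset <- pair_dataset(df, name = "synthetic")
    out_ft <- ft[keep, , drop = FALSE]
    out_ft$label <- label
    out_ft <- feature_table(as.data.frame(out_ft), measure = measure,
                            aspects = attr(ft, "aspects"),
                            checksum = attr(ft, "checksum"))
    list(dataset = dataset, features = out_ft)
  })
}

#' Uniform-feature synthetic table labeled by a truth rule
#'
#' Draws aspect scores i.i.d. uniform on \[0, 1\], labels each row by the
#' truth rule, and flips labels with the given noise. Used for
#' combination-recovery experiments where the feature distribution itself
#' should be uninformative.
#'
#' @param n number of rows.
#' @param truth_model expression string (see [parse_model()]).
#' @param truth_threshold positive labels score strictly above this.
#' @param label_noise flip probability.
#' @param aspects aspect names.
#' @param seed integer seed.
#' @return a labeled `feature_table` with synthetic entity ids.
#' @export
synthetic_feature_table <- function(n, truth_model = "max(BP, CC)",
                                    truth_threshold = 0.6, label_noise = 0.05,
                                    aspects = c("BP", "CC", "MF"), seed = 1L) {
  truth <- parse_model(truth_model, var_names = aspects)
  with_seed(seed, {
    X <- matrix(stats::runif(n * length(aspects)), n, length(aspects))
    raw <- tree_eval(truth$tree, X)
    label <- as.integer(raw > truth_threshold)
    flip <- stats::runif(n) < label_noise
    label[flip] <- 1L - label[flip]
    df <- data.frame(entity1 = sprintf("U%06da", seq_len(n)),
                     entity2 = sprintf("U%06db", seq_len(n)),
                     label = label, stringsAsFactors = FALSE)
    for (k in seq_along(aspects)) df[[paste0("ss_", aspects[[k]])]] <- X[, k]
    feature_table(df, measure = "synthetic", aspects = aspects)
  })
}

#' Write a synthetic study as standard files
#'
#' Writes the ontology as OBO, the annotations as GAF 2.1 and the pairs
#' as TSV, such that re-reading them through [parse_obo()],
#' [parse_gaf()] and [read_pairs()] reproduces the objects.
#'
#' @param graph an `ontology_graph`.
#' @param store an `annotation_store`.
#' @param dataset a `pair_dataset`.
#' @param directory output directory (created if needed).
#' @return named character vector of the written paths.
#' @export
write_fixture <- function(graph, store, dataset, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    obo = file.path(directory, "ontology.obo"),
    gaf = file.path(directory, "annotations.gaf"),
    pairs = file.path(directory, "pairs.tsv")
  )
  write_obo(graph, paths[["obo"]])
  write_gaf(store, paths[["gaf"]])
  write_pairs(dataset, paths[["pairs"]])
  paths
}
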