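# Generational tree-based GP in the vanilla symbolic-regression style:
# ramped half-and-half initialization, tournament selection on a
# parsimony-penalized RMSE, subtree crossover, subtree / hoist / point
# mutation, and best-ever elitist bookkeeping.

#' Genetic-programming parameters
#'
#' Defaults follow the standard vanilla setup for this task: population
#' 500 evolved for 50 generations over the function set
#' \{+, -, x, protected /, max, min\}, RMSE fitness with a parsimony
#' coefficient of 1e-5, tournament size 20, ramped half-and-half
#' initialization at depths 2-6, crossover probability 0.9 and 0.01 each
#' for subtree, hoist and point mutation, with ephemeral constants drawn
#' uniformly from \[-1, 1\].
#'
#' @param population_size,generations positive integers.
#' @param function_set subset of `add, sub, mul, div, max, min`.
#' @param parsimony_coefficient per-node fitness penalty used during
#'   selection only.
#' @param tournament_size positive integer.
#' @param init_depth integer length-2 range for ramped half-and-half.
#' @param p_crossover,p_subtree_mutation,p_hoist_mutation,p_point_mutation
#'   genetic-operator probabilities; the remainder to 1 is reproduction.
#' @param p_point_replace per-node replacement probability inside point
#'   mutation.
#' @param const_range length-2 numeric range for ephemeral constants, or
#'   `NULL` to disable constants.
#' @param max_depth hard depth cap; offspring exceeding it are replaced by
#'   a copy of their parent (bloat control).
#' @param n_variables number of aspect-score terminals.
#' @param on_single_class `"error"` (default) or `"constant"`: behaviour
#'   when the training labels contain a single class.
#' @return a list of class `gp_params`.
#' @export
gp_params <- function(population_size = 500L,
                      generations = 50L,
                      function_set = GP_OPS,
                      parsimony_coefficient = 1e-5,
                      tournament_size = 20L,
                      init_depth = c(2L, 6L),
                      p_crossover = 0.9,
                      p_subtree_mutation = 0.01,
                      p_hoist_mutation = 0.01,
                      p_point_mutation = 0.01,
                      p_point_replace = 0.05,
                      const_range = c(-1, 1),
                      max_depth = 17L,
                      n_variables = 3L,
                      on_single_class = c("error", "constant")) {
  stopifnot(population_size >= 1L, generations >= 0L,
            all(function_set %in% GP_OPS), length(function_set) >= 1L,
            tournament_size >= 1L, length(init_depth) == 2L,
            init_depth[[1L]] >= 0L, init_depth[[2L]] >= init_depth[[1L]])
  probs <- c(p_crossover, p_subtree_mutation, p_hoist_mutation, p_point_mutation)
  if (any(probs < 0) || sum(probs) > 1 + 1e-12) {
    stop("genetic-operator probabilities must be nonnegative and sum to at most 1",
         call. = FALSE)
  }
  structure(list(
    population_size = as.integer(population_size),
    generations = as.integer(generations),
    function_set = function_set,
    parsimony_coefficient = parsimony_coefficient,
    tournament_size = as.integer(tournament_size),
    init_depth = as.integer(init_depth),
    p_crossover = p_crossover,
    p_subtree_mutation = p_subtree_mutation,
    p_hoist_mutation = p_hoist_mutation,
    p_point_mutation = p_point_mutation,
    p_point_replace = p_point_replace,
    const_range = const_range,
    max_depth = as.integer(max_depth),
    n_variables = as.integer(n_variables),
    on_single_class = match.arg(on_single_class)
  ), class = "gp_params")
}

random_terminal <- function(params) {
  # terminals uniform over the variables plus (when enabled) one ephemeral
  # constant slot
  n_choices <- params$n_variables + if (is.null(params$const_range)) 0L else 1L
  k <- sample.int(n_choices, 1L)
  if (k <= params$n_variables) {
    node_var(k)
  } else {
    node_const(stats::runif(1L, params$const_range[[1L]], params$const_range[[2L]]))
  }
}

random_tree <- function(params, depth, method = c("full", "grow")) {
  method <- match.arg(method)
  build <- function(d) {
    make_leaf <- if (method == "full") {
      d == 0L
    } else {
      # grow: terminal chosen with probability proportional to the
      # terminal share of the primitive set, as in standard grow init
      n_term <- params$n_variables + if (is.null(params$const_range)) 0L else 1L
      d == 0L || stats::runif(1L) < n_term / (n_term + length(params$function_set))
    }
    if (make_leaf) return(random_terminal(params))
    op <- params$function_set[[sample.int(length(params$function_set), 1L)]]
    node_op(op, build(d - 1L), build(d - 1L))
  }
  build(depth)
}

# Preorder node bookkeeping. Crossover/mutation points follow the usual
# Koza convention: function (internal) nodes are picked with 90% weight,
# leaves with 10%, which keeps variation structural instead of endlessly
# swapping terminals.
node_kinds <- function(node) {
  if (is_op(node)) c(TRUE, node_kinds(node$l), node_kinds(node$r)) else FALSE
}

sample_node_index <- function(node) {
  internal <- node_kinds(node)
  w <- ifelse(internal, 0.9 / max(1L, sum(internal)),
              0.1 / max(1L, sum(!internal)))
  sample.int(length(internal), 1L, prob = w)
}

get_subtree <- function(node, idx) {
  env <- new.env(parent = emptyenv())
  env$i <- 0L
  env$found <- NULL
  walk <- function(n) {
    if (!is.null(env$found)) return()
    env$i <- env$i + 1L
    if (env$i == idx) { env$found <- n; return() }
    if (is_op(n)) { walk(n$l); walk(n$r) }
  }
  walk(node)
  env$found
}

replace_subtree <- function(node, idx, replacement) {
  counter <- new.env(parent = emptyenv())
  counter$i <- 0L
  walk <- function(n) {
    counter$i <- counter$i + 1L
    if (counter$i == idx) return(replacement)
    if (!is_op(n)) return(n)
    l <- walk(n$l)
    r <- walk(n$r)
    node_op(n$op, l, r)
  }
  walk(node)
}

crossover_trees <- function(parent, donor) {
  i <- sample_node_index(parent)
  j <- sample_node_index(donor)
  replace_subtree(parent, i, get_subtree(donor, j))
}

subtree_mutate <- function(parent, params) {
  i <- sample_node_index(parent)
  d <- sample_range(params$init_depth[[1L]], params$init_depth[[2L]])
  replace_subtree(parent, i, random_tree(params, d, "grow"))
}

hoist_mutate <- function(parent) {
  i <- sample_node_index(parent)
  sub <- get_subtree(parent, i)
  j <- sample_node_index(sub)
  replace_subtree(parent, i, get_subtree(sub, j))
}

point_mutate <- function(parent, params) {
  walk <- function(n) {
    if (stats::runif(1L) < params$p_point_replace) {
      if (is_op(n)) {
        op <- params$function_set[[sample.int(length(params$function_set), 1L)]]
        return(node_op(op, walk(n$l), walk(n$r)))
      }
      return(random_terminal(params))
    }
    if (is_op(n)) return(node_op(n$op, walk(n$l), walk(n$r)))
    n
  }
  walk(parent)
}

#' Evolve a combination of aspect similarity scores
#'
#' Runs generational GP over expression trees whose leaves are the
#' per-aspect similarity scores, in a regression-like setup: labels are
#' numeric targets and raw RMSE is the fitness, with selection acting on
#' RMSE plus `parsimony_coefficient` times the node count. The best
#' individual ever seen (by penalized fitness) is returned; its reported
#' fitness is the unpenalized RMSE. Deterministic given `seed`.
#'
#' @param train a `feature_table` with a `label` column containing both
#'   classes.
#' @param params a [gp_params()] object.
#' @param seed integer seed controlling the whole run.
#' @param trace if `TRUE`, the returned model carries a `trace` attribute:
#'   a data frame with the best-ever penalized fitness and the population
#'   mean raw fitness after each generation.
#' @return a `gp_model` with training RMSE and provenance filled.
#' @export
evolve <- function(train, params = gp_params(), seed = 1L, trace = FALSE) {
  stopifnot(inherits(train, "feature_table"), inherits(params, "gp_params"))
  if (is.null(train$label)) stop("training table has no labels", call. = FALSE)
  if (nrow(train) == 0L) stop("empty training table", call. = FALSE)
  y <- as.numeric(train$label)
  if (length(unique(y)) < 2L) {
    if (params$on_single_class == "error") {
      stop("training labels contain a single class", call. = FALSE)
    }
    warning("single-class training labels; returning the constant majority model",
            call. = FALSE)
    return(gp_model(node_const(y[[1L]]), fitness = 0, seed = seed, generation = 0L))
  }
  X <- feature_matrix(train)
  if (ncol(X) != params$n_variables) {
    stop("feature table has ", ncol(X), " aspects but params expect ",
         params$n_variables, call. = FALSE)
  }

  with_seed(seed, {
    pop_n <- params$population_size
    depths <- seq(params$init_depth[[1L]], params$init_depth[[2L]])
    pop <- vector("list", pop_n)
    for (i in seq_len(pop_n)) {
      d <- depths[[((i - 1L) %% length(depths)) + 1L]]
      meth <- if (i %% 2L == 0L) "full" else "grow"
      pop[[i]] <- random_tree(params, d, meth)
    }

    score <- function(tree) {
      raw <- tree_eval(tree, X)
      rmse <- sqrt(mean((raw - y)^2))
      c(rmse, rmse + params$parsimony_coefficient * tree_size(tree))
    }
    fit <- vapply(pop, score, numeric(2L))
    best_i <- which.min(fit[2L, ])
    best <- list(tree = pop[[best_i]], rmse = fit[1L, best_i],
                 pen = fit[2L, best_i], gen = 0L)
    hist_best <- best$pen
    hist_mean <- mean(fit[1L, ])

    tournament <- function() {
      cand <- sample.int(pop_n, min(params$tournament_size, pop_n))
      cand[[which.min(fit[2L, cand])]]
    }
    cut_cross <- params$p_crossover
    cut_sub <- cut_cross + params$p_subtree_mutation
    cut_hoist <- cut_sub + params$p_hoist_mutation
    cut_point <- cut_hoist + params$p_point_mutation

    for (gen in seq_len(params$generations)) {
      new_pop <- vector("list", pop_n)
      for (i in seq_len(pop_n)) {
        parent <- pop[[tournament()]]
        u <- stats::runif(1L)
        child <- if (u < cut_cross) {
          crossover_trees(parent, pop[[tournament()]])
        } else if (u < cut_sub) {
          subtree_mutate(parent, params)
        } else if (u < cut_hoist) {
          hoist_mutate(parent)
        } else if (u < cut_point) {
          point_mutate(parent, params)
        } else {
          parent
        }
        if (tree_depth(child) > params$max_depth) child <- parent
        new_pop[[i]] <- child
      }
      pop <- new_pop
      fit <- vapply(pop, score, numeric(2L))
      gi <- which.min(fit[2L, ])
      if (fit[2L, gi] < best$pen) {
        best <- list(tree = pop[[gi]], rmse = fit[1L, gi], pen = fit[2L, gi],
                     gen = gen)
      }
      hist_best <- c(hist_best, best$pen)
      hist_mean <- c(hist_mean, mean(fit[1L, ]))
    }
    out <- gp_model(best$tree, fitness = best$rmse, seed = as.integer(seed),
                    generation = best$gen)
    if (trace) {
      attr(out, "trace") <- data.frame(generation = seq_along(hist_best) - 1L,
                                       best_penalized = hist_best,
                                       mean_rmse = hist_mean)
    }
    out
  })
}
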