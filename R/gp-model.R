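# Expression trees over the aspect-score terminals. Internal nodes are
# binary operators from {add, sub, mul, div (protected), max, min}; leaves
# are aspect variables (X0, X1, X2 by column order, i.e. BP, CC, MF for a
# GO-like graph) or real constants. The same language expresses evolved
# classifiers and the synthetic generator's ground-truth rules.

GP_OPS <- c("add", "sub", "mul", "div", "max", "min")

# |denominator| at or below this returns 1, the usual protected-division
# convention in symbolic regression; keeps every tree total and finite.
DIV_PROTECT_EPS <- 1e-3

node_var <- function(i) list(var = as.integer(i))
node_const <- function(v) list(const = as.numeric(v))
node_op <- function(op, l, r) list(op = op, l = l, r = r)

is_var <- function(n) !is.null(n$var)
is_const <- function(n) !is.null(n$const)
is_op <- function(n) !is.null(n$op)

tree_size <- function(node) {
  if (is_op(node)) 1L + tree_size(node$l) + tree_size(node$r) else 1L
}

tree_depth <- function(node) {
  if (is_op(node)) 1L + max(tree_depth(node$l), tree_depth(node$r)) else 0L
}

tree_equal <- function(a, b) identical(a, b)

check_tree <- function(node) {
  ok <- (is_var(node) && length(node$var) == 1L && node$var >= 1L) ||
    (is_const(node) && length(node$const) == 1L && is.finite(node$const)) ||
    (is_op(node) && node$op %in% GP_OPS && !is.null(node$l) && !is.null(node$r) &&
       check_tree(node$l) && check_tree(node$r))
  if (!ok) stop("malformed expression tree", call. = FALSE)
  TRUE
}

# Vectorized evaluation: X is an n x n_vars numeric matrix.
tree_eval <- function(node, X) {
  if (is_var(node)) return(X[, node$var])
  if (is_const(node)) return(rep.int(node$const, nrow(X)))
  l <- tree_eval(node$l, X)
  r <- tree_eval(node$r, X)
  switch(node$op,
    add = l + r,
    sub = l - r,
    mul = l * r,
    div = { out <- l / r; out[abs(r) <= DIV_PROTECT_EPS] <- 1; out },
    max = pmax(l, r),
    min = pmin(l, r),
    stop("unknown operator: ", node$op, call. = FALSE)
  )
}

apply_op_scalar <- function(op, l, r) {
  switch(op,
    add = l + r, sub = l - r, mul = l * r,
    div = if (abs(r) <= DIV_PROTECT_EPS) 1 else l / r,
    max = max(l, r), min = min(l, r))
}

#' Construct a GP model
#'
#' @param tree an expression tree (see [parse_model()]), validated for
#'   well-formedness.
#' @param fitness raw (unpenalized) RMSE on the training data, if known.
#' @param seed,generation provenance of an evolved model.
#' @return an object of class `gp_model`.
#' @export
gp_model <- function(tree, fitness = NA_real_, seed = NA_integer_,
                     generation = NA_integer_) {
  check_tree(tree)
  structure(list(tree = tree, fitness = fitness, seed = seed,
                 generation = generation),
            class = "gp_model")
}

#' @export
print.gp_model <- function(x, ...) {
  cat("<gp_model> ", model_to_string(x), "\n", sep = "")
  if (!is.na(x$fitness)) cat("  training RMSE: ", format(x$fitness), "\n", sep = "")
  invisible(x)
}

#' Evaluate a model on aspect-score inputs
#'
#' Recursive tree evaluation with protected division (denominators of
#' magnitude at most 1e-3 yield 1).
#'
#' @param model a `gp_model`.
#' @param features numeric vector of aspect scores, or an n x n_aspects
#'   matrix / `feature_table` for vectorized evaluation.
#' @return a numeric scalar or vector of raw (real-valued) outputs.
#' @export
evaluate_model <- function(model, features) {
  stopifnot(inherits(model, "gp_model"))
  if (inherits(features, "feature_table")) features <- feature_matrix(features)
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  out <- tree_eval(model$tree, features)
  if (length(out) == 1L) as.numeric(out) else out
}

#' Classify with the fixed 0.5 cutoff
#'
#' Raw outputs strictly greater than 0.5 are class 1; ties at exactly 0.5
#' resolve to class 0.
#'
#' @param object a `gp_model`.
#' @param features as in [evaluate_model()].
#' @param ... unused.
#' @return integer vector of 0/1 labels.
#' @export
predict.gp_model <- function(object, features, ...) {
  as.integer(evaluate_model(object, features) > 0.5)
}

#' Raw RMSE fitness of a model on a labeled feature table
#'
#' Class labels are treated as numeric regression targets (0 = no
#' interaction, 1 = interaction); fitness is the root mean squared error
#' of the raw model outputs. Selection during evolution uses this plus a
#' parsimony penalty; the value reported here is unpenalized.
#'
#' @param model a `gp_model`.
#' @param ft a `feature_table` with a `label` column.
#' @return nonnegative real.
#' @export
model_rmse <- function(model, ft) {
  stopifnot(inherits(ft, "feature_table"))
  if (is.null(ft$label)) stop("feature table has no labels", call. = FALSE)
  if (nrow(ft) == 0L) stop("empty feature table", call. = FALSE)
  raw <- evaluate_model(model, ft)
  sqrt(mean((raw - ft$label)^2))
}

#' Serialize a model tree to a string
#'
#' @param model a `gp_model` or raw tree.
#' @param style `"prefix"` for the functional form
#'   (`"mul(max(X0, X1), max(X0, X2))"`) or `"infix"` for human reading.
#' @param var_names names for the variables, default X0, X1, X2, ...
#' @return a character scalar.
#' @export
model_to_string <- function(model, style = c("prefix", "infix"), var_names = NULL) {
  style <- match.arg(style)
  tree <- if (inherits(model, "gp_model")) model$tree else model
  fmt <- function(n) {
    if (is_var(n)) {
      if (!is.null(var_names)) var_names[[n$var]] else paste0("X", n$var - 1L)
    } else if (is_const(n)) {
      # prefix is the machine-readable form: full precision round-trips
      # through parse_model(); infix is for human eyes
      format(n$const, digits = if (style == "prefix") 17 else 6)
    } else if (style == "prefix") {
      paste0(n$op, "(", fmt(n$l), ", ", fmt(n$r), ")")
    } else {
      sym <- c(add = "+", sub = "-", mul = "*", div = "/")
      if (n$op %in% names(sym)) {
        paste0("(", fmt(n$l), " ", sym[[n$op]], " ", fmt(n$r), ")")
      } else {
        paste0(n$op, "(", fmt(n$l), ", ", fmt(n$r), ")")
      }
    }
  }
  fmt(tree)
}

#' Export a model tree as a JSON string
#' @param model a `gp_model`.
#' @return a JSON character scalar.
#' @export
model_to_json <- function(model) {
  stopifnot(inherits(model, "gp_model"))
  jsonlite::toJSON(model$tree, auto_unbox = TRUE, digits = NA)
}

#' Parse the functional expression language
#'
#' Recursive-descent parser for trees written as nested calls over the
#' operators add, sub, mul, div, max, min, the variables `X0`, `X1`, `X2`
#' (aliases `BP`, `CC`, `MF`), and numeric constants, e.g.
#' `"mul(max(X0, X1), max(X0, X2))"` or `"max(BP, CC)"`. This is also the
#' language of the synthetic generator's ground-truth rules.
#'
#' @param text expression string.
#' @param var_names variable alias table, position = variable index.
#' @return a `gp_model`.
#' @export
parse_model <- function(text, var_names = c("BP", "CC", "MF")) {
  toks <- regmatches(text, gregexpr(
    "[A-Za-z_][A-Za-z0-9_]*|-?[0-9]+\\.?[0-9]*([eE][-+]?[0-9]+)?|[(),]", text))[[1L]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else ""
  take <- function(expect = NULL) {
    if (pos > length(toks)) stop("unexpected end of expression: ", text, call. = FALSE)
    tk <- toks[[pos]]; pos <<- pos + 1L
    if (!is.null(expect) && tk != expect) {
      stop("expected '", expect, "' but found '", tk, "' in: ", text, call. = FALSE)
    }
    tk
  }
  parse_expr <- function() {
    tk <- take()
    if (tk %in% GP_OPS) {
      take("(")
      l <- parse_expr()
      take(",")
      r <- parse_expr()
      take(")")
      return(node_op(tk, l, r))
    }
    if (grepl("^X[0-9]+$", tk)) return(node_var(as.integer(sub("^X", "", tk)) + 1L))
    if (tk %in% var_names) return(node_var(match(tk, var_names)))
    if (grepl("^-?[0-9.]", tk)) return(node_const(as.numeric(tk)))
    stop("unknown token '", tk, "' in expression: ", text, call. = FALSE)
  }
  tree <- parse_expr()
  if (pos <= length(toks)) {
    stop("trailing input after expression: ", paste(toks[pos:length(toks)], collapse = " "),
         call. = FALSE)
  }
  gp_model(tree)
}

# One bottom-up simplification pass.
simplify_node <- function(n) {
  if (!is_op(n)) return(n)
  l <- simplify_node(n$l)
  r <- simplify_node(n$r)
  if (is_const(l) && is_const(r)) {
    return(node_const(apply_op_scalar(n$op, l$const, r$const)))
  }
  const_is <- function(x, v) is_const(x) && isTRUE(all.equal(x$const, v))
  switch(n$op,
    add = {
      if (const_is(l, 0)) return(r)
      if (const_is(r, 0)) return(l)
    },
    sub = {
      if (const_is(r, 0)) return(l)
      if (tree_equal(l, r)) return(node_const(0))
    },
    mul = {
      if (const_is(l, 1)) return(r)
      if (const_is(r, 1)) return(l)
      if (const_is(l, 0) || const_is(r, 0)) return(node_const(0))
    },
    div = {
      if (const_is(r, 1)) return(l)
      # div(x, x) is 1 for |x| > eps and 1 by protection otherwise
      if (tree_equal(l, r)) return(node_const(1))
    },
    max = ,
    min = {
      if (tree_equal(l, r)) return(l)
    }
  )
  node_op(n$op, l, r)
}

#' Simplify a model conservatively
#'
#' Applies identity and annihilator rules, constant folding (under the
#' protected-division semantics), self-cancellation (`x - x`, `x / x`) and
#' max/min idempotence, repeated to a fixed point. Distribution laws over
#' max/min are deliberately not applied, so the rewrite stays verifiable
#' by random probing: the simplified tree is pointwise equal to the
#' original on the input domain.
#'
#' @param model a `gp_model`.
#' @return a simplified `gp_model` (fitness and provenance carried over).
#' @export
simplify_model <- function(model) {
  stopifnot(inherits(model, "gp_model"))
  tree <- model$tree
  repeat {
    new <- simplify_node(tree)
    if (tree_equal(new, tree)) break
    tree <- new
  }
  gp_model(tree, fitness = model$fitness, seed = model$seed,
           generation = model$generation)
}

#' Length and variable frequencies of a model
#'
#' Length is the total node count of the tree; frequencies are each
#' variable's share of the variable-leaf occurrences (summing to 1 when
#' any variable occurs). Models are conventionally simplified first, so
#' redundant code does not inflate the statistics.
#'
#' @param model a `gp_model`.
#' @param n_vars number of variables the frequency table covers.
#' @param var_names optional names for the frequency vector.
#' @return list with `length`, `variable_frequency`, and `constant_only`
#'   (TRUE when no variable occurs at all).
#' @export
model_stats <- function(model, n_vars = 3L, var_names = NULL) {
  stopifnot(inherits(model, "gp_model"))
  counts <- integer(n_vars)
  walk <- function(n) {
    if (is_var(n)) {
      counts[n$var] <<- counts[n$var] + 1L
    } else if (is_op(n)) {
      walk(n$l); walk(n$r)
    }
  }
  walk(model$tree)
  total <- sum(counts)
  freq <- if (total > 0L) counts / total else rep(0, n_vars)
  names(freq) <- var_names %||% paste0("X", seq_len(n_vars) - 1L)
  list(length = tree_size(model$tree), variable_frequency = freq,
       constant_only = total == 0L)
}
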