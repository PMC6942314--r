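#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# uniform draw from lo:hi that is safe when lo == hi (base sample() would
# treat the length-1 vector as 1:n)
sample_range <- function(lo, hi) {
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

#' Evaluate an expression with a local RNG seed
#'
#' Saves and restores the global RNG state so that seeded package
#' operations never leak into, or depend on, the caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# Polynomial rolling hash over a string (modulo 2^31, exact in doubles);
# used for provenance checksums so that a feature table can record which
# graph produced it without a heavy digest dependency.
fnv1a <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 17
  for (b in bytes) {
    h <- (h * 31 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

#' Checksum of an ontology graph
#'
#' A short hex digest of the sorted term and edge sets, recorded in feature
#' table headers and reports for provenance.
#'
#' @param graph an `ontology_graph`.
#' @return a character scalar.
#' @export
graph_checksum <- function(graph) {
  stopifnot(inherits(graph, "ontology_graph"))
  edges <- sort(unlist(lapply(names(graph$parents), function(t) {
    if (length(graph$parents[[t]])) paste(t, graph$parents[[t]], sep = ">")
    else character()
  }), use.names = FALSE))
  fnv1a(paste(c(sort(graph$terms), edges), collapse = "|"))
}
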