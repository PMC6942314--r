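# Annotation store: entity -> aspect -> set of directly annotated terms,
# bound to the ontology graph the terms belong to.

#' Construct an annotation store
#'
#' @param graph the `ontology_graph` the annotation terms belong to.
#' @param direct named list: entity id -> named list: aspect -> character
#'   vector of term ids. Terms must exist in `graph` and sit in the aspect
#'   bucket they are filed under.
#' @return an object of class `annotation_store`.
#' @export
annotation_store <- function(graph, direct) {
  stopifnot(inherits(graph, "ontology_graph"))
  for (e in names(direct)) {
    for (a in names(direct[[e]])) {
      ts <- direct[[e]][[a]]
      bad <- setdiff(ts, graph$terms)
      if (length(bad)) {
        stop("entity '", e, "': term '", bad[[1L]], "' not in the referenced graph",
             call. = FALSE)
      }
      mis <- ts[graph$aspect[ts] != a]
      if (length(mis)) {
        stop("entity '", e, "': term '", mis[[1L]], "' filed under aspect '", a,
             "' but belongs to '", graph$aspect[[mis[[1L]]]], "'", call. = FALSE)
      }
    }
  }
  structure(
    list(direct = direct, graph = graph, graph_ref = graph_checksum(graph)),
    class = "annotation_store"
  )
}

#' @export
print.annotation_store <- function(x, ...) {
  cat("<annotation_store> ", length(x$direct), " entities, graph ", x$graph_ref, "\n", sep = "")
  invisible(x)
}

#' Parse a GAF 2.x annotation file
#'
#' Reads tab-separated gene-association records. Records carrying a NOT
#' qualifier are excluded (they assert the absence of a function), and
#' records whose term is absent from the graph, even via `alt_id`, are
#' dropped with a reported count. The aspect of each kept term is taken
#' from the graph, not from the GAF aspect column.
#'
#' @param path path to a GAF file.
#' @param graph the `ontology_graph` terms are resolved against.
#' @param exclude_not drop NOT-qualified records (default `TRUE`).
#' @param evidence_codes optional character vector; when given, only
#'   records with one of these evidence codes are kept. Default `NULL`
#'   keeps every evidence code.
#' @return an [annotation_store()].
#' @export
parse_gaf <- function(path, graph, exclude_not = TRUE, evidence_codes = NULL) {
  if (!file.exists(path)) stop("GAF file not found: ", path, call. = FALSE)
  stopifnot(inherits(graph, "ontology_graph"))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^!", lines) & nzchar(lines)]
  n_malformed <- 0L
  n_dropped <- 0L
  recs <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 9L || !nzchar(f[[2L]]) || !nzchar(f[[5L]])) {
      n_malformed <- n_malformed + 1L
      next
    }
    if (exclude_not && grepl("(^|\\|)NOT($|\\|)", f[[4L]])) next
    if (!is.null(evidence_codes) && !(f[[7L]] %in% evidence_codes)) next
    term <- canonical_term(graph, f[[5L]])
    if (!term %in% graph$terms) {
      n_dropped <- n_dropped + 1L
      next
    }
    recs[[length(recs) + 1L]] <- c(f[[2L]], term)
  }
  if (n_malformed > 0L) warning(n_malformed, " malformed GAF line(s) skipped", call. = FALSE)
  if (n_dropped > 0L) {
    message("parse_gaf: dropped ", n_dropped, " record(s) with terms absent from the graph")
  }
  if (length(recs) == 0L) stop("no usable annotation records in ", path, call. = FALSE)
  m <- do.call(rbind, recs)
  direct <- lapply(split(m[, 2L], m[, 1L]), function(ts) {
    ts <- unique(ts)
    split(ts, graph$aspect[ts])
  })
  annotation_store(graph, direct)
}

#' Write an annotation store as a GAF 2.1 file
#'
#' Inverse of [parse_gaf()]; annotation sets round-trip exactly. Synthetic
#' aspect labels are written to the GAF aspect column as-is (the parser
#' reassigns aspects from the graph anyway).
#'
#' @param store an `annotation_store`.
#' @param path output file path.
#' @param db database label for column 1.
#' @return `path`, invisibly.
#' @export
write_gaf <- function(store, path, db = "SYN") {
  stopifnot(inherits(store, "annotation_store"))
  aspect_letter <- c(BP = "P", CC = "C", MF = "F")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("!gaf-version: 2.1", con)
  today <- format(Sys.Date(), "%Y%m%d")
  for (e in names(store$direct)) {
    for (a in names(store$direct[[e]])) {
      asp <- if (a %in% names(aspect_letter)) aspect_letter[[a]] else a
      for (t in store$direct[[e]][[a]]) {
        writeLines(paste(db, e, e, "", t, paste0(db, ":0000001"), "IEA", "",
                         asp, "", "", "protein", "taxon:0", today, db, "", "",
                         sep = "\t"), con)
      }
    }
  }
  invisible(path)
}

#' Direct or extended annotations of an entity in one aspect
#'
#' Extended mode closes the direct set under ancestors (direct and
#' inherited annotations), which is what the IC-weighted Jaccard measure
#' consumes. Unknown entities yield an empty set so the pair filter can be
#' applied downstream without special cases.
#'
#' @param store an `annotation_store`.
#' @param entity entity id.
#' @param aspect aspect label.
#' @param mode `"direct"` or `"extended"`.
#' @return character vector of term ids (possibly empty).
#' @export
annotations <- function(store, entity, aspect, mode = c("direct", "extended")) {
  stopifnot(inherits(store, "annotation_store"))
  mode <- match.arg(mode)
  direct <- store$direct[[entity]][[aspect]]
  if (is.null(direct) || length(direct) == 0L) return(character(0L))
  if (mode == "direct") return(direct)
  unique(unlist(store$graph$anc[direct], use.names = FALSE))
}

# TRUE for entities carrying at least one direct annotation in any aspect.
has_any_annotation <- function(store, entity) {
  buckets <- store$direct[[entity]]
  !is.null(buckets) && any(vapply(buckets, length, integer(1L)) > 0L)
}
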