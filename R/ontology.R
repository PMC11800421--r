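#' Construct a disease-ontology graph
#'
#' An `ontology_graph` holds the disease DAG that every panel-expansion method
#' walks: terms (diseases) connected by child-to-parent `subClassOf` edges.
#' All traversal in this package is upward (towards more general diseases)
#' unless stated otherwise.
#'
#' @param terms A data frame with columns `id` (unique, non-empty CURIE-style
#'   identifiers) and optionally `label`. Terms referenced only in `edges` are
#'   added automatically with an empty label.
#' @param edges A data frame with columns `child` and `parent`, one row per
#'   direct `subClassOf` assertion.
#' @param check If `TRUE` (default), refuse to build a cyclic graph. Set to
#'   `FALSE` only to build a graph you intend to pass to
#'   [validate_ontology()].
#'
#' @return An object of class `ontology_graph`: a list with tibbles `terms`
#'   and `edges`, plus precomputed parent/child adjacency used by the
#'   traversal functions.
#' @seealso [read_ontology()], [ontology_parents()], [ancestors_at_distance()]
#' @export
ontology_graph <- function(terms, edges = NULL, check = TRUE) {
  terms <- tibble::as_tibble(terms)
  if (!"id" %in% names(terms)) {
    stop("`terms` must have an `id` column", call. = FALSE)
  }
  if (!"label" %in% names(terms)) terms$label <- ""
  terms$id <- as.character(terms$id)
  terms$label <- dplyr::coalesce(as.character(terms$label), "")
  if (any(!nzchar(terms$id))) {
    stop("term ids must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(terms$id)) {
    dup <- unique(terms$id[duplicated(terms$id)])
    stop("duplicate term ids: ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }

  if (is.null(edges)) {
    edges <- tibble::tibble(child = character(), parent = character())
  }
  edges <- tibble::as_tibble(edges)
  if (!all(c("child", "parent") %in% names(edges))) {
    stop("`edges` must have `child` and `parent` columns", call. = FALSE)
  }
  edges <- dplyr::distinct(
    tibble::tibble(child = as.character(edges$child),
                   parent = as.character(edges$parent))
  )
  # terms referenced in edges but not declared are materialised
  referenced <- setdiff(unique(c(edges$child, edges$parent)), terms$id)
  if (length(referenced)) {
    terms <- dplyr::bind_rows(
      terms, tibble::tibble(id = referenced, label = "")
    )
  }
  terms <- dplyr::arrange(terms, .data$id)
  edges <- dplyr::arrange(edges, .data$child, .data$parent)

  g <- structure(
    list(
      terms = terms,
      edges = edges,
      parents_of = split_adjacency(edges$child, edges$parent, terms$id),
      children_of = split_adjacency(edges$parent, edges$child, terms$id)
    ),
    class = "ontology_graph"
  )

  if (check) {
    cyc <- find_cycle(g)
    if (!is.null(cyc)) {
      stop("ontology is cyclic: ", paste(cyc, collapse = " -> "),
           call. = FALSE)
    }
  }
  g
}

# named list id -> sorted character vector of neighbours (empty for missing)
split_adjacency <- function(from, to, ids) {
  adj <- lapply(split(to, factor(from, levels = ids)), function(x) sort(unique(x)))
  names(adj) <- ids
  adj
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat("<ontology_graph> ", nrow(x$terms), " terms, ", nrow(x$edges),
      " subClassOf edges, ", sum(lengths(x$parents_of) == 0), " root(s)\n",
      sep = "")
  invisible(x)
}

n_terms <- function(graph) nrow(graph$terms)

#' Term identifiers of an ontology graph
#'
#' @param graph An [ontology_graph()].
#' @return Character vector of term ids in lexicographic order.
#' @export
term_ids <- function(graph) graph$terms$id

#' Root terms of an ontology graph
#'
#' Roots are terms with no `subClassOf` parent. A disease ontology subset may
#' have several.
#'
#' @inheritParams term_ids
#' @return Character vector of root ids, sorted.
#' @export
ontology_roots <- function(graph) {
  sort(names(graph$parents_of)[lengths(graph$parents_of) == 0])
}

assert_term <- function(graph, term) {
  if (length(term) != 1L || !is.character(term)) {
    stop("`term` must be a single character id", call. = FALSE)
  }
  if (!term %in% graph$terms$id) {
    stop("unknown term: ", term, call. = FALSE)
  }
  invisible(term)
}

#' Direct parents of a term
#'
#' Returns the direct `subClassOf` targets of a term: the one-level-up
#' ancestors that the 1UAP/1UMP roll-ups select among.
#'
#' @inheritParams term_ids
#' @param term A single term id present in the graph.
#' @return Sorted character vector of parent ids; empty for a root.
#' @export
ontology_parents <- function(graph, term) {
  assert_term(graph, term)
  graph$parents_of[[term]]
}

#' Direct children of a term
#'
#' @inheritParams ontology_parents
#' @return Sorted character vector of child ids; empty for a leaf.
#' @export
ontology_children <- function(graph, term) {
  assert_term(graph, term)
  graph$children_of[[term]]
}

#' Ancestors at an exact upward distance
#'
#' Returns every term reachable from `term` by exactly `n` `subClassOf` steps
#' along at least one upward path. This is the ancestor set the fixed-level
#' roll-ups (1UAP/2UAP and their minimum-path variants) select among.
#'
#' Paths shorter than `n` (those that hit a root first) are handled by
#' `fallback`: with `"deepest"` (the default used by the panel methods) such a
#' path contributes its terminal root, so the result is never empty; with
#' `"strict"` it contributes nothing.
#'
#' @inheritParams ontology_parents
#' @param n Non-negative integer number of upward steps; `n = 0` returns the
#'   term itself.
#' @param fallback `"deepest"` or `"strict"` (see Details).
#' @return Sorted character vector of term ids.
#' @export
ancestors_at_distance <- function(graph, term, n,
                                  fallback = c("deepest", "strict")) {
  assert_term(graph, term)
  fallback <- match.arg(fallback)
  if (length(n) != 1L || is.na(n) || n < 0 || n != floor(n)) {
    stop("`n` must be a single non-negative integer", call. = FALSE)
  }
  frontier <- term
  stalled <- character()
  steps <- 0L
  while (steps < n && length(frontier)) {
    at_root <- frontier[lengths(graph$parents_of[frontier]) == 0]
    stalled <- union(stalled, at_root)
    frontier <- unique(unlist(graph$parents_of[frontier], use.names = FALSE))
    if (is.null(frontier)) frontier <- character()
    steps <- steps + 1L
  }
  out <- frontier
  if (fallback == "deepest") out <- union(out, stalled)
  sort(out)
}

#' All ancestors of a term
#'
#' Every term reachable upward from `term`, including `term` itself.
#'
#' @inheritParams ontology_parents
#' @return Sorted character vector of term ids.
#' @export
ontology_ancestors <- function(graph, term) {
  assert_term(graph, term)
  seen <- character()
  frontier <- term
  while (length(frontier)) {
    seen <- c(seen, frontier)
    frontier <- setdiff(
      unique(unlist(graph$parents_of[frontier], use.names = FALSE)), seen
    )
  }
  sort(unique(seen))
}

# Kahn's algorithm over child->parent edges; returns NULL for a DAG, or one
# cycle as a character vector of ids.
find_cycle <- function(graph) {
  ids <- graph$terms$id
  edges <- graph$edges
  # dangling parent refs are a validation finding, not part of cycle search
  edges <- edges[edges$child %in% ids & edges$parent %in% ids, ]
  parents_of <- lapply(graph$parents_of[ids], function(p) intersect(p, ids))
  indeg <- stats::setNames(integer(length(ids)), ids)
  tab <- table(edges$parent)
  indeg[names(tab)] <- as.integer(tab)
  queue <- names(indeg)[indeg == 0L]
  removed <- 0L
  while (length(queue)) {
    v <- queue[[1]]
    queue <- queue[-1]
    removed <- removed + 1L
    for (p in parents_of[[v]]) {
      indeg[[p]] <- indeg[[p]] - 1L
      if (indeg[[p]] == 0L) queue <- c(queue, p)
    }
  }
  if (removed == length(ids)) return(NULL)
  # walk within the residual (cyclic) subgraph until a node repeats
  residual <- names(indeg)[indeg > 0L]
  if (!length(residual)) {
    # self-loops are rejected at construction, but guard anyway
    residual <- ids
  }
  v <- residual[[1]]
  path <- character()
  while (!v %in% path) {
    path <- c(path, v)
    nxt <- intersect(graph$parents_of[[v]], residual)
    if (!length(nxt)) nxt <- intersect(graph$parents_of[[v]], ids)
    v <- nxt[[1]]
  }
  path[which(path == v)[1]:length(path)]
}

#' Topological order of the ontology (children before parents)
#'
#' @inheritParams term_ids
#' @return Character vector of all term ids such that every child precedes all
#'   of its parents. Errors if the graph is cyclic.
#' @keywords internal
topological_order <- function(graph) {
  ids <- graph$terms$id
  indeg <- stats::setNames(integer(length(ids)), ids)
  tab <- table(graph$edges$parent)
  indeg[names(tab)] <- as.integer(tab)
  queue <- sort(names(indeg)[indeg == 0L])
  out <- character(length(ids))
  i <- 0L
  while (length(queue)) {
    v <- queue[[1]]
    queue <- queue[-1]
    i <- i + 1L
    out[[i]] <- v
    for (p in graph$parents_of[[v]]) {
      indeg[[p]] <- indeg[[p]] - 1L
      if (indeg[[p]] == 0L) queue <- c(queue, p)
    }
  }
  if (i != length(ids)) stop("ontology is cyclic", call. = FALSE)
  out
}

#' Read a disease ontology from file
#'
#' Two dialects are supported:
#'
#' * `"edge_tsv"`: a tab-separated file with header
#'   `child_id<TAB>parent_id` and an optional third column `child_label`.
#'   Lines starting with `#` are comments. A row with an empty `parent_id`
#'   declares an isolated term (no edge).
#' * `"obo_json"`: OBO Graph JSON as produced by standard ontology tooling.
#'   Only nodes of type `CLASS` and edges with predicate `is_a` /
#'   `rdfs:subClassOf` are ingested; obsolete terms and other edge types are
#'   skipped and counted (see the `skipped` attribute of the result).
#'
#' @param path Path to the ontology file.
#' @param format `"auto"` (infer from extension: `.json` means OBO Graph
#'   JSON, anything else edge TSV), `"edge_tsv"`, or `"obo_json"`.
#' @return An [ontology_graph()]. Errors if the file is unreadable, malformed,
#'   or describes a cyclic graph.
#' @export
read_ontology <- function(path, format = c("auto", "edge_tsv", "obo_json")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("ontology file not found: ", path, call. = FALSE)
  }
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "obo_json" else "edge_tsv"
  }
  switch(format,
    edge_tsv = read_ontology_edge_tsv(path),
    obo_json = read_ontology_obo_json(path)
  )
}

read_ontology_edge_tsv <- function(path) {
  tbl <- readr::read_tsv(
    path, comment = "#", col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  required <- c("child_id", "parent_id")
  if (!all(required %in% names(tbl))) {
    stop("edge TSV ", path, " must have columns child_id, parent_id",
         call. = FALSE)
  }
  tbl$child_id <- trimws(dplyr::coalesce(tbl$child_id, ""))
  tbl$parent_id <- trimws(dplyr::coalesce(tbl$parent_id, ""))
  bad <- which(!nzchar(tbl$child_id))
  if (length(bad)) {
    stop("edge TSV ", path, ": empty child_id at data row ", bad[1],
         call. = FALSE)
  }
  labels <- if ("child_label" %in% names(tbl)) {
    dplyr::coalesce(tbl$child_label, "")
  } else {
    rep("", nrow(tbl))
  }
  terms <- tibble::tibble(id = tbl$child_id, label = labels)
  terms <- terms[!duplicated(terms$id) | nzchar(terms$label), ]
  terms <- terms[!duplicated(terms$id), ]
  has_edge <- nzchar(tbl$parent_id)
  edges <- tibble::tibble(child = tbl$child_id[has_edge],
                          parent = tbl$parent_id[has_edge])
  ontology_graph(terms, edges)
}

read_ontology_obo_json <- function(path) {
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("malformed OBO Graph JSON ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  graphs <- doc$graphs
  if (is.null(graphs) || !length(graphs)) {
    stop("OBO Graph JSON ", path, " contains no graphs", call. = FALSE)
  }
  gdoc <- graphs[[1]]
  n_obsolete <- 0L
  n_other_edges <- 0L

  nodes <- gdoc$nodes %||% list()
  keep <- purrr::map(nodes, function(nd) {
    type <- nd$type %||% "CLASS"
    if (!identical(type, "CLASS")) return(NULL)
    if (isTRUE(nd$meta$deprecated)) {
      n_obsolete <<- n_obsolete + 1L
      return(NULL)
    }
    tibble::tibble(id = curieify(nd$id), label = nd$lbl %||% "")
  })
  terms <- dplyr::bind_rows(purrr::compact(keep))
  if (!nrow(terms)) stop("OBO Graph JSON ", path, ": no CLASS nodes", call. = FALSE)

  edge_rows <- purrr::map(gdoc$edges %||% list(), function(e) {
    pred <- e$pred %||% ""
    if (!pred %in% c("is_a", "rdfs:subClassOf", "subClassOf")) {
      n_other_edges <<- n_other_edges + 1L
      return(NULL)
    }
    tibble::tibble(child = curieify(e$sub), parent = curieify(e$obj))
  })
  edges <- dplyr::bind_rows(purrr::compact(edge_rows))
  # drop edges touching skipped (obsolete / non-CLASS) nodes
  if (nrow(edges)) {
    edges <- edges[edges$child %in% terms$id & edges$parent %in% terms$id, ]
  }
  g <- ontology_graph(terms, edges)
  attr(g, "skipped") <- c(obsolete_terms = n_obsolete,
                          non_subclass_edges = n_other_edges)
  g
}

# OBO PURLs like http://purl.obolibrary.org/obo/MONDO_0000001 -> MONDO:0000001
curieify <- function(id) {
  if (is.null(id)) return("")
  if (grepl("^https?://", id)) {
    tail <- sub(".*[/#]", "", id)
    if (grepl("^[A-Za-z0-9]+_[A-Za-z0-9]+$", tail)) {
      return(sub("_", ":", tail))
    }
    return(tail)
  }
  id
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an ontology graph as an edge-list TSV
#'
#' Inverse of [read_ontology()]'s `edge_tsv` dialect: every term gets at least
#' one row (isolated terms get an empty `parent_id`), and output order is
#' lexicographic so identical graphs serialize identically.
#'
#' @inheritParams term_ids
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ontology <- function(graph, path) {
  edges <- graph$edges
  isolated <- setdiff(graph$terms$id, edges$child)
  labels <- stats::setNames(graph$terms$label, graph$terms$id)
  rows <- dplyr::bind_rows(
    tibble::tibble(child_id = edges$child, parent_id = edges$parent),
    tibble::tibble(child_id = isolated, parent_id = "")
  )
  rows$child_label <- unname(labels[rows$child_id])
  rows <- dplyr::arrange(rows, .data$child_id, .data$parent_id)
  readr::write_tsv(rows, path, progress = FALSE)
  invisible(path)
}

#' Validate an ontology graph
#'
#' Reports structural problems instead of raising: cycles (as id sequences)
#' and dangling parent references (edges whose parent id resolves to no term).
#' A graph built by [ontology_graph()] or [read_ontology()] cannot contain
#' dangling references (referenced terms are materialised), but graphs
#' assembled by hand or with `check = FALSE` can.
#'
#' @inheritParams term_ids
#' @return A list of class `ontology_validation` with fields `n_terms`,
#'   `n_edges`, `n_roots`, `cycles` (list of character vectors) and
#'   `dangling_parent_refs` (tibble with columns `child`, `parent`).
#' @export
validate_ontology <- function(graph) {
  known <- graph$terms$id
  dangling <- graph$edges[!graph$edges$parent %in% known, c("child", "parent")]
  cyc <- find_cycle(graph)
  structure(
    list(
      n_terms = nrow(graph$terms),
      n_edges = nrow(graph$edges),
      n_roots = sum(lengths(graph$parents_of) == 0),
      cycles = if (is.null(cyc)) list() else list(cyc),
      dangling_parent_refs = tibble::as_tibble(dangling)
    ),
    class = "ontology_validation"
  )
}

#' @export
print.ontology_validation <- function(x, ...) {
  cat("<ontology_validation>\n")
  cat("  terms:  ", x$n_terms, "\n", sep = "")
  cat("  edges:  ", x$n_edges, "\n", sep = "")
  cat("  roots:  ", x$n_roots, "\n", sep = "")
  if (length(x$cycles)) {
    cat("  cycles: ", paste(x$cycles[[1]], collapse = " -> "), "\n", sep = "")
  } else {
    cat("  cycles: none\n")
  }
  cat("  dangling parent refs: ", nrow(x$dangling_parent_refs), "\n", sep = "")
  invisible(x)
}
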