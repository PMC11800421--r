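#' Read gene-disease associations from TSV
#'
#' Expects a tab-separated file with header
#' `disease_id<TAB>gene_id<TAB>source` (`#` lines are comments). Disease ids
#' may be ontology CURIEs (e.g. `MONDO:0010011`) or foreign identifiers from
#' the curated sources (e.g. `OMIM:100100`, `ORPHA:558`) to be resolved later
#' with [resolve_identifiers()]. Duplicate (disease, gene) pairs are merged
#' into one record whose `source` concatenates the distinct tags with `;`.
#'
#' @param path Path to the association TSV.
#' @return A tibble with columns `disease_id`, `gene_id`, `source`, one row
#'   per unique pair, in lexicographic order.
#' @export
read_associations <- function(path) {
  if (!file.exists(path)) {
    stop("association file not found: ", path, call. = FALSE)
  }
  tbl <- readr::read_tsv(
    path, comment = "#",
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  required <- c("disease_id", "gene_id", "source")
  missing <- setdiff(required, names(tbl))
  if (length(missing)) {
    stop("association TSV ", path, " lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tbl$disease_id <- trimws(dplyr::coalesce(tbl$disease_id, ""))
  tbl$gene_id <- trimws(dplyr::coalesce(tbl$gene_id, ""))
  tbl$source <- dplyr::coalesce(tbl$source, "")
  bad <- which(!nzchar(tbl$disease_id) | !nzchar(tbl$gene_id))
  if (length(bad)) {
    stop("association TSV ", path, ": empty disease_id or gene_id at data row ",
         bad[1], call. = FALSE)
  }
  tbl |>
    dplyr::group_by(.data$disease_id, .data$gene_id) |>
    dplyr::summarise(
      source = paste(sort(unique(.data$source)), collapse = ";"),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$disease_id, .data$gene_id)
}

#' Read a foreign-to-ontology identifier map
#'
#' Tab-separated with header `foreign_id<TAB>ontology_id`; used to rewrite
#' MIM/Orpha disease identifiers to their equivalent ontology CURIEs. A
#' foreign id listed twice with different targets is an error — equivalence
#' must be unambiguous.
#'
#' @param path Path to the identifier-map TSV.
#' @return A tibble with columns `foreign_id`, `ontology_id`.
#' @export
read_id_map <- function(path) {
  if (!file.exists(path)) {
    stop("identifier map not found: ", path, call. = FALSE)
  }
  tbl <- readr::read_tsv(
    path, comment = "#",
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (!all(c("foreign_id", "ontology_id") %in% names(tbl))) {
    stop("identifier map ", path,
         " must have columns foreign_id, ontology_id", call. = FALSE)
  }
  tbl <- dplyr::distinct(tbl[, c("foreign_id", "ontology_id")])
  dup <- unique(tbl$foreign_id[duplicated(tbl$foreign_id)])
  if (length(dup)) {
    stop("identifier map ", path, ": foreign id(s) mapped to multiple ",
         "ontology ids: ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  dplyr::arrange(tbl, .data$foreign_id)
}

#' Construct an association set
#'
#' An `association_set` is the resolved gene-disease association table: every
#' `disease_id` is an ontology CURIE, and the rows define the direct gene set
#' G0(d) of each disease term.
#'
#' @param assocs A data frame with columns `disease_id`, `gene_id` and
#'   optionally `source`.
#' @param n_dropped_unmapped Count of associations discarded during
#'   identifier resolution (bookkeeping; defaults to 0).
#' @param normalize_genes If `TRUE`, gene identifiers are upper-cased before
#'   comparison. Off by default: sources mix HGNC symbols, NCBI Gene ids and
#'   HGNC ids, and silent fuzzy matching would corrupt set sizes.
#' @return An object of class `association_set`.
#' @export
association_set <- function(assocs, n_dropped_unmapped = 0L,
                            normalize_genes = FALSE) {
  assocs <- tibble::as_tibble(assocs)
  if (!all(c("disease_id", "gene_id") %in% names(assocs))) {
    stop("`assocs` must have disease_id and gene_id columns", call. = FALSE)
  }
  if (!"source" %in% names(assocs)) assocs$source <- ""
  assocs$disease_id <- as.character(assocs$disease_id)
  assocs$gene_id <- as.character(assocs$gene_id)
  if (normalize_genes) assocs$gene_id <- toupper(assocs$gene_id)
  assocs <- assocs |>
    dplyr::group_by(.data$disease_id, .data$gene_id) |>
    dplyr::summarise(
      source = paste(sort(unique(.data$source)), collapse = ";"),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$disease_id, .data$gene_id)
  structure(
    list(
      associations = assocs,
      by_disease = lapply(
        split(assocs$gene_id, assocs$disease_id), function(g) sort(unique(g))
      ),
      n_dropped_unmapped = as.integer(n_dropped_unmapped)
    ),
    class = "association_set"
  )
}

#' @export
print.association_set <- function(x, ...) {
  cat("<association_set> ", nrow(x$associations), " associations over ",
      length(x$by_disease), " disease terms (",
      length(unique(x$associations$gene_id)), " genes); ",
      x$n_dropped_unmapped, " dropped as unmapped\n", sep = "")
  invisible(x)
}

#' Resolve foreign disease identifiers to ontology CURIEs
#'
#' Associations whose `disease_id` already looks like an ontology id pass
#' through unchanged. Ids in a foreign namespace (by default `OMIM`, `MIM`,
#' `ORPHA`, `Orphanet`) are rewritten via the identifier map; foreign ids with
#' no map entry are dropped and counted in `n_dropped_unmapped`.
#'
#' @param assocs A tibble as returned by [read_associations()].
#' @param idmap A tibble as returned by [read_id_map()], or `NULL` for an
#'   empty map.
#' @param foreign_prefixes CURIE prefixes treated as foreign (case
#'   insensitive).
#' @param normalize_genes Passed to [association_set()].
#' @return An [association_set()].
#' @export
resolve_identifiers <- function(assocs, idmap = NULL,
                                foreign_prefixes = c("OMIM", "MIM", "ORPHA",
                                                     "Orphanet"),
                                normalize_genes = FALSE) {
  assocs <- tibble::as_tibble(assocs)
  prefix <- toupper(sub(":.*$", "", assocs$disease_id))
  foreign <- prefix %in% toupper(foreign_prefixes)
  map <- if (is.null(idmap) || !nrow(idmap)) {
    stats::setNames(character(), character())
  } else {
    stats::setNames(idmap$ontology_id, idmap$foreign_id)
  }
  mapped <- unname(map[assocs$disease_id])
  resolved <- ifelse(foreign, mapped, assocs$disease_id)
  dropped <- foreign & is.na(mapped)
  out <- assocs[!dropped, , drop = FALSE]
  out$disease_id <- resolved[!dropped]
  association_set(out, n_dropped_unmapped = sum(dropped),
                  normalize_genes = normalize_genes)
}

#' Genes directly associated with a disease term
#'
#' The direct set G0(d): genes curated against the term itself, without any
#' contribution from its descendants. Most ontology terms carry no direct
#' genes, so an unknown or unannotated id returns the empty set rather than
#' erroring.
#'
#' @param assocs An [association_set()].
#' @param d A disease term id.
#' @return Sorted character vector of gene ids.
#' @export
direct_genes <- function(assocs, d) {
  stopifnot(inherits(assocs, "association_set"))
  assocs$by_disease[[d]] %||% character()
}

#' Gene closure of a disease term
#'
#' The closure G(d) is what "genes associated with d" means throughout this
#' package: the union of G0 over d and every descendant reachable through
#' `subClassOf`. Closures are what every panel-expansion method unions, and
#' they are monotone: a parent's closure always contains each child's.
#'
#' For repeated queries build a [closure_index()] once and pass it via
#' `index`; closures for all terms of an n-term graph are then computed in a
#' single bottom-up pass.
#'
#' @param graph An [ontology_graph()].
#' @param assocs An [association_set()].
#' @param d A disease term id present in the graph.
#' @param index Optional [closure_index()] (computed on the fly when absent).
#' @return Sorted character vector of gene ids.
#' @export
closure_genes <- function(graph, assocs, d, index = NULL) {
  assert_term(graph, d)
  index <- index %||% closure_index(graph, assocs)
  index$closures[[d]]
}

#' Precomputed gene closures for every term
#'
#' Computes G(d) for all terms in one bottom-up pass over a topological order
#' (children before parents), so the total cost is polynomial in the graph
#' size rather than re-walking paths per query. All expansion and evaluation
#' functions accept one of these to avoid recomputation.
#'
#' @inheritParams closure_genes
#' @return An object of class `closure_index` with fields `closures` (named
#'   list of sorted gene vectors) and `sizes` (named integer vector).
#' @export
closure_index <- function(graph, assocs) {
  stopifnot(inherits(graph, "ontology_graph"),
            inherits(assocs, "association_set"))
  ord <- topological_order(graph)
  closures <- vector("list", length(ord))
  names(closures) <- ord
  for (t in ord) {
    kids <- graph$children_of[[t]]
    own <- assocs$by_disease[[t]] %||% character()
    if (length(kids)) {
      closures[[t]] <- sort(unique(c(
        own, unlist(closures[kids], use.names = FALSE)
      )))
    } else {
      closures[[t]] <- own
    }
  }
  closures <- closures[sort(ord)]
  structure(
    list(closures = closures, sizes = lengths(closures)),
    class = "closure_index"
  )
}

#' @export
print.closure_index <- function(x, ...) {
  cat("<closure_index> ", length(x$closures), " terms; closure sizes ",
      min(x$sizes), "-", max(x$sizes), "\n", sep = "")
  invisible(x)
}

#' Closure sizes |G(d)| for all terms
#'
#' @inheritParams closure_genes
#' @return A tibble with columns `disease_id`, `n_direct`, `n_closure`.
#' @export
closure_sizes <- function(graph, assocs, index = NULL) {
  index <- index %||% closure_index(graph, assocs)
  ids <- names(index$closures)
  tibble::tibble(
    disease_id = ids,
    n_direct = vapply(ids, function(d) length(direct_genes(assocs, d)),
                      integer(1)),
    n_closure = unname(index$sizes[ids])
  )
}

#' Write an association set (or table) as TSV
#'
#' @param assocs An [association_set()] or a data frame with columns
#'   `disease_id`, `gene_id`, `source`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_associations <- function(assocs, path) {
  tbl <- if (inherits(assocs, "association_set")) assocs$associations else
    tibble::as_tibble(assocs)
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}
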