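#' @title Virtual gene panel expansion methods
#' @description
#' A virtual gene panel (VGP) for a diagnosed disease d is, at its simplest,
#' the gene closure G(d). When the initial diagnosis is slightly off — a
#' sibling or parent of the true disease — that panel can miss the causal
#' gene. The expansion methods here roll the diagnosis up the ontology before
#' collecting genes:
#'
#' * `OR` — the original set G(d), no roll-up.
#' * `1UAP` / `2UAP` — climb one/two `subClassOf` levels and union the
#'   closures of all ancestors at that distance.
#' * `1UMP` / `2UMP` — same ancestors, but keep only the one with the
#'   smallest closure.
#' * `THkAP` — climb each upward path until the first term whose closure size
#'   exceeds the threshold k, and union the closures of all such stop terms.
#' * `THkMP` — same stop terms, but keep only the one with the smallest
#'   closure.
#'
#' Paths that reach a root without satisfying the rule contribute the root
#' (deepest-reachable fallback), so every method always returns a panel.
#' All tie-breaks use the lexicographically smallest term id.
#' @name panel_expansion
NULL

vgp_methods <- c("OR", "1UAP", "2UAP", "1UMP", "2UMP", "THkAP", "THkMP")

new_panel <- function(method, parameters, diagnoses, selected, index) {
  selected <- sort(unique(selected))
  genes <- sort(unique(unlist(index$closures[selected], use.names = FALSE)))
  if (is.null(genes)) genes <- character()
  structure(
    list(
      method = method,
      parameters = parameters,
      input_diagnoses = diagnoses,
      selected_terms = selected,
      term_sizes = index$sizes[selected],
      genes = genes,
      empty = length(genes) == 0L
    ),
    class = "virtual_gene_panel"
  )
}

#' @export
print.virtual_gene_panel <- function(x, ...) {
  par_str <- if (length(x$parameters)) {
    paste0(" (", paste(names(x$parameters), unlist(x$parameters),
                       sep = "=", collapse = ", "), ")")
  } else ""
  cat("<virtual_gene_panel> method ", x$method, par_str, "\n", sep = "")
  cat("  diagnoses: ", paste(x$input_diagnoses, collapse = ", "), "\n", sep = "")
  cat("  selected:  ",
      paste(sprintf("%s [%d]", x$selected_terms, x$term_sizes), collapse = ", "),
      "\n", sep = "")
  cat("  genes:     ", length(x$genes),
      if (x$empty) "  (empty panel)" else "", "\n", sep = "")
  invisible(x)
}

#' Original-set panel (OR)
#'
#' The unexpanded panel: the gene closure of the diagnosis itself.
#'
#' @param graph An [ontology_graph()].
#' @param assocs An [association_set()].
#' @param d Diagnosed disease term id.
#' @param index Optional [closure_index()]; computed when absent.
#' @return A `virtual_gene_panel` object. An empty panel (term with empty
#'   closure) is allowed and flagged via its `empty` field.
#' @export
expand_or <- function(graph, assocs, d, index = NULL) {
  assert_term(graph, d)
  index <- index %||% closure_index(graph, assocs)
  new_panel("OR", list(), d, d, index)
}

#' Fixed-level roll-up over all paths (1UAP / 2UAP)
#'
#' Selects every ancestor exactly `levels` `subClassOf` steps above the
#' diagnosis (paths that hit a root earlier contribute the root) and unions
#' their closures. Because closures are monotone, the result always contains
#' the OR panel.
#'
#' @inheritParams expand_or
#' @param levels 1 or 2 upward steps.
#' @export
expand_up_all <- function(graph, assocs, d, levels = 1, index = NULL) {
  assert_term(graph, d)
  if (!levels %in% c(1, 2)) stop("`levels` must be 1 or 2", call. = FALSE)
  index <- index %||% closure_index(graph, assocs)
  sel <- ancestors_at_distance(graph, d, levels, fallback = "deepest")
  if (!length(sel)) sel <- d
  new_panel(paste0(levels, "UAP"), list(levels = levels), d, sel, index)
}

#' Fixed-level roll-up over the minimum path (1UMP / 2UMP)
#'
#' Among the ancestors `levels` steps up, keeps only the term with the
#' smallest gene closure (lexicographically smallest id on ties) and returns
#' its closure.
#'
#' @inheritParams expand_up_all
#' @export
expand_up_min <- function(graph, assocs, d, levels = 1, index = NULL) {
  assert_term(graph, d)
  if (!levels %in% c(1, 2)) stop("`levels` must be 1 or 2", call. = FALSE)
  index <- index %||% closure_index(graph, assocs)
  cand <- ancestors_at_distance(graph, d, levels, fallback = "deepest")
  if (!length(cand)) cand <- d
  sel <- min_closure_term(cand, index)
  new_panel(paste0(levels, "UMP"), list(levels = levels), d, sel, index)
}

# smallest closure first, id as tie-break (cand assumed sorted)
min_closure_term <- function(cand, index) {
  cand[order(index$sizes[cand], cand)][1]
}

# Stop set of the threshold walk: breadth-first upward from d; each upward
# path stops at the first term whose closure qualifies, or contributes its
# root if it exhausts without qualifying.
threshold_stop_terms <- function(graph, d, index, k,
                                 threshold_mode = c("strict", "inclusive")) {
  threshold_mode <- match.arg(threshold_mode)
  qualifies <- function(t) {
    if (threshold_mode == "strict") index$sizes[[t]] > k else index$sizes[[t]] >= k
  }
  if (qualifies(d)) return(d)
  stops <- character()
  visited <- d
  frontier <- d
  while (length(frontier)) {
    nxt <- character()
    for (v in frontier) {
      ps <- graph$parents_of[[v]]
      if (!length(ps)) {
        stops <- c(stops, v)  # root fallback
        next
      }
      for (p in ps) {
        if (qualifies(p)) {
          stops <- c(stops, p)
        } else if (!p %in% visited) {
          visited <- c(visited, p)
          nxt <- c(nxt, p)
        }
      }
    }
    frontier <- unique(nxt)
  }
  sort(unique(stops))
}

#' Threshold roll-up over all paths (TH k AP)
#'
#' Walks upward from the diagnosis; each upward path stops at the first term
#' whose closure size exceeds `k` (the diagnosis itself qualifies when
#' |G(d)| > k, making `k = 0` coincide with OR for any term with a non-empty
#' closure). A path that reaches a root without qualifying contributes the
#' root. The panel is the union of all stop-term closures.
#'
#' @inheritParams expand_or
#' @param k Non-negative size threshold.
#' @param threshold_mode `"strict"` (stop when |G| > k, the default) or
#'   `"inclusive"` (|G| >= k).
#' @export
expand_threshold_all <- function(graph, assocs, d, k,
                                 threshold_mode = c("strict", "inclusive"),
                                 index = NULL) {
  assert_term(graph, d)
  threshold_mode <- match.arg(threshold_mode)
  if (length(k) != 1L || is.na(k) || k < 0) {
    stop("`k` must be a single non-negative number", call. = FALSE)
  }
  index <- index %||% closure_index(graph, assocs)
  sel <- threshold_stop_terms(graph, d, index, k, threshold_mode)
  new_panel("THkAP", list(k = k, threshold_mode = threshold_mode), d, sel, index)
}

#' Threshold roll-up over the minimum path (TH k MP)
#'
#' Computes the same stop set as [expand_threshold_all()], then keeps only
#' the stop term with the smallest closure (lexicographic tie-break).
#'
#' @inheritParams expand_threshold_all
#' @export
expand_threshold_min <- function(graph, assocs, d, k,
                                 threshold_mode = c("strict", "inclusive"),
                                 index = NULL) {
  assert_term(graph, d)
  threshold_mode <- match.arg(threshold_mode)
  if (length(k) != 1L || is.na(k) || k < 0) {
    stop("`k` must be a single non-negative number", call. = FALSE)
  }
  index <- index %||% closure_index(graph, assocs)
  stops <- threshold_stop_terms(graph, d, index, k, threshold_mode)
  sel <- min_closure_term(stops, index)
  new_panel("THkMP", list(k = k, threshold_mode = threshold_mode), d, sel, index)
}

#' Expand a panel for a full diagnostic case
#'
#' Patients may carry one to three initial diagnoses; the case panel is the
#' union of the per-diagnosis panels (union is the only aggregation that can
#' never remove a causal gene a single-diagnosis panel retained).
#'
#' @inheritParams expand_or
#' @param diagnoses Non-empty character vector of diagnosis term ids.
#' @param method One of `"OR"`, `"1UAP"`, `"2UAP"`, `"1UMP"`, `"2UMP"`,
#'   `"THkAP"`, `"THkMP"`.
#' @param k Size threshold; required for (and only accepted by) the TH
#'   methods.
#' @param threshold_mode Threshold comparison mode for TH methods.
#' @return A `virtual_gene_panel` whose `selected_terms` is the union of the
#'   per-diagnosis selections.
#' @export
expand_case <- function(graph, assocs, diagnoses, method,
                        k = NULL, threshold_mode = c("strict", "inclusive"),
                        index = NULL) {
  if (!length(diagnoses)) {
    stop("`diagnoses` must be non-empty", call. = FALSE)
  }
  method <- match.arg(method, vgp_methods)
  threshold_mode <- match.arg(threshold_mode)
  is_th <- method %in% c("THkAP", "THkMP")
  if (is_th && is.null(k)) {
    stop("method ", method, " requires a threshold `k`", call. = FALSE)
  }
  if (!is_th && !is.null(k)) {
    stop("parameter `k` not accepted by method ", method, call. = FALSE)
  }
  for (d in diagnoses) assert_term(graph, d)
  index <- index %||% closure_index(graph, assocs)
  panels <- lapply(unique(diagnoses), function(d) {
    switch(method,
      OR = expand_or(graph, assocs, d, index = index),
      `1UAP` = expand_up_all(graph, assocs, d, levels = 1, index = index),
      `2UAP` = expand_up_all(graph, assocs, d, levels = 2, index = index),
      `1UMP` = expand_up_min(graph, assocs, d, levels = 1, index = index),
      `2UMP` = expand_up_min(graph, assocs, d, levels = 2, index = index),
      THkAP = expand_threshold_all(graph, assocs, d, k, threshold_mode, index),
      THkMP = expand_threshold_min(graph, assocs, d, k, threshold_mode, index)
    )
  })
  params <- panels[[1]]$parameters
  new_panel(method, params, sort(unique(diagnoses)),
            unlist(lapply(panels, `[[`, "selected_terms")), index)
}

#' Write a panel to disk
#'
#' Writes a TSV (one sorted `gene_id` per line) and, optionally, a JSON
#' document with the method, parameters, input diagnoses, selected terms with
#' their closure sizes, and the gene list. Output is deterministic for a
#' given panel.
#'
#' @param panel A `virtual_gene_panel`.
#' @param tsv_path Path for the gene-list TSV, or `NULL` to skip.
#' @param json_path Path for the JSON document, or `NULL` to skip.
#' @return The panel, invisibly.
#' @export
write_panel <- function(panel, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(panel, "virtual_gene_panel"))
  if (!is.null(tsv_path)) {
    readr::write_tsv(tibble::tibble(gene_id = panel$genes), tsv_path,
                     progress = FALSE)
  }
  if (!is.null(json_path)) {
    doc <- list(
      method = panel$method,
      parameters = panel$parameters,
      input_diagnoses = panel$input_diagnoses,
      selected_terms = lapply(seq_along(panel$selected_terms), function(i) {
        list(id = panel$selected_terms[[i]],
             closure_size = unname(panel$term_sizes[[i]]))
      }),
      n_genes = length(panel$genes),
      genes = panel$genes
    )
    jsonlite::write_json(doc, json_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(panel)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a virtual gene panel
#'
#' @param x A `virtual_gene_panel`.
#' @param ... Unused.
#' @return A tibble with one row per panel gene.
#' @method tidy virtual_gene_panel
#' @export
tidy.virtual_gene_panel <- function(x, ...) {
  tibble::tibble(gene_id = x$genes)
}

#' One-row summary of a virtual gene panel
#'
#' @inheritParams tidy.virtual_gene_panel
#' @return A tibble with the method, its parameters, and panel sizes.
#' @method glance virtual_gene_panel
#' @export
glance.virtual_gene_panel <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    k = x$parameters$k %||% NA_real_,
    levels = x$parameters$levels %||% NA_integer_,
    n_diagnoses = length(x$input_diagnoses),
    n_selected_terms = length(x$selected_terms),
    n_genes = length(x$genes)
  )
}
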