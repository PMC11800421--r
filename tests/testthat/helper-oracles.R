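# Independent brute-force oracles used to check the graph algorithms.
# These deliberately avoid the package's topological-order dynamic programme
# and BFS walks: descendants come from a naive reachability fixpoint, the
# threshold stop set from a recursive per-path formulation.

# all terms reachable downward from t (including t), by set fixpoint
brute_descendants <- function(graph, t) {
  seen <- t
  repeat {
    nxt <- unique(unlist(graph$children_of[seen], use.names = FALSE))
    nxt <- setdiff(nxt, seen)
    if (!length(nxt)) return(sort(seen))
    seen <- c(seen, nxt)
  }
}

# closure oracle: union of direct gene sets over all descendants
brute_closure <- function(graph, assocs, t) {
  sort(unique(unlist(
    lapply(brute_descendants(graph, t), function(d) direct_genes(assocs, d)),
    use.names = FALSE
  )))
}

# threshold-walk oracle: recursively follow every upward path and record the
# first qualifying term (or the root when a path exhausts unqualified)
brute_threshold_stops <- function(graph, sizes, d, k, strict = TRUE) {
  qualifies <- function(t) if (strict) sizes[[t]] > k else sizes[[t]] >= k
  rec <- function(v) {
    if (qualifies(v)) return(v)
    ps <- graph$parents_of[[v]]
    if (!length(ps)) return(v)
    unique(unlist(lapply(ps, rec), use.names = FALSE))
  }
  sort(unique(rec(d)))
}

# all terms reachable by exactly n upward steps, by explicit path extension;
# with deepest fallback, stalled paths contribute their terminal root
brute_at_distance <- function(graph, t, n, deepest = TRUE) {
  frontier <- t
  stalled <- character()
  for (i in seq_len(n)) {
    if (!length(frontier)) break
    stepped <- character()
    for (v in frontier) {
      ps <- graph$parents_of[[v]]
      if (!length(ps)) stalled <- c(stalled, v) else stepped <- c(stepped, ps)
    }
    frontier <- unique(stepped)
  }
  out <- frontier
  if (deepest) out <- union(out, stalled)
  sort(unique(out))
}

# small random test instance: DAG plus associations with shared genes
# (genes drawn from a fixed pool so closures overlap, unlike the unique-gene
# simulator)
random_instance <- function(seed, n_terms = NULL, pool_size = 400) {
  withr::with_seed(seed, {
    nt <- n_terms %||% sample(2:50, 1)
    graph <- simulate_ontology(nt, max_parents = 3,
                               seed = sample.int(1e6, 1))
    pool <- sprintf("gene%04d", seq_len(pool_size))
    rows <- purrr::map_dfr(term_ids(graph), function(t) {
      ng <- stats::rpois(1, 3)
      if (!ng) return(NULL)
      tibble::tibble(disease_id = t,
                     gene_id = sample(pool, min(ng, pool_size)),
                     source = "rand")
    })
    if (!nrow(rows)) {
      rows <- tibble::tibble(disease_id = term_ids(graph)[1],
                             gene_id = pool[1], source = "rand")
    }
    list(graph = graph, assocs = association_set(rows))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

n_distinct_terms <- function(graph) length(term_ids(graph))

fixture_env <- new.env()
fixture <- function() {
  if (is.null(fixture_env$ex)) {
    ex <- schizencephaly_example()
    ex$index <- closure_index(ex$graph, ex$associations)
    fixture_env$ex <- ex
  }
  fixture_env$ex
}

# the two-patient toy case set used to pin down the evaluation formulas
toy_eval_instance <- function() {
  graph <- ontology_graph(tibble::tibble(id = c("T:1", "T:2")))
  assocs <- association_set(tibble::tibble(
    disease_id = c("T:1", "T:1", "T:2"),
    gene_id = c("a", "b", "f"),
    source = "toy"
  ))
  cases <- patient_cases(tibble::tibble(
    patient_id = c("P1", "P2"),
    diagnoses = list("T:1", "T:2"),
    candidate_genes = list(c("a", "b", "c", "d"), c("e", "f", "h", "i")),
    causal_gene = c("a", "e")
  ))
  list(graph = graph, assocs = assocs, cases = cases)
}
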