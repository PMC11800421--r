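#' Simulate a disease-ontology DAG
#'
#' Terms are created in a fixed order; each term after the first receives
#' between 1 and `max_parents` parents drawn uniformly from earlier terms,
#' which guarantees acyclicity by construction. Output is bit-reproducible
#' for a given seed.
#'
#' @param n_terms Number of terms (>= 1).
#' @param max_parents Maximum parents per term (>= 1).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return An [ontology_graph()].
#' @export
simulate_ontology <- function(n_terms, max_parents = 3, seed = NULL) {
  if (n_terms < 1 || max_parents < 1) {
    stop("`n_terms` and `max_parents` must be >= 1", call. = FALSE)
  }
  with_seed_if(seed, {
    ids <- sprintf("SIM:%04d", seq_len(n_terms))
    edges <- purrr::map_dfr(seq_len(n_terms)[-1], function(i) {
      npar <- sample.int(min(max_parents, i - 1L), 1L)
      tibble::tibble(
        child = ids[[i]],
        parent = ids[sample.int(i - 1L, npar)]
      )
    })
    if (n_terms == 1L) edges <- NULL
    ontology_graph(tibble::tibble(id = ids, label = ""), edges)
  })
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

#' Simulate gene-disease associations over an ontology
#'
#' Each term independently receives zero direct genes with probability
#' `zero_fraction`, otherwise a count drawn from a negative-binomial
#' distribution with the given mean and dispersion. Gene identifiers are
#' globally unique per term (no gene is shared between terms), so every
#' closure size equals the analytic sum of direct counts over the term's
#' descendants — a closed-form oracle the test-suite exploits.
#'
#' @param graph An [ontology_graph()].
#' @param mean_direct_genes Mean direct-gene count for annotated terms.
#' @param zero_fraction Probability a term carries no direct genes.
#' @param dispersion Negative-binomial `size`; smaller is more dispersed.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return An [association_set()] with attribute `direct_counts`, a named
#'   integer vector of the drawn counts per term.
#' @export
simulate_associations <- function(graph, mean_direct_genes = 5,
                                  zero_fraction = 0.3, dispersion = 2,
                                  seed = NULL) {
  stopifnot(inherits(graph, "ontology_graph"))
  if (zero_fraction < 0 || zero_fraction > 1) {
    stop("`zero_fraction` must be in [0, 1]", call. = FALSE)
  }
  if (mean_direct_genes < 0) {
    stop("`mean_direct_genes` must be non-negative", call. = FALSE)
  }
  with_seed_if(seed, {
    ids <- term_ids(graph)
    zero <- stats::runif(length(ids)) < zero_fraction
    counts <- ifelse(
      zero, 0L,
      stats::rnbinom(length(ids), mu = mean_direct_genes, size = dispersion)
    )
    names(counts) <- ids
    total <- sum(counts)
    gene_ids <- sprintf("g%05d", seq_len(total))
    rows <- tibble::tibble(
      disease_id = rep(ids, counts),
      gene_id = gene_ids,
      source = "simulated"
    )
    assocs <- association_set(rows)
    attr(assocs, "direct_counts") <- as.integer(counts) |>
      stats::setNames(ids)
    assocs
  })
}

#' Simulate a diagnostic patient cohort
#'
#' Emulates a whole-exome diagnostic case series: each patient has a true
#' disease drawn uniformly from the gene-bearing ontology terms, one causal
#' gene drawn from that disease's direct gene set, and a candidate gene list
#' (the causal gene plus background genes from the global pool) whose size
#' follows a negative-binomial law. The recorded first diagnosis equals the
#' true disease with probability `p_exact`; otherwise it is perturbed one
#' step — to a parent or to a sibling (a co-child of one of the true
#' disease's parents) — modelling a slightly incorrect initial diagnosis.
#' Additional diagnoses (patients carry 1-3, most often 1) are random terms.
#'
#' Every generated case satisfies the case invariants (causal gene among the
#' candidates, at least one diagnosis) by construction.
#'
#' @param graph An [ontology_graph()].
#' @param assocs An [association_set()]; at least one term must carry direct
#'   genes.
#' @param n_cases Number of patients.
#' @param candidate_mean,candidate_dispersion Negative-binomial mean and
#'   `size` for the candidate-list length |C(p)| (floored at 1).
#' @param n_dx_weights Sampling weights over 1, 2 or 3 recorded diagnoses.
#' @param p_exact Probability the first diagnosis is the true disease.
#' @param perturbation `"mixed"` (parent or sibling, equal odds), `"parent"`,
#'   or `"sibling"`. Sibling perturbation falls back to a parent when the
#'   true disease has no sibling, and a root with no parents keeps its true
#'   diagnosis.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A `patient_cases` tibble with attribute `true_diseases`, the
#'   generating disease of each case.
#' @export
simulate_cases <- function(graph, assocs, n_cases = 74,
                           candidate_mean = 384, candidate_dispersion = 20,
                           n_dx_weights = c(0.7, 0.2, 0.1),
                           p_exact = 0.5,
                           perturbation = c("mixed", "parent", "sibling"),
                           seed = NULL) {
  stopifnot(inherits(graph, "ontology_graph"),
            inherits(assocs, "association_set"))
  perturbation <- match.arg(perturbation)
  if (n_cases < 1) stop("`n_cases` must be >= 1", call. = FALSE)
  if (p_exact < 0 || p_exact > 1) stop("`p_exact` must be in [0, 1]", call. = FALSE)
  gene_bearing <- intersect(names(assocs$by_disease), term_ids(graph))
  gene_bearing <- gene_bearing[lengths(assocs$by_disease[gene_bearing]) > 0]
  if (!length(gene_bearing)) {
    stop("no ontology term carries direct genes; cohort unsatisfiable",
         call. = FALSE)
  }
  pool <- sort(unique(assocs$associations$gene_id))
  all_terms <- term_ids(graph)

  with_seed_if(seed, {
    rows <- purrr::map_dfr(seq_len(n_cases), function(i) {
      d_true <- gene_bearing[[sample.int(length(gene_bearing), 1L)]]
      g0 <- assocs$by_disease[[d_true]]
      causal <- g0[[sample.int(length(g0), 1L)]]

      n_cand <- max(1L, stats::rnbinom(1L, mu = candidate_mean,
                                       size = candidate_dispersion))
      background <- setdiff(pool, causal)
      n_bg <- min(n_cand - 1L, length(background))
      candidates <- sort(c(causal, sample(background, n_bg)))

      first_dx <- if (stats::runif(1) < p_exact) {
        d_true
      } else {
        perturb_diagnosis(graph, d_true, perturbation)
      }
      n_dx <- sample.int(3L, 1L, prob = n_dx_weights)
      extra <- if (n_dx > 1L) {
        others <- setdiff(all_terms, first_dx)
        sample(others, min(n_dx - 1L, length(others)))
      } else character()

      tibble::tibble(
        patient_id = sprintf("P%04d", i),
        diagnoses = list(c(first_dx, extra)),
        phenotypes = list(character()),
        candidate_genes = list(candidates),
        causal_gene = causal,
        true_disease = d_true
      )
    })
    out <- patient_cases(rows[, setdiff(names(rows), "true_disease")])
    attr(out, "true_diseases") <- rows$true_disease
    out
  })
}

# one-step diagnosis perturbation: parent or co-child of a parent
perturb_diagnosis <- function(graph, d_true, mode) {
  parents <- graph$parents_of[[d_true]]
  if (!length(parents)) return(d_true)  # root: nowhere to perturb
  if (mode == "mixed") {
    mode <- if (stats::runif(1) < 0.5) "parent" else "sibling"
  }
  if (mode == "sibling") {
    sibs <- setdiff(
      unique(unlist(graph$children_of[parents], use.names = FALSE)), d_true
    )
    if (length(sibs)) return(sibs[[sample.int(length(sibs), 1L)]])
    # no sibling: fall back to a parent
  }
  parents[[sample.int(length(parents), 1L)]]
}

#' Simulate a complete study bundle
#'
#' Convenience wrapper generating an ontology, its associations and a patient
#' cohort with a single master seed (sub-seeds are derived deterministically),
#' mirroring the shape of a real ontology + curation + case-series input.
#'
#' @param n_terms,max_parents Passed to [simulate_ontology()].
#' @param mean_direct_genes,zero_fraction,dispersion Passed to
#'   [simulate_associations()].
#' @param n_cases,candidate_mean,candidate_dispersion,n_dx_weights,p_exact,perturbation
#'   Passed to [simulate_cases()].
#' @param seed Master integer seed.
#' @return A list with elements `graph`, `associations`, `cases`.
#' @export
simulate_study <- function(n_terms = 500, max_parents = 3,
                           mean_direct_genes = 5, zero_fraction = 0.3,
                           dispersion = 2,
                           n_cases = 74, candidate_mean = 384,
                           candidate_dispersion = 20,
                           n_dx_weights = c(0.7, 0.2, 0.1),
                           p_exact = 0.5,
                           perturbation = c("mixed", "parent", "sibling"),
                           seed = 1L) {
  perturbation <- match.arg(perturbation)
  seeds <- with_seed_if(seed, sample.int(.Machine$integer.max - 1L, 3L))
  graph <- simulate_ontology(n_terms, max_parents, seed = seeds[[1]])
  assocs <- simulate_associations(graph, mean_direct_genes, zero_fraction,
                                  dispersion, seed = seeds[[2]])
  cases <- simulate_cases(graph, assocs, n_cases, candidate_mean,
                          candidate_dispersion, n_dx_weights, p_exact,
                          perturbation, seed = seeds[[3]])
  list(graph = graph, associations = assocs, cases = cases)
}
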