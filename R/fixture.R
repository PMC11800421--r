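#' The schizencephaly worked example
#'
#' A fixed six-term slice of a disease ontology around schizencephaly, the
#' example on which all seven expansion methods are easiest to see. The terms
#' (with their mnemonic ids) and child-to-parent edges are:
#'
#' * `EX:SCH` schizencephaly -> `EX:ECD` encephaloclastic disorder and
#'   `EX:CNS` congenital nervous system disorder
#' * `EX:ECD` -> `EX:CM` cerebral malformation
#' * `EX:CM` -> `EX:DDE` developmental defect during embryogenesis
#' * `EX:CNS` -> `EX:NSD` nervous system disorder
#'
#' Direct gene counts are synthetic (gene ids `g0001`...), chosen so the
#' closure sizes are |G(SCH)| = 10, |G(ECD)| = 40, |G(CM)| = 300,
#' |G(CNS)| = 1200, |G(DDE)| = 1500, |G(NSD)| = 2000. These numbers are not
#' real ontology annotation counts; they satisfy exactly the orderings that
#' make the methods distinct: 1UMP picks ECD (40 < 1200), 2UMP picks CM
#' (300 < 2000), a threshold of 1000 stops at {CNS, DDE}, and TH 1000 MP
#' picks CNS (1200 < 1500).
#'
#' @return A list with elements `graph` (an [ontology_graph()]) and
#'   `associations` (an [association_set()]).
#' @examples
#' ex <- schizencephaly_example()
#' glance(expand_up_min(ex$graph, ex$associations, "EX:SCH", levels = 1))
#' @export
schizencephaly_example <- function() {
  terms <- tibble::tribble(
    ~id,      ~label,
    "EX:SCH", "schizencephaly",
    "EX:ECD", "encephaloclastic disorder",
    "EX:CNS", "congenital nervous system disorder",
    "EX:CM",  "cerebral malformation",
    "EX:NSD", "nervous system disorder",
    "EX:DDE", "developmental defect during embryogenesis"
  )
  edges <- tibble::tribble(
    ~child,   ~parent,
    "EX:SCH", "EX:ECD",
    "EX:SCH", "EX:CNS",
    "EX:ECD", "EX:CM",
    "EX:CM",  "EX:DDE",
    "EX:CNS", "EX:NSD"
  )
  graph <- ontology_graph(terms, edges)

  # direct counts back-solved from the target closure sizes
  direct <- c("EX:SCH" = 10L, "EX:ECD" = 30L, "EX:CM" = 260L,
              "EX:CNS" = 1190L, "EX:DDE" = 1200L, "EX:NSD" = 800L)
  gene_ids <- sprintf("g%04d", seq_len(sum(direct)))
  rows <- tibble::tibble(
    disease_id = rep(names(direct), direct),
    gene_id = gene_ids,
    source = "example"
  )
  list(graph = graph, associations = association_set(rows))
}
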