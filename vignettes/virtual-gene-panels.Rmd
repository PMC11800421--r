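---
title: "Designing and evaluating ontology-driven virtual gene panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and evaluating ontology-driven virtual gene panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When a rare-disease patient is sequenced, whole-exome variant interpretation
typically leaves a few hundred candidate genes. A *virtual gene panel* (VGP)
— the set of genes known to be associated with the clinically suspected
disease — filters that list down to the handful worth manual review. The
catch is that initial diagnoses of rare diseases are often *slightly* wrong:
the clinician picks a sibling or parent term of the disease the patient
actually has. A panel built strictly from the recorded diagnosis then
excludes the causal gene entirely, and the filtering step that was meant to
save time instead hides the answer.

`vgpanel` implements a family of panel-design methods that trade panel size
against robustness to that kind of near-miss diagnosis, by rolling the
diagnosis up a disease-ontology DAG (such as Mondo) before collecting genes,
plus the evaluation machinery to measure the trade-off on a case series.

## The model

The disease ontology is a directed acyclic graph whose nodes are disease
terms and whose edges are `subClassOf` (is-a) relations, stored
child-to-parent. Curated gene–disease associations attach a *direct* gene
set $G_0(d)$ to some terms. The gene set "associated with" a term is its
**closure**

$$G(d) = G_0(d) \;\cup\; \bigcup_{d'\ \mathrm{subClassOf}\ d} G(d'),$$

i.e. the union of direct sets over $d$ and all of its descendants. Closures
are monotone along edges — $G(\text{parent}) \supseteq G(\text{child})$ —
which is the single property all the expansion methods lean on:
rolling a diagnosis upward can only grow the panel, never lose a gene.
`closure_index()` computes all closures in one bottom-up pass over a
topological order, so the cost for an $n$-term graph is polynomial rather
than an exponential re-walk of paths.

### The seven expansion methods

Given a diagnosis $d$:

* **OR** — the original set $G(d)$, no expansion.
* **1UAP / 2UAP** ("one/two classes up, all paths") — take every ancestor
  exactly one/two `subClassOf` steps above $d$ and union their closures.
* **1UMP / 2UMP** ("minimum path") — among those same ancestors, keep only
  the one with the *smallest* closure; the panel is that single closure.
* **TH k AP** — walk upward from $d$; each upward path stops at the first
  term whose closure size exceeds the threshold $k$ ($d$ itself qualifies
  when $|G(d)| > k$). The panel is the union of all stop-term closures.
* **TH k MP** — same stop set, but keep only the stop term with the smallest
  closure.

On the bundled schizencephaly example (`schizencephaly_example()`, six terms
with closure sizes 10/40/300/1200/1500/2000), 1UAP selects the two direct
parents (encephaloclastic disorder, congenital nervous system disorder),
1UMP keeps the smaller of the two (40 < 1200 genes), 2UMP keeps cerebral
malformation (300 < 2000), and at $k = 1000$ the threshold walk stops at
congenital nervous system disorder (1200) and developmental defect during
embryogenesis (1500), with the MP variant keeping the former.

### Decisions a faithful implementation has to make

Several corners of the method family are underdetermined, and the package
fixes them explicitly:

* **Strict vs inclusive threshold.** The stop rule compares $|G(d')|$ to $k$
  either strictly ($>$, the default) or inclusively ($\geq$). Strict
  comparison makes $k = 0$ a genuinely different method from OR — a term
  with an *empty* closure keeps climbing until some ancestor carries genes —
  which is the behaviour that distinguishes a $k=0$ threshold panel from an
  unexpanded one on sparsely annotated ontologies. Both modes are exposed
  (`threshold_mode`).
* **First-qualifying stop, not all qualifying ancestors.** Every qualifying
  ancestor *above* a stop term also qualifies (monotonicity), so "all
  qualifying ancestors" would drag in everything up to the roots. The walk
  therefore stops at the first qualifying term per path. For the MP variant
  the two readings coincide: the minimum-size qualifying ancestor is always
  a first-qualifying term on some path.
* **Root fallback.** A path that reaches a root without qualifying
  contributes that root; likewise a fixed-level roll-up whose path is
  shorter than the requested distance contributes its terminal root
  (`fallback = "deepest"` in `ancestors_at_distance()`). Without this rule,
  patients whose diagnoses sit near a root would silently get no panel at
  all. Multiple roots are permitted and no artificial super-root is added —
  adding one would change which terms the threshold walk can reach.
* **Tie-breaks.** Wherever a single minimum-closure term is selected, ties
  break to the lexicographically smallest term id, making every output
  deterministic.
* **Multi-diagnosis cases.** Patients carry one to three diagnoses; the
  case panel is the union of per-diagnosis panels. Union is the only
  aggregation that can never remove a causal gene that a single-diagnosis
  panel had retained.

## Evaluation metrics

For a case set with candidate genes $C(p)$ and causal gene $g(p)$, and the
per-patient panel $VGP(p)$:

* **Coverage** — the fraction of patients with $g(p) \in VGP(p)$.
* **Median intersection** — the median over *all* patients of
  $|C(p) \cap VGP(p)|$. The median over covered patients only is reported
  separately as the *conditional median*; the two are easy to conflate and
  the package exposes both. Even-count medians are the mean of the central
  pair, so fractional medians are expected.
* **Expectation** — the expected number of genes a diagnostician must
  inspect:

$$E = \frac{1}{n}\Big(\sum_{g(p) \in VGP(p)} |C(p)\cap VGP(p)|
      \;+\; \sum_{g(p) \notin VGP(p)} |C(p)|\Big).$$

When the panel covers the causal gene only the intersection needs review;
when it misses, the whole candidate list does. *Lower expectation is
better* — it is a workload, not a score. `sweep_thresholds()` reports
`best_k` as the expectation-minimising threshold, breaking ties toward the
smaller (cheaper) $k$. Coverage rises with $k$ while the intersections
grow too, so expectation is typically U-shaped in $k$ and the sweep makes
the coverage/workload trade-off explicit.

## The synthetic cohort generator

Real diagnostic case series are protected data, so the package ships a
generator (`simulate_ontology()`, `simulate_associations()`,
`simulate_cases()`, bundled as `simulate_study()`) that reproduces the
*statistical shape* of such a series:

* an ontology DAG built by giving each new term 1–3 parents among earlier
  terms (acyclic by construction);
* direct gene sets that are empty with a configurable probability and
  otherwise negative-binomially sized, with globally unique gene ids per
  term — uniqueness makes every closure size equal the analytic sum of
  direct counts over descendants, a closed-form oracle the tests exploit;
* patients whose true disease is uniform over gene-bearing terms, causal
  gene uniform over that term's direct set, candidate count
  negative-binomial with mean 384 (matching the summary statistics of a
  typical exome series: median ≈ 384 candidates), 1–3 recorded diagnoses
  with weights (0.7, 0.2, 0.1) so the median is 1, and — the key knob — a
  probability `p_exact` that the recorded diagnosis is the true disease.
  With probability `1 - p_exact` the diagnosis is perturbed one step, to a
  parent or to a sibling (a co-child of one of the true disease's parents),
  operationalising a "slightly incorrect" initial diagnosis. The default
  `p_exact = 0.5` makes roughly half the cohort exactly diagnosed, the
  regime in which unexpanded panels cover about half the patients and
  roll-up has something to rescue.

What the generator does **not** emulate: the real topology statistics of
Mondo (term depths, fan-out, the density of multi-parent terms), genes
shared across unrelated disease families, phenotype annotations, and any
correlation between candidate-list content and the true disease beyond the
causal gene itself (background candidates are drawn uniformly from the
global gene pool). Two consequences matter when reading results. First,
because the perturbation is exactly one ontology step, a one-level roll-up
can reach perfect coverage on synthetic cohorts — real misdiagnoses are
messier and real coverage curves saturate more slowly. Second, absolute
metric values on synthetic cohorts depend on the generator's scale
parameters and are not comparable to any particular real case series; the
*orderings* and *monotonicities* (coverage non-decreasing in $k$, MP panels
nested in AP panels, roll-up rescuing perturbed diagnoses) are the
transferable content, and those are what the test suite asserts.

## Numerical and engineering choices

* All returned gene sets and term sets are lexicographically sorted; files
  serialize deterministically, so identical inputs and seeds give
  byte-identical outputs (checked end-to-end through the CLI).
* Every generator takes an explicit integer seed; `simulate_study()` derives
  its three sub-seeds from one master seed.
* Graph validation (`validate_ontology()`) reports rather than raises:
  cycles are returned as id sequences, dangling parent references as a
  table. Parsers, by contrast, fail fast — a cyclic ontology is refused at
  load time with one cycle named.
* Identifier resolution drops associations whose foreign id (OMIM/Orphanet
  namespaces) has no ontology mapping and counts them, rather than guessing;
  an identifier map that sends one foreign id to two ontology terms is
  refused outright. Gene identifiers are compared as opaque strings; an
  optional flag upper-cases them first, off by default, because the curated
  sources mix HGNC symbols, NCBI Gene ids and HGNC ids, and silent fuzzy
  matching would corrupt panel sizes.
* Terms with no path to any gene-bearing ancestor simply yield empty or
  root-fallback panels; they are surfaced through validation statistics and
  the panel's `empty` flag rather than being dropped.

The test suite runs the oracle comparisons on batches of 200 random DAGs of
up to 50 terms with gene pools of up to 400 shared genes — small enough for
the brute-force oracles (reachability fixpoints and recursive per-path
walks) to stay exact and fast, large enough to hit diamonds, multi-root
graphs and deep chains. The end-to-end acceptance run simulates a 2000-term
ontology and a 74-patient cohort and sweeps both threshold methods over
their full grids (0–4500 by 250 for AP, 0–500 by 10 for MP).

## Known limitations

* Only `subClassOf` propagates genes; other ontology relations (part-of,
  equivalence axioms between ontology terms) are ignored by design.
* No gene ranking, no variant-level filtering, no phenotype-similarity
  expansion: the package designs and scores gene *sets*.
* The threshold methods assume the closure sizes of an annotated ontology
  are informative; on an ontology with pathologically uniform annotation,
  every choice of $k$ collapses to the same few stop terms.
* Evaluation metrics are point estimates over the supplied case set; no
  uncertainty quantification or between-method testing is attempted.
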