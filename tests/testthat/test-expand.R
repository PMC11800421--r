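test_that("the worked example reproduces every method's narrative selection", {
  ex <- fixture()
  g <- ex$graph; a <- ex$associations; idx <- ex$index

  or <- expand_or(g, a, "EX:SCH", idx)
  expect_equal(or$selected_terms, "EX:SCH")
  expect_length(or$genes, 10)

  or_root <- expand_or(g, a, "EX:NSD", idx)
  expect_length(or_root$genes, 2000)

  up1 <- expand_up_all(g, a, "EX:SCH", 1, idx)
  expect_equal(up1$selected_terms, c("EX:CNS", "EX:ECD"))
  expect_length(up1$genes, 1230)  # 40 + 1200 - 10 shared

  up2 <- expand_up_all(g, a, "EX:SCH", 2, idx)
  expect_equal(up2$selected_terms, c("EX:CM", "EX:NSD"))
  expect_length(up2$genes, 2290)  # 300 + 2000 - 10 shared

  expect_equal(expand_up_min(g, a, "EX:SCH", 1, idx)$selected_terms, "EX:ECD")
  expect_equal(expand_up_min(g, a, "EX:SCH", 2, idx)$selected_terms, "EX:CM")

  th <- expand_threshold_all(g, a, "EX:SCH", 1000, index = idx)
  expect_equal(th$selected_terms, c("EX:CNS", "EX:DDE"))
  expect_length(th$genes, 2690)  # 1200 + 1500 - 10 shared

  expect_equal(expand_threshold_min(g, a, "EX:SCH", 1000, index = idx)$selected_terms,
               "EX:CNS")
})

test_that("threshold edge cases: k = 0 equals OR, huge k falls back to roots", {
  ex <- fixture()
  th0 <- expand_threshold_all(ex$graph, ex$associations, "EX:SCH", 0,
                              index = ex$index)
  expect_equal(th0$selected_terms, "EX:SCH")
  expect_equal(th0$genes, expand_or(ex$graph, ex$associations, "EX:SCH",
                                    ex$index)$genes)
  expect_equal(expand_threshold_min(ex$graph, ex$associations, "EX:SCH", 0,
                                    index = ex$index)$selected_terms, "EX:SCH")

  far <- expand_threshold_all(ex$graph, ex$associations, "EX:SCH", 10000,
                              index = ex$index)
  expect_equal(far$selected_terms, c("EX:DDE", "EX:NSD"))
})

test_that("inclusive threshold mode stops one term earlier at exact sizes", {
  ex <- fixture()
  # |G(CM)| = 300: inclusive mode stops at CM for k = 300, strict walks past
  inc <- expand_threshold_all(ex$graph, ex$associations, "EX:SCH", 300,
                              threshold_mode = "inclusive", index = ex$index)
  expect_true("EX:CM" %in% inc$selected_terms)
  strict <- expand_threshold_all(ex$graph, ex$associations, "EX:SCH", 300,
                                 index = ex$index)
  expect_false("EX:CM" %in% strict$selected_terms)
})

test_that("minimum-path ties break to the lexicographically smaller id", {
  g <- ontology_graph(
    tibble::tibble(id = c("T:c", "T:pa", "T:pb")),
    tibble::tibble(child = c("T:c", "T:c"), parent = c("T:pa", "T:pb"))
  )
  a <- association_set(tibble::tibble(
    disease_id = c("T:pa", "T:pb"), gene_id = c("x", "y"), source = "s"
  ))
  expect_equal(expand_up_min(g, a, "T:c", 1)$selected_terms, "T:pa")
  # both parents qualify at k = 0 with equal closure size 1
  expect_equal(expand_threshold_min(g, a, "T:c", 0)$selected_terms, "T:pa")
})

test_that("a term with an empty closure yields an empty, flagged panel", {
  g <- ontology_graph(tibble::tibble(id = "T:1"))
  a <- association_set(tibble::tibble(disease_id = character(),
                                      gene_id = character(),
                                      source = character()))
  p <- expand_or(g, a, "T:1")
  expect_length(p$genes, 0)
  expect_true(p$empty)
})

test_that("unknown terms and bad parameters error cleanly", {
  ex <- fixture()
  expect_error(expand_or(ex$graph, ex$associations, "EX:none"), "unknown term")
  expect_error(expand_threshold_all(ex$graph, ex$associations, "EX:SCH", -1),
               "non-negative")
  expect_error(expand_up_all(ex$graph, ex$associations, "EX:SCH", 3),
               "1 or 2")
})

test_that("case-level expansion unions per-diagnosis panels", {
  ex <- fixture()
  single <- expand_case(ex$graph, ex$associations, "EX:SCH", "OR",
                        index = ex$index)
  expect_equal(single$genes,
               expand_or(ex$graph, ex$associations, "EX:SCH", ex$index)$genes)

  multi <- expand_case(ex$graph, ex$associations, c("EX:ECD", "EX:CNS"), "OR",
                       index = ex$index)
  expect_equal(multi$selected_terms, c("EX:CNS", "EX:ECD"))
  expect_length(multi$genes, 1230)

  expect_error(expand_case(ex$graph, ex$associations, character(), "OR"),
               "non-empty")
  expect_error(expand_case(ex$graph, ex$associations, "EX:SCH", "OR", k = 5),
               "not accepted")
  expect_error(expand_case(ex$graph, ex$associations, "EX:SCH", "THkMP"),
               "requires a threshold")
})

test_that("every panel's genes equal the union of its selected-term closures", {
  for (seed in 1:15) {
    inst <- random_instance(seed)
    idx <- closure_index(inst$graph, inst$assocs)
    d <- term_ids(inst$graph)[[1 + seed %% n_distinct_terms(inst$graph)]]
    panels <- list(
      expand_or(inst$graph, inst$assocs, d, idx),
      expand_up_all(inst$graph, inst$assocs, d, 1, idx),
      expand_up_all(inst$graph, inst$assocs, d, 2, idx),
      expand_up_min(inst$graph, inst$assocs, d, 1, idx),
      expand_up_min(inst$graph, inst$assocs, d, 2, idx),
      expand_threshold_all(inst$graph, inst$assocs, d, 5, index = idx),
      expand_threshold_min(inst$graph, inst$assocs, d, 5, index = idx)
    )
    for (p in panels) {
      expect_gt(length(p$selected_terms), 0)
      expect_equal(
        p$genes,
        sort(unique(unlist(idx$closures[p$selected_terms], use.names = FALSE))),
        info = sprintf("seed %d method %s", seed, p$method)
      )
    }
  }
})

test_that("panels nest: OR within 1UAP within 2UAP; MP within AP", {
  for (seed in 16:35) {
    inst <- random_instance(seed)
    idx <- closure_index(inst$graph, inst$assocs)
    d <- term_ids(inst$graph)[[1 + seed %% n_distinct_terms(inst$graph)]]
    or <- expand_or(inst$graph, inst$assocs, d, idx)$genes
    up1 <- expand_up_all(inst$graph, inst$assocs, d, 1, idx)$genes
    up2 <- expand_up_all(inst$graph, inst$assocs, d, 2, idx)$genes
    expect_true(all(or %in% up1))
    expect_true(all(up1 %in% up2))
    expect_true(all(expand_up_min(inst$graph, inst$assocs, d, 1, idx)$genes %in% up1))
    expect_true(all(expand_up_min(inst$graph, inst$assocs, d, 2, idx)$genes %in% up2))
    for (k in c(0, 3, 10)) {
      ap <- expand_threshold_all(inst$graph, inst$assocs, d, k, index = idx)$genes
      mp <- expand_threshold_min(inst$graph, inst$assocs, d, k, index = idx)$genes
      expect_true(all(mp %in% ap))
      expect_true(all(or %in% ap))
    }
  }
})

test_that("threshold panels grow with k (AP supersets, MP sizes non-decreasing)", {
  ks <- c(0, 1, 5, 20, 100)
  for (seed in 36:50) {
    inst <- random_instance(seed)
    idx <- closure_index(inst$graph, inst$assocs)
    d <- term_ids(inst$graph)[[1 + seed %% n_distinct_terms(inst$graph)]]
    prev_ap <- character()
    prev_mp_size <- 0L
    for (k in ks) {
      ap <- expand_threshold_all(inst$graph, inst$assocs, d, k, index = idx)$genes
      mp <- expand_threshold_min(inst$graph, inst$assocs, d, k, index = idx)
      expect_true(all(prev_ap %in% ap),
                  info = sprintf("seed %d k %d AP monotone", seed, k))
      expect_gte(length(mp$genes), prev_mp_size)
      # size bound: the MP panel exceeds k whenever any term qualified
      if (any(idx$sizes[ontology_ancestors(inst$graph, d)] > k)) {
        expect_gt(length(mp$genes), k)
      }
      prev_ap <- ap
      prev_mp_size <- length(mp$genes)
    }
  }
})

test_that("threshold stop sets match the recursive per-path oracle", {
  for (seed in 51:80) {
    inst <- random_instance(seed)
    idx <- closure_index(inst$graph, inst$assocs)
    d <- term_ids(inst$graph)[[1 + seed %% n_distinct_terms(inst$graph)]]
    for (k in c(0, 1, 5, 20, 100)) {
      oracle <- brute_threshold_stops(inst$graph, idx$sizes, d, k)
      ap <- expand_threshold_all(inst$graph, inst$assocs, d, k, index = idx)
      expect_equal(ap$selected_terms, oracle,
                   info = sprintf("seed %d k %d", seed, k))
      mp <- expand_threshold_min(inst$graph, inst$assocs, d, k, index = idx)
      expect_equal(mp$selected_terms,
                   oracle[order(idx$sizes[oracle], oracle)][1])
    }
  }
})

test_that("panel files serialize deterministically", {
  ex <- fixture()
  p <- expand_threshold_min(ex$graph, ex$associations, "EX:SCH", 1000,
                            index = ex$index)
  t1 <- withr::local_tempfile(fileext = ".tsv")
  j1 <- withr::local_tempfile(fileext = ".json")
  t2 <- withr::local_tempfile(fileext = ".tsv")
  j2 <- withr::local_tempfile(fileext = ".json")
  write_panel(p, t1, j1)
  write_panel(p, t2, j2)
  expect_identical(readLines(t1), readLines(t2))
  expect_identical(readLines(j1), readLines(j2))
  doc <- jsonlite::fromJSON(j1)
  expect_equal(doc$method, "THkMP")
  expect_equal(doc$selected_terms$id, "EX:CNS")
  expect_equal(doc$selected_terms$closure_size, 1200)
  expect_equal(nrow(readr::read_tsv(t1, show_col_types = FALSE)), 1200)
})
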