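#' Assemble a patient case table
#'
#' A diagnostic case records the patient's initial diagnoses (1-3 ontology
#' terms), the candidate genes C(p) produced by upstream exome variant
#' interpretation, and the single causal gene g(p), which is guaranteed to be
#' among the candidates. Phenotype terms are carried through when present but
#' play no role in scoring.
#'
#' @param cases A data frame with columns `patient_id` (character),
#'   `diagnoses` (list of character vectors), `candidate_genes` (list of
#'   character vectors), `causal_gene` (character) and optionally
#'   `phenotypes` (list of character vectors).
#' @return A validated tibble of class `patient_cases`.
#' @export
patient_cases <- function(cases) {
  cases <- tibble::as_tibble(cases)
  required <- c("patient_id", "diagnoses", "candidate_genes", "causal_gene")
  missing <- setdiff(required, names(cases))
  if (length(missing)) {
    stop("case table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"phenotypes" %in% names(cases)) {
    cases$phenotypes <- rep(list(character()), nrow(cases))
  }
  cases$patient_id <- as.character(cases$patient_id)
  cases$causal_gene <- as.character(cases$causal_gene)
  cases$diagnoses <- lapply(cases$diagnoses, as.character)
  cases$candidate_genes <- lapply(cases$candidate_genes,
                                  function(g) sort(unique(as.character(g))))
  cases$phenotypes <- lapply(cases$phenotypes, as.character)

  for (i in seq_len(nrow(cases))) {
    pid <- cases$patient_id[[i]]
    if (!nzchar(pid)) stop("case ", i, " has an empty patient_id", call. = FALSE)
    if (!length(cases$diagnoses[[i]])) {
      stop("patient ", pid, " has no diagnoses", call. = FALSE)
    }
    if (!cases$causal_gene[[i]] %in% cases$candidate_genes[[i]]) {
      stop("patient ", pid, ": causal gene ", cases$causal_gene[[i]],
           " is not in its candidate gene list", call. = FALSE)
    }
  }
  cases <- cases[, c("patient_id", "diagnoses", "phenotypes",
                     "candidate_genes", "causal_gene")]
  class(cases) <- c("patient_cases", class(cases))
  cases
}

#' Read patient cases from JSON or TSV
#'
#' JSON: an array of objects with fields `patient_id`, `diagnoses`,
#' `phenotypes` (optional), `candidate_genes`, `causal_gene`. TSV: the same
#' columns with `;`-delimited list cells. Validation rejects any case whose
#' causal gene is missing from its candidate list, naming the patient.
#'
#' @param path Path to the case file.
#' @param format `"auto"` (by extension), `"json"` or `"tsv"`.
#' @return A `patient_cases` tibble.
#' @export
read_cases <- function(path, format = c("auto", "json", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("case file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  if (format == "json") {
    raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (!length(raw)) stop("case file ", path, " contains no cases", call. = FALSE)
    tbl <- tibble::tibble(
      patient_id = vapply(raw, function(x) x$patient_id %||% "", character(1)),
      diagnoses = lapply(raw, function(x) unlist(x$diagnoses) %||% character()),
      phenotypes = lapply(raw, function(x) unlist(x$phenotypes) %||% character()),
      candidate_genes = lapply(raw, function(x) unlist(x$candidate_genes) %||% character()),
      causal_gene = vapply(raw, function(x) x$causal_gene %||% "", character(1))
    )
  } else {
    tbl <- readr::read_tsv(
      path, comment = "#",
      col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE
    )
    required <- c("patient_id", "diagnoses", "candidate_genes", "causal_gene")
    missing <- setdiff(required, names(tbl))
    if (length(missing)) {
      stop("case TSV ", path, " lacks column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    split_cell <- function(x) {
      lapply(x, function(s) {
        if (is.na(s) || !nzchar(s)) character() else strsplit(s, ";", fixed = TRUE)[[1]]
      })
    }
    tbl$diagnoses <- split_cell(tbl$diagnoses)
    tbl$candidate_genes <- split_cell(tbl$candidate_genes)
    tbl$phenotypes <- if ("phenotypes" %in% names(tbl)) {
      split_cell(tbl$phenotypes)
    } else {
      rep(list(character()), nrow(tbl))
    }
  }
  patient_cases(tbl)
}

#' Write patient cases as JSON
#'
#' @param cases A `patient_cases` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cases <- function(cases, path) {
  docs <- lapply(seq_len(nrow(cases)), function(i) {
    list(
      patient_id = cases$patient_id[[i]],
      diagnoses = as.list(cases$diagnoses[[i]]),
      phenotypes = as.list(cases$phenotypes[[i]]),
      candidate_genes = as.list(cases$candidate_genes[[i]]),
      causal_gene = cases$causal_gene[[i]]
    )
  })
  jsonlite::write_json(docs, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Evaluate a panel-design method on a case set
#'
#' For every patient p a panel VGP(p) is built from the case's diagnoses with
#' the requested method, then scored:
#'
#' * coverage — fraction of patients whose panel contains the causal gene;
#' * median intersection — median over all patients of |C(p) n VGP(p)|
#'   (even-count medians are the mean of the central pair);
#' * conditional median — the same median over covered patients only
#'   (`NA` when no patient is covered);
#' * expectation — the expected number of genes a diagnostician inspects:
#'   the intersection size when the panel covers the causal gene, the full
#'   candidate list size otherwise, averaged over patients.
#'
#' @inheritParams expand_case
#' @param cases A `patient_cases` tibble.
#' @return An object of class `method_evaluation`; see
#'   [tidy.method_evaluation()] and [glance.method_evaluation()].
#' @export
evaluate_method <- function(graph, assocs, cases, method,
                            k = NULL, threshold_mode = c("strict", "inclusive"),
                            index = NULL) {
  stopifnot(inherits(cases, "patient_cases"))
  method <- match.arg(method, vgp_methods)
  threshold_mode <- match.arg(threshold_mode)
  index <- index %||% closure_index(graph, assocs)

  records <- purrr::map_dfr(seq_len(nrow(cases)), function(i) {
    pid <- cases$patient_id[[i]]
    panel <- tryCatch(
      expand_case(graph, assocs, cases$diagnoses[[i]], method,
                  k = k, threshold_mode = threshold_mode, index = index),
      error = function(e) {
        stop("patient ", pid, ": ", conditionMessage(e), call. = FALSE)
      }
    )
    cand <- cases$candidate_genes[[i]]
    inter <- sum(cand %in% panel$genes)
    tibble::tibble(
      patient_id = pid,
      covered = cases$causal_gene[[i]] %in% panel$genes,
      intersection_size = inter,
      candidate_count = length(cand)
    )
  })

  n <- nrow(records)
  covered <- records$covered
  expectation <- (sum(records$intersection_size[covered]) +
                    sum(records$candidate_count[!covered])) / n
  structure(
    list(
      method = method,
      parameters = if (method %in% c("THkAP", "THkMP")) {
        list(k = k, threshold_mode = threshold_mode)
      } else list(),
      n_cases = n,
      coverage = mean(covered),
      median_intersection = stats::median(records$intersection_size),
      conditional_median = if (any(covered)) {
        stats::median(records$intersection_size[covered])
      } else NA_real_,
      expectation = expectation,
      records = records
    ),
    class = "method_evaluation"
  )
}

#' @export
print.method_evaluation <- function(x, ...) {
  par_str <- if (length(x$parameters)) {
    paste0(" (k=", x$parameters$k, ")")
  } else ""
  cat("<method_evaluation> ", x$method, par_str, " on ", x$n_cases,
      " cases\n", sep = "")
  cat(sprintf("  coverage: %.4f   median: %s   conditional median: %s   expectation: %.2f\n",
              x$coverage, format(x$median_intersection),
              format(x$conditional_median), x$expectation))
  invisible(x)
}

#' Per-patient records of a method evaluation
#'
#' @param x A `method_evaluation`.
#' @param ... Unused.
#' @return A tibble with columns `patient_id`, `covered`,
#'   `intersection_size`, `candidate_count`.
#' @method tidy method_evaluation
#' @export
tidy.method_evaluation <- function(x, ...) x$records

#' One-row summary of a method evaluation
#'
#' @inheritParams tidy.method_evaluation
#' @return A tibble with the method, threshold, and the four headline
#'   metrics.
#' @method glance method_evaluation
#' @export
glance.method_evaluation <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    k = x$parameters$k %||% NA_real_,
    n_cases = x$n_cases,
    coverage = x$coverage,
    median_intersection = x$median_intersection,
    conditional_median = x$conditional_median,
    expectation = x$expectation
  )
}

#' Sweep a threshold method over a grid of k values
#'
#' Evaluates `THkAP` or `THkMP` at every threshold in `k_values` and reports
#' the best threshold: the k minimising expectation (smallest k on ties —
#' cheaper panels are preferred at equal expected workload). Low expectation
#' is good: it is the expected number of genes that must be inspected.
#'
#' @inheritParams evaluate_method
#' @param method `"THkAP"` or `"THkMP"`.
#' @param k_values Non-empty vector of non-negative thresholds.
#' @return A tibble of class `threshold_sweep` with one row per k (columns
#'   `method`, `k`, `coverage`, `median_intersection`, `conditional_median`,
#'   `expectation`) and attributes `best_k` / `best_expectation`.
#' @export
sweep_thresholds <- function(graph, assocs, cases, method = c("THkMP", "THkAP"),
                             k_values,
                             threshold_mode = c("strict", "inclusive"),
                             index = NULL) {
  method <- match.arg(method)
  threshold_mode <- match.arg(threshold_mode)
  if (!length(k_values)) stop("`k_values` must be non-empty", call. = FALSE)
  if (any(is.na(k_values) | k_values < 0)) {
    stop("`k_values` must be non-negative", call. = FALSE)
  }
  index <- index %||% closure_index(graph, assocs)
  rows <- purrr::map_dfr(k_values, function(k) {
    glance(evaluate_method(graph, assocs, cases, method, k = k,
                           threshold_mode = threshold_mode, index = index))
  })
  best_i <- order(rows$expectation, rows$k)[1]
  out <- rows
  class(out) <- c("threshold_sweep", class(out))
  attr(out, "best_k") <- rows$k[[best_i]]
  attr(out, "best_expectation") <- rows$expectation[[best_i]]
  out
}

#' Best threshold of a sweep
#'
#' @param sweep A `threshold_sweep`.
#' @return The k minimising expectation (smallest such k on ties).
#' @export
best_k <- function(sweep) {
  stopifnot(inherits(sweep, "threshold_sweep"))
  attr(sweep, "best_k")
}

#' Compare several panel-design methods on one case set
#'
#' @inheritParams evaluate_method
#' @param specs A data frame with columns `method` and `k` (`k` is `NA` for
#'   the non-threshold methods), or a list of `list(method=, k=)` entries.
#'   Duplicate specs yield duplicate rows.
#' @return A tibble with one evaluation row per spec, in input order.
#' @export
compare_methods <- function(graph, assocs, cases, specs,
                            threshold_mode = c("strict", "inclusive"),
                            index = NULL) {
  threshold_mode <- match.arg(threshold_mode)
  if (is.data.frame(specs)) {
    specs <- purrr::map(seq_len(nrow(specs)), function(i) {
      list(method = specs$method[[i]],
           k = if ("k" %in% names(specs)) specs$k[[i]] else NA)
    })
  }
  if (!length(specs)) stop("`specs` must be non-empty", call. = FALSE)
  index <- index %||% closure_index(graph, assocs)
  purrr::map_dfr(specs, function(s) {
    k <- s$k
    if (!is.null(k) && length(k) == 1 && is.na(k)) k <- NULL
    glance(evaluate_method(graph, assocs, cases, s$method, k = k,
                           threshold_mode = threshold_mode, index = index))
  })
}

#' Plot a threshold sweep
#'
#' Expectation and coverage as a function of the threshold k. Expectation is
#' the expected number of genes to inspect, so lower is better; the best k
#' is marked.
#'
#' @param object A `threshold_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot threshold_sweep
#' @export
autoplot.threshold_sweep <- function(object, ...) {
  long <- tibble::tibble(
    k = rep(object$k, 2),
    metric = rep(c("expectation", "coverage"), each = nrow(object)),
    value = c(object$expectation, object$coverage)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = attr(object, "best_k"),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(
      x = "threshold k (closure-size cut-off)",
      y = NULL,
      title = paste0(object$method[[1]], " threshold sweep"),
      subtitle = paste0("dashed line: best k = ", attr(object, "best_k"),
                        " (minimum expectation)")
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
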