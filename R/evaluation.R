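#' @importFrom rlang .data
NULL

# Candidate directed site pairs for one inferred path row: one (source,
# recipient) pair per annotated source area. Multi-area sources arise when a
# parent node's best range spans two sites; credit is given if any candidate
# matches a true path.
path_candidates <- function(source, recipient) {
  lapply(seq_along(source), function(i) {
    paste(strsplit(source[i], ",")[[1]], recipient[i], sep = "->")
  })
}

# Core matcher shared by score_paths() and classify_counts().
match_paths <- function(inferred, truth, mode = c("unique", "multiset")) {
  mode <- match.arg(mode)
  if (!setequal(attr(inferred, "sites"), attr(truth, "sites"))) {
    stop("inferred and truth graphs are over different site sets",
         call. = FALSE)
  }
  if (any(grepl(",", truth$source))) {
    stop("truth paths must have single-site sources", call. = FALSE)
  }
  tr <- tibble::tibble(pair = paste(truth$source, truth$recipient,
                                    sep = "->"),
                       class = truth$class)
  inf <- tibble::tibble(source = inferred$source,
                        recipient = inferred$recipient,
                        class = inferred$class)

  if (mode == "unique") {
    tr <- dplyr::distinct(tr, .data$pair, .keep_all = TRUE)
    inf <- dplyr::distinct(inf, .data$source, .data$recipient,
                           .keep_all = TRUE)
  }
  cand <- path_candidates(inf$source, inf$recipient)

  if (mode == "unique") {
    covered <- vapply(tr$pair, function(p) {
      any(vapply(cand, function(cs) p %in% cs, logical(1)))
    }, logical(1))
    inf_matched <- vapply(cand, function(cs) any(tr$pair %in% cs),
                          logical(1))
  } else {
    covered <- logical(nrow(tr))
    inf_matched <- logical(nrow(inf))
    for (i in seq_len(nrow(tr))) {      # greedy one-to-one matching
      hit <- which(!inf_matched &
                     vapply(cand, function(cs) tr$pair[i] %in% cs,
                            logical(1)))
      if (length(hit)) {
        covered[i] <- TRUE
        inf_matched[hit[1]] <- TRUE
      }
    }
  }
  list(
    tp_class = tr$class[covered],
    fn_class = tr$class[!covered],
    fp_class = inf$class[!inf_matched]
  )
}

#' Score an inferred migration graph against ground truth
#'
#' Directed site-to-site paths are compared: true positives are true paths
#' recovered by the inference, false positives are inferred paths matching no
#' true path, false negatives are true paths not inferred. Precision, recall
#' and F1 (their harmonic mean) follow the usual definitions. By default
#' paths are compared as unique directed site pairs (`mode = "unique"`);
#' `mode = "multiset"` matches path instances one-to-one, so repeated
#' seeding of the same site pair must be recovered repeatedly.
#'
#' @param inferred,truth `migration_graph` objects over the same site set.
#' @param mode `"unique"` (default) or `"multiset"`.
#' @return A one-row tibble: `TP`, `FP`, `FN`, `precision`, `recall`, `f1`.
#' @export
score_paths <- function(inferred, truth, mode = c("unique", "multiset")) {
  m <- match_paths(inferred, truth, mode)
  TP <- length(m$tp_class)
  FP <- length(m$fp_class)
  FN <- length(m$fn_class)
  precision <- if (TP + FP > 0) TP / (TP + FP) else as.numeric(FN == 0)
  recall <- if (TP + FN > 0) TP / (TP + FN) else as.numeric(FP == 0)
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  tibble::tibble(TP = TP, FP = FP, FN = FN,
                 precision = precision, recall = recall, f1 = f1)
}

#' Per-class correct / erroneous / not-inferred path counts
#'
#' Splits the comparison of [score_paths()] by path class — primary to
#' metastasis (`P->M`), metastasis to metastasis (`M->M`), metastasis to
#' primary (`M->P`) — reporting, per class, the number of correct (TP),
#' erroneous (FP) and not-inferred (FN) paths. Class sums equal the overall
#' TP/FP/FN.
#'
#' @inheritParams score_paths
#' @return A tibble with columns `class`, `correct`, `erroneous`,
#'   `not_inferred` (one row per class, in the order P->M, M->M, M->P).
#' @export
classify_counts <- function(inferred, truth, mode = c("unique", "multiset")) {
  m <- match_paths(inferred, truth, mode)
  classes <- c("P->M", "M->M", "M->P")
  tibble::tibble(
    class = classes,
    correct = as.integer(table(factor(m$tp_class, classes))),
    erroneous = as.integer(table(factor(m$fp_class, classes))),
    not_inferred = as.integer(table(factor(m$fn_class, classes)))
  )
}

#' Aggregate per-dataset benchmark rows into summary tables
#'
#' Takes the long table produced by [run_benchmark()] (one row per dataset x
#' model) and computes the benchmark summaries: mean F1 per model, per model
#' and tumor-count group (m5/m8), and per model and seeding scenario; the
#' percentage of datasets in which the likelihood-ratio test rejects the base
#' model per family (overall and per cell); the percentage of datasets in
#' which each model has the best AICc; and the mean number of multiple-range
#' ancestral annotations per model.
#'
#' @param rows Tibble with columns `dataset`, `m_group`, `scenario`, `model`,
#'   `family`, `founder`, `k`, `AICc`, `f1`, `n_multiple`, `lrt_p` (non-`NA`
#'   on `+J` rows).
#' @param alpha Significance level for the LRT rejection rate (default 0.05).
#' @return An object of class `benchmark_summary`: a list of tibbles
#'   `f1_by_model`, `f1_by_group`, `f1_by_scenario`, `lrt_overall`,
#'   `lrt_by_cell`, `best_aicc_pct`, `multiple_ranges`, plus `n_datasets`.
#' @export
aggregate_benchmark <- function(rows, alpha = 0.05) {
  rows <- tibble::as_tibble(rows)
  need <- c("dataset", "m_group", "scenario", "model", "family", "founder",
            "k", "AICc", "f1", "n_multiple")
  missing_cols <- setdiff(need, names(rows))
  if (length(missing_cols)) {
    stop("`rows` is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  f1_by_model <- rows |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(mean_f1 = mean(.data$f1), n = dplyr::n(),
                     .groups = "drop")
  f1_by_group <- rows |>
    dplyr::group_by(.data$model, .data$m_group) |>
    dplyr::summarise(mean_f1 = mean(.data$f1), n = dplyr::n(),
                     .groups = "drop")
  f1_by_scenario <- rows |>
    dplyr::group_by(.data$model, .data$scenario) |>
    dplyr::summarise(mean_f1 = mean(.data$f1), n = dplyr::n(),
                     .groups = "drop")

  lrt_rows <- dplyr::filter(rows, .data$founder, !is.na(.data$lrt_p))
  lrt_overall <- lrt_rows |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(pct_reject = 100 * mean(.data$lrt_p < alpha),
                     n = dplyr::n(), .groups = "drop")
  lrt_by_cell <- lrt_rows |>
    dplyr::group_by(.data$family, .data$m_group, .data$scenario) |>
    dplyr::summarise(pct_reject = 100 * mean(.data$lrt_p < alpha),
                     n = dplyr::n(), .groups = "drop")

  best <- rows |>
    dplyr::group_by(.data$dataset) |>
    dplyr::arrange(.data$AICc, .data$k, .data$model, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  n_data <- dplyr::n_distinct(rows$dataset)
  best_aicc_pct <- tibble::tibble(model = sort(unique(rows$model))) |>
    dplyr::left_join(dplyr::count(best, .data$model), by = "model") |>
    dplyr::mutate(pct_best = 100 * dplyr::coalesce(.data$n, 0L) / n_data) |>
    dplyr::select("model", "pct_best")

  multiple_ranges <- rows |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(mean_multiple = mean(.data$n_multiple),
                     .groups = "drop")

  structure(
    list(
      f1_by_model = f1_by_model, f1_by_group = f1_by_group,
      f1_by_scenario = f1_by_scenario,
      lrt_overall = lrt_overall, lrt_by_cell = lrt_by_cell,
      best_aicc_pct = best_aicc_pct, multiple_ranges = multiple_ranges,
      n_datasets = n_data, alpha = alpha
    ),
    class = "benchmark_summary"
  )
}

#' @export
print.benchmark_summary <- function(x, ...) {
  cat("<benchmark_summary> ", x$n_datasets, " datasets\n", sep = "")
  cat("\nMean F1 by model:\n"); print(x$f1_by_model)
  cat("\nLRT rejection % by family (alpha = ", x$alpha, "):\n", sep = "")
  print(x$lrt_overall)
  cat("\nBest-AICc %:\n"); print(x$best_aicc_pct)
  cat("\nMean multiple-range annotations:\n"); print(x$multiple_ranges)
  invisible(x)
}

#' Two-sample t-test on per-dataset F1 between two models
#'
#' @param rows Benchmark rows as in [aggregate_benchmark()].
#' @param model_a,model_b Model names to compare.
#' @return A one-row tibble: `model_a`, `model_b`, `mean_a`, `mean_b`,
#'   `t`, `df`, `p_value`.
#' @export
compare_f1 <- function(rows, model_a, model_b) {
  a <- rows$f1[rows$model == model_a]
  b <- rows$f1[rows$model == model_b]
  if (!length(a) || !length(b)) stop("model not found in `rows`",
                                     call. = FALSE)
  tt <- stats::t.test(a, b)
  tibble::tibble(model_a = model_a, model_b = model_b,
                 mean_a = mean(a), mean_b = mean(b),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value)
}
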