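mg <- function(pairs, sites = c("P", "M1", "M2"), primary = "P") {
  if (length(pairs) == 0) {
    return(migration_graph(
      tibble::tibble(source = character(), recipient = character()),
      sites = sites, primary = primary))
  }
  parts <- strsplit(pairs, ">")
  migration_graph(
    tibble::tibble(source = vapply(parts, `[`, "", 1),
                   recipient = vapply(parts, `[`, "", 2)),
    sites = sites, primary = primary)
}

test_that("precision, recall and F1 follow their formulas", {
  truth <- mg(c("P>M1", "P>M2", "M1>M2"))

  # perfect inference
  r <- score_paths(truth, truth)
  expect_equal(r$precision, 1)
  expect_equal(r$recall, 1)
  expect_equal(r$f1, 1)

  # TP = 2, FP = 1, FN = 1 -> precision = recall = F1 = 2/3
  inf <- mg(c("P>M1", "P>M2", "M2>M1"))
  truth2 <- mg(c("P>M1", "P>M2", "M1>M2"))
  r <- score_paths(inf, truth2)
  expect_equal(c(r$TP, r$FP, r$FN), c(2, 1, 1))
  expect_equal(r$precision, 2 / 3)
  expect_equal(r$recall, 2 / 3)
  expect_equal(r$f1, 2 / 3)

  # nothing inferred: all truth paths are missed
  r <- score_paths(mg(character(0)), truth)
  expect_equal(c(r$TP, r$FP, r$FN), c(0, 0, 3))
  expect_equal(r$f1, 0)

  # both empty counts as perfect
  r <- score_paths(mg(character(0)), mg(character(0)))
  expect_equal(r$f1, 1)
})

test_that("graphs over different site sets are rejected", {
  a <- mg("P>M1", sites = c("P", "M1"))
  b <- mg("P>M1", sites = c("P", "M1", "M2"))
  expect_error(score_paths(a, b), "site set")
})

test_that("multi-area sources get credit if any candidate pair is true", {
  truth <- mg(c("M1>M2"))
  inf <- migration_graph(
    tibble::tibble(source = "P,M1", recipient = "M2"),
    sites = c("P", "M1", "M2"), primary = "P")
  r <- score_paths(inf, truth)
  expect_equal(c(r$TP, r$FP, r$FN), c(1, 0, 0))
})

test_that("per-class counts split the overall TP/FP/FN", {
  truth <- mg(c("P>M1"))
  inf <- mg(c("P>M1", "M1>M2"))
  cc <- classify_counts(inf, truth)
  expect_equal(cc$correct[cc$class == "P->M"], 1)
  expect_equal(cc$erroneous[cc$class == "M->M"], 1)
  expect_equal(sum(cc$not_inferred), 0)

  truth <- mg(c("M1>P"))
  cc <- classify_counts(mg(character(0)), truth)
  expect_equal(cc$not_inferred[cc$class == "M->P"], 1)
  expect_equal(sum(cc$correct) + sum(cc$erroneous), 0)
})

test_that("class sums equal overall counts on random graphs", {
  set.seed(101)
  sites <- c("P", paste0("M", 1:4))
  all_pairs <- expand.grid(s = sites, r = sites,
                           stringsAsFactors = FALSE)
  all_pairs <- all_pairs[all_pairs$s != all_pairs$r, ]
  for (rep in 1:100) {
    draw <- function() {
      k <- sample(0:8, 1)
      if (k == 0) return(mg(character(0), sites = sites))
      rows <- all_pairs[sample(nrow(all_pairs), k, replace = TRUE), ]
      mg(paste0(rows$s, ">", rows$r), sites = sites)
    }
    inf <- draw(); truth <- draw()
    for (mode in c("unique", "multiset")) {
      sc <- score_paths(inf, truth, mode = mode)
      cc <- classify_counts(inf, truth, mode = mode)
      expect_equal(sum(cc$correct), sc$TP)
      expect_equal(sum(cc$erroneous), sc$FP)
      expect_equal(sum(cc$not_inferred), sc$FN)
    }
  }
})

test_that("unique and multiset modes agree when no pair repeats", {
  set.seed(202)
  sites <- c("P", "M1", "M2", "M3")
  all_pairs <- expand.grid(s = sites, r = sites, stringsAsFactors = FALSE)
  all_pairs <- all_pairs[all_pairs$s != all_pairs$r, ]
  for (rep in 1:20) {
    draw <- function() {
      k <- sample(0:6, 1)
      if (k == 0) return(mg(character(0), sites = sites))
      rows <- all_pairs[sample(nrow(all_pairs), k), ]
      mg(paste0(rows$s, ">", rows$r), sites = sites)
    }
    inf <- draw(); truth <- draw()
    expect_equal(score_paths(inf, truth, "unique"),
                 score_paths(inf, truth, "multiset"))
  }
})

test_that("F1 is invariant under relabeling sites in both graphs", {
  sites <- c("P", "M1", "M2")
  relabel <- c(P = "P", M1 = "M2", M2 = "M1")
  inf <- mg(c("P>M1", "M1>M2"))
  truth <- mg(c("P>M1", "M2>M1"))
  swap <- function(g) {
    tb <- tibble::as_tibble(g)
    mg(paste0(relabel[tb$source], ">", relabel[tb$recipient]))
  }
  expect_equal(score_paths(inf, truth)$f1,
               score_paths(swap(inf), swap(truth))$f1)
})

test_that("benchmark aggregation reproduces hand-computed summaries", {
  rows <- tidyr::expand_grid(
    dataset = paste0("d", 1:4),
    model = c("DEC", "DEC+J")
  )
  rows$m_group <- rep(c("m5", "m5", "m8", "m8"), each = 2)
  rows$scenario <- rep(c("mS", "pR", "mS", "pR"), each = 2)
  rows$family <- "DEC"
  rows$founder <- rows$model == "DEC+J"
  rows$k <- ifelse(rows$founder, 3, 2)
  rows$AICc <- c(10, 12, 10, 8, 5, 5, 7, 6)   # ties broken by fewer params
  rows$f1 <- c(0.8, 0.6, 0.9, 0.7, 1.0, 0.8, 0.5, 0.3)
  rows$n_multiple <- c(2, 0, 1, 0, 3, 1, 0, 0)
  rows$lrt_p <- ifelse(rows$founder, c(NA, 0.01, NA, 0.2, NA, 0.03,
                                       NA, 0.04), NA)

  s <- aggregate_benchmark(rows)
  expect_equal(s$n_datasets, 4)
  expect_equal(s$f1_by_model$mean_f1[s$f1_by_model$model == "DEC"],
               mean(c(0.8, 0.9, 1.0, 0.5)))
  m5dec <- s$f1_by_group$mean_f1[s$f1_by_group$model == "DEC" &
                                   s$f1_by_group$m_group == "m5"]
  expect_equal(m5dec, mean(c(0.8, 0.9)))
  expect_equal(s$lrt_overall$pct_reject, 75)  # 3 of 4 below 0.05
  # datasets d1 (tie -> DEC), d3, d4 best for DEC+J? AICc pairs:
  # d1: 10 vs 12 -> DEC; d2: 10 vs 8 -> DEC+J; d3: 5 vs 5 tie -> DEC;
  # d4: 7 vs 6 -> DEC+J
  bp <- setNames(s$best_aicc_pct$pct_best, s$best_aicc_pct$model)
  expect_equal(unname(bp["DEC"]), 50)
  expect_equal(unname(bp["DEC+J"]), 50)
  expect_equal(
    s$multiple_ranges$mean_multiple[s$multiple_ranges$model == "DEC"],
    mean(c(2, 1, 3, 0)))
})

test_that("LRT percentage arithmetic: 6 rejections of 10 is 60%", {
  rows <- tibble::tibble(
    dataset = paste0("d", 1:10), m_group = "m5", scenario = "mS",
    model = "DEC+J", family = "DEC", founder = TRUE, k = 3,
    AICc = 1, f1 = 1, n_multiple = 0,
    lrt_p = c(rep(0.01, 6), rep(0.5, 4))
  )
  base <- rows
  base$model <- "DEC"; base$founder <- FALSE; base$k <- 2
  base$lrt_p <- NA
  s <- aggregate_benchmark(dplyr::bind_rows(rows, base))
  expect_equal(s$lrt_overall$pct_reject, 60)
})

test_that("the F1 t-test helper compares two models", {
  set.seed(404)
  rows <- tibble::tibble(model = rep(c("A", "B"), each = 6),
                         f1 = c(rnorm(6, 0.8, 0.05), rnorm(6, 0.5, 0.05)))
  out <- compare_f1(rows, "A", "B")
  expect_equal(out$mean_a, mean(rows$f1[rows$model == "A"]))
  expect_lt(out$p_value, 0.05)
})
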