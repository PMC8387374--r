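test_that("two clones in the primary on zero branches give lnL = ln(1/3)", {
  # only the root state {P} can produce the data; uniform prior over 3 states
  tr <- ape::read.tree(text = "(a:0,b:0);")
  loc <- tibble::tibble(clone = c("a", "b"), site = c("P", "P"))
  sp <- range_space(2)
  for (model in c("DEC", "DIVALIKE", "BAYAREALIKE")) {
    expect_equal(clone_loglik(tr, loc, model, d = 0.2, e = 0.1, space = sp),
                 log(1 / 3), tolerance = 1e-12)
  }
})

test_that("pruning equals exhaustive enumeration on small random trees", {
  set.seed(7)
  for (rep in 1:25) {
    n_tips <- sample(2:5, 1)
    ds <- random_dataset(n_tips, n_areas = sample(2:3, 1))
    model <- sample(biogeo_model_names(), 1)
    d <- runif(1, 0, 0.5); e <- runif(1, 0, 0.3)
    j <- if (grepl("J", model)) runif(1, 0, 2) else 0
    ll <- clone_loglik(ds$tree, ds$locations, model, d, e, j,
                       space = ds$space)
    ref <- oracle_loglik(ds$tree, ds$locations, model, d, e, j, ds$space)
    expect_equal(ll, ref, tolerance = 1e-9)
  }
})

test_that("the +J model at j = 0 matches the base model exactly", {
  set.seed(11)
  ds <- random_dataset(6, 3)
  for (fam in c("BAYAREALIKE", "DEC", "DIVALIKE")) {
    l0 <- clone_loglik(ds$tree, ds$locations, fam, 0.2, 0.05,
                       space = ds$space)
    lj <- clone_loglik(ds$tree, ds$locations, paste0(fam, "+J"), 0.2, 0.05,
                       j = 0, space = ds$space)
    expect_identical(l0, lj)
  }
})

test_that("lnL is invariant to tip order and to zero-length pass-throughs", {
  set.seed(13)
  ds <- random_dataset(6, 3)
  ll <- clone_loglik(ds$tree, ds$locations, "DEC+J", 0.2, 0.05, 0.5,
                     space = ds$space)

  rot <- ape::rotateConstr(ds$tree, rev(ds$tree$tip.label))
  expect_equal(clone_loglik(rot, ds$locations, "DEC+J", 0.2, 0.05, 0.5,
                            space = ds$space), ll, tolerance = 1e-10)

  shuffled <- ds$locations[sample(nrow(ds$locations)), ]
  expect_equal(clone_loglik(ds$tree, shuffled, "DEC+J", 0.2, 0.05, 0.5,
                            space = ds$space), ll, tolerance = 1e-12)

  # a degree-2 pass-through node on a zero-length branch changes nothing
  txt <- ape::write.tree(ds$tree)
  with_single <- gsub("(t1:[0-9.e-]+)", "(\\1):0", txt)
  tr2 <- ape::read.tree(text = with_single)
  expect_equal(clone_loglik(tr2, ds$locations, "DEC+J", 0.2, 0.05, 0.5,
                            space = ds$space), ll, tolerance = 1e-9)
})

test_that("missing locations and polytomies are rejected", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  sp <- range_space(2)
  expect_error(
    clone_loglik(tr, tibble::tibble(clone = c("a", "b"),
                                    site = c("P", "M1")),
                 "DEC", 0.1, 0.1, space = sp),
    "no location")
  poly <- ape::read.tree(text = "(a:1,b:1,c:1);")
  expect_error(
    clone_loglik(poly, tibble::tibble(clone = c("a", "b", "c"),
                                      site = c("P", "P", "M1")),
                 "DEC", 0.1, 0.1, space = sp),
    "binary")
})

test_that("information criteria follow their formulas", {
  # AICc bookkeeping: lnL = -10, k = 2, n = 9 -> AIC 24, AICc 26
  set.seed(5)
  ds <- random_dataset(9, 2)
  f <- fit_biogeo(ds$tree, ds$locations, "DEC", space = ds$space)
  expect_equal(f$AIC, 2 * f$k - 2 * f$logLik)
  expect_equal(f$AICc, f$AIC + 2 * f$k * (f$k + 1) / (f$n_obs - f$k - 1))
  expect_equal(f$BIC, f$k * log(f$n_obs) - 2 * f$logLik)
  expect_equal(f$n_obs, 9)
  aic <- 2 * 2 - 2 * (-10)
  expect_equal(aic, 24)
  expect_equal(aic + 2 * 2 * 3 / (9 - 2 - 1), 26)
})

test_that("the fitted maximum dominates a parameter grid and hits the data-generating region", {
  sim <- simulate_under_model(15, "DEC", d = 0.3, e = 0.05, seed = 21)
  f <- fit_biogeo(sim$tree, sim$locations, "DEC", space = sim$space)
  expect_true(f$converged)
  for (d in c(0.05, 0.3, 1)) {
    for (e in c(0.01, 0.1, 1)) {
      expect_gte(f$logLik + 1e-6,
                 clone_loglik(sim$tree, sim$locations, "DEC", d, e,
                              space = sim$space))
    }
  }
})

test_that("data without expansions drives d to its lower bound", {
  # every clone in the primary: no dispersal signal, d collapses to the
  # boundary
  set.seed(3)
  ds <- random_dataset(10, 3)
  ds$locations$site <- "P"
  f <- fit_biogeo(ds$tree, ds$locations, "DEC", space = ds$space)
  expect_lt(f$d, 1e-6)
})

test_that("per-node marginal probabilities are proper and match restricted enumeration", {
  set.seed(17)
  ds <- random_dataset(4, 2)
  f <- fit_biogeo(ds$tree, ds$locations, "DEC", space = ds$space)
  expect_equal(rowSums(f$node_probs), rep(1, nrow(f$node_probs)),
               ignore_attr = TRUE, tolerance = 1e-8)
  for (node_chr in rownames(f$node_probs)) {
    ref <- oracle_marginal(f$tree, ds$locations, "DEC", f$d, f$e, 0,
                           ds$space, as.integer(node_chr))
    expect_equal(unname(f$node_probs[node_chr, ]), ref, tolerance = 1e-6)
  }
})

test_that("likelihood-ratio test arithmetic matches the chi-square df = 1 tail", {
  set.seed(23)
  ds <- random_dataset(8, 3)
  f0 <- fit_biogeo(ds$tree, ds$locations, "DEC", space = ds$space)
  f1 <- fit_biogeo(ds$tree, ds$locations, "DEC+J", space = ds$space)
  lrt <- likelihood_ratio_test(f0, f1)
  expect_gte(lrt$stat, 0)
  expect_equal(lrt$p_value, pchisq(lrt$stat, 1, lower.tail = FALSE))
  expect_equal(lrt$delta_bic, f0$BIC - f1$BIC)

  # reference tail values for the statistic magnitudes seen in breast-cancer
  # clone analyses
  expect_equal(pchisq(4.5, 1, lower.tail = FALSE), 0.0339, tolerance = 1e-2)
  expect_equal(pchisq(10, 1, lower.tail = FALSE), 0.00157, tolerance = 1e-2)

  # equal likelihoods give stat 0 and p 1
  lrt0 <- likelihood_ratio_test(f0, f0b <- local({
    x <- f1; x$logLik <- f0$logLik; x
  }))
  expect_equal(lrt0$stat, 0)
  expect_equal(lrt0$p_value, 1)

  # mixture reference halves the tail probability
  expect_equal(likelihood_ratio_test(f0, f1, boundary = "mixture")$p_value,
               lrt$p_value / 2)

  expect_error(likelihood_ratio_test(f1, f0), "counterpart")
})

test_that("model table ranks by AICc with ties broken by parsimony", {
  set.seed(29)
  ds <- random_dataset(8, 2)
  fits <- fit_all_models(ds$tree, ds$locations,
                         models = c("DEC", "DEC+J", "DIVALIKE"),
                         space = ds$space)
  tab <- model_table(fits)
  expect_equal(nrow(tab), 3)
  expect_true(!is.unsorted(tab$AICc))
  expect_equal(tab$delta_AICc[1], 0)
  expect_equal(sum(tab$weight_AICc), 1)

  # equal lnL: the 2-parameter model must rank above the 3-parameter one
  f2 <- fits$DEC
  f3 <- fits$`DEC+J`
  f3$logLik <- f2$logLik
  f3$AICc <- 2 * 3 - 2 * f3$logLik + 2 * 3 * 4 / (f3$n_obs - 4)
  expect_equal(model_table(list(f3, f2))$model[1], "DEC")
  expect_equal(model_table(list(f2))$model, "DEC")
})
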