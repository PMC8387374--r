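check_scenario_postconditions <- function(sim) {
  cfg <- sim$config
  truth <- sim$truth
  sites <- attr(truth, "sites")
  mets <- setdiff(sites, "P")

  # configured ranges
  expect_true(cfg$n_sites >= 5 && cfg$n_sites <= 11)
  expect_true(cfg$n_clones >= 7 && cfg$n_clones <= 28)
  expect_true(cfg$n_snvs >= 9 && cfg$n_snvs <= 99)
  expect_equal(cfg$m_group, if (cfg$n_sites <= 7) "m5" else "m8")

  # every site hosts at least one clone; truth sites all appear at tips
  expect_setequal(unique(sim$locations$site), sites)
  expect_true(all(c(truth$source, truth$recipient) %in%
                    sim$locations$site))

  pair <- paste(truth$source, truth$recipient)
  per_recipient <- table(truth$recipient)
  first_seed <- !duplicated(truth$recipient)

  if (cfg$scenario == "mS") {
    expect_true(all(truth$source == "P"))
    expect_true(all(per_recipient == 1))
    expect_setequal(truth$recipient, mets)
  }
  if (cfg$scenario == "pS") {
    expect_true(all(truth$source == "P"))
    expect_true(all(per_recipient >= 2))
    expect_setequal(truth$recipient, mets)
  }
  if (cfg$scenario %in% c("pM", "pR")) {
    expect_gte(length(unique(truth$source)), 2)
  }
  if (cfg$scenario == "pR") {
    # at least one reseeding edge, always including one into the primary
    expect_true("P" %in% truth$recipient)
    expect_true(any(truth$class == "M->P"))
  } else {
    expect_false("P" %in% truth$recipient)
  }

  # the primary reaches every metastasis through the seeding edges
  reached <- "P"
  edges <- unique(truth[, c("source", "recipient")])
  repeat {
    new <- unique(edges$recipient[edges$source %in% reached])
    if (all(new %in% reached)) break
    reached <- union(reached, new)
  }
  expect_setequal(reached, sites)

  # tree structure: rooted binary, tips = clones, lengths are SNV fractions
  expect_equal(ape::Ntip(sim$tree), cfg$n_clones)
  expect_true(ape::is.binary(sim$tree))
  expect_true(ape::is.rooted(sim$tree))
  expect_equal(sum(sim$tree$edge.length) * cfg$n_snvs, cfg$n_snvs,
               tolerance = 1e-9)

  # genotype matrix: clones x SNVs, compatible with a perfect phylogeny
  expect_equal(dim(sim$genotypes), c(cfg$n_clones, cfg$n_snvs))
  expect_true(admits_perfect_phylogeny(sim$genotypes))
}

test_that("seeding scenarios satisfy their postconditions across seeded draws", {
  for (i in 1:10) {
    for (scen in c("mS", "pS", "pM", "pR")) {
      for (grp in c("m5", "m8")) {
        sim <- simulate_seeding(scen, m_group = grp, seed = 1000 + i)
        check_scenario_postconditions(sim)
      }
    }
  }
})

test_that("mS with 5 sites has exactly 4 seeding edges", {
  sim <- simulate_seeding("mS", n_sites = 5, seed = 42)
  expect_equal(nrow(sim$truth), 4)
  expect_true(all(table(sim$truth$recipient) == 1))
})

test_that("the same seed reproduces the dataset exactly", {
  a <- simulate_seeding("pR", seed = 99)
  b <- simulate_seeding("pR", seed = 99)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  expect_identical(a$locations, b$locations)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(tibble::as_tibble(a$truth), tibble::as_tibble(b$truth))
})

test_that("infeasible configurations are rejected before sampling", {
  expect_error(simulate_seeding("mS", n_sites = 8, n_clones = 7, seed = 1),
               "infeasible")
  expect_error(simulate_seeding("mS", n_sites = 5, n_snvs = 5, seed = 1),
               "9..99")
})

test_that("maximum parsimony on the genotypes recovers the generating tree length", {
  skip_if_not_installed("phangorn")
  sim <- simulate_seeding("mS", n_sites = 5, n_clones = 8, seed = 7)
  dat <- phangorn::phyDat(sim$genotypes, type = "USER", levels = c(0, 1))
  # no homoplasy: the generating tree needs exactly one change per variable
  # SNV, and branch-and-bound search finds no shorter tree
  variable <- sum(apply(sim$genotypes, 2, function(x) length(unique(x))) > 1)
  expect_equal(phangorn::parsimony(sim$tree, dat), variable)
  bb <- phangorn::bab(dat, trace = 0)
  best <- min(phangorn::parsimony(bb, dat))
  expect_equal(best, variable)
})

test_that("model-based simulation respects its degenerate limits", {
  sim <- simulate_under_model(10, "BAYAREALIKE", d = 0, e = 0, seed = 8)
  expect_equal(length(unique(sim$locations$site)), 1)
  root_state <- sim$node_states[ape::Ntip(sim$tree) + 1]
  expect_equal(unique(sim$locations$site),
               sim$space$areas$label[sim$space$states[[root_state]]])
})

test_that("sampled cladogenetic events follow the table probabilities", {
  set.seed(33)
  sp <- range_space(3)
  ct <- clado_table(sp, "DEC+J", j = 0.5)
  m <- ct$table[[state_of(sp, c("P", "M1"))]]
  n_draw <- 1e5
  draws <- replicate(n_draw, tumorgeo:::sample_clado_event(m)[["left"]])
  for (lv in unique(m[, "left"])) {
    p <- sum(m[m[, "left"] == lv, "prob"])
    phat <- mean(draws == lv)
    se <- sqrt(p * (1 - p) / n_draw)
    expect_lt(abs(phat - p), 4 * se + 1e-12)
  }
})

test_that("the benchmark grid covers all cells with derived seeds", {
  bench <- make_benchmark(n_per_cell = 1, seed = 5)
  expect_equal(nrow(bench), 8)
  expect_equal(nrow(dplyr::distinct(bench, m_group, scenario)), 8)
  bench2 <- make_benchmark(n_per_cell = 2, seed = 5)
  expect_equal(nrow(bench2), 16)
  expect_equal(unname(table(paste(bench2$m_group, bench2$scenario))),
               rep(2L, 8), ignore_attr = TRUE)
  # reproducible
  again <- make_benchmark(n_per_cell = 1, seed = 5)
  expect_identical(bench$seed, again$seed)
  expect_identical(bench$data[[3]]$genotypes, again$data[[3]]$genotypes)
})
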