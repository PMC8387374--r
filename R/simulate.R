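#' @importFrom stats rexp runif
NULL

sample1 <- function(x) x[sample.int(length(x), 1L)]

#' Simulate a metastatic seeding dataset
#'
#' Generates a clone phylogeny, per-clone tumor-site labels, an
#' infinite-sites SNV genotype matrix and the true migration graph under one
#' of four seeding scenarios of increasing complexity:
#' * `mS` — monoclonal single-source: every metastasis seeded by exactly one
#'   clone from the primary tumor.
#' * `pS` — polyclonal single-source: 2-3 clones from the primary seed each
#'   metastasis.
#' * `pM` — polyclonal multi-source: metastases are seeded (2-3 clones each)
#'   from several distinct source sites, primary or earlier metastases.
#' * `pR` — polyclonal reseeding: as `pM`, plus at least one reseeding
#'   migration into an already-colonized site, always including a
#'   metastasis-to-primary edge.
#'
#' The tree grows by random binary splitting of extant clone lineages; a
#' migration is a founder split in which one daughter colonizes the
#' recipient site. SNVs are dropped uniformly on tree edges (no homoplasy;
#' the implied outgroup carries no mutations) and branch lengths are
#' per-branch mutation counts divided by the total SNV count — the
#' "ultrametric-like" mutations-per-site time proxy. Datasets are fully
#' reproducible from `seed`.
#'
#' @param scenario One of `"mS"`, `"pS"`, `"pM"`, `"pR"`.
#' @param n_sites Number of tumor sites: 5-7 (group m5) or 8-11 (group m8).
#'   Sampled from `m_group` when `NULL`.
#' @param n_clones Number of clones (tree tips), 7-28. Sampled to fit the
#'   seeding plan when `NULL`.
#' @param n_snvs Number of SNVs, 9-99. Sampled when `NULL`.
#' @param m_group `"m5"` or `"m8"`; used to sample `n_sites` when that is
#'   `NULL`.
#' @param seed Integer RNG seed (optional but recommended).
#' @return An object of class `sim_dataset`: a list with `tree` (`phylo`),
#'   `locations` (tibble `clone`, `site`), `genotypes` (clone x SNV 0/1
#'   matrix), `truth` (a `migration_graph`), and `config`.
#' @examples
#' sim <- simulate_seeding("mS", n_sites = 5, seed = 1)
#' sim$truth
#' @export
simulate_seeding <- function(scenario = c("mS", "pS", "pM", "pR"),
                             n_sites = NULL, n_clones = NULL, n_snvs = NULL,
                             m_group = c("m5", "m8"), seed = NULL) {
  scenario <- match.arg(scenario)
  m_group <- match.arg(m_group)
  run <- function() {
    simulate_seeding_impl(scenario, n_sites, n_clones, n_snvs, m_group)
  }
  if (is.null(seed)) return(run())
  out <- withr::with_seed(seed, run())
  out$config$seed <- seed
  out
}

simulate_seeding_impl <- function(scenario, n_sites, n_clones, n_snvs,
                                  m_group) {
  if (is.null(n_sites)) {
    n_sites <- if (m_group == "m5") sample1(5:7) else sample1(8:11)
  }
  if (n_sites < 2) stop("need at least 2 sites", call. = FALSE)
  m_group <- if (n_sites <= 7) "m5" else "m8"
  sites <- c("P", paste0("M", seq_len(n_sites - 1L)))
  mets <- sites[-1]

  # --- seeding plan: ordered list of (source, recipient, k clones) ---------
  order_mets <- sample(mets)
  k_of <- function() if (scenario == "mS") 1L else sample1(2:3)
  events <- list()
  colonized <- "P"
  for (m in order_mets) {
    src <- switch(scenario,
      mS = "P", pS = "P",
      pM = sample1(colonized), pR = sample1(colonized))
    events[[length(events) + 1]] <- list(src = src, rec = m, k = k_of())
    colonized <- c(colonized, m)
  }
  if (scenario %in% c("pM", "pR") && length(mets) > 1) {
    srcs <- vapply(events, `[[`, character(1), "src")
    if (length(unique(srcs)) == 1) {   # force a second source site
      events[[length(events)]]$src <- order_mets[1]
    }
  }
  if (scenario == "pR") {              # reseeding: always one edge into P
    events[[length(events) + 1]] <- list(src = sample1(mets), rec = "P",
                                         k = sample1(1:3))
    if (runif(1) < 0.5 && length(mets) > 1) {
      rec <- sample1(mets)
      events[[length(events) + 1]] <-
        list(src = sample1(setdiff(sites, rec)), rec = rec, k = sample1(1:3))
    }
  }
  m_total <- sum(vapply(events, `[[`, integer(1), "k"))
  min_clones <- max(7L, m_total + 2L, n_sites)
  if (min_clones > 28L) {              # trim polyclonal events to fit
    for (i in seq_along(events)) events[[i]]$k <- min(events[[i]]$k, 2L)
    m_total <- sum(vapply(events, `[[`, integer(1), "k"))
    min_clones <- max(7L, m_total + 2L, n_sites)
  }
  if (is.null(n_clones)) {
    n_clones <- if (min_clones >= 28L) 28L else sample1(min_clones:28L)
  }
  if (n_clones < n_sites) {
    stop("infeasible: n_clones < n_sites", call. = FALSE)
  }
  if (n_clones - 1L < m_total) {
    stop("infeasible: fewer splits than migrating clones", call. = FALSE)
  }
  if (is.null(n_snvs)) n_snvs <- sample1(9:99)
  if (n_snvs < 9 || n_snvs > 99) {
    stop("`n_snvs` must be in 9..99", call. = FALSE)
  }

  # --- grow the clone tree -------------------------------------------------
  mig_ops <- unlist(lapply(events, function(ev) {
    replicate(ev$k, list(src = ev$src, rec = ev$rec), simplify = FALSE)
  }), recursive = FALSE)
  n_splits <- n_clones - 1L
  op_type <- sample(c(rep("mig", length(mig_ops)),
                      rep("plain", n_splits - length(mig_ops))))

  parent <- rep(NA_integer_, 2L * n_clones - 1L)
  site <- rep(NA_character_, 2L * n_clones - 1L)
  site[1] <- "P"
  n_nodes <- 1L
  active <- 1L
  mig_i <- 0L
  truth_src <- character(0); truth_rec <- character(0)
  truth_child <- integer(0)

  for (op in op_type) {
    if (op == "mig") {
      mig_i <- mig_i + 1L
      mo <- mig_ops[[mig_i]]
      x <- sample1(active[site[active] == mo$src])
      c1 <- n_nodes + 1L; c2 <- n_nodes + 2L
      site[c1] <- mo$src; site[c2] <- mo$rec
      truth_src <- c(truth_src, mo$src)
      truth_rec <- c(truth_rec, mo$rec)
      truth_child <- c(truth_child, c2)
    } else {
      x <- sample1(active)
      c1 <- n_nodes + 1L; c2 <- n_nodes + 2L
      site[c1] <- site[x]; site[c2] <- site[x]
    }
    parent[c1] <- x; parent[c2] <- x
    n_nodes <- n_nodes + 2L
    active <- c(setdiff(active, x), c1, c2)
  }

  # --- convert to phylo ----------------------------------------------------
  n_all <- n_nodes
  has_child <- tabulate(parent[!is.na(parent)], nbins = n_all) > 0
  my_tips <- which(!has_child)
  my_internal <- c(1L, setdiff(which(has_child), 1L))
  id_map <- integer(n_all)
  id_map[my_tips] <- seq_along(my_tips)
  id_map[my_internal] <- length(my_tips) + seq_along(my_internal)

  non_root <- setdiff(seq_len(n_all), 1L)
  edge <- cbind(id_map[parent[non_root]], id_map[non_root])

  # infinite-sites SNVs: each mutation on one edge (edge keyed by child node)
  snv_edge_child <- non_root[sample.int(length(non_root), n_snvs,
                                        replace = TRUE)]
  counts <- tabulate(match(snv_edge_child, non_root),
                     nbins = length(non_root))
  edge_len <- counts / n_snvs

  tip_labels <- paste0("C", seq_along(my_tips))
  tree <- structure(
    list(edge = edge, edge.length = edge_len,
         tip.label = tip_labels, Nnode = length(my_internal)),
    class = "phylo"
  )
  tree <- ape::reorder.phylo(tree, "cladewise")

  # genotypes: SNV present in a tip if its edge lies on the root path
  path_nodes <- function(x) {
    out <- integer(0)
    while (!is.na(parent[x])) { out <- c(out, x); x <- parent[x] }
    out
  }
  tip_paths <- lapply(my_tips, path_nodes)
  genotypes <- matrix(0L, length(my_tips), n_snvs,
                      dimnames = list(tip_labels,
                                      paste0("snv", seq_len(n_snvs))))
  for (i in seq_along(my_tips)) {
    genotypes[i, ] <- as.integer(snv_edge_child %in% tip_paths[[i]])
  }

  locations <- tibble::tibble(clone = tip_labels, site = site[my_tips])

  truth_edge <- match(id_map[truth_child], tree$edge[, 2])
  truth <- migration_graph(
    tibble::tibble(edge = truth_edge, source = truth_src,
                   recipient = truth_rec),
    sites = sites, primary = "P"
  )

  structure(
    list(
      tree = tree, locations = locations, genotypes = genotypes,
      truth = truth,
      config = list(scenario = scenario, m_group = m_group,
                    n_sites = n_sites, n_clones = n_clones,
                    n_snvs = n_snvs, seed = NULL)
    ),
    class = "sim_dataset"
  )
}

#' @export
print.sim_dataset <- function(x, ...) {
  cfg <- x$config
  cat("<sim_dataset> ", cfg$scenario, " (", cfg$m_group, "): ",
      cfg$n_sites, " sites, ", cfg$n_clones, " clones, ", cfg$n_snvs,
      " SNVs, ", nrow(x$truth), " true migration path(s)\n", sep = "")
  invisible(x)
}

# sample one cladogenetic event row from a per-parent event matrix
sample_clado_event <- function(event_matrix) {
  event_matrix[sample.int(nrow(event_matrix), 1L,
                          prob = event_matrix[, 3L]), , drop = TRUE]
}

# jump-chain simulation of the anagenetic CTMC for time t from state s
sim_ctmc <- function(Q, s, t) {
  repeat {
    rate <- -Q[s, s]
    if (rate <= 0) return(s)
    w <- rexp(1, rate)
    if (w > t) return(s)
    t <- t - w
    p <- Q[s, ]
    p[s] <- 0
    s <- sample.int(ncol(Q), 1L, prob = p)
  }
}

#' Simulate tip sites under a biogeographic model (generative counterpart of
#' the likelihood)
#'
#' Samples a root range uniformly, a cladogenetic event at each internal
#' node from the model's event table, and an anagenetic
#' dispersal/extinction history along each branch, then reduces each tip
#' range to one uniformly sampled occupied site for the location label.
#' Used for parameter-recovery experiments.
#'
#' @param n_tips Number of clones.
#' @param model A [biogeo_model()] or name.
#' @param d,e,j Model parameters.
#' @param n_areas Number of tumor sites (default 3).
#' @param depth Multiplier applied to the random tree's branch lengths.
#' @param seed Optional RNG seed.
#' @return A list with `tree`, `locations` (tibble), `space`, `node_states`
#'   (true range state per node), and the generating parameters.
#' @export
simulate_under_model <- function(n_tips, model, d, e, j = 0, n_areas = 3,
                                 depth = 1, seed = NULL) {
  run <- function() {
    model <- biogeo_model(model)
    space <- range_space(n_areas)
    tree <- ape::rtree(n_tips)
    tree$edge.length <- tree$edge.length * depth
    Q <- rate_matrix(space, d, e)
    ct <- clado_table(space, model, j)$table

    ntip <- ape::Ntip(tree)
    n_nodes <- ntip + tree$Nnode
    state <- integer(n_nodes)
    state[ntip + 1L] <- sample.int(space$n_states, 1L)

    pre <- ape::reorder.phylo(tree, "cladewise")   # parents before children
    child_rows <- split(seq_len(nrow(pre$edge)), pre$edge[, 1])
    for (v in unique(pre$edge[, 1])) {
      rows <- child_rows[[as.character(v)]]
      ev <- sample_clado_event(ct[[state[v]]])
      starts <- c(ev[["left"]], ev[["right"]])
      for (i in 1:2) {
        ch <- pre$edge[rows[i], 2]
        state[ch] <- sim_ctmc(Q, starts[i], pre$edge.length[rows[i]])
      }
    }
    tip_site <- vapply(seq_len(ntip), function(i) {
      space$areas$label[sample1(space$states[[state[i]]])]
    }, character(1))
    list(
      tree = tree,
      locations = tibble::tibble(clone = tree$tip.label, site = tip_site),
      space = space, node_states = state,
      model = model, d = d, e = e, j = j
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate a full simulated benchmark
#'
#' Produces `n_per_cell` datasets for each of the 8 cells of the benchmark
#' design: tumor-count group (m5: 5-7 sites, m8: 8-11 sites) crossed with
#' the four seeding scenarios (mS, pS, pM, pR). The default `n_per_cell =
#' 10` gives the 80-dataset design.
#'
#' @param n_per_cell Datasets per (group, scenario) cell (>= 1).
#' @param seed Integer seed; per-dataset seeds are derived from it.
#' @return A tibble with one row per dataset: `dataset`, `m_group`,
#'   `scenario`, `n_sites`, `n_clones`, `n_snvs`, `seed`, and a list-column
#'   `data` of `sim_dataset` objects.
#' @export
make_benchmark <- function(n_per_cell = 10, seed = 1) {
  stopifnot(n_per_cell >= 1)
  cells <- tidyr::expand_grid(m_group = c("m5", "m8"),
                              scenario = c("mS", "pS", "pM", "pR"))
  rows <- purrr::map_dfr(seq_len(nrow(cells)), function(ci) {
    purrr::map_dfr(seq_len(n_per_cell), function(i) {
      ds_seed <- as.integer((as.numeric(seed) * 1009 + ci * 101 + i) %%
                              2147483647)
      sim <- simulate_seeding(cells$scenario[ci],
                              m_group = cells$m_group[ci], seed = ds_seed)
      tibble::tibble(
        dataset = paste0(cells$m_group[ci], cells$scenario[ci], "_", i),
        m_group = cells$m_group[ci], scenario = cells$scenario[ci],
        n_sites = sim$config$n_sites, n_clones = sim$config$n_clones,
        n_snvs = sim$config$n_snvs, seed = ds_seed,
        data = list(sim)
      )
    })
  })
  rows
}

#' Run the model-fitting benchmark on simulated datasets
#'
#' For every dataset and model this fits the model, annotates ancestral
#' ranges, extracts migration paths, scores them against the dataset's true
#' migration graph, and attaches the founder-event likelihood-ratio test to
#' each `+J` row. The result feeds [aggregate_benchmark()].
#'
#' @param bench A benchmark tibble from [make_benchmark()].
#' @param models Model names to fit (default all six).
#' @param mode Path-scoring mode, see [score_paths()].
#' @return A tibble with one row per dataset x model: metadata, parameter
#'   estimates, `lnL`, `k`, `AIC`, `AICc`, `BIC`, `converged`, `n_multiple`,
#'   `TP`, `FP`, `FN`, `precision`, `recall`, `f1`, `lrt_stat`, `lrt_p`.
#' @export
run_benchmark <- function(bench, models = biogeo_model_names(),
                          mode = "unique") {
  purrr::map_dfr(seq_len(nrow(bench)), function(bi) {
    sim <- bench$data[[bi]]
    space <- space_from_locations(sim$locations)
    fits <- fit_all_models(sim$tree, sim$locations, models = models,
                           space = space)
    per_model <- purrr::map_dfr(fits, function(f) {
      ann <- annotate_ranges(f)
      paths <- migration_paths(ann, f$tree, f$space)
      sc <- score_paths(paths, sim$truth, mode = mode)
      tibble::tibble(
        model = f$model$name, family = f$model$family,
        founder = f$model$founder,
        d = f$d, e = f$e, j = f$j,
        lnL = f$logLik, k = f$k, AIC = f$AIC, AICc = f$AICc, BIC = f$BIC,
        converged = f$converged,
        n_multiple = n_multiple_ranges(ann),
        n_paths = nrow(paths)
      ) |> dplyr::bind_cols(sc)
    })
    per_model$lrt_stat <- NA_real_
    per_model$lrt_p <- NA_real_
    for (fam in unique(per_model$family)) {
      base <- fits[[fam]]
      alt <- fits[[paste0(fam, "+J")]]
      if (!is.null(base) && !is.null(alt)) {
        lrt <- likelihood_ratio_test(base, alt)
        sel <- per_model$model == paste0(fam, "+J")
        per_model$lrt_stat[sel] <- lrt$stat
        per_model$lrt_p[sel] <- lrt$p_value
      }
    }
    dplyr::bind_cols(
      bench[bi, c("dataset", "m_group", "scenario", "n_sites", "n_clones",
                  "n_snvs")],
      per_model
    )
  })
}
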