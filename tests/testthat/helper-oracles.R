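# Independent oracles used by the tests. These deliberately avoid the
# package's pruning/eigen machinery: matrix exponentials come from a
# truncated series, cladogenetic events from standalone set logic, and the
# tree likelihood from exhaustive enumeration over ancestral states.

series_expm <- function(Q, t, kmax = 40) {
  n <- nrow(Q)
  P <- diag(n)
  term <- diag(n)
  for (k in seq_len(kmax)) {
    term <- term %*% (Q * t) / k
    P <- P + term
  }
  P
}

# All ordered daughter pairs (area-id sets) allowed at a parent range, with
# weights, re-derived from the model definitions for max range size 2.
oracle_clado <- function(parent, family, founder, j, n_areas) {
  ev <- list()
  add <- function(l, r, w) ev[[length(ev) + 1]] <<- list(l = sort(l),
                                                         r = sort(r), w = w)
  if (family == "BAYAREALIKE" || length(parent) == 1) {
    add(parent, parent, 1)
  } else {
    a <- parent[1]; b <- parent[2]
    if (family == "DEC") {
      add(a, parent, 1); add(parent, a, 1)
      add(b, parent, 1); add(parent, b, 1)
    }
    add(a, b, 1); add(b, a, 1)
  }
  if (founder) {
    for (x in setdiff(seq_len(n_areas), parent)) {
      add(parent, x, j); add(x, parent, j)
    }
  }
  ev
}

# Exhaustive-enumeration log-likelihood: sums, over every assignment of a
# range state to every internal node, the product of the uniform root prior,
# the per-node cladogenetic mixture, and series-expm branch factors.
oracle_loglik <- function(tree, locations, model_name, d, e, j, space) {
  model <- biogeo_model(model_name)
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  n_states <- space$n_states
  loc <- setNames(locations$site, locations$clone)
  tip_state <- vapply(tree$tip.label,
                      function(tl) state_of(space, loc[[tl]]), integer(1))

  Q <- rate_matrix(space, d, e)
  edge <- tree$edge
  Pser <- lapply(tree$edge.length, function(t) series_expm(Q, t))

  # per-parent clado events as index matrices (l, r, p)
  clado <- oracle_clado_matrices(space, model, j)

  children <- split(seq_len(nrow(edge)), edge[, 1])
  internal <- (ntip + 1L):(ntip + nnode)
  grid <- as.matrix(expand.grid(rep(list(seq_len(n_states)), nnode)))

  total <- 0
  for (g in seq_len(nrow(grid))) {
    assign_state <- c(tip_state, grid[g, ])
    prod_v <- 1 / n_states        # uniform root prior
    for (v in internal) {
      rows <- children[[as.character(v)]]
      s1 <- assign_state[edge[rows[1], 2]]
      s2 <- assign_state[edge[rows[2], 2]]
      cm <- clado[[assign_state[v]]]
      node_sum <- sum(cm[, 3] * Pser[[rows[1]]][cbind(cm[, 1], s1)] *
                        Pser[[rows[2]]][cbind(cm[, 2], s2)])
      prod_v <- prod_v * node_sum
      if (prod_v == 0) break
    }
    total <- total + prod_v
  }
  unname(log(total))
}

oracle_clado_matrices <- function(space, model, j) {
  lapply(seq_len(space$n_states), function(s) {
    ev <- oracle_clado(space$states[[s]], model$family, model$founder, j,
                       space$n_areas)
    w <- vapply(ev, `[[`, numeric(1), "w")
    cbind(vapply(ev, function(x) state_of(space, x$l), integer(1)),
          vapply(ev, function(x) state_of(space, x$r), integer(1)),
          w / sum(w))
  })
}

# Marginal ancestral probabilities at one internal node by restricted
# enumeration (same machinery as oracle_loglik, conditioning on the state).
oracle_marginal <- function(tree, locations, model_name, d, e, j, space,
                            node) {
  n_states <- space$n_states
  full <- exp(oracle_loglik(tree, locations, model_name, d, e, j, space))
  ntip <- ape::Ntip(tree)
  vapply(seq_len(n_states), function(s) {
    restricted_loglik(tree, locations, model_name, d, e, j, space, node,
                      s) / full
  }, numeric(1))
}

restricted_loglik <- function(tree, locations, model_name, d, e, j, space,
                              node, state) {
  model <- biogeo_model(model_name)
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  n_states <- space$n_states
  loc <- setNames(locations$site, locations$clone)
  tip_state <- vapply(tree$tip.label,
                      function(tl) state_of(space, loc[[tl]]), integer(1))
  Q <- rate_matrix(space, d, e)
  edge <- tree$edge
  Pser <- lapply(tree$edge.length, function(t) series_expm(Q, t))
  clado <- oracle_clado_matrices(space, model, j)
  children <- split(seq_len(nrow(edge)), edge[, 1])
  internal <- (ntip + 1L):(ntip + nnode)
  grid <- as.matrix(expand.grid(rep(list(seq_len(n_states)), nnode)))
  grid <- grid[grid[, match(node, internal)] == state, , drop = FALSE]
  total <- 0
  for (g in seq_len(nrow(grid))) {
    assign_state <- c(tip_state, grid[g, ])
    prod_v <- 1 / n_states
    for (v in internal) {
      rows <- children[[as.character(v)]]
      s1 <- assign_state[edge[rows[1], 2]]
      s2 <- assign_state[edge[rows[2], 2]]
      cm <- clado[[assign_state[v]]]
      node_sum <- sum(cm[, 3] * Pser[[rows[1]]][cbind(cm[, 1], s1)] *
                        Pser[[rows[2]]][cbind(cm[, 2], s2)])
      prod_v <- prod_v * node_sum
      if (prod_v == 0) break
    }
    total <- total + prod_v
  }
  unname(total)
}

# Random rooted binary tree with uniform branch lengths and random tip sites.
random_dataset <- function(n_tips, n_areas, max_bl = 1) {
  tree <- ape::rtree(n_tips)
  tree$edge.length <- runif(nrow(tree$edge), 0, max_bl)
  space <- range_space(n_areas)
  locations <- tibble::tibble(
    clone = tree$tip.label,
    site = sample(space$areas$label, n_tips, replace = TRUE)
  )
  list(tree = tree, locations = locations, space = space)
}

# Binary characters with an all-zero root admit a perfect phylogeny iff all
# column pairs are compatible (no pair shows the 11, 10 and 01 patterns).
admits_perfect_phylogeny <- function(genotypes) {
  m <- ncol(genotypes)
  if (m < 2) return(TRUE)
  for (i in seq_len(m - 1)) {
    for (k in (i + 1):m) {
      a <- genotypes[, i]; b <- genotypes[, k]
      if (any(a & b) && any(a & !b) && any(!a & b)) return(FALSE)
    }
  }
  TRUE
}
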