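#' @importFrom stats optim pchisq setNames
NULL

# --- internal helpers -------------------------------------------------------

# Standardize a locations table (tibble/data.frame with columns clone, site,
# or a named character vector) into a tibble.
as_locations <- function(locations) {
  if (is.character(locations) && !is.null(names(locations))) {
    locations <- tibble::tibble(clone = names(locations),
                                site = unname(locations))
  }
  locations <- tibble::as_tibble(locations)
  if (!all(c("clone", "site") %in% names(locations))) {
    stop("`locations` needs columns `clone` and `site`", call. = FALSE)
  }
  tibble::tibble(clone = as.character(locations$clone),
                 site = as.character(locations$site))
}

#' Build a range space from a locations table
#'
#' Site labels are taken from the table; the primary site is placed first so
#' that area ids are stable, the metastases follow in sorted order.
#'
#' @param locations Tibble with columns `clone`, `site` (or named vector
#'   clone -> site).
#' @param primary Label of the primary tumor site. Default `"P"`; if absent
#'   from the data the first sorted site is used with a warning.
#' @param max_range_size Passed to [range_space()].
#' @return A [range_space()].
#' @export
space_from_locations <- function(locations, primary = "P",
                                 max_range_size = 2) {
  locations <- as_locations(locations)
  sites <- sort(unique(locations$site))
  if (!primary %in% sites) {
    warning("primary site '", primary, "' not among sampled sites; using '",
            sites[1], "'", call. = FALSE)
    primary <- sites[1]
  }
  labels <- c(primary, setdiff(sites, primary))
  range_space(length(labels), max_range_size = max_range_size,
              labels = labels, primary = 1L)
}

# Validate tree + locations; return list(tree, tip_idx) where tip_idx is the
# singleton state index for each tip, in tree$tip.label order.
prep_tree <- function(tree, locations, space) {
  stopifnot(inherits(tree, "phylo"))
  tree <- ape::collapse.singles(tree)
  if (is.null(tree$edge.length)) {
    stop("tree must have branch lengths", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("negative branch lengths are not allowed", call. = FALSE)
  }
  kids <- tabulate(tree$edge[, 1], nbins = ape::Ntip(tree) + tree$Nnode)
  internal <- kids[(ape::Ntip(tree) + 1):(ape::Ntip(tree) + tree$Nnode)]
  if (any(internal != 2)) {
    stop("tree must be binary (resolve polytomies upstream)", call. = FALSE)
  }
  locations <- as_locations(locations)
  m <- match(tree$tip.label, locations$clone)
  if (anyNA(m)) {
    stop("no location for tip(s): ",
         paste(tree$tip.label[is.na(m)], collapse = ", "), call. = FALSE)
  }
  tip_idx <- vapply(locations$site[m], function(s) state_of(space, s),
                    integer(1))
  list(tree = tree, tip_idx = unname(tip_idx))
}

# Felsenstein pruning over the range space with cladogenetic mixing at nodes.
# getP(t) returns the branch transition matrix; ctab is a flattened clado
# table (clado_flat_probs()). Returns list(loglik, below = per-node scaled
# conditional vectors, meta = per-node bookkeeping for the downward pass).
prune_tree <- function(tree, tip_idx, ctab, getP, n_states) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  edge <- po$edge
  elen <- po$edge.length

  below <- matrix(0, ntip + nnode, n_states)
  logscale <- numeric(ntip + nnode)
  for (i in seq_len(ntip)) below[i, tip_idx[i]] <- 1

  # children edges per internal node, in encounter order (first = left slot)
  child_rows <- split(seq_len(nrow(edge)), edge[, 1])
  # postorder over internal nodes: order of completion in the edge list
  node_order <- unique(edge[, 1])

  meta <- vector("list", ntip + nnode)
  for (v in node_order) {
    rows <- child_rows[[as.character(v)]]
    ch <- edge[rows, 2]
    P1 <- getP(elen[rows[1]])
    P2 <- getP(elen[rows[2]])
    D1 <- as.vector(P1 %*% below[ch[1], ])
    D2 <- as.vector(P2 %*% below[ch[2], ])
    Lv <- as.vector(rowsum(ctab$p * D1[ctab$l] * D2[ctab$r], ctab$g))
    sc <- max(Lv)
    if (!is.finite(sc) || sc <= 0) {
      return(list(loglik = -Inf, below = below, meta = meta,
                  root = ntip + 1L, node_order = node_order))
    }
    below[v, ] <- Lv / sc
    logscale[v] <- logscale[ch[1]] + logscale[ch[2]] + log(sc)
    meta[[v]] <- list(children = ch, P = list(P1, P2), D = list(D1, D2))
  }
  root <- ntip + 1L
  ll <- log(sum(below[root, ]) / n_states) + logscale[root]
  list(loglik = ll, below = below, meta = meta, root = root,
       node_order = node_order)
}

# Marginal ancestral-state probabilities per internal node (state of the
# lineage at the node, immediately before cladogenesis), by an outside/
# downward pass complementing prune_tree()'s upward pass.
node_marginals <- function(pr, ctab, n_states) {
  ntip <- pr$root - 1L
  outside <- matrix(0, nrow(pr$below), n_states)
  outside[pr$root, ] <- 1 / n_states
  for (v in rev(pr$node_order)) {     # root first (reverse postorder)
    info <- pr$meta[[v]]
    ov <- outside[v, ]
    prelim1 <- numeric(n_states)      # daughter-start distribution, left slot
    prelim2 <- numeric(n_states)
    for (s in which(ov > 0)) {
      m <- ctab[[s]]
      w1 <- ov[s] * m[, 3L] * info$D[[2]][m[, 2L]]
      w2 <- ov[s] * m[, 3L] * info$D[[1]][m[, 1L]]
      # accumulate row by row: daughter states repeat across events
      for (r in seq_len(nrow(m))) {
        prelim1[m[r, 1L]] <- prelim1[m[r, 1L]] + w1[r]
        prelim2[m[r, 2L]] <- prelim2[m[r, 2L]] + w2[r]
      }
    }
    ch <- info$children
    o1 <- as.vector(crossprod(info$P[[1]], prelim1))
    o2 <- as.vector(crossprod(info$P[[2]], prelim2))
    if (sum(o1) > 0) o1 <- o1 / sum(o1)
    if (sum(o2) > 0) o2 <- o2 / sum(o2)
    outside[ch[1], ] <- o1
    outside[ch[2], ] <- o2
  }
  internal <- (ntip + 1L):nrow(pr$below)
  probs <- pr$below[internal, , drop = FALSE] *
    outside[internal, , drop = FALSE]
  rs <- rowSums(probs)
  degenerate <- !is.finite(rs) | rs <= 0
  probs[degenerate, ] <- 1 / n_states
  rs[degenerate] <- 1
  probs / rs
}

# --- public likelihood -------------------------------------------------------

#' Log-likelihood of a clone phylogeny under a biogeographic model
#'
#' Computes the pruning (Felsenstein) likelihood of the observed tip sites:
#' each tip's conditional likelihood is the indicator of its observed
#' singleton range, branches propagate states through `exp(Qt)` with the
#' anagenetic rates `(d, e)`, internal nodes mix daughter states through the
#' model's cladogenetic table, and the root sums over a uniform prior on all
#' range states.
#'
#' @param tree A rooted binary `phylo` with branch lengths (mutations per
#'   site as a time proxy). Degree-2 nodes are collapsed by branch-length
#'   addition.
#' @param locations Tibble with columns `clone`, `site` (one site per tip;
#'   clones observed in several sites must be pre-split with
#'   [split_multisite_tips()]).
#' @param model A [biogeo_model()] or model name.
#' @param d,e Anagenetic dispersal and extinction rates.
#' @param j Founder-event weight (only with a `+J` model).
#' @param space Optional [range_space()]; built from `locations` when `NULL`.
#' @param primary Primary-site label used when building the space.
#' @return The log-likelihood (a single number).
#' @examples
#' tr <- ape::read.tree(text = "((a:0,b:0):0,c:0);")
#' loc <- tibble::tibble(clone = c("a", "b", "c"), site = c("P", "P", "P"))
#' clone_loglik(tr, loc, "DEC", d = 0.1, e = 0.05)
#' @export
clone_loglik <- function(tree, locations, model, d, e, j = 0,
                         space = NULL, primary = "P") {
  model <- biogeo_model(model)
  if (is.null(space)) space <- space_from_locations(locations, primary)
  pt <- prep_tree(tree, locations, space)
  Q <- rate_matrix(space, d, e)
  prop <- make_propagator(Q)
  Pcache <- new.env(parent = emptyenv())
  getP <- function(t) {
    key <- sprintf("%.15g", t)
    P <- Pcache[[key]]
    if (is.null(P)) {
      P <- prop(t)
      Pcache[[key]] <- P
    }
    P
  }
  if (j < 0) stop("`j` must be >= 0", call. = FALSE)
  if (j > 0 && !model$founder) {
    stop("j > 0 supplied for a model without founder events", call. = FALSE)
  }
  ct <- clado_flat_probs(clado_flatten(clado_structure(space, model)), j)
  prune_tree(pt$tree, pt$tip_idx, ct, getP, space$n_states)$loglik
}

# --- model fitting -----------------------------------------------------------

default_start_grid <- function(founder) {
  g <- data.frame(d = c(0.01, 0.10, 0.50, 0.01),
                  e = c(0.001, 0.010, 0.100, 0.100))
  if (founder) g$j <- c(0.01, 0.10, 1.00, 3.00)
  g
}

#' Fit a biogeographic model by maximum likelihood
#'
#' Maximizes [clone_loglik()] over `d`, `e` (and `j` for `+J` models) with
#' bounded quasi-Newton (L-BFGS-B) searches from a fixed four-point start
#' grid; rates are optimized on a log scale. The fit is deterministic. The
#' returned object carries the information criteria (`n` = number of tips)
#' and the marginal per-node probabilities over all range states at the MLE.
#'
#' @inheritParams clone_loglik
#' @param lower,upper Named bounds for `d`, `e`, `j` on the natural scale.
#' @param starts Optional data frame of start values (columns `d`, `e`, and
#'   `j` for founder models) replacing the default grid.
#' @param control Passed to [stats::optim()] (merged over
#'   `list(factr = 1e7, maxit = 200)`).
#' @return An object of class `biogeo_fit` with elements `model`, `d`, `e`,
#'   `j`, `logLik`, `k`, `n_obs`, `AIC`, `AICc`, `BIC`, `converged`,
#'   `node_probs` (internal nodes x states, rows sum to 1), `space`, `tree`,
#'   `locations`.
#' @seealso [tidy.biogeo_fit()], [glance.biogeo_fit()], [annotate_ranges()]
#' @export
fit_biogeo <- function(tree, locations, model, space = NULL, primary = "P",
                       lower = c(d = 1e-9, e = 1e-9, j = 1e-6),
                       upper = c(d = 5, e = 5, j = 10),
                       starts = NULL, control = list()) {
  model <- biogeo_model(model)
  if (is.null(space)) space <- space_from_locations(locations, primary)
  pt <- prep_tree(tree, locations, space)
  n_states <- space$n_states
  if (is.null(starts)) starts <- default_start_grid(model$founder)

  # caches shared across optimizer evaluations: propagator + P(t) per (d,e),
  # clado table per j
  de_cache <- new.env(parent = emptyenv())
  ct_cache <- new.env(parent = emptyenv())
  get_de <- function(d, e) {
    key <- sprintf("%.14g_%.14g", d, e)
    entry <- de_cache[[key]]
    if (is.null(entry)) {
      prop <- make_propagator(rate_matrix(space, d, e))
      Pmap <- new.env(parent = emptyenv())
      entry <- function(t) {
        tk <- sprintf("%.15g", t)
        P <- Pmap[[tk]]
        if (is.null(P)) {
          P <- prop(t)
          Pmap[[tk]] <- P
        }
        P
      }
      de_cache[[key]] <- entry
    }
    entry
  }
  struct <- clado_structure(space, model)
  flat_struct <- clado_flatten(struct)
  get_ct <- function(j) {
    key <- sprintf("%.14g", j)
    ct <- ct_cache[[key]]
    if (is.null(ct)) {
      ct <- clado_flat_probs(flat_struct, j)
      ct_cache[[key]] <- ct
    }
    ct
  }

  eval_ll <- function(d, e, j) {
    prune_tree(pt$tree, pt$tip_idx, get_ct(j), get_de(d, e),
               n_states)$loglik
  }
  negll <- function(par) {
    d <- 10^par[1]; e <- 10^par[2]
    j <- if (model$founder) 10^par[3] else 0
    ll <- eval_ll(d, e, j)
    if (!is.finite(ll)) 1e10 else -ll
  }

  np <- model$n_free_params
  lo <- log10(c(lower[["d"]], lower[["e"]],
                if (model$founder) lower[["j"]]))
  hi <- log10(c(upper[["d"]], upper[["e"]],
                if (model$founder) upper[["j"]]))
  ctrl <- utils::modifyList(list(factr = 1e7, maxit = 200), control)

  best <- NULL
  any_conv <- FALSE
  for (i in seq_len(nrow(starts))) {
    p0 <- log10(c(starts$d[i], starts$e[i],
                  if (model$founder) starts$j[i]))
    p0 <- pmin(pmax(p0, lo), hi)
    res <- tryCatch(
      optim(p0, negll, method = "L-BFGS-B", lower = lo, upper = hi,
            control = ctrl),
      error = function(err) NULL
    )
    if (is.null(res)) next
    if (res$convergence == 0) any_conv <- TRUE
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    stop("optimization failed from every start", call. = FALSE)
  }

  d_hat <- 10^best$par[1]
  e_hat <- 10^best$par[2]
  j_hat <- if (model$founder) 10^best$par[3] else 0
  ntip <- ape::Ntip(pt$tree)

  if (best$value >= 1e10) {
    # the data have probability zero under this model for every parameter
    # value (e.g. zero-length sibling tips at different sites under a
    # copy-only cladogenetic model): flag rather than fail
    ll <- -Inf
    any_conv <- FALSE
    probs <- matrix(1 / n_states, pt$tree$Nnode, n_states)
  } else {
    ll <- -best$value
    pr <- prune_tree(pt$tree, pt$tip_idx, get_ct(j_hat),
                     get_de(d_hat, e_hat), n_states)
    probs <- node_marginals(pr, clado_probs(struct, j_hat), n_states)
  }
  rownames(probs) <- as.character((ntip + 1L):(ntip + pt$tree$Nnode))
  colnames(probs) <- space$state_labels

  n <- ntip
  k <- np
  aic <- 2 * k - 2 * ll
  aicc <- if (n - k - 1 > 0) aic + 2 * k * (k + 1) / (n - k - 1) else Inf
  bic <- k * log(n) - 2 * ll

  structure(
    list(
      model = model, d = d_hat, e = e_hat, j = j_hat,
      logLik = ll, k = k, n_obs = n,
      AIC = aic, AICc = aicc, BIC = bic,
      converged = any_conv,
      node_probs = probs,
      tip_states = pt$tip_idx,
      space = space, tree = pt$tree,
      locations = as_locations(locations)
    ),
    class = "biogeo_fit"
  )
}

#' @export
print.biogeo_fit <- function(x, ...) {
  cat("<biogeo_fit> ", x$model$name, " on ", x$n_obs, " clones, ",
      x$space$n_areas, " sites\n", sep = "")
  cat(sprintf("  lnL = %.4f  (d = %.4g, e = %.4g%s)\n", x$logLik, x$d, x$e,
              if (x$model$founder) sprintf(", j = %.4g", x$j) else ""))
  cat(sprintf("  AIC = %.2f  AICc = %.2f  BIC = %.2f  converged: %s\n",
              x$AIC, x$AICc, x$BIC, x$converged))
  invisible(x)
}

#' @export
logLik.biogeo_fit <- function(object, ...) {
  structure(object$logLik, df = object$k, nobs = object$n_obs,
            class = "logLik")
}

#' Fit all (or a subset of) the six biogeographic models
#'
#' @inheritParams fit_biogeo
#' @param models Character vector of model names (default all six).
#' @param ... Passed to [fit_biogeo()].
#' @return A named list of `biogeo_fit` objects, class `biogeo_fits`.
#' @export
fit_all_models <- function(tree, locations, models = biogeo_model_names(),
                           space = NULL, primary = "P", ...) {
  if (length(models) == 0) stop("`models` must be non-empty", call. = FALSE)
  if (is.null(space)) space <- space_from_locations(locations, primary)
  fits <- lapply(models, function(m) {
    fit_biogeo(tree, locations, m, space = space, ...)
  })
  names(fits) <- vapply(fits, function(f) f$model$name, character(1))
  structure(fits, class = "biogeo_fits")
}

#' Likelihood-ratio test of a founder-event (+J) model against its base model
#'
#' The base model (d, e) is nested in its +J counterpart (d, e, j) at j = 0,
#' so twice the log-likelihood gain is referred to a chi-square with one
#' degree of freedom. Because j = 0 sits on the boundary of its parameter
#' space, a conservative 50:50 mixture reference (point mass at 0 and
#' chi-square df 1) is available via `boundary = "mixture"`; the plain
#' chi-square is the default.
#'
#' @param null_fit,alt_fit `biogeo_fit` objects for the base and +J model of
#'   the same family.
#' @param boundary `"chisq"` (default) or `"mixture"`.
#' @return A one-row tibble: `family`, `stat` (2 delta lnL, clipped at 0),
#'   `df`, `p_value`, `delta_bic` (BIC_null - BIC_alt).
#' @export
likelihood_ratio_test <- function(null_fit, alt_fit,
                                  boundary = c("chisq", "mixture")) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(null_fit, "biogeo_fit"), inherits(alt_fit, "biogeo_fit"))
  if (null_fit$model$family != alt_fit$model$family ||
      null_fit$model$founder || !alt_fit$model$founder) {
    stop("fits must be a base model and its +J counterpart (same family)",
         call. = FALSE)
  }
  stat <- 2 * (alt_fit$logLik - null_fit$logLik)
  # degenerate fits: both impossible -> no evidence; only the null
  # impossible -> overwhelming evidence for the founder model
  if (is.nan(stat)) stat <- 0
  stat <- max(0, stat)
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  if (boundary == "mixture") p <- if (stat == 0) 1 else p / 2
  delta_bic <- null_fit$BIC - alt_fit$BIC
  if (is.nan(delta_bic)) delta_bic <- 0
  tibble::tibble(
    family = null_fit$model$family,
    stat = stat, df = 1L, p_value = p,
    delta_bic = delta_bic
  )
}

#' Model-selection table ranked by AICc
#'
#' @param fits A list of `biogeo_fit` objects (e.g. from [fit_all_models()]).
#' @return A tibble sorted by AICc (ties broken by fewer parameters, then
#'   model name) with columns `model`, `family`, `founder`, `k`, `lnL`,
#'   `AIC`, `AICc`, `delta_AICc`, `weight_AICc`, `BIC`.
#' @export
model_table <- function(fits) {
  if (inherits(fits, "biogeo_fit")) fits <- list(fits)
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, logical(1),
                                          "biogeo_fit")))
  tab <- purrr::map_dfr(fits, function(f) {
    tibble::tibble(
      model = f$model$name, family = f$model$family,
      founder = f$model$founder, k = f$k, lnL = f$logLik,
      AIC = f$AIC, AICc = f$AICc, BIC = f$BIC
    )
  })
  tab <- dplyr::arrange(tab, .data$AICc, .data$k, .data$model)
  tab$delta_AICc <- tab$AICc - tab$AICc[1]
  w <- exp(-0.5 * tab$delta_AICc)
  tab$weight_AICc <- w / sum(w)
  dplyr::relocate(tab, "delta_AICc", "weight_AICc", .after = "AICc")
}
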