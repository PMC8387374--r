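#' Annotate tree nodes with their highest-probability ancestral range
#'
#' Internal nodes receive the range state with the highest marginal
#' probability under the fitted model (ties broken deterministically by
#' canonical state order, with `tie` flagged); tips keep their observed
#' sampling site with probability 1 and are never re-estimated.
#'
#' @param fit A [fit_biogeo()] result.
#' @return A tibble with one row per tree node: `node` (ape node id), `type`
#'   (`"tip"`/`"internal"`), `label` (clone name for tips), `state`
#'   (state index), `range` (state label), `size`, `probability`,
#'   `is_multiple` (range spans >= 2 sites), `tie`.
#' @export
annotate_ranges <- function(fit) {
  stopifnot(inherits(fit, "biogeo_fit"))
  tree <- fit$tree
  ntip <- ape::Ntip(tree)
  space <- fit$space

  tips <- tibble::tibble(
    node = seq_len(ntip),
    type = "tip",
    label = tree$tip.label,
    state = fit$tip_states,
    probability = 1,
    tie = FALSE
  )

  probs <- fit$node_probs
  best <- apply(probs, 1, which.max)
  maxp <- probs[cbind(seq_len(nrow(probs)), best)]
  tie <- vapply(seq_len(nrow(probs)), function(i) {
    sum(probs[i, ] >= maxp[i] - 1e-12) > 1
  }, logical(1))
  internal <- tibble::tibble(
    node = as.integer(rownames(probs)),
    type = "internal",
    label = NA_character_,
    state = unname(best),
    probability = unname(maxp),
    tie = tie
  )

  ann <- dplyr::bind_rows(tips, internal)
  ann$range <- space$state_labels[ann$state]
  ann$size <- lengths(space$states)[ann$state]
  ann$is_multiple <- ann$size >= 2
  dplyr::relocate(ann, "range", "size", .after = "state")
}

#' Count multiple-range annotations at ancestral nodes
#'
#' The number of internal nodes whose best-supported ancestral range spans
#' two or more tumor sites. Models that favor vicariance (DEC, DIVALIKE)
#' tend to inflate this count; founder-event (+J) models suppress it.
#'
#' @param annotations Output of [annotate_ranges()].
#' @return An integer count.
#' @export
n_multiple_ranges <- function(annotations) {
  sum(annotations$is_multiple & annotations$type == "internal")
}

path_class <- function(source_is_primary, recipient_is_primary) {
  dplyr::case_when(
    recipient_is_primary ~ "M->P",
    source_is_primary ~ "P->M",
    TRUE ~ "M->M"
  )
}

#' Extract directed migration paths from ancestral-range annotations
#'
#' A migration path is emitted for every tree edge whose parent and child
#' annotations differ: one path per area present in the child range but not
#' the parent range, with the full parent range as the source. Paths are
#' classified by the primary flag of source and recipient: primary to
#' metastasis (`P->M`), metastasis to metastasis (`M->M`), and reseeding of
#' the primary (`M->P`). When the source annotation spans several areas the
#' `source` field carries all of them (comma-separated); evaluation treats
#' each as a candidate source site.
#'
#' @param annotations Output of [annotate_ranges()].
#' @param tree The fitted `phylo` (e.g. `fit$tree`).
#' @param space The [range_space()] used (e.g. `fit$space`); supplies labels
#'   and the primary flag.
#' @return A `migration_graph`: a tibble with columns `edge` (tree edge row),
#'   `source` (comma-separated site labels), `recipient` (single site label),
#'   `class`; attributes `sites` and `primary`.
#' @export
migration_paths <- function(annotations, tree, space) {
  stopifnot(inherits(tree, "phylo"), inherits(space, "range_space"))
  states <- space$states
  labels <- space$areas$label
  primary <- labels[space$areas$is_primary]
  ann_state <- setNames(annotations$state, annotations$node)

  rows <- list()
  for (k in seq_len(nrow(tree$edge))) {
    par <- tree$edge[k, 1]
    ch <- tree$edge[k, 2]
    sp_areas <- states[[ann_state[[as.character(par)]]]]
    ch_areas <- states[[ann_state[[as.character(ch)]]]]
    gained <- setdiff(ch_areas, sp_areas)
    for (a in gained) {
      src <- setdiff(sp_areas, a)
      rows[[length(rows) + 1]] <- tibble::tibble(
        edge = k,
        source = paste(labels[src], collapse = ","),
        recipient = labels[a],
        class = path_class(primary %in% labels[src], labels[a] == primary)
      )
    }
  }
  g <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(edge = integer(), source = character(),
                   recipient = character(), class = character())
  new_migration_graph(g, sites = labels, primary = primary)
}

new_migration_graph <- function(tbl, sites, primary) {
  tbl <- tibble::as_tibble(tbl)
  attr(tbl, "sites") <- sites
  attr(tbl, "primary") <- primary
  class(tbl) <- c("migration_graph", class(tbl))
  tbl
}

#' Construct a migration graph from a plain edge table
#'
#' @param paths A data frame with columns `source` and `recipient` (site
#'   labels; `source` may be comma-separated for multi-area sources) and
#'   optionally `edge`.
#' @param sites All site labels of the dataset.
#' @param primary The primary-site label.
#' @return A `migration_graph` tibble with a derived `class` column.
#' @export
migration_graph <- function(paths, sites, primary) {
  paths <- tibble::as_tibble(paths)
  stopifnot(all(c("source", "recipient") %in% names(paths)))
  used <- unique(c(unlist(strsplit(paths$source, ",")), paths$recipient))
  if (!all(used %in% sites)) {
    stop("path site(s) not in `sites`: ",
         paste(setdiff(used, sites), collapse = ", "), call. = FALSE)
  }
  if (!"edge" %in% names(paths)) paths$edge <- seq_len(nrow(paths))
  src_primary <- vapply(strsplit(paths$source, ","),
                        function(s) primary %in% s, logical(1))
  paths$class <- path_class(src_primary, paths$recipient == primary)
  new_migration_graph(paths[, c("edge", "source", "recipient", "class")],
                      sites = sites, primary = primary)
}

#' @export
print.migration_graph <- function(x, ...) {
  cat("<migration_graph> ", nrow(x), " path(s) over sites: ",
      paste(attr(x, "sites"), collapse = ", "),
      " (primary: ", attr(x, "primary"), ")\n", sep = "")
  if (nrow(x)) print(tibble::as_tibble(x), ...)
  invisible(x)
}
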