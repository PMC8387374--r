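#' Construct the state space of geographic ranges over tumor sites
#'
#' Tumor sites play the role of biogeographic areas; a clone lineage's *range*
#' is the non-empty set of sites it occupies. Following common practice for
#' clone-migration analyses the null (empty) range is removed from the state
#' space and ranges are capped at `max_range_size` areas (default 2), so for
#' `n` sites the space has `choose(n, 1) + choose(n, 2)` states.
#'
#' States are ordered canonically: all singletons in ascending area id, then
#' pairs in lexicographic order (then triples, and so on, if a larger
#' `max_range_size` is requested). This ordering is stable and is what indexes
#' rate matrices, cladogenetic tables and per-node probability vectors.
#'
#' @param n_areas Number of tumor sites (>= 2).
#' @param max_range_size Largest allowed range (default 2, >= 1).
#' @param labels Optional character vector of site names, length `n_areas`.
#'   Defaults to `"P", "M1", ..., "M<n-1>"`.
#' @param primary Which area (index or label) is the primary tumor. Default
#'   the first.
#'
#' @return An object of class `range_space`: a list with elements
#'   `n_areas`, `max_range_size`, `areas` (tibble: `id`, `label`,
#'   `is_primary`), `states` (list of integer area-id vectors),
#'   `state_labels`, and `n_states`.
#'
#' @examples
#' sp <- range_space(5)
#' sp$n_states  # 15 = choose(5,1) + choose(5,2)
#' state_of(sp, c("M1", "P"))
#' @export
range_space <- function(n_areas, max_range_size = 2, labels = NULL,
                        primary = 1L) {
  if (!is.numeric(n_areas) || length(n_areas) != 1 || n_areas < 2) {
    stop("`n_areas` must be a single integer >= 2", call. = FALSE)
  }
  n_areas <- as.integer(n_areas)
  if (!is.numeric(max_range_size) || max_range_size < 1) {
    stop("`max_range_size` must be >= 1", call. = FALSE)
  }
  max_range_size <- as.integer(max_range_size)
  if (max_range_size > n_areas) {
    stop("`max_range_size` cannot exceed `n_areas`", call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- c("P", paste0("M", seq_len(n_areas - 1L)))
  }
  if (length(labels) != n_areas || anyDuplicated(labels)) {
    stop("`labels` must be ", n_areas, " unique site names", call. = FALSE)
  }
  if (is.character(primary)) primary <- match(primary, labels)
  if (is.na(primary) || primary < 1 || primary > n_areas) {
    stop("`primary` must identify one of the areas", call. = FALSE)
  }

  states <- list()
  for (k in seq_len(max_range_size)) {
    combos <- utils::combn(n_areas, k, simplify = FALSE)
    states <- c(states, lapply(combos, as.integer))
  }
  state_labels <- vapply(
    states, function(s) paste(labels[s], collapse = "+"), character(1)
  )

  # fast index tables for the hot paths (rate matrix, clado tables)
  singleton_index <- integer(n_areas)
  pair_index <- matrix(NA_integer_, n_areas, n_areas)
  for (k in seq_along(states)) {
    s <- states[[k]]
    if (length(s) == 1) singleton_index[s] <- k
    if (length(s) == 2) pair_index[s[1], s[2]] <- pair_index[s[2], s[1]] <- k
  }

  structure(
    list(
      n_areas = n_areas,
      max_range_size = max_range_size,
      areas = tibble::tibble(
        id = seq_len(n_areas),
        label = labels,
        is_primary = seq_len(n_areas) == as.integer(primary)
      ),
      states = states,
      state_labels = state_labels,
      n_states = length(states),
      singleton_index = singleton_index,
      pair_index = pair_index
    ),
    class = "range_space"
  )
}

#' @export
print.range_space <- function(x, ...) {
  cat("<range_space> ", x$n_areas, " areas (",
      paste(x$areas$label, collapse = ", "), "), max range size ",
      x$max_range_size, ", ", x$n_states, " states\n", sep = "")
  invisible(x)
}

# canonical lookup key for a set of area ids
state_key <- function(ids) paste(sort(unique(as.integer(ids))), collapse = ",")

state_index_map <- function(space) {
  keys <- vapply(space$states, state_key, character(1))
  stats::setNames(seq_along(keys), keys)
}

# fast area-ids -> state-index lookup (O(1) for sizes 1-2, map fallback)
state_lookup <- function(space) {
  idx <- if (space$max_range_size > 2) state_index_map(space) else NULL
  function(ids) {
    if (length(ids) == 1) return(space$singleton_index[ids])
    if (length(ids) == 2) return(space$pair_index[ids[1], ids[2]])
    idx[[state_key(ids)]]
  }
}

#' Look up the canonical state for a set of site labels
#'
#' @param space A [range_space()].
#' @param labels Character vector of site names (or integer area ids) making
#'   up the range. Must be non-empty: the null range is excluded from the
#'   state space.
#'
#' @return The integer state index into `space$states`.
#' @examples
#' sp <- range_space(3)
#' state_of(sp, "P")
#' state_of(sp, c("M2", "M1"))
#' @export
state_of <- function(space, labels) {
  stopifnot(inherits(space, "range_space"))
  labels <- unique(labels)
  if (length(labels) == 0) {
    stop("the null (empty) range is removed from the state space",
         call. = FALSE)
  }
  if (is.character(labels)) {
    ids <- match(labels, space$areas$label)
    if (anyNA(ids)) {
      stop("unknown site label(s): ",
           paste(labels[is.na(ids)], collapse = ", "), call. = FALSE)
    }
  } else {
    ids <- as.integer(labels)
    if (any(ids < 1 | ids > space$n_areas)) {
      stop("area id out of range", call. = FALSE)
    }
  }
  if (length(ids) > space$max_range_size) {
    stop("range of size ", length(ids), " exceeds max_range_size = ",
         space$max_range_size, call. = FALSE)
  }
  idx <- state_index_map(space)[[state_key(ids)]]
  if (is.null(idx)) stop("state not in range space", call. = FALSE)
  idx
}

#' Tabulate the states of a range space
#'
#' @param space A [range_space()].
#' @return A tibble with one row per state: `index`, `label`, `size`, and a
#'   list-column `areas` of integer area ids.
#' @export
range_states <- function(space) {
  stopifnot(inherits(space, "range_space"))
  tibble::tibble(
    index = seq_len(space$n_states),
    label = space$state_labels,
    size = lengths(space$states),
    areas = space$states
  )
}
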