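#' Specify a biogeographic model
#'
#' Six models are supported: three families — `BAYAREALIKE` (range copied
#' unchanged at divergence), `DEC` (subset sympatry and vicariance at
#' divergence), `DIVALIKE` (vicariance only) — each with an optional
#' founder-event ("+J") extension in which one daughter jumps to a single
#' area outside the parental range. Base models have two free parameters
#' (d, e); +J models add the founder weight j for a third.
#'
#' @param name Model name: one of `"BAYAREALIKE"`, `"DEC"`, `"DIVALIKE"`,
#'   optionally suffixed `"+J"` (e.g. `"DEC+J"`).
#' @return An object of class `biogeo_model` with fields `family`, `founder`,
#'   `n_free_params` and `name`.
#' @examples
#' biogeo_model("DIVALIKE+J")
#' @export
biogeo_model <- function(name) {
  if (inherits(name, "biogeo_model")) return(name)
  stopifnot(is.character(name), length(name) == 1)
  nm <- toupper(gsub("\\s", "", name))
  founder <- grepl("\\+J$", nm)
  family <- sub("\\+J$", "", nm)
  if (!family %in% c("BAYAREALIKE", "DEC", "DIVALIKE")) {
    stop("unknown model family: ", family, call. = FALSE)
  }
  structure(
    list(
      family = family,
      founder = founder,
      n_free_params = 2L + as.integer(founder),
      name = paste0(family, if (founder) "+J")
    ),
    class = "biogeo_model"
  )
}

#' @export
print.biogeo_model <- function(x, ...) {
  cat("<biogeo_model> ", x$name, " (", x$n_free_params,
      " free parameters)\n", sep = "")
  invisible(x)
}

#' The six standard model names
#' @return Character vector of the six model names in canonical order.
#' @export
biogeo_model_names <- function() {
  c("BAYAREALIKE", "BAYAREALIKE+J", "DEC", "DEC+J", "DIVALIKE", "DIVALIKE+J")
}

#' Enumerate cladogenetic events for one parent range
#'
#' At an internal node the parent range is partitioned between two daughters
#' according to the model family. With `max_range_size = 2`:
#' * **BAYAREALIKE**: the range is copied to both daughters, nothing else.
#' * **DEC**, singleton parent: copy; pair parent \{A,B\}: subset sympatry
#'   (one daughter a single parental area, the other the full range, both
#'   orders) and vicariance (\{A\},\{B\} in both orders).
#' * **DIVALIKE**, singleton parent: copy; pair parent: vicariance only.
#' * **+J** adds, for every family and parent, jump events in which one
#'   daughter keeps the parent range and the other colonizes a single area
#'   outside it (both orders).
#'
#' Each allowed non-jump ordered event carries weight 1 and each jump event
#' weight `j`; [clado_table()] normalizes weights to probabilities per parent.
#'
#' @param space A [range_space()].
#' @param parent Parent state index (see [state_of()]).
#' @param model A [biogeo_model()] or model name.
#' @param j Founder-event weight (>= 0; must be 0 for non-founder models).
#' @return A tibble with columns `left`, `right` (daughter state indices)
#'   and `weight`.
#' @examples
#' sp <- range_space(2)
#' clado_events(sp, state_of(sp, c("P", "M1")), "DEC")
#' @export
clado_events <- function(space, parent, model, j = 0) {
  stopifnot(inherits(space, "range_space"))
  model <- biogeo_model(model)
  if (parent < 1 || parent > space$n_states) {
    stop("parent state not in range space", call. = FALSE)
  }
  if (j < 0) stop("`j` must be >= 0", call. = FALSE)
  if (j > 0 && !model$founder) {
    stop("j > 0 supplied for a model without founder events", call. = FALSE)
  }
  m <- clado_parent_structure(space, parent, model)
  tibble::tibble(left = as.integer(m[, 1L]), right = as.integer(m[, 2L]),
                 weight = as.numeric(ifelse(m[, 3L] == 1L, j, 1)))
}

# Fixed event structure for one parent: integer matrix with columns
# left, right, jump (1 for founder jumps, 0 otherwise). The structure does
# not depend on j, so fits reuse it and only reweight per j.
clado_parent_structure <- function(space, parent, model) {
  lookup <- state_lookup(space)
  s <- space$states[[parent]]
  left <- integer(0); right <- integer(0); jump <- integer(0)
  add <- function(l, r, jmp) {
    left <<- c(left, l); right <<- c(right, r); jump <<- c(jump, jmp)
  }

  if (model$family == "BAYAREALIKE" || length(s) == 1) {
    add(parent, parent, 0L)                     # sympatric copy
  } else {
    if (model$family == "DEC") {
      for (a in s) {                            # subset sympatry
        sing <- lookup(a)
        add(sing, parent, 0L); add(parent, sing, 0L)
      }
    }
    for (a in s) {                              # vicariance: singleton + rest
      add(lookup(a), lookup(setdiff(s, a)), 0L)
    }
  }
  if (model$founder) {                          # founder-event jumps
    for (a in setdiff(seq_len(space$n_areas), s)) {
      sing <- lookup(a)
      add(parent, sing, 1L); add(sing, parent, 1L)
    }
  }
  cbind(left = left, right = right, jump = jump)
}

clado_structure <- function(space, model) {
  model <- biogeo_model(model)
  lapply(seq_len(space$n_states), function(p) {
    clado_parent_structure(space, p, model)
  })
}

# weight the fixed structure for a given j and normalize per parent
clado_probs <- function(struct, j) {
  lapply(struct, function(m) {
    w <- ifelse(m[, 3L] == 1L, j, 1)
    cbind(left = m[, 1L], right = m[, 2L], prob = w / sum(w))
  })
}

# flattened form of the structure used by the pruning hot path: one event
# per entry, grouped by parent state
clado_flatten <- function(struct) {
  m <- do.call(rbind, struct)
  list(l = m[, 1L], r = m[, 2L], jump = m[, 3L] == 1L,
       g = rep(seq_along(struct), vapply(struct, nrow, integer(1))))
}

# per-j event probabilities on the flattened structure
clado_flat_probs <- function(flat, j) {
  w <- ifelse(flat$jump, j, 1)
  tot <- as.vector(rowsum(w, flat$g))
  list(l = flat$l, r = flat$r, p = w / tot[flat$g], g = flat$g)
}

#' Build the full cladogenetic probability table
#'
#' @inheritParams clado_events
#' @return An object of class `clado_table`: a list with one matrix per
#'   parent state (columns `left`, `right`, `prob`; per-parent probabilities
#'   sum to 1), plus the model and j used.
#' @examples
#' sp <- range_space(2)
#' ct <- clado_table(sp, "DEC+J", j = 1)
#' ct$table[[1]]  # copy and two jump orders, probability 1/3 each
#' @export
clado_table <- function(space, model, j = 0) {
  model <- biogeo_model(model)
  if (j < 0) stop("`j` must be >= 0", call. = FALSE)
  if (j > 0 && !model$founder) {
    stop("j > 0 supplied for a model without founder events", call. = FALSE)
  }
  # j = 0 in a +J model: jump rows get probability 0, base events renormalize
  tab <- clado_probs(clado_structure(space, model), j)
  structure(
    list(table = tab, model = model, j = j, space = space),
    class = "clado_table"
  )
}

#' @export
print.clado_table <- function(x, ...) {
  cat("<clado_table> ", x$model$name, ", j = ", format(x$j), ", ",
      length(x$table), " parent states\n", sep = "")
  invisible(x)
}
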