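#' Read a rooted clone phylogeny from a Newick file
#'
#' @param path Path to a Newick file (branch lengths in mutations per site).
#' @return A rooted `phylo` object.
#' @export
read_clone_tree <- function(path) {
  tree <- tryCatch(ape::read.tree(path), error = function(err) NULL)
  if (is.null(tree)) stop("could not parse Newick file: ", path,
                          call. = FALSE)
  if (!ape::is.rooted(tree)) {
    stop("tree in ", path, " is unrooted; clone trees must be rooted",
         call. = FALSE)
  }
  tree
}

#' Write a clone tree to Newick
#' @param tree A `phylo`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_clone_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Tips attached by zero-length branches
#'
#' Such tips are treated as sampled ancestral clones: they sit at their
#' parent node with no subsequent diversification.
#'
#' @param tree A `phylo`.
#' @return Character vector of tip labels on zero-length pendant edges.
#' @export
zero_length_tips <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  tip_rows <- tree$edge[, 2] <= ape::Ntip(tree)
  zero <- tree$edge.length[tip_rows] == 0
  tree$tip.label[tree$edge[tip_rows, 2][zero]]
}

#' Read a clone-to-site location table
#'
#' A TSV with columns `clone` and `site`; a clone sampled in several sites
#' appears on several rows and must be pre-split with
#' [split_multisite_tips()] before fitting.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `clone`, `site`.
#' @export
read_locations <- function(path) {
  loc <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  as_locations(loc)
}

#' Pre-split clones observed in more than one tumor site
#'
#' A clone sampled in k > 1 sites is treated as k distinct clones: the tip
#' is replaced by k tips named `clone@site` joined by zero-length branches,
#' so each analysis tip occupies exactly one site (the likelihood requires
#' singleton tip ranges, and zero-length attachment leaves the likelihood of
#' the rest of the tree unchanged).
#'
#' @param tree A rooted `phylo`.
#' @param locations Tibble `clone`, `site` (possibly several rows per clone).
#' @return A list with the expanded `tree` and a one-row-per-tip
#'   `locations` tibble.
#' @export
split_multisite_tips <- function(tree, locations) {
  locations <- as_locations(locations)
  missing_tips <- setdiff(tree$tip.label, locations$clone)
  if (length(missing_tips)) {
    stop("no location for tip(s): ", paste(missing_tips, collapse = ", "),
         call. = FALSE)
  }
  multi <- unique(locations$clone[duplicated(locations$clone)])
  for (cl in multi) {
    sites <- locations$site[locations$clone == cl]
    new_tips <- paste0(cl, "@", sites)
    nwk <- paste0(new_tips[1], ":0")
    for (s in new_tips[-1]) nwk <- paste0("(", nwk, ",", s, ":0):0")
    sub <- ape::read.tree(text = paste0(nwk, ";"))
    tree <- ape::bind.tree(tree, sub,
                           where = which(tree$tip.label == cl))
  }
  loc_out <- locations
  loc_out$clone <- ifelse(loc_out$clone %in% multi,
                          paste0(loc_out$clone, "@", loc_out$site),
                          loc_out$clone)
  list(tree = tree, locations = loc_out)
}

#' Write / read a presence-matrix geography file
#'
#' PHYLIP-style dialect used by biogeography tools: a header
#' `"<n_taxa> <n_areas> (<area labels>)"` followed by one row per clone with
#' a 0/1 presence string over the areas.
#'
#' @param locations Tibble `clone`, `site` (one or more rows per clone).
#' @param space A [range_space()] supplying area order and labels.
#' @param path Output file.
#' @return `path` invisibly (writer); a tibble `clone`, `site` (reader).
#' @export
write_geography <- function(locations, space, path) {
  locations <- as_locations(locations)
  clones <- unique(locations$clone)
  labels <- space$areas$label
  unknown <- setdiff(locations$site, labels)
  if (length(unknown)) {
    stop("unknown site(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  lines <- c(sprintf("%d %d (%s)", length(clones), length(labels),
                     paste(labels, collapse = " ")))
  for (cl in clones) {
    pres <- as.integer(labels %in% locations$site[locations$clone == cl])
    lines <- c(lines, paste0(cl, "\t", paste(pres, collapse = "")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_geography
#' @export
read_geography <- function(path) {
  lines <- readLines(path)
  header <- regmatches(lines[1], regexec("^(\\d+) (\\d+) \\((.*)\\)$",
                                         lines[1]))[[1]]
  if (length(header) != 4) stop("malformed geography header", call. = FALSE)
  labels <- strsplit(header[4], " ")[[1]]
  rows <- strsplit(lines[-1], "\t")
  out <- purrr::map_dfr(rows, function(r) {
    pres <- as.integer(strsplit(r[2], "")[[1]])
    if (length(pres) != length(labels) || sum(pres) < 1) {
      stop("malformed geography row for clone ", r[1], call. = FALSE)
    }
    tibble::tibble(clone = r[1], site = labels[pres == 1])
  })
  out
}

#' Write / read a migration-path edge list (TSV)
#'
#' @param graph A `migration_graph`.
#' @param path File path.
#' @return `path` invisibly (writer); a `migration_graph` (reader).
#' @export
write_paths <- function(graph, path) {
  readr::write_tsv(tibble::as_tibble(graph)[, c("edge", "source",
                                                "recipient", "class")],
                   path)
  invisible(path)
}

#' @rdname write_paths
#' @param sites,primary Site labels and primary label for the reader.
#' @export
read_paths <- function(path, sites, primary) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    edge = "i", source = "c", recipient = "c", class = "c"))
  migration_graph(tbl[, c("edge", "source", "recipient")],
                  sites = sites, primary = primary)
}

#' Write a migration graph in Graphviz DOT format
#'
#' Site-pair paths are aggregated; the edge label carries the multiplicity
#' and class.
#'
#' @param graph A `migration_graph`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_migration_dot <- function(graph, path) {
  sites <- attr(graph, "sites")
  primary <- attr(graph, "primary")
  agg <- tibble::as_tibble(graph) |>
    dplyr::count(.data$source, .data$recipient, .data$class)
  lines <- c("digraph migrations {")
  for (s in sites) {
    shape <- if (s == primary) "doublecircle" else "circle"
    lines <- c(lines, sprintf("  \"%s\" [shape=%s];", s, shape))
  }
  if (nrow(agg)) {
    lines <- c(lines, sprintf(
      "  \"%s\" -> \"%s\" [label=\"%s x%d\"];",
      agg$source, agg$recipient, agg$class, agg$n))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a simulated dataset as plain-text files
#'
#' Writes `tree.nwk`, `locations.tsv`, `genotypes.tsv`, `truth_paths.tsv`
#' and `manifest.json` into a directory.
#'
#' @param sim A `sim_dataset` from [simulate_seeding()].
#' @param dir Output directory (created if missing).
#' @return `dir` invisibly (writer); a `sim_dataset` (reader).
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_clone_tree(sim$tree, file.path(dir, "tree.nwk"))
  readr::write_tsv(sim$locations, file.path(dir, "locations.tsv"))
  geno <- tibble::as_tibble(sim$genotypes, rownames = "clone")
  readr::write_tsv(geno, file.path(dir, "genotypes.tsv"))
  write_paths(sim$truth, file.path(dir, "truth_paths.tsv"))
  manifest <- c(sim$config,
                list(sites = attr(sim$truth, "sites"),
                     primary = attr(sim$truth, "primary")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  tree <- read_clone_tree(file.path(dir, "tree.nwk"))
  locations <- read_locations(file.path(dir, "locations.tsv"))
  geno <- readr::read_tsv(file.path(dir, "genotypes.tsv"),
                          col_types = readr::cols(clone = "c",
                                                  .default = "i"))
  genotypes <- as.matrix(geno[, -1])
  rownames(genotypes) <- geno$clone
  truth <- read_paths(file.path(dir, "truth_paths.tsv"),
                      sites = manifest$sites, primary = manifest$primary)
  structure(
    list(tree = tree, locations = locations, genotypes = genotypes,
         truth = truth,
         config = manifest[c("scenario", "m_group", "n_sites", "n_clones",
                             "n_snvs", "seed")]),
    class = "sim_dataset"
  )
}

#' Run the full analysis pipeline on one dataset
#'
#' Fits the requested biogeographic models to a clone tree and location
#' table, writes the model-selection and likelihood-ratio-test tables, the
#' per-model ancestral-range annotations, migration-path edge lists (TSV and
#' DOT), per-node range probabilities (JSON), and — when a true migration
#' graph is supplied — the evaluation table, plus a manifest recording the
#' configuration. Outputs are a pure function of the inputs.
#'
#' @param tree A `phylo` or path to a Newick file.
#' @param locations A locations tibble or path to a TSV.
#' @param out_dir Output directory.
#' @param models Model names to fit.
#' @param primary Primary-site label.
#' @param truth Optional `migration_graph` (or path to a truth-paths TSV)
#'   for evaluation.
#' @param mode Path-scoring mode, see [score_paths()].
#' @param alpha LRT significance level recorded in the manifest.
#' @return Invisibly, a list with `fits`, `model_table`, `lrt_table`,
#'   `paths` (per model), and `evaluation` (or `NULL`).
#' @export
run_pipeline <- function(tree, locations, out_dir,
                         models = biogeo_model_names(), primary = "P",
                         truth = NULL, mode = "unique", alpha = 0.05) {
  if (is.character(tree)) tree <- read_clone_tree(tree)
  if (is.character(locations)) locations <- read_locations(locations)
  locations <- as_locations(locations)
  if (anyDuplicated(locations$clone)) {
    pre <- split_multisite_tips(tree, locations)
    tree <- pre$tree
    locations <- pre$locations
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  space <- space_from_locations(locations, primary)
  if (is.character(truth)) {
    truth <- read_paths(truth, sites = space$areas$label, primary = primary)
  }

  fits <- fit_all_models(tree, locations, models = models, space = space)
  mt <- model_table(fits)
  readr::write_tsv(mt, file.path(out_dir, "model_table.tsv"))

  fams <- unique(vapply(fits, function(f) f$model$family, character(1)))
  lrt_rows <- list()
  for (fam in fams) {
    if (!is.null(fits[[fam]]) && !is.null(fits[[paste0(fam, "+J")]])) {
      lrt_rows[[fam]] <- likelihood_ratio_test(fits[[fam]],
                                               fits[[paste0(fam, "+J")]])
    }
  }
  lrt_tab <- if (length(lrt_rows)) dplyr::bind_rows(lrt_rows) else
    tibble::tibble(family = character(), stat = numeric(), df = integer(),
                   p_value = numeric(), delta_bic = numeric())
  readr::write_tsv(lrt_tab, file.path(out_dir, "lrt_tests.tsv"))

  paths_by_model <- list()
  eval_rows <- list()
  node_probs <- list()
  for (nm in names(fits)) {
    f <- fits[[nm]]
    ann <- annotate_ranges(f)
    safe <- gsub("\\+", "_", nm)
    readr::write_tsv(ann, file.path(out_dir,
                                    paste0("annotations_", safe, ".tsv")))
    paths <- migration_paths(ann, f$tree, f$space)
    paths_by_model[[nm]] <- paths
    write_paths(paths, file.path(out_dir, paste0("paths_", safe, ".tsv")))
    write_migration_dot(paths, file.path(out_dir,
                                         paste0("paths_", safe, ".dot")))
    node_probs[[nm]] <- f$node_probs
    if (!is.null(truth)) {
      eval_rows[[nm]] <- dplyr::bind_cols(
        tibble::tibble(model = nm), score_paths(paths, truth, mode = mode))
    }
  }
  jsonlite::write_json(
    lapply(node_probs, function(p) {
      list(nodes = rownames(p), states = colnames(p), probs = unname(p))
    }),
    file.path(out_dir, "node_probs.json"), digits = NA)

  evaluation <- NULL
  if (!is.null(truth)) {
    evaluation <- dplyr::bind_rows(eval_rows)
    readr::write_tsv(evaluation, file.path(out_dir, "evaluation.tsv"))
  }

  manifest <- list(
    package = "tumorgeo",
    version = as.character(utils::packageVersion("tumorgeo")),
    models = models, primary = primary, mode = mode, alpha = alpha,
    n_tips = ape::Ntip(tree), sites = space$areas$label
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)

  invisible(list(fits = fits, model_table = mt, lrt_table = lrt_tab,
                 paths = paths_by_model, evaluation = evaluation))
}
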