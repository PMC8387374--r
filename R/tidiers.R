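#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted biogeographic model
#'
#' @param x A [fit_biogeo()] result.
#' @param ... Unused.
#' @return A tibble with one row per free parameter: `term`, `estimate`.
#' @export
tidy.biogeo_fit <- function(x, ...) {
  terms <- c("d", "e", if (x$model$founder) "j")
  tibble::tibble(
    term = terms,
    estimate = unlist(x[terms], use.names = FALSE)
  )
}

#' One-row model summary of a fitted biogeographic model
#'
#' @param x A [fit_biogeo()] result.
#' @param ... Unused.
#' @return A one-row tibble: `model`, `family`, `founder`, `logLik`, `k`,
#'   `n_obs`, `AIC`, `AICc`, `BIC`, `converged`.
#' @export
glance.biogeo_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model$name, family = x$model$family,
    founder = x$model$founder,
    logLik = x$logLik, k = x$k, n_obs = x$n_obs,
    AIC = x$AIC, AICc = x$AICc, BIC = x$BIC, converged = x$converged
  )
}

#' Per-node range probabilities of a fit, in long form
#'
#' @param fit A [fit_biogeo()] result.
#' @return A tibble: `node`, `range`, `probability`.
#' @export
node_probabilities <- function(fit) {
  stopifnot(inherits(fit, "biogeo_fit"))
  p <- fit$node_probs
  tibble::tibble(
    node = rep(as.integer(rownames(p)), times = ncol(p)),
    range = rep(colnames(p), each = nrow(p)),
    probability = as.vector(p)
  )
}

#' Heatmap of per-node ancestral range probabilities
#'
#' @param fit A [fit_biogeo()] result.
#' @return A ggplot object (internal nodes x range states, fill =
#'   probability).
#' @export
plot_node_probs <- function(fit) {
  dat <- node_probabilities(fit)
  dat$range <- factor(dat$range, levels = fit$space$state_labels)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$range,
                                    y = factor(.data$node),
                                    fill = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "ancestral range", y = "internal node",
                  fill = "probability",
                  title = paste0(fit$model$name, " ancestral ranges")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @export
autoplot.biogeo_fit <- function(object, ...) plot_node_probs(object)

#' Diagram of a migration graph
#'
#' Sites on a circle, one arrow per aggregated site pair, width scaled by
#' multiplicity and color by path class.
#'
#' @param graph A `migration_graph`.
#' @return A ggplot object.
#' @export
plot_migration_graph <- function(graph) {
  sites <- attr(graph, "sites")
  primary <- attr(graph, "primary")
  theta <- seq(0, 2 * pi, length.out = length(sites) + 1)[-(length(sites) +
                                                              1)]
  layout <- tibble::tibble(site = sites, x = cos(theta), y = sin(theta),
                           is_primary = sites == primary)
  agg <- tibble::as_tibble(graph) |>
    dplyr::count(.data$source, .data$recipient, .data$class) |>
    tidyr::separate_rows("source", sep = ",") |>
    dplyr::left_join(layout, by = c(source = "site")) |>
    dplyr::left_join(layout, by = c(recipient = "site"),
                     suffix = c("", "_to"))
  p <- ggplot2::ggplot(layout, ggplot2::aes(x = .data$x, y = .data$y))
  if (nrow(agg)) {
    p <- p + ggplot2::geom_curve(
      data = agg,
      ggplot2::aes(xend = .data$x_to, yend = .data$y_to,
                   color = .data$class, linewidth = .data$n),
      curvature = 0.15,
      arrow = ggplot2::arrow(length = ggplot2::unit(0.12, "in"),
                             type = "closed"))
  }
  p +
    ggplot2::geom_point(ggplot2::aes(shape = .data$is_primary), size = 9,
                        fill = "white", color = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$site), size = 3) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 21, `FALSE` = 1),
                                guide = "none") +
    ggplot2::scale_linewidth(range = c(0.4, 1.6), guide = "none") +
    ggplot2::coord_equal(xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3)) +
    ggplot2::theme_void() +
    ggplot2::labs(color = "path class")
}

#' @export
autoplot.migration_graph <- function(object, ...) {
  plot_migration_graph(object)
}

#' F1-score distributions across models from benchmark rows
#'
#' @param rows Per-dataset benchmark rows from [run_benchmark()].
#' @param by Optional facet: `"m_group"` or `"scenario"`.
#' @return A ggplot box plot of F1 by model.
#' @export
plot_f1 <- function(rows, by = NULL) {
  p <- ggplot2::ggplot(rows, ggplot2::aes(x = .data$model, y = .data$f1)) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 18,
                          size = 2, color = "red") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "F1-score") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
  if (!is.null(by)) p <- p + ggplot2::facet_wrap(by)
  p
}
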