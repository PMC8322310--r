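#' Plot a force-extension curve
#'
#' Sawtooth force-extension trace with the true unfolding events (when the
#' curve carries a ground-truth log) marked.
#'
#' @param object A `force_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.force_curve <- function(object, ...) {
  truth <- attr(object, "truth_events")
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$extension_nm,
                                    y = .data$force_pN)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey30") +
    ggplot2::labs(x = "extension (nm)", y = "force (pN)")
  if (!is.null(truth) && nrow(truth) > 0) {
    ev <- data.frame(extension_nm = object$extension_nm[truth$index],
                     force_pN = truth$force_pN)
    p <- p + ggplot2::geom_point(data = ev, colour = "red", size = 1.5)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Histogram of contour-length increments with the mixture fit overlaid
#'
#' @param x An `increment_histogram` from [fit_gaussian_mixture_hist()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.increment_histogram <- function(x, ...) {
  bars <- data.frame(mid = x$mids, count = x$counts)
  grid <- seq(min(x$breaks), max(x$breaks), length.out = 400)
  fit <- rowSums(vapply(seq_len(nrow(x$components)), function(k) {
    with(x$components[k, ],
         amplitude * exp(-(grid - mean_nm)^2 / (2 * sd_nm^2)))
  }, numeric(length(grid))))
  ggplot2::ggplot(bars, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = diff(x$breaks)[1], fill = "grey80",
                      colour = "grey40") +
    ggplot2::geom_line(data = data.frame(mid = grid, count = fit),
                       colour = "red") +
    ggplot2::labs(x = expression(Delta * L[c] ~ "(nm)"), y = "count")
}

#' Dynamic force spectrum with the Bell-Evans fit line
#'
#' Most-probable force against loading rate (log axis) with the fitted
#' Bell-Evans line.
#'
#' @param object A `bell_evans_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bell_evans_fit <- function(object, ...) {
  pts <- object$points
  lr <- exp(seq(log(min(pts$loading_rate_pN_per_s)),
                log(max(pts$loading_rate_pN_per_s)), length.out = 100))
  line <- data.frame(
    loading_rate_pN_per_s = lr,
    f_mp_pN = bell_evans_force(lr, object$k_u0, object$x_beta,
                               object$temperature)
  )
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$loading_rate_pN_per_s,
                                    y = .data$f_mp_pN)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = line, colour = "blue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "loading rate (pN/s)",
                  y = expression(F[mp] ~ "(pN)"))
}

#' Per-residue centrality profiles of a contact network
#'
#' @param network A `contact_network`.
#' @return A ggplot of closeness and normalized betweenness per node.
#' @export
plot_centrality <- function(network) {
  dat <- dplyr::left_join(closeness_centrality(network),
                          betweenness_centrality(network), by = "node") |>
    tidyr::pivot_longer(c("closeness", "betweenness"),
                        names_to = "measure", values_to = "value")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$node, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~measure, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "residue (node index)", y = "centrality")
}

#' Node participation profile of a (merged) path set
#'
#' @param path_set A `path_set` or `merged_path_set`.
#' @param n_nodes Total nodes of the network (zero-participation nodes are
#'   shown when given).
#' @return A ggplot.
#' @export
plot_participation <- function(path_set, n_nodes = NULL) {
  part <- node_path_participation(path_set)
  if (!is.null(n_nodes)) {
    part <- tidyr::complete(part, node = seq_len(n_nodes),
                            fill = list(n_paths = 0L))
  }
  ggplot2::ggplot(part, ggplot2::aes(x = .data$node, y = .data$n_paths)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::labs(x = "residue (node index)", y = "paths through node")
}
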