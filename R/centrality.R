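#' Node centralities on the confidence-filtered interactome
#'
#' Computes, for every node, the local interaction density (unweighted degree)
#' and two global centralities on hop-count shortest paths: closeness, the
#' reciprocal of the sum of shortest-path lengths from the node to all other
#' nodes reachable in its connected component (0 for isolated nodes), and
#' betweenness, the amount of all-pairs shortest-path traffic routed through
#' the node (each unordered pair counted once, endpoints excluded, equal-length
#' paths sharing credit fractionally). Edge confidences act only as the
#' retention filter, never as distances.
#'
#' @param net An `interaction_network`.
#' @param normalize_closeness If `TRUE`, closeness is multiplied by
#'   (component size - 1), giving the size-normalized variant. Default `FALSE`
#'   (the raw reciprocal-of-sum form).
#' @return A tibble with columns `node`, `degree`, `closeness`, `betweenness`,
#'   `component_size`.
#' @export
node_centrality <- function(net, normalize_closeness = FALSE) {
  stopifnot(inherits(net, "interaction_network"))
  g <- net$graph
  nodes <- igraph::V(g)$name
  deg <- igraph::degree(g, loops = FALSE)
  d <- igraph::distances(g, weights = NA) # hop metric
  finite_sum <- apply(d, 1, function(r) sum(r[is.finite(r)]))
  comp <- igraph::components(g)
  comp_size <- comp$csize[comp$membership]
  clo <- ifelse(finite_sum > 0, 1 / finite_sum, 0)
  if (normalize_closeness) clo <- clo * pmax(comp_size - 1, 0)
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA)
  tibble::tibble(node = nodes, degree = as.integer(unname(deg)),
                 closeness = unname(clo), betweenness = unname(btw),
                 component_size = as.integer(unname(comp_size)))
}

#' Summarize per-node measures by phylostratum
#'
#' Averages node-level centralities within each stratum of the gene-age map.
#' Network nodes absent from the map are excluded from the summary (their
#' count is reported as an attribute).
#'
#' @param centrality Tibble from [node_centrality()] (or any tibble with a
#'   `node` column plus numeric measure columns).
#' @param strata Stratum map tibble (`gene_id`, `stratum`).
#' @return A tibble with columns `stratum`, `measure`, `mean`, `sem`, `n`;
#'   `sem` is 0 when `n = 1`. Attribute `n_unmapped` counts excluded nodes.
#' @export
stratum_summary <- function(centrality, strata) {
  stopifnot(is.data.frame(centrality), "node" %in% names(centrality))
  strata <- validate_stratum_map(strata[c("gene_id", "stratum")])
  joined <- dplyr::inner_join(centrality, strata,
                              by = c(node = "gene_id"))
  n_unmapped <- nrow(centrality) - nrow(joined)
  measures <- setdiff(names(centrality), c("node", "component_size"))
  out <- joined |>
    tidyr::pivot_longer(dplyr::all_of(measures), names_to = "measure",
                        values_to = "value") |>
    dplyr::group_by(.data$stratum, .data$measure) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sem = if (dplyr::n() > 1) stats::sd(.data$value) / sqrt(dplyr::n()) else 0,
      n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$measure, .data$stratum)
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Plot a per-stratum centrality profile
#'
#' @param summary Tibble from [stratum_summary()].
#' @return A ggplot: stratum index on x, mean with +/- 1 sem ribbon on y,
#'   one panel per measure.
#' @export
plot_centrality_profile <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$stratum, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$measure), scales = "free_y") +
    ggplot2::scale_x_continuous(breaks = c(1, 4, 8, 12, 17)) +
    ggplot2::labs(x = "phylostratum (1 = oldest)", y = "mean ± sem")
}
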