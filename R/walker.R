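#' Single uniform random walk on the interactome
#'
#' Starting from `start`, performs `length` steps, each to a uniformly chosen
#' neighbour; revisiting earlier nodes is allowed. An isolated start node
#' terminates the walk immediately.
#'
#' @param net An `interaction_network`.
#' @param start Start node identifier (must be in the network).
#' @param length Number of steps (>= 0).
#' @param seed Integer seed; the walk is deterministic given the seed.
#' @return The identifier of the final node.
#' @export
random_walk_end <- function(net, start, length, seed = 1L) {
  nodes <- network_nodes(net)
  idx <- match(start, nodes)
  if (is.na(idx)) stop("start node not in network", call. = FALSE)
  adj <- igraph::as_adj_list(net$graph, mode = "all")
  adj <- lapply(adj, function(v) as.integer(v) - 1L)
  end <- walk_ends_cpp(adj, idx - 1L, as.integer(length), 1L, as.numeric(seed))
  nodes[end]
}

#' Random-walk ensemble with per-stratum endpoint tally
#'
#' Runs `n_repeats` independent uniform random walks of `walk_length` steps,
#' each starting from a uniformly drawn node of the start stratum (with
#' replacement across repeats), and tallies where walks end. Endpoint counts
#' per stratum are normalized by the number of stratum genes present in the
#' filtered network, so a stratum's normalized frequency is comparable across
#' strata of different sizes. Walks use per-repeat counter-based substreams:
#' the tally is reproducible bit-for-bit for a given seed and independent of
#' execution order.
#'
#' @param net An `interaction_network`.
#' @param strata Stratum map tibble (`gene_id`, `stratum`).
#' @param walk_length Steps per walk (default 1000; endpoint frequencies
#'   stabilize after a few tens of steps on connected networks).
#' @param n_repeats Number of walks (default 10000).
#' @param start_stratum Stratum whose network nodes form the start pool
#'   (default 17, the youngest).
#' @param seed Integer master seed.
#' @param stratum_sizes Optional named vector giving an external per-stratum
#'   gene-count denominator; defaults to counts of stratum genes present in
#'   the network.
#' @return A `walk_end_distribution`: a tibble with columns `stratum`
#'   (1..17, plus `NA` for endpoints without a stratum assignment), `n_genes`,
#'   `raw_count` and `normalized` (`raw_count / n_genes`). Attributes record
#'   the configuration and `n_dead_end` terminations.
#' @export
run_walk_ensemble <- function(net, strata, walk_length = 1000,
                              n_repeats = 10000, start_stratum = 17,
                              seed = 1L, stratum_sizes = NULL) {
  stopifnot(inherits(net, "interaction_network"),
            n_repeats >= 1, walk_length >= 0)
  strata <- validate_stratum_map(strata[c("gene_id", "stratum")])
  nodes <- network_nodes(net)
  node_stratum <- strata$stratum[match(nodes, strata$gene_id)]
  pool <- which(node_stratum == start_stratum)
  if (length(pool) == 0) {
    stop(sprintf("no network node belongs to start stratum %d", start_stratum),
         call. = FALSE)
  }
  adj <- igraph::as_adj_list(net$graph, mode = "all")
  adj <- lapply(adj, function(v) as.integer(v) - 1L)
  ends <- walk_ends_cpp(adj, pool - 1L, as.integer(walk_length),
                        as.integer(n_repeats), as.numeric(seed))
  n_dead_end <- sum(lengths(adj)[ends] == 0 & walk_length > 0)
  end_stratum <- node_stratum[ends]
  counts <- table(factor(end_stratum, levels = 1:17), useNA = "always")
  if (is.null(stratum_sizes)) {
    sizes <- table(factor(node_stratum, levels = 1:17))
    n_genes <- as.integer(sizes)
  } else {
    n_genes <- as.integer(stratum_sizes[as.character(1:17)])
  }
  out <- tibble::tibble(
    stratum = c(1:17, NA_integer_),
    n_genes = c(n_genes, sum(is.na(node_stratum))),
    raw_count = as.integer(counts))
  out$normalized <- ifelse(out$n_genes > 0, out$raw_count / out$n_genes, NA_real_)
  structure(out,
            class = c("walk_end_distribution", class(out)),
            walk_length = walk_length, n_repeats = n_repeats,
            start_stratum = start_stratum, seed = seed,
            n_dead_end = n_dead_end)
}

#' @export
glance.walk_end_distribution <- function(x, ...) {
  tibble::tibble(walk_length = attr(x, "walk_length"),
                 n_repeats = attr(x, "n_repeats"),
                 start_stratum = attr(x, "start_stratum"),
                 seed = attr(x, "seed"),
                 n_dead_end = attr(x, "n_dead_end"))
}

#' Endpoint distributions over a grid of walk lengths
#'
#' Runs one walk ensemble per length, with per-length seeds derived from the
#' master seed, and reports a convergence diagnostic: the total-variation
#' distance between the endpoint-stratum frequencies of successive lengths.
#' On connected networks the endpoint law approaches the degree-proportional
#' stationary distribution, so successive distances shrink toward
#' Monte-Carlo noise; the headline sweep 5-10000 shows stabilization from a
#' few tens of steps.
#'
#' @param net,strata,n_repeats,start_stratum,seed As [run_walk_ensemble()].
#' @param lengths Integer vector of walk lengths (default the headline grid
#'   `c(5, 10, 20, 30, 100, 1000, 10000)`).
#' @return A tibble with one row per (length, stratum), columns as in
#'   [run_walk_ensemble()] plus `walk_length`; attribute `convergence` holds a
#'   tibble of TV distances between successive lengths.
#' @export
walk_length_sweep <- function(net, strata,
                              lengths = c(5, 10, 20, 30, 100, 1000, 10000),
                              n_repeats = 10000, start_stratum = 17,
                              seed = 1L) {
  stopifnot(length(lengths) > 0)
  runs <- purrr::map(lengths, function(len) {
    run_walk_ensemble(net, strata, walk_length = len, n_repeats = n_repeats,
                      start_stratum = start_stratum,
                      seed = stage_seed(seed, paste0("walk_len_", len)))
  })
  tv <- purrr::map2_dbl(runs[-1], runs[-length(runs)], function(a, b) {
    pa <- a$raw_count / sum(a$raw_count)
    pb <- b$raw_count / sum(b$raw_count)
    sum(abs(pa - pb)) / 2
  })
  out <- purrr::map2_dfr(runs, lengths, function(r, len) {
    dplyr::mutate(tibble::as_tibble(r), walk_length = len, .before = 1)
  })
  attr(out, "convergence") <- tibble::tibble(
    from_length = lengths[-length(lengths)], to_length = lengths[-1],
    tv_distance = tv)
  out
}

#' Degree-proportional stationary distribution of the uniform walk
#'
#' On a connected non-bipartite graph the endpoint law of a long uniform walk
#' converges to deg(v) / 2|E|; this closed form is the reference against which
#' simulated endpoint frequencies are compared.
#'
#' @param net An `interaction_network`.
#' @return A tibble with columns `node` and `stationary_prob`.
#' @export
stationary_distribution <- function(net) {
  deg <- igraph::degree(net$graph, loops = FALSE)
  tibble::tibble(node = names(deg),
                 stationary_prob = as.numeric(deg) / (2 * igraph::ecount(net$graph)))
}

#' Plot normalized walk-endpoint frequencies by phylostratum
#'
#' @param object A `walk_end_distribution`.
#' @param ... Unused.
#' @return A ggplot of normalized endpoint frequency versus stratum index.
#' @export
autoplot.walk_end_distribution <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), !is.na(.data$stratum))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stratum, y = .data$normalized)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::scale_x_continuous(breaks = c(1, 4, 8, 12, 17)) +
    ggplot2::labs(x = "phylostratum of walk end (1 = oldest)",
                  y = "walk ends per stratum gene",
                  title = sprintf("%d walks of %d steps from stratum %d",
                                  attr(object, "n_repeats"),
                                  attr(object, "walk_length"),
                                  attr(object, "start_stratum")))
}

#' Node-level endpoint tally of a walk ensemble
#'
#' Like [run_walk_ensemble()] but tallies endpoints per node rather than per
#' stratum, for direct comparison with the stationary law deg(v) / 2|E|.
#'
#' @param net An `interaction_network`.
#' @param start_nodes Character vector: the start pool (uniform with
#'   replacement across repeats).
#' @param walk_length Steps per walk.
#' @param n_repeats Number of walks.
#' @param seed Integer master seed.
#' @return A tibble with columns `node` and `count` (sums to `n_repeats`).
#' @export
walk_end_counts <- function(net, start_nodes, walk_length, n_repeats,
                            seed = 1L) {
  nodes <- network_nodes(net)
  pool <- match(start_nodes, nodes)
  if (anyNA(pool)) stop("start node not in network", call. = FALSE)
  adj <- igraph::as_adj_list(net$graph, mode = "all")
  adj <- lapply(adj, function(v) as.integer(v) - 1L)
  ends <- walk_ends_cpp(adj, pool - 1L, as.integer(walk_length),
                        as.integer(n_repeats), as.numeric(seed))
  tibble::tibble(node = nodes,
                 count = as.integer(tabulate(ends, nbins = length(nodes))))
}
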