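#' Read a confidence-filtered protein interaction network
#'
#' Reads a STRING-style tab-separated edge list (`protein1`, `protein2`,
#' `combined_score`) and returns the undirected network of interactions whose
#' confidence is strictly greater than `threshold`. Self-loops are dropped and
#' symmetric duplicate records are collapsed (the maximum score is kept).
#' STRING distributes scores as integers on a 0-1000 scale; when the largest
#' score in the file exceeds 1 the column is divided by 1000, and the rescaling
#' is reported.
#'
#' @param path Path to a TSV file with a header row naming columns
#'   `protein1`, `protein2` and `combined_score` (or `score`).
#' @param threshold Confidence cut-off in `[0, 1)`; only edges with score
#'   strictly greater than this are retained. Default 0.5, the top-half
#'   confidence filter.
#' @return An `interaction_network` object. Use [tidy()] for the edge table,
#'   [glance()] for a one-row summary, and [network_nodes()] for node names.
#' @export
read_network <- function(path, threshold = 0.5) {
  stopifnot(is.numeric(threshold), threshold >= 0, threshold < 1)
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  names(df) <- tolower(names(df))
  score_col <- intersect(c("combined_score", "score"), names(df))[1]
  if (!all(c("protein1", "protein2") %in% names(df)) || is.na(score_col)) {
    stop("edge list must have columns protein1, protein2, combined_score/score",
         call. = FALSE)
  }
  score <- suppressWarnings(as.numeric(df[[score_col]]))
  bad <- which(!is.finite(score) | is.na(df$protein1) | is.na(df$protein2))
  if (length(bad) > 0) {
    stop(sprintf("malformed edge record at line %d of %s",
                 bad[1] + 1L, path), call. = FALSE)
  }
  rescaled <- FALSE
  if (max(score) > 1) {
    score <- score / 1000
    rescaled <- TRUE
    message("scores look STRING-scaled (max > 1); divided by 1000")
  }
  edges <- tibble::tibble(protein1 = df$protein1, protein2 = df$protein2,
                          combined_score = score)
  as_interaction_network(edges, threshold = threshold,
                         score_rescaled = rescaled, source = path)
}

#' Build an interaction network from an edge table
#'
#' Applies the strict confidence filter, removes self-loops, collapses
#' symmetric duplicates, and wraps the result as an undirected igraph.
#'
#' @param edges Data frame with columns `protein1`, `protein2`,
#'   `combined_score` (scores in `(0, 1]`).
#' @param threshold Strict lower confidence bound; edges with
#'   `combined_score > threshold` are kept.
#' @param score_rescaled,source Metadata recorded on the object.
#' @return An `interaction_network`.
#' @export
as_interaction_network <- function(edges, threshold = 0.5,
                                   score_rescaled = FALSE, source = NA_character_) {
  edges <- tibble::as_tibble(edges)[c("protein1", "protein2", "combined_score")]
  n_in <- nrow(edges)
  edges <- dplyr::filter(edges, .data$combined_score > threshold)
  n_below <- n_in - nrow(edges)
  n_loops <- sum(edges$protein1 == edges$protein2)
  edges <- dplyr::filter(edges, .data$protein1 != .data$protein2)
  if (nrow(edges) == 0) stop("no edges above threshold", call. = FALSE)
  # canonical orientation, then collapse duplicates keeping the max score
  edges <- dplyr::mutate(edges,
                         a = pmin(.data$protein1, .data$protein2),
                         b = pmax(.data$protein1, .data$protein2))
  n_pre <- nrow(edges)
  edges <- edges |>
    dplyr::group_by(.data$a, .data$b) |>
    dplyr::summarise(combined_score = max(.data$combined_score), .groups = "drop") |>
    dplyr::transmute(protein1 = .data$a, protein2 = .data$b,
                     combined_score = .data$combined_score) |>
    dplyr::arrange(.data$protein1, .data$protein2)
  n_dup <- n_pre - nrow(edges)
  if (nrow(edges) == 0) stop("no edges above threshold", call. = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  structure(
    list(graph = g, threshold = threshold,
         dropped = c(below_threshold = n_below, self_loops = n_loops,
                     duplicates = n_dup),
         score_rescaled = score_rescaled, source = source),
    class = "interaction_network"
  )
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("<interaction_network> %d nodes, %d edges (score > %g)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph), x$threshold))
  d <- x$dropped
  cat(sprintf("  dropped: %d below threshold, %d self-loops, %d duplicates\n",
              d[["below_threshold"]], d[["self_loops"]], d[["duplicates"]]))
  invisible(x)
}

#' @describeIn read_network Node identifiers of the filtered network.
#' @param net An `interaction_network`.
#' @export
network_nodes <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  igraph::V(net$graph)$name
}

#' Tidy an interaction network into its canonical edge table
#'
#' @param x An `interaction_network`.
#' @param ... Unused.
#' @return A tibble with columns `protein1`, `protein2`, `combined_score`,
#'   one row per undirected edge in canonical (sorted) orientation.
#' @export
tidy.interaction_network <- function(x, ...) {
  e <- igraph::as_data_frame(x$graph, what = "edges")
  tibble::tibble(protein1 = pmin(e$from, e$to), protein2 = pmax(e$from, e$to),
                 combined_score = e$combined_score) |>
    dplyr::arrange(.data$protein1, .data$protein2)
}

#' @export
glance.interaction_network <- function(x, ...) {
  tibble::tibble(n_nodes = igraph::vcount(x$graph),
                 n_edges = igraph::ecount(x$graph),
                 threshold = x$threshold,
                 n_dropped_below = unname(x$dropped[["below_threshold"]]),
                 n_self_loops = unname(x$dropped[["self_loops"]]),
                 n_duplicates = unname(x$dropped[["duplicates"]]),
                 score_rescaled = x$score_rescaled)
}

#' Names of the seventeen phylostrata
#'
#' Stratum 1 is the oldest (cellular organisms) and 17 the youngest
#' (Hominidae). Strata 1-3 predate Metazoa and are referred to as the
#' unicellular (UC) strata; 4-17 are the multicellular (MC) strata.
#'
#' @return A character vector of length 17, named by stratum index.
#' @export
stratum_labels <- function() {
  setNames(c("cellular organisms (Prokaryota)", "Eukaryota", "Opisthokonta",
             "Metazoa", "Eumetazoa", "Bilateria", "Chordata", "Vertebrata",
             "Euteleostomi", "Tetrapoda", "Amniota", "Mammalia", "Theria",
             "Eutheria", "Boreoeutheria", "Primates", "Hominidae"),
           as.character(1:17))
}

#' Read a gene-to-phylostratum map
#'
#' @param path TSV with header columns `gene_id` and `stratum` (integers 1-17).
#' @return A tibble with columns `gene_id` (character, unique) and `stratum`
#'   (integer in 1..17), plus a `label` column with the stratum name.
#' @export
read_stratum_map <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(gene_id = readr::col_character(),
                                                stratum = readr::col_double()))
  validate_stratum_map(df)
}

#' Validate a stratum map data frame
#'
#' @param df Data frame with columns `gene_id` and `stratum`.
#' @return The validated map as a tibble with a stratum `label` column.
#' @export
validate_stratum_map <- function(df) {
  df <- tibble::as_tibble(df)
  stopifnot(all(c("gene_id", "stratum") %in% names(df)))
  s <- df$stratum
  if (any(is.na(s)) || any(s != as.integer(s)) || any(s < 1) || any(s > 17)) {
    stop("stratum indices must be integers in 1..17", call. = FALSE)
  }
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup) > 0) {
    stop(sprintf("duplicate gene identifier in stratum map: %s", dup[1]),
         call. = FALSE)
  }
  dplyr::transmute(df, gene_id = as.character(.data$gene_id),
                   stratum = as.integer(.data$stratum),
                   label = unname(stratum_labels()[as.character(.data$stratum)]))
}

#' Read a flagged gene set (e.g. ZF-C2H2 members)
#'
#' @param path Text file with one gene identifier per line (a `gene_id` header
#'   line is tolerated).
#' @param name Name of the set, e.g. `"ZF-C2H2"`.
#' @return A list with elements `name` and `members` (character vector).
#' @export
read_gene_set <- function(path, name = "gene_set") {
  x <- readr::read_lines(path, progress = FALSE)
  x <- x[nzchar(x)]
  x <- setdiff(x, "gene_id")
  list(name = name, members = unique(x))
}

#' Read a GO-style DAG from term-edge and annotation tables
#'
#' The canonical dialect is two TSV files: `child`/`parent` term pairs
#' (`is_a`-style links) and direct `term`/`gene` annotations. The DAG is
#' checked for cycles on construction.
#'
#' @param edges_path TSV with header columns `term_child`, `term_parent`.
#' @param annot_path TSV with header columns `term`, `gene`.
#' @return A `go_dag` object: `terms`, `parents` (child -> parent terms),
#'   `children`, and `direct` (term -> directly annotated genes).
#' @export
read_go_dag <- function(edges_path, annot_path) {
  ed <- readr::read_tsv(edges_path, show_col_types = FALSE, progress = FALSE,
                        col_types = "cc")
  an <- readr::read_tsv(annot_path, show_col_types = FALSE, progress = FALSE,
                        col_types = "cc")
  stopifnot(all(c("term_child", "term_parent") %in% names(ed)),
            all(c("term", "gene") %in% names(an)))
  as_go_dag(edges = ed, annotations = an)
}

#' Build a `go_dag` from edge and annotation tables
#'
#' @param edges Data frame with `term_child`, `term_parent`.
#' @param annotations Data frame with `term`, `gene` direct annotations.
#' @param terms Optional full term universe (defaults to terms seen in either
#'   table).
#' @return A `go_dag`.
#' @export
as_go_dag <- function(edges, annotations, terms = NULL) {
  edges <- tibble::as_tibble(edges)
  annotations <- tibble::as_tibble(annotations)
  terms <- unique(c(terms, edges$term_child, edges$term_parent,
                    annotations$term))
  if (nrow(edges) > 0) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = edges$term_child, to = edges$term_parent),
      directed = TRUE, vertices = terms)
    if (!igraph::is_dag(g)) {
      cyc <- igraph::feedback_arc_set(g)
      offender <- igraph::tail_of(g, cyc[1])$name
      stop(sprintf("term relation graph contains a cycle through '%s'",
                   offender), call. = FALSE)
    }
  }
  parents <- split(edges$term_parent, factor(edges$term_child, levels = terms))
  children <- split(edges$term_child, factor(edges$term_parent, levels = terms))
  direct <- lapply(split(annotations$gene,
                         factor(annotations$term, levels = terms)), unique)
  structure(list(terms = terms, parents = parents, children = children,
                 direct = direct),
            class = "go_dag")
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("<go_dag> %d terms, %d parent links, %d direct annotations\n",
              length(x$terms), sum(lengths(x$parents)), sum(lengths(x$direct))))
  invisible(x)
}

#' Propagate annotations down-to-up through the DAG
#'
#' A gene belongs to a term if it is directly annotated to the term or to any
#' of the term's descendants; each term's propagated set is the union of its
#' direct annotations and its children's propagated sets. Sets are computed
#' once in topological order (children before parents).
#'
#' @param dag A `go_dag`.
#' @return A named list, term -> character vector of member genes.
#' @export
propagate_annotations <- function(dag) {
  stopifnot(inherits(dag, "go_dag"))
  terms <- dag$terms
  # topological order with child->parent edges puts children first
  ord <- terms
  if (sum(lengths(dag$parents)) > 0) {
    ed <- tibble::tibble(
      from = rep(terms, lengths(dag$parents)),
      to = unlist(dag$parents, use.names = FALSE))
    g <- igraph::graph_from_data_frame(ed, directed = TRUE, vertices = terms)
    ord <- igraph::topo_sort(g, mode = "out")$name
  }
  out <- setNames(vector("list", length(terms)), terms)
  for (t in ord) {
    kids <- dag$children[[t]]
    out[[t]] <- unique(c(dag$direct[[t]],
                         unlist(out[kids], use.names = FALSE)))
  }
  lapply(out, function(v) if (is.null(v)) character(0) else sort(v))
}
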