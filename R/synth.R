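#' Generate an age-layered core-periphery network with its stratum map
#'
#' Emulates gradual core-to-periphery interactome growth: nodes are added in
#' stratum order 1 (oldest) to 17 (youngest), so early nodes accumulate
#' connections and end up forming the dense ancient core. Two growth models
#' are available: preferential attachment (each new node attaches `m` edges
#' to existing nodes with probability proportional to degree + 1) and
#' duplication-divergence (each new node copies a random template's
#' neighbourhood, losing each inherited edge with probability `divergence`;
#' if nothing is inherited it links to the template). Edge confidences are
#' drawn above the 0.5 filter so the generated network survives the standard
#' confidence cut unchanged; `n_noise_edges` adds sub-threshold records for
#' exercising the filter.
#'
#' @param n_per_stratum Integer vector of length 17 (or length 1, recycled):
#'   genes per stratum.
#' @param model `"preferential"` (default) or `"duplication"`.
#' @param m Edges attached per new node (preferential model).
#' @param divergence Edge-loss probability in the duplication model.
#' @param n_noise_edges Extra random edges with scores in (0, 0.5].
#' @param seed Integer seed; generation is fully deterministic.
#' @return A list: `network` (an `interaction_network`, threshold 0.5),
#'   `strata` (stratum map tibble), and `edges` (the raw edge tibble as it
#'   would appear on disk, including sub-threshold noise records).
#' @export
gen_network <- function(n_per_stratum = 30, model = c("preferential", "duplication"),
                        m = 3, divergence = 0.3, n_noise_edges = 0, seed = 1L) {
  model <- match.arg(model)
  if (length(n_per_stratum) == 1) n_per_stratum <- rep(n_per_stratum, 17)
  stopifnot(length(n_per_stratum) == 17, all(n_per_stratum >= 1), m >= 1)
  n <- sum(n_per_stratum)
  genes <- sprintf("g%04d", seq_len(n))
  strata <- tibble::tibble(gene_id = genes,
                           stratum = rep(1:17, n_per_stratum))
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  deg <- integer(n)
  from <- integer(0); to <- integer(0)
  nbrs <- vector("list", n)
  for (i in seq_len(n)[-1]) {
    existing <- seq_len(i - 1)
    if (model == "preferential") {
      k <- min(m, length(existing))
      w <- deg[existing] + 1
      targets <- sample(existing, k, prob = w)
    } else {
      tmpl <- if (length(existing) == 1) existing else sample(existing, 1)
      inherit <- nbrs[[tmpl]]
      keep <- inherit[runif(length(inherit)) >= divergence]
      targets <- if (length(keep) > 0) keep else tmpl
    }
    from <- c(from, rep(i, length(targets))); to <- c(to, targets)
    deg[i] <- deg[i] + length(targets)
    deg[targets] <- deg[targets] + 1
    nbrs[[i]] <- targets
    for (t in targets) nbrs[[t]] <- c(nbrs[[t]], i)
  }
  edges <- tibble::tibble(
    protein1 = genes[pmin(from, to)], protein2 = genes[pmax(from, to)],
    combined_score = runif(length(from), 0.5 + 1e-6, 1))
  if (n_noise_edges > 0) {
    a <- sample(n, n_noise_edges, replace = TRUE)
    b <- sample(n, n_noise_edges, replace = TRUE)
    edges <- dplyr::bind_rows(edges, tibble::tibble(
      protein1 = genes[a], protein2 = genes[b],
      combined_score = runif(n_noise_edges, 0.01, 0.5)))
  }
  list(network = as_interaction_network(edges, threshold = 0.5,
                                        source = "gen_network"),
       strata = validate_stratum_map(strata), edges = edges)
}

# save/restore the global RNG state around generator calls
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv)) {
    get(".Random.seed", envir = .GlobalEnv)
  }
  set.seed(seed)
  old
}
restore_seed <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
}

#' Generate a stratified two-group expression matrix
#'
#' Each gene's log2-scale baseline depends on its stratum (by default a
#' gentle decline with youth, mimicking the higher expression of ancient
#' genes), and cells of the case group are shifted by a per-stratum effect
#' `delta` — the planted fold gradient that downstream profile analysis
#' should recover. Noise is lognormal (Gaussian on the log2 scale with sd
#' `sigma`) or negative binomial on counts.
#'
#' @param strata Stratum map tibble; one gene per row is emitted.
#' @param n_cells Cells per group (>= 2).
#' @param baseline Length-17 vector of log2 baselines per stratum (or one
#'   value, recycled). Default `8 - 0.15 * (s - 1)`.
#' @param baseline_sd Gene-level spread (sd, log2 scale) around the stratum
#'   baseline (default 2). Real transcriptomes span orders of magnitude
#'   between genes; this dispersion also keeps a gene's rank within a cell
#'   from being determined by its stratum, which matters because rank-based
#'   quantile normalization cancels any shift that is predictable from rank.
#' @param delta Length-17 vector of planted case-vs-control log2 effects per
#'   stratum (or one value, recycled). Default 0 (null).
#' @param noise `"lognormal"` (default) or `"nb"`.
#' @param sigma Log2-scale noise sd for the lognormal model.
#' @param dispersion Negative-binomial dispersion (`size = 1/dispersion`).
#' @param case_label,control_label Group names (default cancer/normal).
#' @param seed Integer seed.
#' @return An `expression_matrix` of raw (unnormalized) values.
#' @export
gen_expression <- function(strata, n_cells = 40,
                           baseline = 8 - 0.15 * (0:16), baseline_sd = 2,
                           delta = 0, noise = c("lognormal", "nb"),
                           sigma = 0.5, dispersion = 0.5,
                           case_label = "cancer", control_label = "normal",
                           seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(n_cells >= 2)
  if (length(baseline) == 1) baseline <- rep(baseline, 17)
  if (length(delta) == 1) delta <- rep(delta, 17)
  stopifnot(length(baseline) == 17, length(delta) == 17)
  strata <- validate_stratum_map(strata[c("gene_id", "stratum")])
  genes <- strata$gene_id
  b <- baseline[strata$stratum]
  d <- delta[strata$stratum]
  cells <- c(sprintf("case_%03d", seq_len(n_cells)),
             sprintf("ctrl_%03d", seq_len(n_cells)))
  groups <- tibble::tibble(cell = cells,
                           group = rep(c(case_label, control_label),
                                       each = n_cells))
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  b <- b + rnorm(length(b), sd = baseline_sd)
  mu_log2 <- outer(b, rep(1, 2 * n_cells)) +
    outer(d, c(rep(1, n_cells), rep(0, n_cells)))
  if (noise == "lognormal") {
    mat <- 2^(mu_log2 + matrix(rnorm(length(mu_log2), sd = sigma),
                               nrow = length(genes)))
  } else {
    mat <- matrix(rnbinom(length(mu_log2), mu = 2^mu_log2,
                          size = 1 / dispersion),
                  nrow = length(genes))
  }
  dimnames(mat) <- list(genes, cells)
  expression_matrix(mat, groups, case_label = case_label,
                    dataset = "synthetic")
}

#' Generate a random annotated DAG with optional planted leaf terms
#'
#' Terms are laid out by depth; every non-root term receives 1-2 parents
#' among shallower terms, so the child-parent relation is acyclic by
#' construction. Each term gets a random set of direct gene annotations.
#' Planted terms are added as leaves with exactly the requested number of
#' direct genes; shift their genes' values with [gen_go_values()] to create
#' ground-truth enrichment signal.
#'
#' @param genes Character vector, the annotation universe.
#' @param n_terms Number of background terms.
#' @param max_depth Maximum DAG depth (default 4).
#' @param size_range Range of direct-annotation sizes per background term.
#' @param planted_sizes Integer vector; one planted leaf term per entry with
#'   that many direct genes.
#' @param seed Integer seed.
#' @return A list: `dag` (a `go_dag`) and `planted` (character vector of
#'   planted term ids).
#' @export
gen_go <- function(genes, n_terms = 30, max_depth = 4,
                   size_range = c(10, 60), planted_sizes = integer(0),
                   seed = 1L) {
  stopifnot(n_terms >= 1, max_depth >= 1)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  terms <- sprintf("T%03d", seq_len(n_terms))
  depth <- c(0, sample(seq_len(max_depth), n_terms - 1, replace = TRUE))
  edges <- purrr::map_dfr(seq_len(n_terms)[-1], function(i) {
    shallower <- which(depth < depth[i])
    np <- min(sample(1:2, 1), length(shallower))
    tibble::tibble(term_child = terms[i],
                   term_parent = terms[sample(shallower, np)])
  })
  sizes <- sample(size_range[1]:size_range[2], n_terms, replace = TRUE)
  annot <- purrr::map_dfr(seq_len(n_terms), function(i) {
    tibble::tibble(term = terms[i],
                   gene = sample(genes, min(sizes[i], length(genes))))
  })
  planted <- character(0)
  if (length(planted_sizes) > 0) {
    planted <- sprintf("T_planted_%d", seq_along(planted_sizes))
    edges <- dplyr::bind_rows(edges, tibble::tibble(
      term_child = planted, term_parent = terms[1]))
    annot <- dplyr::bind_rows(annot, purrr::map_dfr(
      seq_along(planted), function(i) {
        tibble::tibble(term = planted[i],
                       gene = sample(genes, planted_sizes[i]))
      }))
  }
  list(dag = as_go_dag(edges, annot), planted = planted)
}

#' Per-gene values with planted term-level shifts
#'
#' Draws standard-normal-scale values for a gene universe and shifts the
#' genes of selected terms (after DAG propagation) by `shift` — the ground
#' truth for enrichment-recovery tests.
#'
#' @param dag A `go_dag`.
#' @param genes The gene universe (value table rows).
#' @param planted Character vector of terms whose propagated genes get the
#'   shift.
#' @param shift Added to planted genes' values (default 1).
#' @param sd Noise standard deviation (default 1).
#' @param seed Integer seed.
#' @return A tibble with columns `gene`, `value`.
#' @export
gen_go_values <- function(dag, genes, planted = character(0), shift = 1,
                          sd = 1, seed = 1L) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  v <- rnorm(length(genes), sd = sd)
  names(v) <- genes
  if (length(planted) > 0) {
    ann <- propagate_annotations(dag)
    for (t in planted) {
      hit <- intersect(ann[[t]], genes)
      v[hit] <- v[hit] + shift
    }
  }
  tibble::tibble(gene = genes, value = unname(v))
}
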