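# Independent brute-force oracles and tiny fixture builders. Everything here
# avoids the package's own computational paths (igraph, the C++ samplers).

# ---- graph fixtures -------------------------------------------------------

edge_tbl <- function(pairs, score = 0.9) {
  tibble::tibble(protein1 = vapply(pairs, `[[`, "", 1),
                 protein2 = vapply(pairs, `[[`, "", 2),
                 combined_score = rep_len(score, length(pairs)))
}

path_net <- function(nodes = c("A", "B", "C")) {
  pairs <- Map(c, nodes[-length(nodes)], nodes[-1])
  as_interaction_network(edge_tbl(pairs))
}

star_net <- function(center = "H", leaves = paste0("L", 1:4)) {
  as_interaction_network(edge_tbl(Map(c, center, leaves)))
}

# random connected-ish simple graph as an adjacency matrix + network
random_graph <- function(n, p = 0.12, seed = 1) {
  set.seed(seed)
  adj <- matrix(0L, n, n)
  adj[upper.tri(adj)] <- rbinom(n * (n - 1) / 2, 1, p)
  # string a spanning path through so most nodes are non-isolated
  for (i in seq_len(n - 1)) if (runif(1) < 0.8) adj[i, i + 1] <- 1L
  adj <- adj + t(adj)
  diag(adj) <- 0L
  nodes <- sprintf("n%02d", seq_len(n))
  dimnames(adj) <- list(nodes, nodes)
  idx <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  net <- as_interaction_network(tibble::tibble(
    protein1 = nodes[idx[, 1]], protein2 = nodes[idx[, 2]],
    combined_score = 0.9))
  list(adj = adj, net = net, nodes = nodes)
}

# ---- shortest-path oracles (hand-rolled BFS; no igraph) -------------------

bfs_dist <- function(adj, src) {
  n <- nrow(adj)
  d <- rep(Inf, n)
  d[src] <- 0
  frontier <- src
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (v in frontier) {
      for (w in which(adj[v, ] > 0)) {
        if (is.infinite(d[w])) { d[w] <- d[v] + 1; nxt <- c(nxt, w) }
      }
    }
    frontier <- nxt
  }
  d
}

oracle_centrality <- function(adj) {
  n <- nrow(adj)
  D <- t(vapply(seq_len(n), function(s) bfs_dist(adj, s), numeric(n)))
  closeness <- vapply(seq_len(n), function(v) {
    s <- sum(D[v, is.finite(D[v, ])])
    if (s > 0) 1 / s else 0
  }, numeric(1))
  # geodesic counts sigma[s, t] by DP over nodes ordered by distance from s
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    ord <- order(D[s, ])
    for (t in ord) {
      if (t == s || is.infinite(D[s, t])) next
      preds <- which(adj[t, ] > 0 & D[s, ] == D[s, t] - 1)
      sigma[s, t] <- sum(sigma[s, preds])
    }
  }
  # pair dependency: sigma_sv * sigma_vt / sigma_st when v lies on a geodesic
  btw <- numeric(n)
  for (v in seq_len(n)) {
    acc <- 0
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
      if (s == v || t == v || !is.finite(D[s, t])) next
      if (D[s, v] + D[v, t] == D[s, t]) {
        acc <- acc + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
    }
    btw[v] <- acc
  }
  list(degree = rowSums(adj > 0), closeness = closeness, betweenness = btw)
}

# ---- walk oracle: exact k-step endpoint law by transition-matrix power ----

walk_law <- function(adj, start_probs, steps) {
  P <- adj / pmax(rowSums(adj), 1)
  p <- start_probs
  for (i in seq_len(steps)) p <- as.numeric(p %*% P)
  p
}

tv_dist <- function(p, q) sum(abs(p - q)) / 2

# ---- enumeration oracle for the mean-contrast test ------------------------

exact_contrast_p <- function(values, k) {
  total_mean <- mean(values)
  combos <- utils::combn(seq_along(values), k)
  devs <- apply(combos, 2, function(ix) abs(mean(values[ix]) - total_mean))
  function(obs_dev) mean(devs >= obs_dev - 1e-12 * (1 + obs_dev))
}

# ---- DAG descendant oracle: repeated edge expansion -----------------------

oracle_propagate <- function(edges, direct, terms) {
  # descendants via transitive closure of parent->child
  desc <- setNames(lapply(terms, function(t) character(0)), terms)
  kids <- split(edges$term_child, factor(edges$term_parent, levels = terms))
  repeat {
    changed <- FALSE
    for (t in terms) {
      new <- unique(c(desc[[t]], kids[[t]],
                      unlist(desc[kids[[t]]], use.names = FALSE)))
      if (length(new) != length(desc[[t]])) { desc[[t]] <- new; changed <- TRUE }
    }
    if (!changed) break
  }
  lapply(setNames(nm = terms), function(t) {
    sort(unique(unlist(c(direct[t], direct[desc[[t]]]), use.names = FALSE)))
  })
}

random_dag <- function(n_terms, seed) {
  set.seed(seed)
  terms <- sprintf("D%02d", seq_len(n_terms))
  edges <- purrr::map_dfr(seq_len(n_terms)[-1], function(i) {
    np <- sample(1:min(2, i - 1), 1)
    tibble::tibble(term_child = terms[i],
                   term_parent = terms[sample(i - 1, np)])
  })
  genes <- sprintf("x%03d", 1:60)
  annot <- purrr::map_dfr(terms, function(t) {
    tibble::tibble(term = t, gene = sample(genes, sample(1:6, 1)))
  })
  list(edges = edges, annot = annot, terms = terms)
}

hand_bh <- function(p) {
  m <- length(p)
  if (m == 1) return(p)
  o <- order(p)
  q <- numeric(m)
  q[o[m]] <- p[o[m]]
  for (i in (m - 1):1) {
    q[o[i]] <- min(p[o[i]] * m / i, q[o[i + 1]])
  }
  q
}

write_edges_tsv <- function(edges, path) {
  readr::write_tsv(edges, path, progress = FALSE)
  path
}

# stratified gaussian test data for the ANOM simulations
sim_anom_data <- function(sizes, shifts = 0, seed = 1) {
  set.seed(seed)
  strata_idx <- rep(seq_along(sizes), sizes)
  shifts <- rep_len(shifts, length(sizes))
  tibble::tibble(
    gene = sprintf("g%04d", seq_along(strata_idx)),
    value = rnorm(length(strata_idx)) + shifts[strata_idx],
    stratum = strata_idx)
}
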