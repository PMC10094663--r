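test_that("single walks follow forced trajectories", {
  net <- as_interaction_network(edge_tbl(list(c("A", "B"))))
  for (s in 1:5) expect_equal(random_walk_end(net, "A", 1, seed = s), "B")
  expect_equal(random_walk_end(net, "A", 0, seed = 1), "A")
  expect_error(random_walk_end(net, "Z", 1), "not in network")
})

test_that("two-step walks on a path match the exhaustive enumeration", {
  # A-B-C from A: after 2 steps the walk is at A or C with probability 1/2,
  # and can never be at B
  net <- path_net(c("A", "B", "C"))
  ends <- vapply(1:2000, function(s) random_walk_end(net, "A", 2, seed = s),
                 character(1))
  expect_false(any(ends == "B"))
  expect_equal(mean(ends == "A"), 0.5, tolerance = 0.07)
})

test_that("ensembles tally endpoints by stratum and respect forced fixtures", {
  net <- as_interaction_network(edge_tbl(list(c("A", "B"))))
  strata <- tibble::tibble(gene_id = c("A", "B"), stratum = c(17, 1))
  d <- run_walk_ensemble(net, strata, walk_length = 1, n_repeats = 100,
                         seed = 4)
  expect_equal(d$raw_count[which(d$stratum == 1)], 100)
  expect_equal(sum(d$raw_count), 100)
  expect_equal(d$normalized[which(d$stratum == 1)], 100)
  expect_error(run_walk_ensemble(net, strata, start_stratum = 5),
               "start stratum 5")
})

test_that("3-step endpoint law matches the transition-matrix-power oracle", {
  # 4-node fixture: triangle ABC plus pendant D-A
  pairs <- list(c("A", "B"), c("B", "C"), c("A", "C"), c("A", "D"))
  net <- as_interaction_network(edge_tbl(pairs))
  nodes <- network_nodes(net)
  adj <- matrix(0, 4, 4, dimnames = list(nodes, nodes))
  for (pr in pairs) { adj[pr[1], pr[2]] <- 1; adj[pr[2], pr[1]] <- 1 }
  strata <- tibble::tibble(
    gene_id = nodes,
    stratum = c(17, 1, 2, 3)[match(nodes, c("D", "A", "B", "C"))])
  n_rep <- 40000
  d <- run_walk_ensemble(net, strata, walk_length = 3, n_repeats = n_rep,
                         start_stratum = 17, seed = 7)
  start <- as.numeric(nodes == "D")
  p_exact <- walk_law(adj, start, 3)
  for (i in seq_along(nodes)) {
    s <- strata$stratum[strata$gene_id == nodes[i]]
    obs <- d$raw_count[which(d$stratum == s)] / n_rep
    mc_se <- sqrt(p_exact[i] * (1 - p_exact[i]) / n_rep)
    expect_lt(abs(obs - p_exact[i]), 3 * mc_se + 1e-9)
  }
})

test_that("ensembles are bit-reproducible for a fixed seed", {
  gen <- gen_network(n_per_stratum = 8, m = 2, seed = 3)
  d1 <- run_walk_ensemble(gen$network, gen$strata, walk_length = 50,
                          n_repeats = 2000, seed = 123)
  d2 <- run_walk_ensemble(gen$network, gen$strata, walk_length = 50,
                          n_repeats = 2000, seed = 123)
  d3 <- run_walk_ensemble(gen$network, gen$strata, walk_length = 50,
                          n_repeats = 2000, seed = 124)
  expect_identical(d1$raw_count, d2$raw_count)
  expect_false(identical(d1$raw_count, d3$raw_count))
  expect_equal(sum(d1$raw_count), 2000)
})

test_that("long walks converge to the degree-proportional stationary law", {
  gen <- gen_network(n_per_stratum = 6, m = 2, seed = 21)
  net <- gen$network
  expect_true(igraph::is_connected(net$graph))
  n_rep <- 20000
  d <- run_walk_ensemble(net, gen$strata, walk_length = 400,
                         n_repeats = n_rep, seed = 31)
  pi_v <- stationary_distribution(net)
  # aggregate stationary law to strata
  st <- gen$strata$stratum[match(pi_v$node, gen$strata$gene_id)]
  pi_s <- tapply(pi_v$stationary_prob, factor(st, levels = 1:17), sum)
  pi_s[is.na(pi_s)] <- 0
  obs <- d$raw_count[!is.na(d$stratum)] / n_rep
  expect_lt(tv_dist(obs, as.numeric(pi_s)), 0.03)
})

test_that("dead-end starts terminate in place and are counted", {
  net <- as_interaction_network(edge_tbl(list(c("B", "C"))))
  net$graph <- igraph::add_vertices(net$graph, 1, name = "iso")
  strata <- tibble::tibble(gene_id = c("B", "C", "iso"),
                           stratum = c(1, 2, 17))
  d <- run_walk_ensemble(net, strata, walk_length = 10, n_repeats = 50,
                         seed = 2)
  expect_equal(d$raw_count[which(d$stratum == 17)], 50)
  expect_equal(glance(d)$n_dead_end, 50)

  # and length 0 concentrates on the start stratum without dead-end counting
  d0 <- run_walk_ensemble(net, strata, walk_length = 0, n_repeats = 50,
                          seed = 2)
  expect_equal(d0$raw_count[which(d0$stratum == 17)], 50)
  expect_equal(glance(d0)$n_dead_end, 0)
})

test_that("length sweeps derive per-length seeds and report shrinking TV diagnostics", {
  gen <- gen_network(n_per_stratum = 6, m = 2, seed = 21)
  sw <- walk_length_sweep(gen$network, gen$strata, lengths = c(0, 5, 30, 200),
                          n_repeats = 5000, seed = 17)
  conv <- attr(sw, "convergence")
  expect_equal(nrow(conv), 3)
  # length 0: all mass on the start stratum
  l0 <- dplyr::filter(sw, walk_length == 0)
  expect_equal(l0$raw_count[which(l0$stratum == 17)], 5000)
  # convergence: TV to the exact stationary law shrinks from 5 to 30 steps
  pi_v <- stationary_distribution(gen$network)
  st <- gen$strata$stratum[match(pi_v$node, gen$strata$gene_id)]
  pi_s <- as.numeric(tapply(pi_v$stationary_prob, factor(st, levels = 1:17), sum))
  tv_at <- function(len) {
    d <- dplyr::filter(sw, walk_length == len, !is.na(stratum))
    tv_dist(d$raw_count / sum(d$raw_count), pi_s)
  }
  expect_lt(tv_at(30), tv_at(5))
  # stabilization: distributions at >= 30 steps agree within Monte-Carlo noise
  expect_lt(dplyr::filter(conv, from_length == 30)$tv_distance, 0.05)
})

test_that("normalized endpoint frequency tracks mean stratum degree over strata", {
  # mechanism check: normalized frequency -> (mean degree of stratum) / 2|E|
  gen <- gen_network(n_per_stratum = 10, m = 3, seed = 42)
  d <- run_walk_ensemble(gen$network, gen$strata, walk_length = 300,
                         n_repeats = 30000, seed = 5)
  cent <- node_centrality(gen$network)
  degsum <- stratum_summary(cent, gen$strata)
  deg <- dplyr::filter(degsum, measure == "degree")
  obs <- d$normalized[match(deg$stratum, d$stratum)] / sum(d$raw_count)
  expected <- deg$mean / (2 * igraph::ecount(gen$network$graph))
  expect_gt(cor(obs, expected, method = "spearman"), 0.9)
})
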