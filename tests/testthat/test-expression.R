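make_expr <- function(mat, groups = NULL, case = NULL) {
  if (is.null(groups)) {
    half <- ncol(mat) / 2
    groups <- tibble::tibble(cell = colnames(mat),
                             group = rep(c("cancer", "normal"), each = half))
  }
  expression_matrix(mat, groups, case_label = case)
}

test_that("quantile normalization forces a common column distribution", {
  m <- cbind(c1 = c(1, 2, 3), c2 = c(4, 5, 6))
  rownames(m) <- paste0("g", 1:3)
  # two cells only: below the group-size rule, so build the object by hand
  ex <- structure(list(values = m,
                       cell_groups = tibble::tibble(cell = c("c1", "c2"),
                                                    group = c("a", "b")),
                       case_label = "a", control_label = "b",
                       dataset = NA, normalized = FALSE),
                  class = "expression_matrix")
  qn <- quantile_normalize(ex, log_transform = FALSE)
  expect_equal(unname(qn$values[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn$values[, 2]), c(2.5, 3.5, 4.5))

  # identical columns are a fixed point (up to the log transform)
  m2 <- cbind(a = c(5, 1, 7), b = c(5, 1, 7), c = c(5, 1, 7), d = c(5, 1, 7))
  rownames(m2) <- paste0("g", 1:3)
  qn2 <- quantile_normalize(make_expr(m2), log_transform = FALSE)
  expect_equal(qn2$values, m2)
})

test_that("all columns share identical sorted values after normalization, ties averaged", {
  set.seed(8)
  m <- matrix(rlnorm(200, 3, 1), nrow = 20, # continuous: no ties
              dimnames = list(paste0("g", 1:20), paste0("c", 1:10)))
  qn <- quantile_normalize(make_expr(m))
  sorted <- apply(qn$values, 2, sort)
  for (j in 2:ncol(sorted)) {
    expect_equal(sorted[, j], sorted[, 1], ignore_attr = TRUE)
  }
  # tied input values in a cell collapse to the mean of their reference
  # quantiles, and pre-log column totals stay equal to the reference total
  m2 <- matrix(rpois(200, 20), nrow = 20,
               dimnames = dimnames(m))
  m2[1:5, 1] <- 13
  qn2 <- quantile_normalize(make_expr(m2), log_transform = FALSE)
  expect_equal(length(unique(qn2$values[1:5, 1])), 1)
  ref <- rowMeans(apply(m2, 2, sort))
  expect_equal(colSums(qn2$values), setNames(rep(sum(ref), 10), colnames(m2)))
})

test_that("authored quantile normalization agrees with the limma reference", {
  skip_if_not_installed("limma")
  set.seed(3)
  m <- matrix(rlnorm(300, 3, 1), nrow = 30,
              dimnames = list(paste0("g", 1:30), paste0("c", 1:10)))
  qn <- quantile_normalize(make_expr(m), log_transform = FALSE)
  ref <- limma::normalizeQuantiles(m, ties = TRUE)
  expect_equal(unname(qn$values), unname(ref), tolerance = 1e-10)
})

test_that("group folds are case-minus-control and antisymmetric under label swap", {
  m <- rbind(flat = rep(4, 6), up = c(8, 8, 8, 4, 4, 4),
             dn = c(2, 2, 2, 4, 4, 4))
  colnames(m) <- paste0("c", 1:6)
  groups <- tibble::tibble(cell = colnames(m),
                           group = rep(c("cancer", "normal"), each = 3))
  ex <- expression_matrix(m, groups, case_label = "cancer")
  ex$normalized <- TRUE # values already on the log scale for this toy
  ft <- group_fold(ex)
  expect_equal(ft$log2_fold[ft$gene == "flat"], 0)
  expect_equal(ft$log2_fold[ft$gene == "up"], 4)
  expect_equal(attr(ft, "orientation"), "cancer - normal")

  ex_sw <- expression_matrix(m, groups, case_label = "normal")
  ex_sw$normalized <- TRUE
  expect_equal(group_fold(ex_sw)$log2_fold, -ft$log2_fold)

  # a 2x linear expression ratio gives fold 1 after the log2 pipeline
  m3 <- matrix(rep(c(200, 100), each = 4), nrow = 1, byrow = FALSE,
               dimnames = list("g", paste0("c", 1:8)))
  m3[] <- c(rep(200, 4), rep(100, 4))
  ex3 <- expression_matrix(m3, tibble::tibble(
    cell = colnames(m3), group = rep(c("cancer", "normal"), each = 4)),
    case_label = "cancer")
  ex3$values <- log2(ex3$values) # identical columns: qnorm is identity
  ex3$normalized <- TRUE
  expect_equal(group_fold(ex3)$log2_fold, 1)
})

test_that("spreadsheet-style fold recomputation matches on a printed toy matrix", {
  m <- rbind(g1 = c(2, 4, 6, 1, 3, 5), g2 = c(10, 12, 8, 9, 11, 7),
             g3 = c(0, 1, 2, 3, 4, 5), g4 = c(7, 7, 7, 7, 7, 7))
  colnames(m) <- paste0("c", 1:6)
  ex <- expression_matrix(m, tibble::tibble(
    cell = colnames(m), group = rep(c("cancer", "normal"), each = 3)))
  ex$normalized <- TRUE
  ft <- group_fold(ex)
  hand <- apply(m, 1, function(r) mean(r[1:3]) - mean(r[4:6]))
  expect_equal(ft$log2_fold, unname(hand))
})

test_that("stratum profiles bin correctly, flag empty bins and localize exclusions", {
  vals <- tibble::tibble(gene = c("g1", "g2", "g3"), log2_fold = c(1, 3, 2))
  strata <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                           stratum = c(1, 1, 17))
  prof <- stratum_profile(vals, strata,
                          bins = list(1:16, 17))
  expect_equal(prof$mean, c(2, 2))
  expect_equal(prof$n, c(2L, 1L))

  # default bins partition 1..17; an empty bin is kept with n = 0, mean NA
  prof2 <- stratum_profile(vals, strata)
  expect_equal(nrow(prof2), 6)
  empty <- dplyr::filter(prof2, bin == "4-6")
  expect_equal(empty$n, 0L)
  expect_true(is.na(empty$mean))
  expect_error(stratum_profile(vals, strata, bins = list(1:16)),
               "partition")

  # exclusion only alters bins containing excluded genes
  prof3 <- stratum_profile(vals, strata, bins = list(1:16, 17),
                           exclude = list(name = "flag", members = "g2"))
  all_s <- dplyr::filter(prof3, series == "all")
  rem <- dplyr::filter(prof3, series == "excluded_removed")
  expect_equal(rem$mean[rem$strata_hi == 17], all_s$mean[all_s$strata_hi == 17])
  expect_equal(rem$mean[rem$strata_lo == 1], 1)
})

test_that("planted per-stratum fold gradients are recovered by the profile", {
  gen <- gen_network(n_per_stratum = 60, m = 2, seed = 14)
  delta <- 0.5 - 0.03 * (0:16)
  ex <- gen_expression(gen$strata, n_cells = 40, delta = delta, sigma = 0.5,
                       seed = 15)
  ft <- group_fold(quantile_normalize(ex))
  prof <- stratum_profile(ft, gen$strata, bins = as.list(1:17))
  # quantile normalization equalizes whole-cell distributions, so the
  # genome-wide mean of the planted shift is not identifiable; the gradient
  # (deviations across strata) is. Compare against the centered gradient.
  centered <- delta - mean(delta)
  ok <- abs(prof$mean - centered[prof$strata_lo]) <= 2 * prof$sem + 0.05
  expect_gte(mean(ok), 15 / 17)
  fit <- stats::lm(mean ~ strata_lo, data = prof)
  slope <- summary(fit)$coefficients[2, ]
  expect_lt(slope["Estimate"], 0) # gradient sign recovered
  expect_equal(unname(slope["Estimate"]), -0.03,
               tolerance = max(0.3, 2 * slope["Std. Error"] / 0.03))

  # null gradient: stratum means straddle zero
  ex0 <- gen_expression(gen$strata, n_cells = 40, delta = 0, sigma = 0.5,
                        seed = 16)
  ft0 <- group_fold(quantile_normalize(ex0))
  prof0 <- stratum_profile(ft0, gen$strata, bins = as.list(1:17))
  expect_true(all(abs(prof0$mean) <= 3 * prof0$sem + 0.05))
})

test_that("stratum composition concentration and rank correlation behave", {
  set.seed(30)
  strata <- tibble::tibble(gene_id = sprintf("g%04d", 1:1700),
                           stratum = rep(1:17, each = 100))
  # set drawn uniformly: no rank correlation signal
  comp_null <- stratum_composition(sample(strata$gene_id, 500), strata)
  expect_lt(abs(glance(comp_null)$spearman_r), 0.5)
  # set entirely ancient: maximal concentration
  comp_uc <- suppressWarnings(
    stratum_composition(strata$gene_id[strata$stratum == 1], strata))
  expect_equal(tidy(comp_uc)$proportion[1], 1)
  # planted geometric decline toward young strata
  probs <- 0.7^(rep(1:17, each = 100))
  planted <- sample(strata$gene_id, 600, prob = probs)
  comp_g <- stratum_composition(planted, strata)
  expect_lt(glance(comp_g)$spearman_r, -0.8)
  expect_lt(glance(comp_g)$p_value, 0.01)
})
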