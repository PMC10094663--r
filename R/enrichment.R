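#' Monte-Carlo mean-contrast test for one gene category
#'
#' Compares the mean value (typically a log2 cancer/normal fold) of a gene
#' category against the mean of the whole measured gene set. Significance is
#' assessed by drawing `n_samples` random gene subsets of the category's size
#' from the full value table without replacement (the pool is restored between
#' draws) and counting samples whose mean deviates from the total mean at
#' least as much as the category's. The two-tailed p-value uses the add-one
#' estimator `(1 + exceedances) / (1 + n_samples)`, which never returns 0.
#'
#' @param values Data frame with columns `gene` and a numeric value column,
#'   or a named numeric vector.
#' @param category_genes Character vector of category members (genes absent
#'   from `values` are ignored).
#' @param n_samples Number of random samplings (default 20000).
#' @param seed Integer seed; samples use per-draw substreams, so the estimate
#'   is independent of execution order.
#' @return A one-row tibble: `n_genes`, `category_mean`, `total_mean`,
#'   `fold_difference` (category mean - total mean), `p_value`.
#' @export
contrast_test <- function(values, category_genes, n_samples = 20000,
                          seed = 1L) {
  v <- as_value_vector(values)
  members <- intersect(unique(category_genes), names(v))
  k <- length(members)
  if (k == 0) stop("category has no genes in the value table", call. = FALSE)
  if (k > length(v)) stop("category larger than universe", call. = FALSE)
  total_mean <- mean(v)
  cat_mean <- mean(v[members])
  if (k == length(v)) {
    return(tibble::tibble(n_genes = k, category_mean = cat_mean,
                          total_mean = total_mean, fold_difference = 0,
                          p_value = 1))
  }
  obs_dev <- abs(cat_mean - total_mean)
  exceed <- contrast_exceed_cpp(unname(v), k, obs_dev,
                                as.integer(n_samples), as.numeric(seed))
  tibble::tibble(n_genes = k, category_mean = cat_mean,
                 total_mean = total_mean,
                 fold_difference = cat_mean - total_mean,
                 p_value = (1 + exceed) / (1 + n_samples))
}

as_value_vector <- function(values) {
  if (is.numeric(values) && !is.null(names(values))) return(values)
  stopifnot(is.data.frame(values), "gene" %in% names(values))
  v <- setNames(values[[value_column(values)]], values$gene)
  v[is.finite(v)]
}

#' Contrast-test enrichment over a GO-style DAG
#'
#' Propagates annotations through the DAG (a gene belongs to a term if it is
#' annotated to the term or any descendant), intersects each term's gene set
#' with the measured genes, keeps terms with at least `min_genes` members, and
#' runs the Monte-Carlo mean-contrast test per term with independent seed
#' substreams, followed by multiple-testing correction.
#'
#' @param values Data frame (`gene` + numeric column) or named numeric vector
#'   of per-gene scores, typically log2 folds.
#' @param dag A `go_dag`.
#' @param min_genes Minimum propagated-and-measured category size (default 21,
#'   i.e. the ">20 genes" filter used for biological processes; use 11 for
#'   the ">10 genes" cell-component filter).
#' @param n_samples Random samplings per term (default 20000).
#' @param seed Integer master seed.
#' @param p_adjust `"BH"` (Benjamini-Hochberg, default) or `"BY"`.
#' @return A tibble, one row per tested term, sorted by decreasing
#'   `fold_difference`: `term`, `n_genes`, `category_mean`, `fold_difference`,
#'   `p_value`, `q_value`.
#' @export
run_enrichment <- function(values, dag, min_genes = 21, n_samples = 20000,
                           seed = 1L, p_adjust = c("BH", "BY")) {
  p_adjust <- match.arg(p_adjust)
  v <- as_value_vector(values)
  ann <- propagate_annotations(dag)
  sets <- lapply(ann, function(g) intersect(g, names(v)))
  sets <- sets[lengths(sets) >= min_genes]
  if (length(sets) == 0) {
    warning("no term passes the minimum size filter")
    return(tibble::tibble(term = character(0), n_genes = integer(0),
                          category_mean = numeric(0),
                          fold_difference = numeric(0),
                          p_value = numeric(0), q_value = numeric(0)))
  }
  res <- purrr::imap_dfr(sets, function(genes, term) {
    r <- contrast_test(v, genes, n_samples = n_samples,
                       seed = stage_seed(seed, paste0("term_", term)))
    dplyr::mutate(r, term = term, .before = 1)
  })
  res |>
    dplyr::mutate(q_value = fdr_correct(.data$p_value, method = p_adjust)) |>
    dplyr::select("term", "n_genes", "category_mean", "fold_difference",
                  "p_value", "q_value") |>
    dplyr::arrange(dplyr::desc(.data$fold_difference))
}

#' False-discovery-rate q-values
#'
#' Benjamini-Hochberg step-up q-values (or the Benjamini-Yekutieli variant
#' for dependent tests), via [stats::p.adjust()].
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @param method `"BH"` (default) or `"BY"`.
#' @return Numeric vector of q-values, same length and order as `p_values`.
#' @export
fdr_correct <- function(p_values, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (length(p_values) == 0) return(numeric(0))
  stopifnot(all(p_values > 0 & p_values <= 1))
  p.adjust(p_values, method = method)
}

#' Bar chart of the strongest contrast-test enrichments
#'
#' @param result Tibble from [run_enrichment()].
#' @param top Number of terms to show (default 20), ranked by signed
#'   `fold_difference`; set `direction = "down"` for the most negative terms.
#' @param direction `"up"` or `"down"`.
#' @return A ggplot of fold differences, starred where q < 0.05.
#' @export
plot_enrichment <- function(result, top = 20, direction = c("up", "down")) {
  direction <- match.arg(direction)
  df <- if (direction == "up") {
    dplyr::slice_max(result, .data$fold_difference, n = top)
  } else {
    dplyr::slice_min(result, .data$fold_difference, n = top)
  }
  df <- dplyr::mutate(df,
                      term = factor(.data$term, levels = rev(.data$term)),
                      sig = ifelse(.data$q_value < 0.05, "*", ""))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fold_difference, y = .data$term)) +
    ggplot2::geom_col(fill = ifelse(direction == "up", "firebrick", "steelblue")) +
    ggplot2::geom_text(ggplot2::aes(label = .data$sig), hjust = -0.3) +
    ggplot2::labs(x = "fold difference (category mean - total mean, log2)",
                  y = NULL)
}
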