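#' Construct a two-group expression matrix
#'
#' Wraps a genes x cells matrix of non-negative counts or intensities with
#' its cell-group labels (e.g. cancer/normal, invasive/non-invasive,
#' polyploid/diploid). The first label in `case_label` is the group whose mean
#' enters fold computation with positive sign.
#'
#' @param mat Numeric matrix, genes in rows (rownames required), cells in
#'   columns (colnames required), no negative entries.
#' @param cell_groups Data frame with columns `cell`, `group` covering every
#'   column of `mat`; exactly two groups, each with at least 2 cells.
#' @param case_label The group treated as "case" (fold = case - control);
#'   defaults to the first group label in `cell_groups`.
#' @param dataset Dataset name recorded on the object.
#' @return An `expression_matrix` object.
#' @export
expression_matrix <- function(mat, cell_groups, case_label = NULL,
                              dataset = NA_character_) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  if (any(mat < 0)) stop("expression values must be non-negative", call. = FALSE)
  cell_groups <- tibble::as_tibble(cell_groups)[c("cell", "group")]
  if (!all(colnames(mat) %in% cell_groups$cell)) {
    stop("every cell must have a group label", call. = FALSE)
  }
  cell_groups <- cell_groups[match(colnames(mat), cell_groups$cell), ]
  groups <- unique(cell_groups$group)
  if (length(groups) != 2) stop("exactly two cell groups required", call. = FALSE)
  if (any(table(cell_groups$group) < 2)) {
    stop("each group needs at least 2 cells", call. = FALSE)
  }
  if (is.null(case_label)) case_label <- groups[1]
  stopifnot(case_label %in% groups)
  structure(list(values = mat, cell_groups = cell_groups,
                 case_label = case_label,
                 control_label = setdiff(groups, case_label),
                 dataset = dataset, normalized = FALSE),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  tab <- table(x$cell_groups$group)
  cat(sprintf("<expression_matrix> %d genes x %d cells (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  cat(sprintf("  fold orientation: %s - %s; normalized: %s\n",
              x$case_label, x$control_label, x$normalized))
  invisible(x)
}

#' Read an expression matrix and cell labels from TSV files
#'
#' @param path Genes x cells TSV; first column gene identifiers, remaining
#'   columns one per cell.
#' @param labels_path TSV with columns `cell`, `group`.
#' @param case_label,dataset Passed to [expression_matrix()].
#' @return An `expression_matrix`.
#' @export
read_expression <- function(path, labels_path, case_label = NULL,
                            dataset = NA_character_) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  mat <- as.matrix(df[-1])
  rownames(mat) <- df[[1]]
  labels <- readr::read_tsv(labels_path, show_col_types = FALSE,
                            progress = FALSE, col_types = "cc")
  expression_matrix(mat, labels, case_label = case_label, dataset = dataset)
}

#' Quantile normalization with log2 transform
#'
#' Forces every cell (column) onto a common distribution: the sorted values of
#' each column are replaced by the across-column mean of sorted values, and
#' tied values within a column receive the mean of their reference quantiles.
#' Count-like data are then log2(x + offset) transformed; set `offset = 0`
#' for already-continuous intensities.
#'
#' @param x An `expression_matrix` (raw, non-negative).
#' @param offset Pseudocount added before the log2 transform (default 1).
#' @param log_transform Apply log2 after normalization (default `TRUE`).
#' @return The normalized `expression_matrix` (`normalized = TRUE`).
#' @export
quantile_normalize <- function(x, offset = 1, log_transform = TRUE) {
  stopifnot(inherits(x, "expression_matrix"))
  mat <- x$values
  if (ncol(mat) < 2) stop("need at least 2 cells", call. = FALSE)
  if (any(mat < 0)) stop("negative values cannot be quantile-normalized",
                         call. = FALSE)
  ref <- rowMeans(apply(mat, 2, sort))
  norm <- apply(mat, 2, function(col) {
    y <- numeric(length(col))
    y[order(col)] <- ref
    # tie groups share the mean of their assigned reference quantiles
    stats::ave(y, col, FUN = mean)
  })
  dimnames(norm) <- dimnames(mat)
  if (log_transform) norm <- log2(norm + offset)
  x$values <- norm
  x$normalized <- TRUE
  x$log_offset <- if (log_transform) offset else NA_real_
  x
}

#' Per-gene log2 group-contrast folds
#'
#' Averages the normalized, log-scale values per gene within each cell group
#' and reports fold = case mean - control mean (positive = up in the case
#' group: cancer, invasive, or polyploid depending on the dataset).
#'
#' @param x A normalized `expression_matrix` (see [quantile_normalize()]).
#' @return A `fold_table` tibble: `gene`, `mean_case`, `mean_control`,
#'   `log2_fold`; attribute `orientation` records the subtraction order.
#' @export
group_fold <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  if (!isTRUE(x$normalized)) {
    warning("expression matrix was not normalized; folds use raw values")
  }
  case_cells <- x$cell_groups$cell[x$cell_groups$group == x$case_label]
  ctrl_cells <- x$cell_groups$cell[x$cell_groups$group == x$control_label]
  if (length(case_cells) == 0 || length(ctrl_cells) == 0) {
    stop("both groups must contain cells", call. = FALSE)
  }
  m_case <- rowMeans(x$values[, case_cells, drop = FALSE])
  m_ctrl <- rowMeans(x$values[, ctrl_cells, drop = FALSE])
  out <- tibble::tibble(gene = rownames(x$values),
                        mean_case = unname(m_case),
                        mean_control = unname(m_ctrl),
                        log2_fold = unname(m_case - m_ctrl))
  attr(out, "orientation") <- sprintf("%s - %s", x$case_label, x$control_label)
  class(out) <- c("fold_table", class(out))
  out
}

#' Read a precomputed log2 fold table
#'
#' For datasets distributed as per-gene folds (e.g. pan-cancer
#' polyploid/diploid contrasts), bypassing normalization.
#'
#' @param path TSV with columns `gene`, `log2_fold`.
#' @param orientation Free-text record of the subtraction order.
#' @return A `fold_table` tibble (`mean_case`/`mean_control` are `NA`).
#' @export
read_fold_table <- function(path, orientation = "case - control") {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = "cd")
  out <- tibble::tibble(gene = df$gene, mean_case = NA_real_,
                        mean_control = NA_real_, log2_fold = df$log2_fold)
  attr(out, "orientation") <- orientation
  class(out) <- c("fold_table", class(out))
  out
}

#' Default phylostratum bins for fold and expression profiles
#'
#' `{1},{2},{3},{4-6},{7-9},{10-17}`: single-stratum resolution across the
#' ancient unicellular strata, then bins mirroring the early-metazoan
#' plateau and the recent decline.
#'
#' @return A named list of integer vectors partitioning 1..17.
#' @export
default_stratum_bins <- function() {
  list("1" = 1L, "2" = 2L, "3" = 3L, "4-6" = 4:6, "7-9" = 7:9, "10-17" = 10:17)
}

#' Per-stratum (or stratum-bin) profile of a gene-level value
#'
#' Averages a per-gene value (expression level or log2 fold) within bins of
#' consecutive phylostrata. The default bins `{1},{2},{3},{4-6},{7-9},{10-17}`
#' separate the ancient unicellular peak, the early-metazoan plateau and the
#' recent decline; any partition of 1..17 may be supplied. When an exclusion
#' set is given (typically the ZF-C2H2 zinc-finger repressors), profiles with
#' and without the flagged genes are returned side by side.
#'
#' @param values Data frame with columns `gene` and a numeric value column
#'   (`log2_fold` or `value`; the first non-gene numeric column is used).
#' @param strata Stratum map tibble (`gene_id`, `stratum`).
#' @param bins Named list of integer vectors partitioning 1..17; default
#'   [default_stratum_bins()]. Use `as.list(1:17)` for single-stratum bins.
#' @param exclude Optional gene set (list with `name`, `members`) to drop in a
#'   parallel profile series.
#' @return A tibble with columns `series` (`"all"` and, when `exclude` is
#'   given, `"excluded_removed"`), `bin`, `strata_lo`, `strata_hi`, `mean`,
#'   `sem`, `n`. Empty bins are kept with `n = 0` and `mean = NA`.
#' @export
stratum_profile <- function(values, strata, bins = default_stratum_bins(),
                            exclude = NULL) {
  covered <- sort(unlist(bins, use.names = FALSE))
  if (!identical(as.integer(covered), 1:17)) {
    stop("bins must partition strata 1..17", call. = FALSE)
  }
  if (is.null(names(bins))) {
    names(bins) <- vapply(bins, function(b) {
      if (length(b) == 1) as.character(b) else sprintf("%d-%d", min(b), max(b))
    }, character(1))
  }
  strata <- validate_stratum_map(strata[c("gene_id", "stratum")])
  val_col <- value_column(values)
  df <- dplyr::inner_join(
    tibble::tibble(gene = values$gene, value = values[[val_col]]),
    strata, by = c(gene = "gene_id"))
  bin_tbl <- tibble::tibble(
    bin = rep(names(bins), lengths(bins)),
    stratum = unlist(bins, use.names = FALSE))
  one_series <- function(d, series) {
    d |>
      dplyr::left_join(bin_tbl, by = "stratum") |>
      dplyr::group_by(.data$bin) |>
      dplyr::summarise(
        mean = mean(.data$value), n = dplyr::n(),
        sem = if (dplyr::n() > 1) stats::sd(.data$value) / sqrt(dplyr::n()) else 0,
        .groups = "drop") |>
      dplyr::right_join(
        tibble::tibble(bin = names(bins),
                       strata_lo = vapply(bins, function(b) as.integer(min(b)),
                                          integer(1)),
                       strata_hi = vapply(bins, function(b) as.integer(max(b)),
                                          integer(1))),
        by = "bin") |>
      dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                    series = series) |>
      dplyr::select("series", "bin", "strata_lo", "strata_hi",
                    "mean", "sem", "n") |>
      dplyr::arrange(.data$strata_lo)
  }
  out <- one_series(df, "all")
  if (!is.null(exclude)) {
    kept <- dplyr::filter(df, !(.data$gene %in% exclude$members))
    out <- dplyr::bind_rows(out, one_series(kept, "excluded_removed"))
    attr(out, "excluded_set") <- exclude$name
  }
  out
}

#' Plot a stratum-binned fold or expression profile
#'
#' @param profile Tibble from [stratum_profile()].
#' @return A ggplot with one line per series (all genes vs exclusion applied).
#' @export
plot_stratum_profile <- function(profile) {
  df <- dplyr::mutate(profile,
                      mid = (.data$strata_lo + .data$strata_hi) / 2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$mean,
                                   colour = .data$series)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(all = "black",
                                            excluded_removed = "red")) +
    ggplot2::labs(x = "phylostratum bin (midpoint)", y = "mean ± sem")
}

#' Stratum composition of a gene set
#'
#' Proportion of the set's genes falling in each phylostratum, and the
#' Spearman rank correlation of that proportion with the stratum index
#' (negative = concentration in ancient strata).
#'
#' @param gene_set Character vector of gene identifiers (or list with
#'   `members`).
#' @param strata Stratum map tibble.
#' @param by_stratum_size If `TRUE`, proportions are instead the set's
#'   coverage of each stratum (set genes in stratum / stratum size).
#' @return A `stratum_composition` object: `$profile` tibble (`stratum`,
#'   `n_set`, `proportion`) and Spearman `$estimate`, `$p_value`. [tidy()] and
#'   [glance()] methods are provided.
#' @export
stratum_composition <- function(gene_set, strata, by_stratum_size = FALSE) {
  if (is.list(gene_set)) gene_set <- gene_set$members
  stopifnot(length(gene_set) > 0)
  strata <- validate_stratum_map(strata[c("gene_id", "stratum")])
  set_strata <- strata$stratum[strata$gene_id %in% gene_set]
  if (length(unique(set_strata)) < 3) {
    warning("fewer than 3 strata represented; correlation is fragile")
  }
  n_set <- as.integer(table(factor(set_strata, levels = 1:17)))
  denom <- if (by_stratum_size) {
    as.integer(table(factor(strata$stratum, levels = 1:17)))
  } else {
    rep(length(set_strata), 17)
  }
  prof <- tibble::tibble(stratum = 1:17, n_set = n_set,
                         proportion = ifelse(denom > 0, n_set / denom, NA_real_))
  ok <- !is.na(prof$proportion)
  ct <- suppressWarnings(
    cor.test(prof$stratum[ok], prof$proportion[ok], method = "spearman"))
  structure(list(profile = prof, estimate = unname(ct$estimate),
                 p_value = ct$p.value, n_genes = length(set_strata),
                 by_stratum_size = by_stratum_size),
            class = "stratum_composition")
}

#' @export
print.stratum_composition <- function(x, ...) {
  cat(sprintf("<stratum_composition> %d mapped genes; Spearman r = %.3f (p = %.3g)\n",
              x$n_genes, x$estimate, x$p_value))
  invisible(x)
}

#' @export
tidy.stratum_composition <- function(x, ...) x$profile

#' @export
glance.stratum_composition <- function(x, ...) {
  tibble::tibble(spearman_r = x$estimate, p_value = x$p_value,
                 n_genes = x$n_genes, by_stratum_size = x$by_stratum_size)
}

# pick the score column of a per-gene value table: prefer the canonical
# names, otherwise the first numeric non-gene column
value_column <- function(values) {
  cand <- intersect(c("log2_fold", "value"), names(values))
  if (length(cand) > 0) return(cand[1])
  other <- setdiff(names(values), "gene")
  other[vapply(values[other], is.numeric, logical(1))][1]
}
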