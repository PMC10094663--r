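#' Analysis of means (ANOM) across phylostrata
#'
#' Tests which stratum means of a per-gene value (expression level or fold)
#' deviate from the grand mean. Decision limits are
#' `grand_mean +/- h * s_p * sqrt(1/n_i - 1/N)` where `s_p` is the pooled
#' within-stratum standard deviation, `N` the total gene count and `h` a
#' critical multiplier at family level `alpha`. By default `h` is the
#' Bonferroni-adjusted t quantile `qt(1 - alpha / (2k), N - k)` over the `k`
#' strata; `method = "mc"` instead calibrates `h` by simulating the null
#' maximum standardized deviation, which respects the correlation between
#' stratum deviations.
#'
#' @param values Data frame with columns `gene` and a numeric value column.
#' @param strata Stratum map tibble (`gene_id`, `stratum`).
#' @param alpha Family-wise significance level (default 0.05).
#' @param method `"bonferroni"` (default) or `"mc"`.
#' @param n_sim Null simulations for `method = "mc"` (default 2000).
#' @param seed Seed for the Monte-Carlo calibration.
#' @return An `anom_result`: tibble with columns `stratum`, `n`, `mean`,
#'   `lower`, `upper`, `flagged`; attributes `grand_mean`, `pooled_sd`, `h`,
#'   `alpha`, `method`. Strata with fewer than 2 genes are excluded with a
#'   warning.
#' @export
anom <- function(values, strata, alpha = 0.05,
                 method = c("bonferroni", "mc"), n_sim = 2000, seed = 1L) {
  method <- match.arg(method)
  strata <- validate_stratum_map(strata[c("gene_id", "stratum")])
  val_col <- value_column(values)
  df <- dplyr::inner_join(
    tibble::tibble(gene = values$gene, value = values[[val_col]]),
    strata, by = c(gene = "gene_id"))
  sizes <- dplyr::count(df, .data$stratum)
  small <- sizes$stratum[sizes$n < 2]
  if (length(small) > 0) {
    warning(sprintf("excluding strata with n < 2: %s",
                    paste(small, collapse = ", ")))
    df <- dplyr::filter(df, !(.data$stratum %in% small))
  }
  grp <- df |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     ss = sum((.data$value - mean(.data$value))^2),
                     .groups = "drop")
  k <- nrow(grp)
  if (k < 2) stop("need at least 2 strata with n >= 2", call. = FALSE)
  N <- sum(grp$n)
  grand <- sum(grp$n * grp$mean) / N
  s_p <- sqrt(sum(grp$ss) / (N - k))
  se_i <- s_p * sqrt(1 / grp$n - 1 / N)
  h <- if (method == "bonferroni") {
    qt(1 - alpha / (2 * k), df = N - k)
  } else {
    anom_mc_h(grp$n, alpha, n_sim, seed)
  }
  out <- grp |>
    dplyr::transmute(.data$stratum, .data$n, .data$mean,
                     lower = grand - h * se_i, upper = grand + h * se_i,
                     flagged = .data$mean < grand - h * se_i |
                       .data$mean > grand + h * se_i)
  structure(out, class = c("anom_result", class(out)),
            grand_mean = grand, pooled_sd = s_p, h = h, alpha = alpha,
            method = method)
}

# (1 - alpha) quantile of the null max standardized stratum deviation,
# simulated from standard-normal groups of the observed sizes
anom_mc_h <- function(sizes, alpha, n_sim, seed) {
  N <- sum(sizes)
  k <- length(sizes)
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    expr
  }
  withr_seed({
    maxes <- vapply(seq_len(n_sim), function(i) {
      x <- rnorm(N)
      f <- rep(seq_len(k), sizes)
      m <- tapply(x, f, mean)
      ss <- tapply(x, f, function(v) sum((v - mean(v))^2))
      sp <- sqrt(sum(ss) / (N - k))
      max(abs(m - mean(x)) / (sp * sqrt(1 / sizes - 1 / N)))
    }, numeric(1))
    unname(quantile(maxes, 1 - alpha, type = 7))
  })
}

#' @export
glance.anom_result <- function(x, ...) {
  tibble::tibble(grand_mean = attr(x, "grand_mean"),
                 pooled_sd = attr(x, "pooled_sd"),
                 h = attr(x, "h"), alpha = attr(x, "alpha"),
                 method = attr(x, "method"),
                 n_flagged = sum(x$flagged))
}

#' ANOM decision chart
#'
#' @param object An `anom_result`.
#' @param ... Unused.
#' @return A ggplot: stratum means with decision limits; flagged strata in red.
#' @export
autoplot.anom_result <- function(object, ...) {
  grand <- attr(object, "grand_mean")
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stratum)) +
    ggplot2::geom_hline(yintercept = grand, linetype = 1) +
    ggplot2::geom_step(ggplot2::aes(y = .data$lower), colour = "red",
                       linetype = 3, direction = "mid") +
    ggplot2::geom_step(ggplot2::aes(y = .data$upper), colour = "red",
                       linetype = 3, direction = "mid") +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean,
                                     colour = .data$flagged), size = 2) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$stratum, y = grand,
                                       yend = .data$mean)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::scale_x_continuous(breaks = c(1, 4, 8, 12, 17)) +
    ggplot2::labs(x = "phylostratum", y = "stratum mean")
}
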