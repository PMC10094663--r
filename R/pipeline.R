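#' Default pipeline configuration
#'
#' Returns the demo configuration used by [run_attractor_pipeline()]:
#' a synthetic age-layered network, a stratified expression matrix with a
#' planted atavism gradient, a walk-length sweep, stratified fold profiles
#' with ANOM limits, and DAG enrichment with one planted term. Any subset of
#' fields may be overridden via a YAML file or a nested list.
#'
#' @return A nested list of configuration values.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1,
    version = as.character(utils::packageVersion("ucattractor")),
    network = list(n_per_stratum = 12, model = "preferential", m = 3),
    expression = list(n_cells = 20, sigma = 0.5,
                      delta_intercept = 0.5, delta_slope = -0.03),
    walk = list(lengths = c(5, 30, 200), n_repeats = 4000,
                start_stratum = 17),
    profile = list(exclude_fraction = 0.05),
    anom = list(alpha = 0.05),
    enrichment = list(n_terms = 15, planted_size = 30, planted_shift = 1,
                      min_genes = 11, n_samples = 1000)
  )
}

read_pipeline_config <- function(config) {
  base <- default_pipeline_config()
  user <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(user)) return(base)
  merge_cfg <- function(a, b) {
    for (k in names(b)) {
      a[[k]] <- if (is.list(a[[k]]) && is.list(b[[k]])) {
        merge_cfg(a[[k]], b[[k]])
      } else b[[k]]
    }
    a
  }
  merge_cfg(base, user)
}

# fixed 9-decimal formatting of reals so reruns are byte-identical
write_tsv_canonical <- function(df, path) {
  out <- dplyr::mutate(df, dplyr::across(
    dplyr::where(function(x) is.double(x) && !is.integer(x)),
    function(x) ifelse(is.na(x), "NA", sprintf("%.9f", x))))
  readr::write_tsv(out, path, progress = FALSE)
  nrow(df)
}

#' Run the full unicellular-attractor analysis
#'
#' Executes, in dependency order: synthetic network + stratum map generation,
#' per-node centralities and their stratum summary, the random-walk endpoint
#' sweep, expression generation + quantile normalization + folds, the binned
#' stratum fold profile (with a random exclusion set standing in for a
#' flagged gene family), ANOM decision limits, and DAG contrast-test
#' enrichment with a planted term. Every stage draws its seed from the master
#' seed by stable hashing, so identical config implies byte-identical
#' outputs. All tables are written as TSV with 9-decimal reals, plus a JSON
#' run manifest with per-file md5 digests and row counts.
#'
#' @param config A YAML file path, a nested list overriding
#'   [default_pipeline_config()], or `NULL` for the demo defaults.
#' @param out_dir Output directory (created if needed).
#' @return The run manifest (invisibly a list; also written to
#'   `manifest.json`).
#' @export
run_attractor_pipeline <- function(config = NULL, out_dir = tempfile("ucrun")) {
  cfg <- read_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  master <- cfg$seed
  files <- list()
  put <- function(name, df) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    n <- write_tsv_canonical(tibble::as_tibble(df), path)
    files[[name]] <<- list(path = path, rows = n)
    df
  }

  net_gen <- gen_network(n_per_stratum = cfg$network$n_per_stratum,
                         model = cfg$network$model, m = cfg$network$m,
                         seed = stage_seed(master, "network"))
  net <- net_gen$network
  strata <- net_gen$strata
  put("edges", tidy(net))
  put("strata", strata[c("gene_id", "stratum")])

  cent <- node_centrality(net)
  put("centrality", cent)
  put("centrality_by_stratum", stratum_summary(cent, strata))

  sweep <- walk_length_sweep(net, strata, lengths = cfg$walk$lengths,
                             n_repeats = cfg$walk$n_repeats,
                             start_stratum = cfg$walk$start_stratum,
                             seed = stage_seed(master, "walk"))
  put("walk_endpoints", sweep)

  s_idx <- 0:16
  delta <- cfg$expression$delta_intercept + cfg$expression$delta_slope * s_idx
  expr <- gen_expression(strata, n_cells = cfg$expression$n_cells,
                         delta = delta, sigma = cfg$expression$sigma,
                         seed = stage_seed(master, "expression"))
  folds <- group_fold(quantile_normalize(expr))
  put("folds", folds)

  old <- local_seed(stage_seed(master, "exclude_set"))
  excl <- list(name = "synthetic_flagged",
               members = sample(strata$gene_id,
                                ceiling(nrow(strata) *
                                          cfg$profile$exclude_fraction)))
  restore_seed(old)
  put("stratum_profile", stratum_profile(folds, strata, exclude = excl))
  put("anom", tibble::as_tibble(anom(folds, strata, alpha = cfg$anom$alpha)))

  go <- gen_go(strata$gene_id, n_terms = cfg$enrichment$n_terms,
               planted_sizes = cfg$enrichment$planted_size,
               seed = stage_seed(master, "go"))
  vals <- gen_go_values(go$dag, strata$gene_id, planted = go$planted,
                        shift = cfg$enrichment$planted_shift,
                        seed = stage_seed(master, "go_values"))
  enr <- run_enrichment(vals, go$dag, min_genes = cfg$enrichment$min_genes,
                        n_samples = cfg$enrichment$n_samples,
                        seed = stage_seed(master, "enrichment"))
  put("enrichment", enr)

  manifest <- list(
    config = cfg,
    stage_seeds = lapply(
      setNames(nm = c("network", "walk", "expression", "exclude_set", "go",
                      "go_values", "enrichment")),
      function(s) stage_seed(master, s)),
    files = lapply(files, function(f) {
      list(path = basename(f$path), rows = f$rows,
           md5 = unname(tools::md5sum(f$path)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
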