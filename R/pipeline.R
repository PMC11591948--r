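# End-to-end pipeline: build/load matrix -> align -> select -> enrich ->
# rank -> write, with a run manifest for reproducibility.

#' Pipeline configuration
#'
#' Collects every knob of the enrichment pipeline. Either
#' \code{sites_path} + \code{events_path} (matrix built in-run) or
#' \code{matrix_path} (prebuilt \code{.mtx} + sidecars) must be given.
#'
#' @param stats_path Event-statistics TSV.
#' @param out_dir Output directory (created; partial outputs are removed
#'   on error).
#' @param sites_path,events_path Interval inputs for
#'   \code{\link{build_exs}}.
#' @param matrix_path Prebuilt matrix (skips the interval inputs).
#' @param window_nt,strand_mode Matrix construction (see
#'   \code{\link{exs_build_config}}).
#' @param select,select_value Selection rule kind and value (see
#'   \code{\link{selection_rule}}).
#' @param methods Subset of \code{c("fisher", "poibin", "gsea",
#'   "wilcoxon")}.
#' @param gsea_n_perm,gsea_max_perm,wilcoxon_alternative Method knobs.
#' @param seed Integer seed (GSEA permutations).
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(stats_path, out_dir,
                            sites_path = NULL, events_path = NULL,
                            matrix_path = NULL,
                            window_nt = 400L,
                            strand_mode = c("ignore", "match"),
                            select = c("pvalue_threshold", "top_n", "fdr_threshold"),
                            select_value = NULL,
                            methods = c("fisher", "poibin", "gsea", "wilcoxon"),
                            gsea_n_perm = 1e4, gsea_max_perm = 1e6,
                            wilcoxon_alternative = "less",
                            seed = 1L) {
  strand_mode <- match.arg(strand_mode)
  select <- match.arg(select)
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(matrix_path) && (is.null(sites_path) || is.null(events_path))) {
    stop_sfe("supply either matrix_path or both sites_path and events_path")
  }
  for (p in c(stats_path, sites_path, events_path, matrix_path)) {
    if (!is.null(p) && !file.exists(p)) stop_sfe(sprintf("input not found: %s", p))
  }
  structure(list(stats_path = stats_path, out_dir = out_dir,
                 sites_path = sites_path, events_path = events_path,
                 matrix_path = matrix_path, window_nt = window_nt,
                 strand_mode = strand_mode, select = select,
                 select_value = select_value, methods = methods,
                 gsea_n_perm = gsea_n_perm, gsea_max_perm = gsea_max_perm,
                 wilcoxon_alternative = wilcoxon_alternative, seed = seed),
            class = "pipeline_config")
}

#' Run the enrichment pipeline
#'
#' Executes build/load matrix, universe alignment, event selection, every
#' requested enrichment method, and ranking; writes one ranked TSV per
#' method, an event-classification TSV and a \code{manifest.yaml}
#' recording the config, its hash, the seed and the package version.
#' Identical config + seed gives identical outputs.
#'
#' @param cfg A \code{\link{pipeline_config}}.
#' @return Named list of ranked tables (one per method), invisibly;
#'   outputs land in \code{cfg$out_dir}.
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "pipeline_config")) stop_sfe("cfg must come from pipeline_config()")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop_sfe(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  mat <- stage("matrix", {
    if (!is.null(cfg$matrix_path)) {
      read_matrix(cfg$matrix_path)
    } else {
      build_exs(read_binding_sites(cfg$sites_path),
                read_events(cfg$events_path),
                exs_build_config(window_nt = cfg$window_nt,
                                 strand_mode = cfg$strand_mode))
    }
  })
  stats <- stage("stats", read_event_stats(cfg$stats_path))
  ali <- stage("align", align_universe(mat, stats))
  selection <- stage("select",
                     select_events(ali$stats,
                                   selection_rule(cfg$select, cfg$select_value)))

  # the hash identifies the analysis parameters; the output location is not
  # part of the analysis
  hash <- config_hash(unclass(cfg)[setdiff(names(unclass(cfg)), "out_dir")])
  header <- c(sprintf("spliceRBP %s", as.character(packageVersion("spliceRBP"))),
              sprintf("config_hash: %s", hash),
              sprintf("seed: %d", as.integer(cfg$seed)))

  model <- NULL
  ranked <- list()
  for (method in cfg$methods) {
    res <- stage(method, switch(method,
      fisher = fisher_enrichment(ali$matrix, selection),
      poibin = {
        model <- fit_probability_model(ali$matrix)
        poibin_enrichment(ali$matrix, selection, model)
      },
      gsea = gsea_enrichment(ali$matrix, ali$stats, n_perm = cfg$gsea_n_perm,
                             max_perm = cfg$gsea_max_perm, seed = cfg$seed),
      wilcoxon = wilcoxon_enrichment(ali$matrix, rank_events(ali$stats),
                                     alternative = cfg$wilcoxon_alternative)
    ))
    tab <- stage(method, rank_rbps(res))
    path <- file.path(cfg$out_dir, sprintf("ranked_%s.tsv", method))
    write_results(tab, path, comments = header)
    written <- c(written, path)
    ranked[[method]] <- tab
  }

  cls_path <- file.path(cfg$out_dir, "event_classification.tsv")
  stage("classify", write_results(classify_events(ali$stats), cls_path,
                                  comments = header))
  written <- c(written, cls_path)

  manifest <- list(
    package = "spliceRBP",
    version = as.character(packageVersion("spliceRBP")),
    config = lapply(unclass(cfg), function(x) if (is.null(x)) NA else x),
    config_hash = hash,
    seed = as.integer(cfg$seed),
    universe = selection$M, selected = selection$K,
    outputs = basename(written)
  )
  yaml::write_yaml(manifest, file.path(cfg$out_dir, "manifest.yaml"))
  invisible(ranked)
}
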