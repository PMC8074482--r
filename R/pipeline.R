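#' Default run configuration
#'
#' Collects every tunable threshold of the pipeline in one place; all stages
#' read their parameters from this object only.
#'
#' @param seed Integer seed used for simulation and any permutation draws.
#' @param out_dir Output directory for stage artifacts.
#' @param n_genes Fixture size when simulation is enabled.
#' @param stages Character vector of stages to run, in dependency order.
#' @return A `chronoseq_config` list.
#' @export
run_config <- function(seed = 1, out_dir = "chronoseq_run",
                       n_genes = 2000,
                       stages = c("simulate", "preprocess", "spline_de",
                                  "pairwise_de", "clustering", "cyclicity",
                                  "granger")) {
  cfg <- list(
    seed = as.integer(seed), out_dir = out_dir, n_genes = n_genes,
    stages = stages,
    counts_path = NULL, samples_path = NULL,
    filter_min_count = 5, filter_min_samples = 2,
    spline_df = 3, spline_horizons = c(8, 48), de_fdr = 0.05,
    pairwise_horizon = 48,
    cluster_k = 4, acf_lags = 10, acf_edge_percentile = 1,
    jtk_periods = c(18, 24, 30), jtk_q = 0.05, jtk_amp = 0.5,
    gc_width = 6, gc_fdr = 0.05, gc_min_consecutive = 3, gc_horizon = 24,
    gc_mode = "bivariate", gc_variant = "nodewise",
    gc_max_genes = 60
  )
  bad <- vapply(cfg[c("filter_min_count", "de_fdr", "gc_fdr")],
                function(v) !is.numeric(v) || v < 0, TRUE)
  if (any(bad)) stop("invalid configuration values")
  structure(cfg, class = "chronoseq_config")
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order on either a simulated
#' fixture or user-supplied counts, writes plain-text artifacts (TSV/JSON)
#' under `config$out_dir`, and returns a machine-readable run report with
#' per-stage gene-set sizes and an artifact manifest with checksums. A rerun
#' with the same configuration and seed reproduces the checksums.
#'
#' @param config A [run_config()].
#' @return The run report (list), also written as `report.json`.
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "chronoseq_config")) stop("expected a `chronoseq_config`")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed, stages = config$stages,
                 package_version = as.character(utils::packageVersion("chronoseq")),
                 sets = list(), artifacts = character())
  art <- function(path) report$artifacts <<- c(report$artifacts, path)
  sim <- NULL; samples <- NULL; counts <- NULL; annotation <- NULL
  grid <- NULL

  if ("simulate" %in% config$stages) {
    sim <- simulate_experiment(fixture_config(n_genes = config$n_genes),
                               seed = config$seed)
    paths <- write_fixture(sim, file.path(config$out_dir, "fixture"))
    for (p in paths) art(p)
    counts <- sim$counts; samples <- sim$samples
    annotation <- sim$annotation; grid <- sim$grid
  } else {
    v <- validate_inputs(config$counts_path, config$samples_path)
    counts <- v$counts; samples <- v$samples
    grid <- grid_from_samples(samples)
    annotation <- data.frame(gene_id = rownames(counts))
  }

  pre <- NULL
  if ("preprocess" %in% config$stages) {
    pre <- preprocess_counts(counts, config$filter_min_count,
                             config$filter_min_samples)
    path <- file.path(config$out_dir, "normalized.tsv")
    write_counts_tsv(round(pre$norm, 6), path); art(path)
    report$sets$n_genes_filtered <- nrow(pre$counts)
    report$sets$n_zero_removed <- pre$n_zero_removed
    report$sets$n_low_removed <- pre$n_low_removed
  }

  spline_sets <- NULL
  if ("spline_de" %in% config$stages) {
    design <- spline_design(samples$time_h, config$spline_df)
    vw <- voom_weights(pre$counts, design, pre$tmm, pre$library_sizes)
    tabs <- lapply(config$spline_horizons, function(h) {
      spline_fit_test(vw$logcpm, samples, horizon_h = h,
                      df = config$spline_df, weights = vw$weights)
    })
    names(tabs) <- paste0("h", config$spline_horizons)
    for (nm in names(tabs)) {
      path <- file.path(config$out_dir, paste0("spline_de_", nm, ".tsv"))
      utils::write.table(tabs[[nm]], path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      art(path)
    }
    spline_sets <- select_time_dependent(tabs[[1]], tabs[[2]], config$de_fdr)
    report$sets$spline_short_only <- length(spline_sets$short_only)
    report$sets$spline_long_only <- length(spline_sets$long_only)
    report$sets$spline_both <- length(spline_sets$both)
    report$sets$spline_union <- length(spline_sets$union)
  }

  tier_sets <- NULL; pw <- NULL; union_sets <- NULL
  if ("pairwise_de" %in% config$stages) {
    pw <- pairwise_de(pre$norm, samples, config$pairwise_horizon)
    path <- file.path(config$out_dir, "pairwise_de.tsv")
    utils::write.table(pw, path, sep = "\t", quote = FALSE, row.names = FALSE)
    art(path)
    tier_sets <- select_tiered(pw)
    report$sets$tier_A <- length(tier_sets$A)
    report$sets$tier_B <- length(tier_sets$B)
    report$sets$tier_CORE <- length(tier_sets$CORE)
    if (!is.null(spline_sets)) {
      union_sets <- build_union_sets(spline_sets, tier_sets, pw, annotation)
      report$sets$predominant <- length(union_sets$predominant)
      report$sets$master <- length(union_sets$master)
    }
  }

  if ("clustering" %in% config$stages && !is.null(union_sets) &&
      length(union_sets$predominant) >= config$cluster_k + 1) {
    sub <- pre$norm[union_sets$predominant, , drop = FALSE]
    hc <- hierarchical_cluster(z_profiles(sub, samples), "pearson",
                               config$cluster_k)
    path <- file.path(config$out_dir, "clusters.tsv")
    utils::write.table(
      data.frame(gene_id = names(hc$cluster), cluster = hc$cluster),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
    art(path)
    report$sets$cluster_sizes <- as.integer(table(hc$cluster))
  }

  cyclic <- character()
  if ("cyclicity" %in% config$stages) {
    scan_genes <- if (!is.null(union_sets)) {
      union(union_sets$predominant,
            rownames(pre$norm)[seq_len(min(200, nrow(pre$norm)))])
    } else rownames(pre$norm)
    calls <- jtk_scan(pre$norm[intersect(scan_genes, rownames(pre$norm)), ,
                               drop = FALSE],
                      samples, config$jtk_periods)
    path <- file.path(config$out_dir, "cycle_calls.tsv")
    utils::write.table(calls, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    art(path)
    cyclic <- select_cyclic(calls, config$jtk_q, config$jtk_amp)
    report$sets$cyclic <- length(cyclic)
  }

  if ("granger" %in% config$stages && !is.null(union_sets)) {
    gc_genes <- union_sets$master
    if (length(gc_genes) > config$gc_max_genes) {
      gc_genes <- gc_genes[seq_len(config$gc_max_genes)]
    }
    if (length(gc_genes) >= 3) {
      scan <- granger_scan(pre$norm[gc_genes, , drop = FALSE], samples, grid,
                           mode = config$gc_mode, variant = config$gc_variant,
                           width = config$gc_width)
      edges <- aggregate_edges(scan, config$gc_fdr)
      net <- filter_network(edges, cyclic, attr(scan, "windows"),
                            config$gc_min_consecutive, config$gc_horizon)
      path <- file.path(config$out_dir, "gc_edges.tsv")
      utils::write.table(
        edges[, c("source", "target", "n_sig", "run_len", "overall_sign")],
        path, sep = "\t", quote = FALSE, row.names = FALSE)
      art(path)
      path <- file.path(config$out_dir, "gc_network.tsv")
      utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      art(path)
      report$sets$gc_nodes <- length(net$nodes)
      report$sets$gc_edges <- nrow(net$edges)
      report$sets$gc_components <- net$n_components
    }
  }

  report$checksums <- as.list(tools::md5sum(report$artifacts))
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  report
}
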