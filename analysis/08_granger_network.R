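#!/usr/bin/env Rscript
## Sliding-window lead-lag inference on the master gene set: bivariate
## Granger tests in every 6-point window, per-window BH, sign-consistent
## consecutive-run aggregation, and the high-confidence negative-edge filter
## (>= 3 consecutive windows inside the first 24 h, cyclic genes removed).
## The multivariate de-biased-LASSO engine is exercised on the first-day
## windows for comparison.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE)[1])), "00_common.R"))

ex <- load_experiment()
design <- spline_design(ex$sim$samples$time_h, 3)
vw <- voom_weights(ex$pre$counts, design, ex$pre$tmm, ex$pre$library_sizes)
sets <- select_time_dependent(
  spline_fit_test(vw$logcpm, ex$sim$samples, 8, weights = vw$weights),
  spline_fit_test(vw$logcpm, ex$sim$samples, 48, weights = vw$weights))
pw <- pairwise_de(ex$pre$norm, ex$sim$samples)
us <- build_union_sets(sets, select_tiered(pw), pw, ex$sim$annotation)
gc_genes <- intersect(us$master, rownames(ex$pre$norm))
message("master set for network inference: ", length(gc_genes), " genes")

cyc <- select_cyclic(jtk_scan(ex$pre$norm, ex$sim$samples))
scan <- granger_scan(ex$pre$norm[gc_genes, ], ex$sim$samples, ex$sim$grid,
                     "bivariate")
edges <- aggregate_edges(scan, 0.05)
net <- filter_network(edges, cyc, attr(scan, "windows"))
message("filtered negative network: ", length(net$nodes), " nodes, ",
        nrow(net$edges), " edges, ", net$n_components, " components")
write_tsv(edges[, c("source", "target", "n_sig", "run_len", "overall_sign")],
          "gc_candidate_edges.tsv")
write_tsv(net$edges, "gc_network_edges.tsv")

mv <- granger_scan(ex$pre$norm[head(gc_genes, 40), ], ex$sim$samples,
                   ex$sim$grid, "multivariate", variant = "nodewise",
                   windows = 1:4)
mv$q <- ave(mv$p, mv$window, FUN = function(p) p.adjust(p, "BH"))
message("multivariate (40 genes, windows 1-4): ", sum(mv$q < 0.05),
        " significant coefficients of ", nrow(mv))
write_tsv(mv[mv$q < 0.05, c("source", "target", "window", "beta", "p")],
          "gc_multivariate_hits.tsv")
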