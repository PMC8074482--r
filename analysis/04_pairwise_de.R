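#!/usr/bin/env Rscript
## Per-timepoint moderated-t contrasts against the 0 h baseline over the
## first 48 h, BH within each time point, the tiered gene sets
## (|log2FC| >= 1, >= 2, and the strict two-timepoint core), and the
## predominant/master unions that downstream clustering and network
## inference consume.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE)[1])), "00_common.R"))

ex <- load_experiment()
pw <- pairwise_de(ex$pre$norm, ex$sim$samples)
write_tsv(pw, "pairwise_de.tsv")
tiers <- select_tiered(pw)
message("tiers: |lfc|>=1 ", length(tiers$A), "; |lfc|>=2 ", length(tiers$B),
        "; core ", length(tiers$CORE))
design <- spline_design(ex$sim$samples$time_h, 3)
vw <- voom_weights(ex$pre$counts, design, ex$pre$tmm, ex$pre$library_sizes)
sets <- select_time_dependent(
  spline_fit_test(vw$logcpm, ex$sim$samples, 8, weights = vw$weights),
  spline_fit_test(vw$logcpm, ex$sim$samples, 48, weights = vw$weights))
us <- build_union_sets(sets, tiers, pw, ex$sim$annotation)
message("predominant set ", length(us$predominant),
        "; master set (annotated, |lfc|>=2) ", length(us$master))
write_tsv(data.frame(gene_id = us$predominant,
                     master = us$predominant %in% us$master),
          "gene_sets.tsv")
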