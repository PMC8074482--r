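#!/usr/bin/env Rscript
## Filter, TMM-normalize and log2-transform the simulated counts, and run
## top-variance PCA. On this fixture nothing is removed by the expression
## filter (every gene is planted well above zero); the PCA's first component
## tracks the global stimulation response.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE)[1])), "00_common.R"))

ex <- load_experiment()
pre <- ex$pre
message("genes kept: ", nrow(pre$counts), " (zero-removed ", pre$n_zero_removed,
        ", low-removed ", pre$n_low_removed, ")")
message("TMM factor range: ", paste(signif(range(pre$tmm), 3), collapse = " - "))
write_tsv(data.frame(sample_id = names(pre$tmm), tmm = as.numeric(pre$tmm),
                     library_size = pre$library_sizes), "tmm_factors.tsv")
pc <- pca_top_variance(pre$norm, 500)
message("PC1-3 variance: ",
        paste(signif(100 * pc$var_frac[1:3], 3), collapse = "% / "), "%")
write_tsv(data.frame(sample_id = rownames(pc$coords),
                     round(pc$coords[, 1:4], 4)), "pca_coordinates.tsv")
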