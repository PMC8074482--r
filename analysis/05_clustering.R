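#!/usr/bin/env Rscript
## Profile clustering two ways: average-linkage hierarchical clustering of
## z-scored trajectories (Pearson distance, k = 4) on the planted signal
## classes, and the autocorrelation-distance network with top-1% edges whose
## connected components separate sustained from transient responders.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE)[1])), "00_common.R"))

ex <- load_experiment()
cls <- ex$sim$truth$class_table
sig <- intersect(cls$gene_id[cls$class %in% c("IMMEDIATE_SUSTAINED", "TRANSIENT",
                                              "DIP_THEN_PEAK", "METABOLIC_DIP")],
                 rownames(ex$pre$norm))
hc <- hierarchical_cluster(z_profiles(ex$pre$norm[sig, ], ex$sim$samples),
                           "pearson", 4)
tab <- table(hc$cluster, cls$class[match(names(hc$cluster), cls$gene_id)])
message("hierarchical clusters vs planted classes:")
print(tab)
write_tsv(data.frame(gene_id = names(hc$cluster), cluster = hc$cluster,
                     class = cls$class[match(names(hc$cluster), cls$gene_id)]),
          "clusters_hierarchical.tsv")
is_tr <- intersect(cls$gene_id[cls$class %in% c("IMMEDIATE_SUSTAINED", "TRANSIENT")],
                   rownames(ex$pre$norm))
net <- acf_cluster_network(ex$pre$norm[is_tr, ], ex$sim$samples)
memb <- data.frame(gene_id = names(net$components),
                   component = as.integer(net$components),
                   class = cls$class[match(names(net$components), cls$gene_id)])
mixed <- tapply(memb$class, memb$component, function(x) length(unique(x)) > 1)
message("ACF network: ", nrow(net$edges), " edges, ",
        length(unique(memb$component)), " components, mixed-class components: ",
        sum(mixed))
write_tsv(memb, "acf_components.tsv")
write_tsv(net$edges, "acf_edges.tsv")
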