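#!/usr/bin/env Rscript
## Generate the synthetic immune-stimulation time course: 2,000 genes over
## 21 time points (0-120 h, two replicates), negative-binomial counts with
## six planted temporal classes and 20 planted lag couplings, and write the
## fixture (counts, sample sheet, ground truth) under results/fixture.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE)[1])), "00_common.R"))

sim <- simulate_experiment(fixture_config(), seed = SEED)
paths <- write_fixture(sim, file.path(RESULTS, "fixture"))
classes <- table(sim$truth$class_table$class)
message("planted classes: ", paste(names(classes), classes, sep = "=", collapse = ", "))
message("planted couplings: ", length(sim$truth$couplings))
message("fixture written to ", dirname(paths[1]))
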