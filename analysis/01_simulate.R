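#!/usr/bin/env Rscript
# Generate the synthetic paired GDM study: 41+41 methylation cohort,
# 30+25 matched expression cohort, planted DEGs / methylation-driven
# genes / network hubs, KGML pathway files, and the external validation
# cohort. All downstream scripts read from results/syndata/.

suppressPackageStartupMessages(library(gdmdiag))

cfg <- synth_config(seed = 20260920L)
sim <- simulate_study(cfg, dir = "results/syndata")

cat(sprintf("methylation: %d probes x %d samples (%.1f%% missing)\n",
            nrow(sim$meth$values), ncol(sim$meth$values),
            100 * mean(is.na(sim$meth$values))))
cat(sprintf("expression:  %d genes x %d samples (%d GDM / %d control)\n",
            nrow(sim$expr$values), ncol(sim$expr$values),
            sum(sim$expr$samples$condition == "GDM"),
            sum(sim$expr$samples$condition == "control")))
cat(sprintf("planted: %d DEGs, %d driver gene-CpG pairs, %d hub genes\n",
            nrow(sim$truth$deg_genes), nrow(sim$truth$driver_pairs),
            length(sim$truth$hub_genes)))
cat(sprintf("pathways: %d KGML files, %d true interactions\n",
            length(sim$kgml$xml), nrow(sim$truth$true_edges)))
cat("artifacts written under results/syndata/\n")
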