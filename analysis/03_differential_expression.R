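#!/usr/bin/env Rscript
# Moderated-t differential expression screen (GDM vs control) at raw
# p < 0.05, followed by pathway over-representation of the DEG list.

suppressPackageStartupMessages(library(gdmdiag))

expr <- read_expression_tsv("results/syndata/expr_matrix.tsv",
                            "results/syndata/expr_samples.tsv")
deg <- deg_screen(expr, alpha = 0.05)
eb <- attr(deg, "ebayes")

dir.create("results", showWarnings = FALSE)
gdmdiag:::write_tsv_base(deg, "results/deg_table.tsv")

sig <- deg[deg$significant, ]
cat(sprintf("empirical-Bayes prior: d0 = %.2f, s0^2 = %.4f\n",
            eb$d0, eb$s0_sq))
cat(sprintf("%d of %d genes differential at p < 0.05 (%d up in GDM, %d up in control)\n",
            nrow(sig), nrow(deg), sum(sig$direction == "up_in_GDM"),
            sum(sig$direction == "up_in_control")))

collection <- read_gmt("results/syndata/pathways.gmt")
enr <- enrich(sig$gene, collection, rownames(expr$values), alpha = 0.05)
gdmdiag:::write_tsv_base(enr, "results/enrichment.tsv")
cat(sprintf("%d of %d pathway sets over-represented at p < 0.05\n",
            sum(enr$significant), nrow(enr)))
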