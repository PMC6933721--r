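#!/usr/bin/env Rscript
# Screen the pathway-network genes for significant negative correlation
# between promoter CpG M-values and expression on the matched samples,
# assemble the gene-gene-CpG network, and select hub genes as the
# intersection of the top-10 degree / closeness / betweenness lists.

suppressPackageStartupMessages(library(gdmdiag))

expr <- read_expression_tsv("results/syndata/expr_matrix.tsv",
                            "results/syndata/expr_samples.tsv")
meth <- read_methylation_tsv("results/processed/meth_M.tsv",
                             "results/processed/meth_probes.tsv",
                             "results/syndata/meth_samples.tsv",
                             scale = "M")
edges <- read.delim("results/pathway_edges.tsv")
net <- gdmdiag:::pathway_graph(unique(c(edges$from, edges$to)), edges)

drivers <- screen_negative(expr, meth, net$nodes, alpha = 0.05)
sm <- attr(drivers, "screen_summary")
cat(sprintf("screened %d genes (%d without promoter CpGs): %d of %d pairs negatively correlated at p < 0.05, %d driver genes\n",
            sm$genes_screened, sm$genes_without_cpg, sm$pairs_retained,
            sm$pairs_tested, sm$driver_genes))

gcnet <- build_network(net, drivers)
cent <- centralities(gcnet)
hubs <- select_hubs(cent, k = 10)

gdmdiag:::write_tsv_base(drivers, "results/driver_table.tsv")
gdmdiag:::write_tsv_base(cent, "results/centralities.tsv")
writeLines(hubs, "results/hub_genes.txt")
write_network_graphml(gcnet, "results/gene_cpg_network.graphml")

cat(sprintf("gene-gene-CpG network: %d genes + %d CpGs, %d edges\n",
            length(gcnet$genes), length(gcnet$cpgs), nrow(gcnet$edges)))
cat("hub genes:", paste(hubs, collapse = ", "), "\n")
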