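#!/usr/bin/env Rscript
# Parse the KGML pathway files, merge them into one gene interaction
# network, and summarize its topology (degree histogram, log-log slope).

suppressPackageStartupMessages(library(gdmdiag))

map <- read.delim("results/syndata/id_to_symbol.tsv")
id_to_symbol <- setNames(map$gene_symbol, map$accession)
files <- list.files("results/syndata/kgml", full.names = TRUE)
graphs <- lapply(files, parse_kgml, id_to_symbol = id_to_symbol)
net <- merge_graphs(graphs)
dd <- degree_distribution(net)

gdmdiag:::write_tsv_base(net$edges, "results/pathway_edges.tsv")
gdmdiag:::write_tsv_base(dd$histogram, "results/degree_histogram.tsv")
write_sif(net, "results/pathway_network.sif")
write_graphml(net, "results/pathway_network.graphml")

cat(sprintf("merged network: %d genes, %d interactions from %d pathways\n",
            length(net$nodes), nrow(net$edges), length(files)))
cat(sprintf("degree distribution: max degree %d (gene %s), log-log slope %.2f\n",
            max(dd$degrees), names(which.max(dd$degrees)), dd$loglog_slope))
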