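#!/usr/bin/env Rscript
# Preprocess both omics layers: methylation beta -> M, missingness filter,
# kNN imputation, blacklist removal, promoter restriction; expression
# passes through deduplication (and, for probe-level input, quantile
# normalization + median collapse).

suppressPackageStartupMessages(library(gdmdiag))

meth <- read_methylation_tsv("results/syndata/meth_beta.tsv",
                             "results/syndata/probe_annotation.tsv",
                             "results/syndata/meth_samples.tsv")
expr <- read_expression_tsv("results/syndata/expr_matrix.tsv",
                            "results/syndata/expr_samples.tsv")

pp <- preprocess_methylation(meth)
expr <- preprocess_expression(expr)

dir.create("results/processed", showWarnings = FALSE, recursive = TRUE)
gdmdiag:::write_matrix_tsv(pp$data$values, "results/processed/meth_M.tsv",
                           id_col = "probe_id")
gdmdiag:::write_tsv_base(pp$data$probes,
                         "results/processed/meth_probes.tsv")
jsonlite::write_json(pp$report, "results/processed/meth_filter_report.json",
                     auto_unbox = TRUE, digits = NA)

cat(sprintf("probes: %d raw -> %d after missingness -> %d after blacklist -> %d promoter\n",
            pp$report$n_probes_input, pp$report$n_probes_after_missing,
            pp$report$n_probes_after_blacklist, pp$report$n_probes_promoter))
cat(sprintf("samples retained: %d; imputation left %d missing values\n",
            pp$report$n_samples, sum(is.na(pp$data$values))))
cat("processed matrices under results/processed/\n")
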