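#!/usr/bin/env Rscript
# Train the hub-gene SVM diagnostic classifier on a random 27-sample
# training split (15 GDM / 12 control), validate on the remaining 28,
# predict the external cohort, and measure resampling stability on the
# external normals.

suppressPackageStartupMessages(library(gdmdiag))

expr <- read_expression_tsv("results/syndata/expr_matrix.tsv",
                            "results/syndata/expr_samples.tsv")
external <- read_expression_tsv("results/syndata/external_matrix.tsv",
                                "results/syndata/external_samples.tsv")
hubs <- readLines("results/hub_genes.txt")

feats <- t(expr$values[hubs, , drop = FALSE])
labels <- expr$samples$condition
split <- split_samples(expr$samples, c(GDM = 15, control = 12), seed = 71L)
tr <- rownames(feats) %in% split$train

model <- train_svm(feats[tr, , drop = FALSE], labels[tr], folds = 10,
                   seed = 72L)
report <- function(name, ev, n) {
  cat(sprintf("%-12s accuracy %.1f%%  sensitivity %.1f%%  specificity %.1f%%  AUC %.3f (n = %d)\n",
              name, 100 * ev$accuracy, 100 * ev$sensitivity,
              100 * ev$specificity, ev$auc, n))
}
cat(sprintf("selected cost %g; 10-fold CV accuracy %.1f%%\n",
            model$cost, 100 * model$cv_accuracy))
ev_tr <- evaluate(model, feats[tr, , drop = FALSE], labels[tr])
ev_va <- evaluate(model, feats[!tr, , drop = FALSE], labels[!tr])
ev_all <- evaluate(model, feats, labels)
report("training", ev_tr, sum(tr))
report("validation", ev_va, sum(!tr))
report("all samples", ev_all, length(labels))

fx <- t(external$values[hubs, , drop = FALSE])
ext_labels <- external$samples$condition
ev_ext <- evaluate(model, fx, ext_labels)
report("external", ev_ext, length(ext_labels))

normals <- fx[ext_labels == "control", , drop = FALSE]
stab <- stability_resample(model, normals, frac = 0.5, reps = 1000,
                           seed = 73L)
cat(sprintf("stability: modal misclassified count %d of %d drawn normals over 1000 draws\n",
            stab$mode, floor(0.5 * nrow(normals))))

cmp <- compare_covariates(ev_ext$predicted,
                          external$samples[, c("age", "bmi")])
print(cmp)

gdmdiag:::write_tsv_base(ev_va$roc, "results/roc_validation.tsv")
gdmdiag:::write_tsv_base(ev_ext$roc, "results/roc_external.tsv")
gdmdiag:::write_tsv_base(
  data.frame(count = as.integer(names(stab$histogram)),
             draws = as.integer(stab$histogram)),
  "results/stability_histogram.tsv")
jsonlite::write_json(
  list(cost = model$cost, cv_accuracy = model$cv_accuracy,
       genes = model$genes,
       scaler = list(center = as.list(model$center),
                     scale = as.list(model$scale))),
  "results/classifier_model.json", auto_unbox = TRUE, digits = NA)
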