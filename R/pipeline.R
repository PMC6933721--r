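## Configuration-driven orchestration of the full workflow: synthetic (or
## user-supplied) data -> methylation / expression preprocessing ->
## differential expression -> pathway enrichment -> KGML network ->
## negative-correlation driver screen -> gene-gene-CpG network and hub
## selection -> SVM training / validation -> external prediction,
## stability and covariate comparison -> baseline-characteristics table.

#' Workflow configuration
#'
#' @param syndata A [synth_config()] describing the synthetic study, or
#'   `NULL` when `paths` is given.
#' @param paths Named list of input files for user-supplied data:
#'   `meth_values`, `meth_probes`, `meth_samples` (beta matrix TSV, probe
#'   annotation TSV, metadata TSV), `expr_values`, `expr_samples`,
#'   optionally `external_values`, `external_samples`, `kgml` (character
#'   vector of KGML files), `id_to_symbol` (mapping TSV), `gmt`.
#' @param deg_alpha,enrich_alpha,corr_alpha Significance thresholds of the
#'   DEG screen, the over-representation analysis and the correlation
#'   screen.
#' @param hub_k,hub_mode,hub_fraction Hub selection depth and mode (see
#'   [select_hubs()]).
#' @param cv_folds Cross-validation folds for [train_svm()].
#' @param train_counts Per-class training-set sizes for
#'   [split_samples()].
#' @param network_pathways `"all"` (build the interaction network from
#'   every supplied pathway) or `"enriched"` (only pathways significant in
#'   the enrichment step).
#' @param stability_frac,stability_reps Resampling-stability parameters.
#' @param split_seed,cv_seed,stability_seed Named seeds; all randomness of
#'   a run flows from these plus the generator seed.
#' @param out_dir Output directory for artifacts and the JSON report, or
#'   `NULL` to keep everything in memory.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(syndata = synth_config(), paths = NULL,
                       deg_alpha = 0.05, enrich_alpha = 0.05,
                       corr_alpha = 0.05, hub_k = 10,
                       hub_mode = c("count", "fraction"), hub_fraction = 0.1,
                       cv_folds = 10, train_counts = c(GDM = 15, control = 12),
                       network_pathways = c("all", "enriched"),
                       stability_frac = 0.5, stability_reps = 1000,
                       split_seed = 101L, cv_seed = 202L,
                       stability_seed = 303L, out_dir = NULL) {
  cfg <- as.list(environment())
  cfg$hub_mode <- match.arg(hub_mode)
  cfg$network_pathways <- match.arg(network_pathways)
  for (a in c("deg_alpha", "enrich_alpha", "corr_alpha")) {
    if (!(cfg[[a]] >= 0 && cfg[[a]] < 1)) {
      abort("run_config: %s must lie in [0, 1)", a)
    }
  }
  if (is.null(syndata) && is.null(paths)) {
    abort("run_config: provide syndata or paths")
  }
  structure(cfg, class = "run_config")
}

pipeline_stage <- function(report, stage, expr) {
  tryCatch(expr, error = function(e) {
    abort("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
}

#' Run the full workflow
#'
#' Executes every stage in order and collects a machine-readable report:
#' preprocessing counts, DEG counts (up in GDM / up in control), enriched
#' sets, pathway-network size and degree summary, the driver table
#' summary, hub genes, classifier metrics on the training / validation /
#' combined / external sets, the resampling-stability histogram, the
#' predicted-group covariate comparison and the baseline table. A run is
#' fully reproducible from the configuration and its seeds. When the
#' correlation screen retains nothing, the run halts gracefully after the
#' screen with `status = "halted_at_network"` and a partial report.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return A list of class `gdm_run` with `report` (plain-list summary,
#'   also written as JSON when `out_dir` is set) and the main intermediate
#'   objects (`deg`, `pathway_graph`, `drivers`, `centralities`, `hubs`,
#'   `model`, evaluations).
#' @export
run_all <- function(config = run_config(), quiet = TRUE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  t0 <- Sys.time()
  report <- list(status = "complete")

  ## ---- inputs -------------------------------------------------------------
  truth <- NULL
  if (!is.null(config$syndata)) {
    sim <- pipeline_stage(report, "simulate", simulate_study(config$syndata))
    meth_raw <- sim$meth
    expr_raw <- sim$expr
    external <- sim$external
    kgml_xml <- sim$kgml$xml
    id_to_symbol <- sim$kgml$id_to_symbol
    collection <- gene_set_collection(sim$kgml$pathway_sets,
                                      category = "pathway")
    truth <- sim$truth
  } else {
    p <- config$paths
    meth_raw <- pipeline_stage(report, "load", read_methylation_tsv(
      p$meth_values, p$meth_probes, p$meth_samples, scale = "beta"))
    expr_raw <- read_expression_tsv(p$expr_values, p$expr_samples)
    external <- if (!is.null(p$external_values)) {
      read_expression_tsv(p$external_values, p$external_samples)
    }
    map <- read_tsv_base(p$id_to_symbol)
    id_to_symbol <- stats::setNames(map$gene_symbol, map$accession)
    kgml_xml <- stats::setNames(p$kgml, basename(p$kgml))
    collection <- read_gmt(p$gmt, category = "pathway")
  }
  say("inputs: %d probes, %d genes", nrow(meth_raw$values),
      nrow(expr_raw$values))

  ## ---- preprocessing ------------------------------------------------------
  meth_pp <- pipeline_stage(report, "preprocess_methylation",
                            preprocess_methylation(meth_raw))
  meth <- meth_pp$data
  expr <- pipeline_stage(report, "preprocess_expression",
                         preprocess_expression(expr_raw))
  report$preprocess <- meth_pp$report
  say("preprocess: %d promoter probes retained", nrow(meth$values))

  ## ---- differential expression -------------------------------------------
  deg <- pipeline_stage(report, "dea", deg_screen(expr, alpha = config$deg_alpha))
  deg_sig <- deg[deg$significant, , drop = FALSE]
  report$dea <- list(
    n_genes = nrow(deg), n_deg = nrow(deg_sig),
    n_up_gdm = sum(deg_sig$direction == "up_in_GDM"),
    n_up_control = sum(deg_sig$direction == "up_in_control"))
  say("dea: %d DEGs (%d up in GDM, %d up in control)", report$dea$n_deg,
      report$dea$n_up_gdm, report$dea$n_up_control)

  ## ---- enrichment ---------------------------------------------------------
  universe <- rownames(expr$values)
  enr <- pipeline_stage(report, "enrich", enrich(
    intersect(deg_sig$gene, universe), collection, universe,
    alpha = config$enrich_alpha))
  report$enrichment <- list(n_sets = nrow(enr),
                            n_significant = sum(enr$significant))

  ## ---- pathway network ----------------------------------------------------
  keep_sets <- if (config$network_pathways == "enriched") {
    enr$set[enr$significant]
  } else {
    names(kgml_xml)
  }
  kgml_use <- kgml_xml[intersect(names(kgml_xml), keep_sets)]
  if (length(kgml_use) == 0) kgml_use <- kgml_xml
  graphs <- pipeline_stage(report, "pathway_network", lapply(
    kgml_use, parse_kgml, id_to_symbol = id_to_symbol))
  net <- merge_graphs(graphs)
  dd <- degree_distribution(net)
  report$network <- list(n_genes = length(net$nodes),
                         n_edges = nrow(net$edges),
                         loglog_slope = dd$loglog_slope)
  say("network: %d genes, %d edges", length(net$nodes), nrow(net$edges))

  ## promoter CpG count distribution over the network genes
  cpg_per_gene <- table(factor(
    meth$probes$gene_symbol[meth$probes$gene_symbol %in% net$nodes],
    levels = net$nodes))
  with_cpg <- cpg_per_gene[cpg_per_gene > 0]
  report$promoter_cpgs <- list(
    n_network_genes = length(net$nodes),
    n_with_cpg = length(with_cpg),
    pct_with_cpg = 100 * length(with_cpg) / length(net$nodes),
    pct_below_20 = if (length(with_cpg)) 100 * mean(with_cpg < 20) else NA)

  ## ---- driver screen ------------------------------------------------------
  drivers <- pipeline_stage(report, "driver_screen", screen_negative(
    expr, meth, net$nodes, alpha = config$corr_alpha))
  report$drivers <- attr(drivers, "screen_summary")
  say("drivers: %d genes with %d CpG pairs", report$drivers$driver_genes,
      report$drivers$pairs_retained)

  out <- list(config = config, truth = truth, deg = deg, enrichment = enr,
              pathway_graph = net, drivers = drivers)
  if (nrow(drivers) == 0) {
    report$status <- "halted_at_network"
    report$runtime_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    out$report <- report
    class(out) <- "gdm_run"
    write_run_artifacts(out)
    return(out)
  }

  ## ---- gene-gene-CpG network and hubs -------------------------------------
  gcnet <- pipeline_stage(report, "hub_selection", build_network(net, drivers))
  cent <- centralities(gcnet)
  hubs <- select_hubs(cent, k = min(config$hub_k, nrow(cent)),
                      mode = config$hub_mode, fraction = config$hub_fraction)
  report$hubs <- list(n_gene_nodes = nrow(cent), n_cpg_nodes = length(gcnet$cpgs),
                      hub_genes = hubs)
  say("hubs: %s", paste(hubs, collapse = ", "))
  out$gene_cpg_network <- gcnet
  out$centralities <- cent
  out$hubs <- hubs
  if (length(hubs) == 0) {
    report$status <- "halted_at_classifier"
    report$runtime_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    out$report <- report
    class(out) <- "gdm_run"
    write_run_artifacts(out)
    return(out)
  }

  ## ---- classifier ---------------------------------------------------------
  features <- t(expr$values[hubs, , drop = FALSE])
  labels <- expr$samples$condition[match(rownames(features),
                                         expr$samples$sample_id)]
  split <- pipeline_stage(report, "classifier", split_samples(
    expr$samples, train_counts = config$train_counts,
    seed = config$split_seed))
  tr <- rownames(features) %in% split$train
  model <- train_svm(features[tr, , drop = FALSE], labels[tr],
                     folds = config$cv_folds, seed = config$cv_seed)
  eval_train <- evaluate(model, features[tr, , drop = FALSE], labels[tr])
  eval_valid <- evaluate(model, features[!tr, , drop = FALSE], labels[!tr])
  eval_all <- evaluate(model, features, labels)
  eval_metrics <- function(ev) list(
    accuracy = ev$accuracy, sensitivity = ev$sensitivity,
    specificity = ev$specificity, auc = ev$auc,
    confusion = list(tp = ev$tp, fp = ev$fp, tn = ev$tn, fn = ev$fn))
  report$classifier <- list(
    n_train = sum(tr), n_validation = sum(!tr), cost = model$cost,
    cv_accuracy = model$cv_accuracy,
    train = eval_metrics(eval_train), validation = eval_metrics(eval_valid),
    all = eval_metrics(eval_all))
  say("classifier: CV %.3f, validation accuracy %.3f", model$cv_accuracy,
      eval_valid$accuracy)
  out$split <- split
  out$model <- model
  out$eval <- list(train = eval_train, validation = eval_valid,
                   all = eval_all)

  ## ---- external validation ------------------------------------------------
  if (!is.null(external)) {
    ext <- pipeline_stage(report, "external_validation", {
      fx <- t(external$values[hubs, , drop = FALSE])
      lab <- external$samples$condition[match(rownames(fx),
                                              external$samples$sample_id)]
      ev <- evaluate(model, fx, lab)
      normals <- fx[lab == "control", , drop = FALSE]
      stab <- stability_resample(model, normals,
                                 frac = config$stability_frac,
                                 reps = config$stability_reps,
                                 seed = config$stability_seed)
      covs <- external$samples[match(rownames(fx), external$samples$sample_id),
                               intersect(c("age", "bmi"),
                                         colnames(external$samples)),
                               drop = FALSE]
      cc <- if (ncol(covs)) compare_covariates(ev$predicted, covs)
      list(eval = ev, stability = stab, covariates = cc)
    })
    report$external <- c(eval_metrics(ext$eval), list(
      stability_mode = ext$stability$mode,
      stability_histogram = as.list(ext$stability$histogram),
      covariate_p = if (!is.null(ext$covariates)) {
        stats::setNames(as.list(ext$covariates$p), ext$covariates$covariate)
      }))
    out$external <- ext
  }

  ## ---- baseline characteristics table -------------------------------------
  covars <- intersect(c("age", "bmi"), colnames(meth_raw$samples))
  if (length(covars)) {
    tab1 <- pipeline_stage(report, "table1", build_table1(
      meth_raw$samples, continuous = covars))
    report$table1 <- stats::setNames(as.list(tab1$p), tab1$variable)
    out$table1 <- tab1
  }

  report$runtime_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  out$report <- report
  class(out) <- "gdm_run"
  write_run_artifacts(out)
  out
}

write_run_artifacts <- function(run) {
  dir <- run$config$out_dir
  if (is.null(dir)) return(invisible(run))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(run$report, file.path(dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write_tsv_base(run$deg, file.path(dir, "deg_table.tsv"))
  write_tsv_base(run$enrichment, file.path(dir, "enrichment.tsv"))
  write_tsv_base(run$pathway_graph$edges, file.path(dir, "pathway_edges.tsv"))
  if (!is.null(run$drivers) && nrow(run$drivers) > 0) {
    write_tsv_base(run$drivers, file.path(dir, "driver_table.tsv"))
  }
  if (!is.null(run$centralities)) {
    write_tsv_base(run$centralities, file.path(dir, "centralities.tsv"))
  }
  if (!is.null(run$hubs)) {
    writeLines(run$hubs, file.path(dir, "hub_genes.txt"))
  }
  if (!is.null(run$eval)) {
    write_tsv_base(run$eval$validation$roc, file.path(dir, "roc_validation.tsv"))
  }
  invisible(run)
}

#' @export
print.gdm_run <- function(x, ...) {
  r <- x$report
  cat(sprintf("gdm_run (%s): %d DEGs; network %d genes / %d edges; %d driver genes; hubs: %s\n",
              r$status, r$dea$n_deg, r$network$n_genes, r$network$n_edges,
              if (!is.null(r$drivers)) r$drivers$driver_genes else 0L,
              if (!is.null(r$hubs)) paste(r$hubs$hub_genes, collapse = ", ")
              else "-"))
  if (!is.null(r$classifier)) {
    cat(sprintf("  classifier: CV %.3f | validation accuracy %.3f (AUC %.3f)\n",
                r$classifier$cv_accuracy, r$classifier$validation$accuracy,
                r$classifier$validation$auc))
  }
  invisible(x)
}
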