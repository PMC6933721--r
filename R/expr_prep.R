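## Expression preprocessing: duplicate-sample removal, quantile
## normalization (the between-array step of standard microarray
## normalization; input is assumed background-corrected and log2 scale),
## and probe-to-gene collapse by the median.

#' Remove duplicated samples
#'
#' @param data An [expression_data].
#' @param duplicate_map List of character vectors; each vector names
#'   samples known to be replicates of one another. The first member of
#'   each group (in its given order) is kept, the rest dropped.
#' @return The deduplicated [expression_data].
#' @export
dedupe_samples <- function(data, duplicate_map = list()) {
  stopifnot(inherits(data, "expression_data"))
  ids <- colnames(data$values)
  unknown <- setdiff(unlist(duplicate_map), ids)
  if (length(unknown)) {
    abort("dedupe_samples: unknown sample id(s): %s",
          paste(unknown, collapse = ", "))
  }
  drop <- unlist(lapply(duplicate_map, function(g) g[-1]))
  keep <- setdiff(ids, drop)
  expression_data(data$values[, keep, drop = FALSE],
                  data$samples[data$samples$sample_id %in% keep, , drop = FALSE],
                  level = data$level, probe_to_gene = data$probe_to_gene)
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample's value distribution to the across-sample mean of
#' the order statistics; tied values within a sample share the mean of the
#' quantiles they span. Idempotent.
#'
#' @param data An [expression_data] with no missing values.
#' @return The normalized [expression_data].
#' @export
quantile_normalize <- function(data) {
  stopifnot(inherits(data, "expression_data"))
  if (anyNA(data$values)) {
    abort("quantile_normalize: missing values are not supported")
  }
  v <- limma::normalizeQuantiles(data$values, ties = TRUE)
  dimnames(v) <- dimnames(data$values)
  data$values <- v
  data
}

#' Collapse probe-level expression to gene level by the median
#'
#' Probes mapping to no gene or to more than one gene are discarded; each
#' remaining gene's per-sample expression is the median over its probes.
#'
#' @param data A probe-level [expression_data] whose `probe_to_gene`
#'   mapping is set (rows `probe_id`, `gene_symbol`; a probe annotated to
#'   several genes appears on several rows).
#' @return A gene-level [expression_data].
#' @export
collapse_probes_median <- function(data) {
  stopifnot(inherits(data, "expression_data"))
  if (data$level != "probe") {
    abort("collapse_probes_median: input must be probe level")
  }
  map <- data$probe_to_gene
  if (is.null(map)) abort("collapse_probes_median: probe_to_gene mapping missing")
  map <- unique(map[, c("probe_id", "gene_symbol")])
  map <- map[map$probe_id %in% rownames(data$values), , drop = FALSE]
  n_genes_per_probe <- table(map$probe_id)
  unique_probes <- names(n_genes_per_probe)[n_genes_per_probe == 1]
  map <- map[map$probe_id %in% unique_probes, , drop = FALSE]
  if (nrow(map) == 0) {
    abort("collapse_probes_median: no probe maps uniquely to a gene")
  }
  genes <- sort(unique(map$gene_symbol))
  out <- matrix(NA_real_, nrow = length(genes), ncol = ncol(data$values),
                dimnames = list(genes, colnames(data$values)))
  by_gene <- split(map$probe_id, map$gene_symbol)
  for (g in genes) {
    sub <- data$values[by_gene[[g]], , drop = FALSE]
    out[g, ] <- apply(sub, 2, stats::median)
  }
  expression_data(out, data$samples, level = "gene")
}

#' Run the expression preprocessing chain
#'
#' Duplicate removal, then (for probe-level input) quantile normalization
#' and median probe collapse. Gene-level input is passed through after
#' deduplication, since it is already on the normalized log2 scale.
#'
#' @param data An [expression_data].
#' @param duplicate_map Passed to [dedupe_samples()].
#' @return A gene-level [expression_data].
#' @export
preprocess_expression <- function(data, duplicate_map = list()) {
  out <- dedupe_samples(data, duplicate_map)
  if (out$level == "probe") {
    out <- collapse_probes_median(quantile_normalize(out))
  }
  out
}
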