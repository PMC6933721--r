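## Lightweight S3 containers for the two omics layers. Both are plain lists
## of a numeric matrix plus annotation data frames, mirroring how the
## matrices travel as TSV on disk.

PROMOTER_CLASSES <- c("TSS1500", "TSS200", "5UTR", "1stExon")
NONPROMOTER_CLASSES <- c("Body", "3UTR")
PROBE_COLUMNS <- c("probe_id", "gene_symbol", "region_class", "chromosome",
                   "flag_snp", "flag_crosshyb")

#' Construct a methylation data object
#'
#' Bundles a CpG-by-sample numeric matrix with its probe annotation and
#' sample metadata. The matrix carries a scale tag: `"beta"` for methylation
#' fractions in \[0, 1\] or `"M"` for `log2(beta / (1 - beta))` values.
#'
#' @param values Numeric matrix, CpG probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids). `NA` marks missing calls.
#' @param probes Data frame with columns `probe_id`, `gene_symbol`,
#'   `region_class` (Illumina region classes, e.g. `TSS200`, `Body`),
#'   `chromosome` (`chr1` ... `chr22`, `chrX`, `chrY`), `flag_snp`,
#'   `flag_crosshyb` (logical blacklist flags). Every matrix row must have
#'   an annotation record.
#' @param samples Data frame with at least `sample_id` and `condition`
#'   (`"GDM"` or `"control"`); extra covariate columns (age, bmi) pass
#'   through untouched.
#' @param scale `"beta"` or `"M"`.
#' @return An object of class `methylation_data`.
#' @export
methylation_data <- function(values, probes, samples, scale = c("beta", "M")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("methylation values must have probe rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) abort("duplicate probe ids in matrix")
  if (anyDuplicated(colnames(values))) abort("duplicate sample ids in matrix")
  missing_cols <- setdiff(PROBE_COLUMNS, colnames(probes))
  if (length(missing_cols)) {
    abort("probe annotation lacks column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(probes$probe_id)) abort("duplicate probe ids in annotation")
  unannotated <- setdiff(rownames(values), probes$probe_id)
  if (length(unannotated)) {
    abort("%d matrix probes have no annotation record (e.g. %s)",
          length(unannotated), unannotated[1])
  }
  if (!all(c("sample_id", "condition") %in% colnames(samples))) {
    abort("sample metadata needs sample_id and condition columns")
  }
  if (anyDuplicated(samples$sample_id)) abort("duplicate sample ids in metadata")
  if (!all(colnames(values) %in% samples$sample_id)) {
    abort("matrix samples missing from metadata")
  }
  if (scale == "beta") {
    v <- values[!is.na(values)]
    if (length(v) && (min(v) < 0 || max(v) > 1)) {
      abort("beta values must lie in [0, 1]")
    }
  }
  ## keep annotation/metadata aligned and restricted to the matrix
  probes <- probes[match(rownames(values), probes$probe_id), , drop = FALSE]
  rownames(probes) <- NULL
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(values = values, probes = probes, samples = samples,
                 scale = scale),
            class = "methylation_data")
}

#' @export
print.methylation_data <- function(x, ...) {
  cat(sprintf("methylation_data: %d probes x %d samples [%s scale], %d missing\n",
              nrow(x$values), ncol(x$values), x$scale, sum(is.na(x$values))))
  invisible(x)
}

## Subset a methylation_data by probe and/or sample ids, keeping alignment.
subset_meth <- function(data, probe_ids = NULL, sample_ids = NULL) {
  v <- data$values
  if (!is.null(probe_ids)) v <- v[probe_ids, , drop = FALSE]
  if (!is.null(sample_ids)) v <- v[, sample_ids, drop = FALSE]
  methylation_data(v, data$probes, data$samples, scale = data$scale)
}

#' Construct an expression data object
#'
#' @param values Numeric matrix of log2-scale expression, features in rows,
#'   samples in columns.
#' @param samples Data frame with `sample_id` and `condition` (`"GDM"` /
#'   `"control"`) plus optional covariates.
#' @param level Feature level of the rows: `"probe"` or `"gene"`.
#' @param probe_to_gene Optional probe annotation data frame with columns
#'   `probe_id` and `gene_symbol`; probes mapping to several genes appear on
#'   several rows. Required by [collapse_probes_median()].
#' @return An object of class `expression_data`.
#' @export
expression_data <- function(values, samples, level = c("gene", "probe"),
                            probe_to_gene = NULL) {
  level <- match.arg(level)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("expression values must have feature rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) abort("duplicate feature ids")
  if (anyDuplicated(colnames(values))) abort("duplicate sample ids")
  if (!all(c("sample_id", "condition") %in% colnames(samples))) {
    abort("sample metadata needs sample_id and condition columns")
  }
  if (!all(colnames(values) %in% samples$sample_id)) {
    abort("matrix samples missing from metadata")
  }
  bad <- setdiff(unique(samples$condition), c("GDM", "control"))
  if (length(bad)) {
    abort("condition labels must be 'GDM' or 'control' (found: %s)",
          paste(bad, collapse = ", "))
  }
  if (!is.null(probe_to_gene) &&
      !all(c("probe_id", "gene_symbol") %in% colnames(probe_to_gene))) {
    abort("probe_to_gene needs probe_id and gene_symbol columns")
  }
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(values = values, samples = samples, level = level,
                 probe_to_gene = probe_to_gene),
            class = "expression_data")
}

#' @export
print.expression_data <- function(x, ...) {
  cat(sprintf("expression_data: %d %ss x %d samples (%d GDM / %d control)\n",
              nrow(x$values), x$level, ncol(x$values),
              sum(x$samples$condition == "GDM"),
              sum(x$samples$condition == "control")))
  invisible(x)
}

#' Read a methylation data set from TSV files
#'
#' @param values_path Matrix TSV (first column probe id, remaining columns
#'   one per sample).
#' @param probes_path Probe annotation TSV.
#' @param samples_path Sample metadata TSV.
#' @inheritParams methylation_data
#' @return A `methylation_data` object.
#' @export
read_methylation_tsv <- function(values_path, probes_path, samples_path,
                                 scale = c("beta", "M")) {
  probes <- read_tsv_base(probes_path)
  probes$flag_snp <- as.logical(probes$flag_snp)
  probes$flag_crosshyb <- as.logical(probes$flag_crosshyb)
  methylation_data(read_matrix_tsv(values_path), probes,
                   read_tsv_base(samples_path), scale = match.arg(scale))
}

#' Read an expression data set from TSV files
#'
#' @inheritParams read_methylation_tsv
#' @inheritParams expression_data
#' @param probe_to_gene_path Optional probe-to-gene mapping TSV.
#' @return An `expression_data` object.
#' @export
read_expression_tsv <- function(values_path, samples_path,
                                level = c("gene", "probe"),
                                probe_to_gene_path = NULL) {
  p2g <- if (!is.null(probe_to_gene_path)) read_tsv_base(probe_to_gene_path)
  expression_data(read_matrix_tsv(values_path), read_tsv_base(samples_path),
                  level = match.arg(level), probe_to_gene = p2g)
}
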