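## Methylation preprocessing: beta -> M conversion, missingness filtering,
## kNN imputation, blacklist removal, promoter restriction. All operations
## take and return a methylation_data object.

#' Convert beta values to M-values
#'
#' `M = log2(beta / (1 - beta))`, with beta clipped into
#' `[epsilon, 1 - epsilon]` so fully (un)methylated calls stay finite.
#' Missing entries stay missing. M-values variance-stabilize methylation
#' fractions and are the scale every downstream statistic uses.
#'
#' @param data A [methylation_data] on the beta scale.
#' @param epsilon Clipping bound, a small positive fraction.
#' @return The same object on the M scale.
#' @export
beta_to_m <- function(data, epsilon = 1e-6) {
  stopifnot(inherits(data, "methylation_data"))
  if (data$scale != "beta") {
    abort("beta_to_m: input is on the '%s' scale, expected 'beta'", data$scale)
  }
  if (!(epsilon > 0 && epsilon < 0.5)) {
    abort("beta_to_m: epsilon must lie in (0, 0.5)")
  }
  b <- pmin(pmax(data$values, epsilon), 1 - epsilon)
  data$values <- log2(b / (1 - b))
  data$scale <- "M"
  data
}

#' Filter probes and samples by missingness
#'
#' Drops probes whose fraction of missing calls exceeds
#' `max_probe_missing` (computed first, over all samples), then samples
#' whose missing fraction over the surviving probes exceeds
#' `max_sample_missing`. The probe-then-sample order matters on edge cases
#' and is fixed.
#'
#' @param data A [methylation_data].
#' @param max_probe_missing,max_sample_missing Missing-fraction thresholds
#'   in (0, 1]; a probe or sample is dropped when its fraction is strictly
#'   greater.
#' @return A list with `data` (the filtered [methylation_data]),
#'   `dropped_probes` and `dropped_samples` (character vectors of ids).
#' @export
filter_missing <- function(data, max_probe_missing = 0.2,
                           max_sample_missing = 0.2) {
  stopifnot(inherits(data, "methylation_data"))
  if (!(max_probe_missing > 0 && max_probe_missing <= 1) ||
      !(max_sample_missing > 0 && max_sample_missing <= 1)) {
    abort("filter_missing: thresholds must lie in (0, 1]")
  }
  miss <- is.na(data$values)
  probe_frac <- rowMeans(miss)
  drop_probes <- rownames(data$values)[probe_frac > max_probe_missing]
  keep <- !(rownames(data$values) %in% drop_probes)
  if (!any(keep)) abort("filter_missing: all probes filtered out")
  sample_frac <- colMeans(miss[keep, , drop = FALSE])
  drop_samples <- colnames(data$values)[sample_frac > max_sample_missing]
  keep_s <- !(colnames(data$values) %in% drop_samples)
  if (!any(keep_s)) abort("filter_missing: all samples filtered out")
  out <- subset_meth(data, rownames(data$values)[keep],
                     colnames(data$values)[keep_s])
  list(data = out, dropped_probes = drop_probes,
       dropped_samples = drop_samples)
}

#' Impute missing M-values by k nearest probes
#'
#' Each missing entry is replaced by the mean, within its sample, of the
#' `k` probes nearest to the incomplete probe. Probe-probe distance is the
#' mean squared difference over the samples where both probes are
#' observed; probes missing in the target sample are skipped when
#' averaging, falling through to the next nearest. Deterministic: ties are
#' broken by probe order.
#'
#' For matrices larger than `max_pool` probes the probe set is first
#' bisected recursively along its leading principal direction (balanced
#' median splits), and neighbours are searched within the resulting pools,
#' as large-matrix kNN imputers for arrays customarily do; below
#' `max_pool` probes the search is exact over all probes.
#'
#' @param data A [methylation_data] (any scale; typically M after
#'   [filter_missing()]).
#' @param k Number of nearest probes averaged.
#' @param max_pool Largest probe pool searched exhaustively.
#' @return The same object with no missing entries; observed entries are
#'   untouched.
#' @export
impute_knn <- function(data, k = 10, max_pool = 1500) {
  stopifnot(inherits(data, "methylation_data"))
  if (!is_count(k)) abort("impute_knn: k must be a positive count")
  X <- data$values
  if (k >= nrow(X)) abort("impute_knn: k must be smaller than the probe count")
  miss <- is.na(X)
  if (!any(miss)) return(data)
  if (any(rowSums(!miss) == 0)) {
    abort("impute_knn: probe with all entries missing (run filter_missing first)")
  }
  X0 <- X
  X0[miss] <- 0
  out <- X
  min_pool <- max(max_pool, 2L * (k + 2L))

  recurse <- function(ind) {
    if (length(ind) <= min_pool) {
      out <<- impute_pool(out, X, X0, miss, ind, k)
      return(invisible())
    }
    ## balanced split along the leading principal direction of the pool
    Xi <- X0[ind, , drop = FALSE]
    Xi <- sweep(Xi, 2, colMeans(Xi))
    v <- eigen(crossprod(Xi), symmetric = TRUE)$vectors[, 1]
    proj <- drop(Xi %*% v)
    ord <- order(proj, ind)
    half <- length(ind) %/% 2L
    recurse(ind[ord[seq_len(half)]])
    recurse(ind[ord[(half + 1L):length(ind)]])
  }
  recurse(seq_len(nrow(X)))
  data$values <- out
  data
}

## Exact kNN imputation within one probe pool; returns `out` with the
## pool's missing cells filled.
impute_pool <- function(out, X, X0, miss, ind, k) {
  sub_miss <- miss[ind, , drop = FALSE]
  targets <- which(rowSums(sub_miss) > 0)
  if (!length(targets)) return(out)
  n <- length(ind)
  n_samp <- ncol(X)
  A <- X0[ind, , drop = FALSE]
  M <- sub_miss * 1
  W <- 1 - M
  SQ <- A^2
  q <- rowSums(SQ)
  ## mean squared difference over shared observed samples:
  ## num_ij = q_i + q_j - 2 (A A')_ij - (M SQ')_ij - (SQ M')_ij
  ## (the cross term vanishes at missing entries thanks to the zero fill)
  num <- -2 * tcrossprod(A) + outer(q, q, "+") -
    tcrossprod(M, SQ) - tcrossprod(SQ, M)
  shared <- tcrossprod(W)
  D2 <- num / shared                       # NaN when no shared samples
  for (b in targets) {
    d <- D2[b, ]
    d[b] <- Inf
    d[!is.finite(d)] <- Inf
    ord <- order(d, seq_len(n))
    for (s in which(sub_miss[b, ])) {
      nb <- ord[W[ord, s] == 1 & is.finite(d[ord])]
      nb <- nb[seq_len(min(k, length(nb)))]
      if (!length(nb)) {
        abort("impute_knn: no observed neighbour for probe %s in sample %s",
              rownames(X)[ind[b]], colnames(X)[s])
      }
      out[ind[b], s] <- mean(X[ind[nb], s])
    }
  }
  out
}

#' Remove blacklisted probes
#'
#' Drops probes on the sex chromosomes and probes flagged as targeting a
#' SNP or cross-hybridizing to multiple genomic locations.
#'
#' @param data A [methylation_data].
#' @return The filtered object.
#' @export
filter_blacklist <- function(data) {
  stopifnot(inherits(data, "methylation_data"))
  bad <- data$probes$chromosome %in% c("chrX", "chrY") |
    data$probes$flag_snp | data$probes$flag_crosshyb
  subset_meth(data, data$probes$probe_id[!bad])
}

#' Restrict to promoter-region probes
#'
#' Keeps probes annotated to the promoter-proximal Illumina region classes
#' TSS1500, TSS200, 5'UTR and 1st exon.
#'
#' @param data A [methylation_data].
#' @return The filtered object.
#' @export
restrict_promoter <- function(data) {
  stopifnot(inherits(data, "methylation_data"))
  keep <- data$probes$region_class %in% PROMOTER_CLASSES
  subset_meth(data, data$probes$probe_id[keep])
}

#' Run the full methylation preprocessing chain
#'
#' beta -> M conversion, missingness filtering, kNN imputation, blacklist
#' removal, promoter restriction, in that order.
#'
#' @param data A [methylation_data] on the beta scale.
#' @param epsilon Clipping bound for [beta_to_m()].
#' @param max_probe_missing,max_sample_missing Thresholds for
#'   [filter_missing()].
#' @param k Neighbours for [impute_knn()].
#' @return A list with `data` (the processed promoter M-value
#'   [methylation_data]) and `report` (dropped probe/sample ids and stage
#'   probe counts).
#' @export
preprocess_methylation <- function(data, epsilon = 1e-6,
                                   max_probe_missing = 0.2,
                                   max_sample_missing = 0.2, k = 10) {
  m <- beta_to_m(data, epsilon = epsilon)
  filt <- filter_missing(m, max_probe_missing, max_sample_missing)
  imp <- impute_knn(filt$data, k = k)
  bl <- filter_blacklist(imp)
  prom <- restrict_promoter(bl)
  list(data = prom,
       report = list(
         dropped_probes_missing = filt$dropped_probes,
         dropped_samples_missing = filt$dropped_samples,
         n_probes_input = nrow(data$values),
         n_probes_after_missing = nrow(filt$data$values),
         n_probes_after_blacklist = nrow(bl$values),
         n_probes_promoter = nrow(prom$values),
         n_samples = ncol(prom$values)))
}
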