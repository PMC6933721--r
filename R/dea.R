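## Two-group differential expression with empirical-Bayes moderated
## t-statistics. Per gene, an ordinary two-group linear model gives the
## log2 fold-change and pooled residual variance; the gene-wise variances
## are then shrunk towards a common prior estimated by moment matching on
## the log variances, and the moderated t is referred to a t distribution
## with the augmented degrees of freedom.

#' Fit per-gene two-group linear models
#'
#' For each gene: `log2_fc = mean(GDM) - mean(control)`, `s2` the pooled
#' residual variance on `n - 2` degrees of freedom, and
#' `se = sqrt(s2 * (1/n1 + 1/n2))`.
#'
#' @param expr A gene-level [expression_data] with both conditions
#'   represented by at least two samples.
#' @return A list with `log2_fc`, `s2`, `se` (named numeric vectors),
#'   `df_residual`, `n1` (GDM), `n2` (control).
#' @export
fit_gene_models <- function(expr) {
  stopifnot(inherits(expr, "expression_data"))
  if (expr$level != "gene") abort("fit_gene_models: input must be gene level")
  grp <- expr$samples$condition[match(colnames(expr$values),
                                      expr$samples$sample_id)]
  n1 <- sum(grp == "GDM")
  n2 <- sum(grp == "control")
  if (n1 < 2 || n2 < 2) {
    abort("fit_gene_models: both groups need at least 2 samples (got %d GDM, %d control)",
          n1, n2)
  }
  x1 <- expr$values[, grp == "GDM", drop = FALSE]
  x2 <- expr$values[, grp == "control", drop = FALSE]
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  rss <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
  df <- n1 + n2 - 2
  s2 <- rss / df
  list(log2_fc = m1 - m2, s2 = s2,
       se = sqrt(s2 * (1 / n1 + 1 / n2)),
       df_residual = df, n1 = n1, n2 = n2)
}

#' Estimate empirical-Bayes variance prior
#'
#' Moment matching on `log(s2)`: under the hierarchical model the excess
#' of `var(log s2)` over `trigamma(df/2)` equals `trigamma(d0/2)`, solved
#' for the prior degrees of freedom `d0` by monotone bisection; the prior
#' variance `s0_sq` then follows from the mean of `log(s2)`. When the
#' dispersion of `log(s2)` does not exceed `trigamma(df/2)`, the prior is
#' degenerate: `d0 = Inf` and `s0_sq` is the (geometric-mean based) common
#' variance.
#'
#' @param s2 Gene-wise residual variances (zeros are ignored for
#'   estimation; at least two must be positive).
#' @param df_residual Residual degrees of freedom shared by all genes.
#' @param tol Bisection tolerance on the moment equation.
#' @return A list with `d0` (prior df, possibly `Inf`) and `s0_sq`.
#' @export
estimate_ebayes <- function(s2, df_residual, tol = 1e-10) {
  s2p <- s2[is.finite(s2) & s2 > 0]
  if (length(s2p) < 2) {
    abort("estimate_ebayes: need at least 2 genes with positive variance")
  }
  df <- df_residual
  if (stats::sd(s2p) == 0) {
    ## degenerate: no dispersion at all, the common value is the prior
    return(list(d0 = Inf, s0_sq = s2p[1]))
  }
  z <- log(s2p)
  e <- z - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  target <- stats::var(e) - trigamma(df / 2)
  if (!is.finite(target) || target <= 0) {
    return(list(d0 = Inf, s0_sq = exp(ebar)))
  }
  ## solve trigamma(d0/2) = target; trigamma is strictly decreasing
  lo <- 1e-8
  hi <- 1e8
  if (trigamma(lo / 2) < target) return(list(d0 = lo, s0_sq = NA_real_))
  if (trigamma(hi / 2) > target) return(list(d0 = Inf, s0_sq = exp(ebar)))
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (trigamma(mid / 2) > target) lo <- mid else hi <- mid
    if (abs(trigamma(mid / 2) - target) < tol && (hi - lo) < tol * mid) break
  }
  d0 <- sqrt(lo * hi)
  s0_sq <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

#' Moderated t-statistics and the DEG table
#'
#' Shrinks each gene's variance to
#' `s2_tilde = (d0 * s0_sq + df * s2) / (d0 + df)` (equal to `s0_sq` when
#' `d0 = Inf`, and to `s2` when `d0 = 0`), forms
#' `t_mod = log2_fc / (s_tilde * sqrt(1/n1 + 1/n2))` and a two-sided
#' p-value from a t distribution on `d0 + df` degrees of freedom (normal
#' when `d0 = Inf`).
#'
#' @param fit Output of [fit_gene_models()].
#' @param params Output of [estimate_ebayes()] (or a list with `d0`,
#'   `s0_sq`).
#' @param alpha Significance threshold for the `significant` column.
#' @return A data frame with columns `gene`, `log2_fc`, `s2`, `s2_post`,
#'   `t_mod`, `df_total`, `p`, `direction` (`up_in_GDM` iff
#'   `log2_fc > 0`), `significant` (`p < alpha`).
#' @export
moderated_t <- function(fit, params, alpha = 0.05) {
  d0 <- params$d0
  s0 <- params$s0_sq
  df <- fit$df_residual
  s2_post <- if (is.infinite(d0)) {
    rep(s0, length(fit$s2))
  } else if (d0 == 0) {
    fit$s2
  } else {
    (d0 * s0 + df * fit$s2) / (d0 + df)
  }
  denom <- sqrt(s2_post * (1 / fit$n1 + 1 / fit$n2))
  t_mod <- ifelse(denom > 0, fit$log2_fc / denom, 0)
  df_total <- d0 + df
  p <- if (is.infinite(df_total)) {
    2 * stats::pnorm(-abs(t_mod))
  } else {
    2 * stats::pt(-abs(t_mod), df = df_total)
  }
  data.frame(
    gene = names(fit$log2_fc),
    log2_fc = unname(fit$log2_fc),
    s2 = unname(fit$s2),
    s2_post = unname(s2_post),
    t_mod = unname(t_mod),
    df_total = df_total,
    p = unname(p),
    direction = ifelse(fit$log2_fc > 0, "up_in_GDM", "up_in_control"),
    significant = unname(p) < alpha,
    stringsAsFactors = FALSE
  )
}

#' Screen differentially expressed genes
#'
#' Runs the full moderated-t pipeline: per-gene linear fits, empirical-
#' Bayes prior estimation, moderated statistics and the raw-p significance
#' call at `alpha` (no multiple-testing correction: the screen's threshold
#' is the raw p-value).
#'
#' @inheritParams fit_gene_models
#' @inheritParams moderated_t
#' @return The [moderated_t()] data frame, with the estimated prior
#'   attached as attribute `ebayes`.
#' @export
deg_screen <- function(expr, alpha = 0.05) {
  fit <- fit_gene_models(expr)
  params <- estimate_ebayes(fit$s2, fit$df_residual)
  tab <- moderated_t(fit, params, alpha = alpha)
  attr(tab, "ebayes") <- params
  tab
}
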