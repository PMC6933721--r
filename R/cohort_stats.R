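## Baseline-characteristics statistics: pooled two-sample t-tests computed
## either from raw data or directly from printed summary statistics
## (mean, SD, n per group), and Pearson chi-square tests on contingency
## tables with the Yates continuity correction for 2x2 tables.

#' Summary statistics of one group
#'
#' @param x Numeric vector, or leave `x` missing and give `mean`, `sd`,
#'   `n` directly (e.g. transcribed from a published table).
#' @param mean,sd,n Explicit summary values.
#' @return A list of class `summary_stat` with `mean`, `sd`, `n`.
#' @export
summary_stat <- function(x = NULL, mean = NULL, sd = NULL, n = NULL) {
  if (!is.null(x)) {
    mean <- base::mean(x)
    sd <- stats::sd(x)
    n <- length(x)
  }
  if (is.null(mean) || is.null(sd) || is.null(n)) {
    abort("summary_stat: provide x, or mean, sd and n")
  }
  if (n < 2 || sd < 0) abort("summary_stat: need n >= 2 and sd >= 0")
  structure(list(mean = mean, sd = sd, n = n), class = "summary_stat")
}

#' Two-sample t-test from summary statistics
#'
#' Pooled-variance (Student) test by default:
#' `sp2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)`,
#' `t = (m1 - m2) / sqrt(sp2 (1/n1 + 1/n2))` on `n1 + n2 - 2` degrees of
#' freedom, two-sided. With `welch = TRUE` the unpooled statistic with
#' Welch-Satterthwaite degrees of freedom is used instead. Both SDs zero
#' with equal means gives `t = 0, p = 1` by convention; both SDs zero with
#' different means is undefined.
#'
#' @param a,b [summary_stat()] objects (or lists with `mean`, `sd`, `n`).
#' @param welch Use the Welch (unequal-variance) form.
#' @return A list with `t`, `df`, `p`.
#' @export
t_test_summary <- function(a, b, welch = FALSE) {
  m1 <- a$mean; s1 <- a$sd; n1 <- a$n
  m2 <- b$mean; s2 <- b$sd; n2 <- b$n
  if (s1 == 0 && s2 == 0) {
    if (m1 == m2) return(list(t = 0, df = n1 + n2 - 2, p = 1))
    abort("t_test_summary: zero variance in both groups with unequal means")
  }
  if (welch) {
    v1 <- s1^2 / n1
    v2 <- s2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  t <- (m1 - m2) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df = df))
}

#' Pearson chi-square test on a contingency table
#'
#' `X2 = sum (O - E)^2 / E` on `(r - 1)(c - 1)` degrees of freedom. With
#' `yates = TRUE` and a 2x2 table, `|O - E|` is reduced by 0.5 (floored at
#' 0) before squaring.
#'
#' @param table Integer matrix of counts (at least 2x2).
#' @param yates Apply the continuity correction to 2x2 tables.
#' @return A list with `statistic`, `df`, `p`.
#' @export
chi_square <- function(table, yates = TRUE) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2) {
    abort("chi_square: table must be at least 2x2")
  }
  if (any(table < 0)) abort("chi_square: negative counts")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("chi_square: zero row or column margin")
  }
  correct <- yates && nrow(table) == 2 && ncol(table) == 2
  res <- suppressWarnings(stats::chisq.test(table, correct = correct))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value))
}

#' Baseline-characteristics report
#'
#' Per continuous variable: group mean (SD) and the pooled two-sample
#' t-test p-value. Per categorical variable: per-group counts and the
#' chi-square p-value (Yates-corrected for 2x2 tables). Variables missing
#' from the metadata are listed as not computable.
#'
#' @param metadata Data frame with a grouping column plus the declared
#'   variables.
#' @param continuous,categorical Character vectors of variable names.
#' @param group Name of the grouping column (must have exactly 2 levels).
#' @param welch Use Welch t-tests instead of pooled.
#' @return A data frame with one row per variable: `variable`, `type`,
#'   `group1`, `group2` (formatted summaries), `p`, `computable`.
#' @export
build_table1 <- function(metadata, continuous = character(),
                         categorical = character(), group = "condition",
                         welch = FALSE) {
  if (!group %in% colnames(metadata)) {
    abort("build_table1: grouping column '%s' missing", group)
  }
  levels_ <- unique(metadata[[group]])
  levels_ <- if (setequal(levels_, c("GDM", "control"))) {
    c("GDM", "control")
  } else {
    sort(levels_)
  }
  if (length(levels_) != 2) {
    abort("build_table1: need exactly 2 groups (found %d)", length(levels_))
  }
  in1 <- metadata[[group]] == levels_[1]
  rows <- list()
  for (v in continuous) {
    if (!v %in% colnames(metadata)) {
      rows[[v]] <- data.frame(variable = v, type = "continuous",
                              group1 = NA, group2 = NA, p = NA_real_,
                              computable = FALSE, stringsAsFactors = FALSE)
      next
    }
    x1 <- metadata[[v]][in1]
    x2 <- metadata[[v]][!in1]
    tt <- t_test_summary(summary_stat(x1), summary_stat(x2), welch = welch)
    rows[[v]] <- data.frame(
      variable = v, type = "continuous",
      group1 = sprintf("%.3f (%.3f)", mean(x1), stats::sd(x1)),
      group2 = sprintf("%.3f (%.3f)", mean(x2), stats::sd(x2)),
      p = tt$p, computable = TRUE, stringsAsFactors = FALSE)
  }
  for (v in categorical) {
    if (!v %in% colnames(metadata)) {
      rows[[v]] <- data.frame(variable = v, type = "categorical",
                              group1 = NA, group2 = NA, p = NA_real_,
                              computable = FALSE, stringsAsFactors = FALSE)
      next
    }
    tab <- table(metadata[[v]], metadata[[group]])[, levels_, drop = FALSE]
    ct <- chi_square(tab, yates = TRUE)
    fmt <- function(cnt) paste(sprintf("%s:%d (%.1f%%)", rownames(tab), cnt,
                                       100 * cnt / sum(cnt)), collapse = ", ")
    rows[[v]] <- data.frame(
      variable = v, type = "categorical",
      group1 = fmt(tab[, 1]), group2 = fmt(tab[, 2]),
      p = ct$p, computable = TRUE, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "groups") <- levels_
  rownames(out) <- NULL
  out
}
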