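#' Row-wise unpaired Student's t-test
#'
#' Two-sided, equal-variance (pooled) t-test of each matrix row between two
#' sample groups; Welch's unequal-variance form available via `var_equal`.
#' Rows with zero pooled variance get p = 1 when the group means are equal
#' and p = 0 when they differ (infinite t).
#'
#' @param m numeric matrix, features x samples.
#' @param group1,group2 column indices (or names) of the two groups.
#' @param var_equal use the pooled-variance Student form (default) or Welch.
#' @return data frame with columns `t_stat`, `df`, `p_value`, one row per
#'   feature.
#' @export
row_ttest <- function(m, group1, group2, var_equal = TRUE) {
  x <- m[, group1, drop = FALSE]
  y <- m[, group2, drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  if (n1 < 2L || n2 < 2L) stop("need >= 2 samples per group")
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (n1 - 1)
  vy <- rowSums((y - my)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * vx + (n2 - 1) * vy) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, nrow(m))
  } else {
    se <- sqrt(vx / n1 + vy / n2)
    df <- (vx / n1 + vy / n2)^2 /
      ((vx / n1)^2 / (n1 - 1) + (vy / n2)^2 / (n2 - 1))
    df[!is.finite(df)] <- n1 + n2 - 2
  }
  t_stat <- (mx - my) / se
  p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  degenerate <- se == 0
  if (any(degenerate)) {
    eq <- degenerate & (mx == my)
    t_stat[eq] <- 0; p[eq] <- 1
    t_stat[degenerate & !eq] <- sign(mx - my)[degenerate & !eq] * Inf
    p[degenerate & !eq] <- 0
  }
  data.frame(t_stat = t_stat, df = df, p_value = p, row.names = rownames(m))
}

#' Differential expression between tumor and normal samples
#'
#' Screens every mRNA and miRNA with an unpaired Student's t-test plus a fold
#' change criterion. Fold change is computed on the linear scale as
#' `log2((mean_tumor + pseudo) / (mean_normal + pseudo))` (or as a mean
#' difference when the bundle is log2 or `fc_on_log = TRUE`). p-values are
#' corrected by Benjamini-Hochberg separately within the mRNA and miRNA sets,
#' and a feature is called differential when all three conditions hold:
#' `fdr < fdr_threshold`, `|log2fc| > lfc_threshold`, `p < p_threshold`.
#'
#' @param bundle an [expression_bundle()].
#' @param fdr_threshold FDR cutoff (default 0.01).
#' @param lfc_threshold absolute log2 fold-change cutoff (default 2).
#' @param p_threshold raw p-value cutoff (default 0.05).
#' @param var_equal pooled-variance Student's t (default) vs Welch.
#' @param fc_on_log compute fold change as difference of means of
#'   log2-transformed data instead of the linear-scale ratio.
#' @param pseudocount added to both group means before the ratio to guard
#'   against division by zero (default 1e-9).
#' @return data frame with one row per feature: `feature`, `kind`, `log2fc`,
#'   `t_stat`, `p_value`, `fdr`, `is_differential`.
#' @export
compute_differential <- function(bundle, fdr_threshold = 0.01,
                                 lfc_threshold = 2, p_threshold = 0.05,
                                 var_equal = TRUE, fc_on_log = FALSE,
                                 pseudocount = 1e-9) {
  stopifnot(inherits(bundle, "ExpressionBundle"),
            fdr_threshold > 0, lfc_threshold > 0, p_threshold > 0)
  tumor <- which(bundle$phenotype == "tumor")
  normal <- which(bundle$phenotype == "normal")
  if (length(tumor) < 2L || length(normal) < 2L)
    stop("both phenotype groups must have >= 2 samples")
  per_kind <- function(m, kind) {
    tt <- row_ttest(m, tumor, normal, var_equal = var_equal)
    if (bundle$is_log2 || fc_on_log) {
      mlog <- if (bundle$is_log2) m else log2(m + pseudocount)
      lfc <- rowMeans(mlog[, tumor, drop = FALSE]) -
        rowMeans(mlog[, normal, drop = FALSE])
    } else {
      lfc <- log2((rowMeans(m[, tumor, drop = FALSE]) + pseudocount) /
                  (rowMeans(m[, normal, drop = FALSE]) + pseudocount))
    }
    data.frame(feature = rownames(m), kind = kind, log2fc = lfc,
               t_stat = tt$t_stat, p_value = tt$p_value,
               fdr = stats::p.adjust(tt$p_value, method = "BH"),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- rbind(per_kind(bundle$mrna, "mRNA"), per_kind(bundle$mirna, "miRNA"))
  out$is_differential <- out$fdr < fdr_threshold &
    abs(out$log2fc) > lfc_threshold & out$p_value < p_threshold
  out
}

#' Raw differential p-values as a lookup vector
#' @param diff result of [compute_differential()].
#' @return named numeric vector, feature id to raw t-test p-value.
#' @export
differential_p_lookup <- function(diff) {
  stats::setNames(diff$p_value, diff$feature)
}
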