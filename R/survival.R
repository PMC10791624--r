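#' Stratify samples by K-means on target-gene expression
#'
#' Standardizes each feature across samples and clusters the samples with
#' k-means (multiple restarts, seeded, so the assignment is deterministic
#' given the seed).
#'
#' @param expr_targets numeric matrix, target features x samples.
#' @param k number of clusters (default 2).
#' @param seed integer seed for the restarts.
#' @param n_init number of random restarts (default 10).
#' @return integer vector of cluster labels (1..k) named by sample.
#' @export
stratify_kmeans <- function(expr_targets, k = 2, seed = 1, n_init = 10) {
  stopifnot(is.matrix(expr_targets), nrow(expr_targets) >= 1)
  n <- ncol(expr_targets)
  if (n < k) stop("fewer samples than clusters")
  z <- t(scale(t(expr_targets)))
  z[!is.finite(z)] <- 0
  x <- t(z)  # samples x features
  attr(x, "scaled:center") <- attr(x, "scaled:scale") <- NULL
  if (all(stats::dist(x) == 0)) stop("degenerate clustering: all samples identical")
  if (n == k)  # kmeans requires n > k; with n == k each sample is its own group
    return(stats::setNames(seq_len(n), colnames(expr_targets)))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  km <- stats::kmeans(x, centers = k, nstart = n_init, iter.max = 100)
  stats::setNames(km$cluster, colnames(expr_targets))
}

#' Two-group log-rank test
#'
#' Standard two-group log-rank chi-square statistic on 1 degree of freedom
#' (via [survival::survdiff()]) with its upper-tail chi-square p-value.
#' When no event occurs in either group the statistic is 0 and p is 1, with
#' a warning.
#'
#' @param times follow-up times.
#' @param events event indicators (1 = event, 0 = censored).
#' @param groups two-level group labels.
#' @return list with `statistic` and `p`.
#' @export
logrank_test <- function(times, events, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2L)
    stop("log-rank test needs exactly 2 non-empty groups")
  if (sum(events) == 0) {
    warning("no events in either group: log-rank statistic 0")
    return(list(statistic = 0, p = 1))
  }
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  stat <- sd$chisq
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Survival stratification of a drug combination's target signature
#'
#' Clusters tumor samples into two groups by k-means on the standardized
#' log2 expression of the combination's targets (log2 stabilizes the
#' heavy right tail of linear-scale abundances, which otherwise dominates
#' the clustering), orients the groups so that
#' `high_risk` is the one with the smaller median survival (Kaplan-Meier
#' median; ties broken toward group 1), and tests the survival difference
#' with the log-rank test.
#'
#' @param bundle an `ExpressionBundle`.
#' @param surv a `SurvivalTable` covering (a subset of) the tumor samples.
#' @param target_features feature ids (mRNA and/or miRNA) to cluster on;
#'   ids absent from the bundle are dropped.
#' @param seed seed for [stratify_kmeans()].
#' @param n_init k-means restarts.
#' @return object of class `SurvivalSplit`: list with `groups` (named
#'   `"high_risk"`/`"low_risk"` per sample), `logrank_stat`, `p_value`,
#'   `median_survival` (per group) and `km` (data frame of Kaplan-Meier
#'   curves: group, time, n_risk, surv).
#' @export
survival_split <- function(bundle, surv, target_features, seed = 1,
                           n_init = 10) {
  stopifnot(inherits(bundle, "ExpressionBundle"),
            inherits(surv, "SurvivalTable"))
  tumor <- bundle_samples(bundle)[bundle$phenotype == "tumor"]
  samples <- intersect(surv$sample, tumor)
  if (length(samples) < 4L) stop("need at least 4 tumor samples with survival data")
  expr <- bundle_matrix(bundle)
  if (!bundle$is_log2) expr <- log2(expr + 1e-9)
  feats <- intersect(unique(target_features), rownames(expr))
  if (length(feats) == 0L) stop("no target feature present in the expression data")
  cl <- stratify_kmeans(expr[feats, samples, drop = FALSE], k = 2,
                        seed = seed, n_init = n_init)
  st <- surv[match(samples, surv$sample), , drop = FALSE]
  fit <- survival::survfit(survival::Surv(st$time, st$event) ~ cl)
  med <- summary(fit)$table[, "median"]
  med[is.na(med)] <- Inf  # median never reached
  high <- if (med[1L] <= med[2L]) 1L else 2L
  labels <- ifelse(cl == high, "high_risk", "low_risk")
  lr <- logrank_test(st$time, st$event, labels)
  km <- data.frame(group = rep(ifelse(seq_along(fit$strata) == high,
                                      "high_risk", "low_risk"),
                               fit$strata),
                   time = fit$time, n_risk = fit$n.risk, surv = fit$surv,
                   stringsAsFactors = FALSE)
  structure(list(groups = stats::setNames(labels, samples),
                 logrank_stat = lr$statistic, p_value = lr$p,
                 median_survival = stats::setNames(
                   as.numeric(med[c(high, setdiff(1:2, high))]),
                   c("high_risk", "low_risk")),
                 km = km),
            class = "SurvivalSplit")
}

#' @export
print.SurvivalSplit <- function(x, ...) {
  cat(sprintf("SurvivalSplit: %d high-risk / %d low-risk samples, log-rank chi^2 = %.3f, p = %.3g\n",
              sum(x$groups == "high_risk"), sum(x$groups == "low_risk"),
              x$logrank_stat, x$p_value))
  invisible(x)
}
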