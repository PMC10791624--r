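#' Weighted co-expression adjacency
#'
#' Soft-thresholded correlation network: `|cor|^power` (unsigned) or
#' `((1 + cor)/2)^power` (signed). Constant features get zero correlation to
#' everything (with a warning); the diagonal is 1.
#'
#' @param expr_sub numeric matrix, features x samples.
#' @param power soft-threshold exponent, >= 1.
#' @param signed use the signed transform.
#' @return symmetric adjacency matrix with unit diagonal.
#' @export
build_adjacency <- function(expr_sub, power = 6, signed = FALSE) {
  stopifnot(is.matrix(expr_sub), ncol(expr_sub) >= 3, power >= 1)
  sds <- apply(expr_sub, 1L, stats::sd)
  if (any(sds == 0))
    warning(sum(sds == 0), " constant feature(s): correlations set to 0")
  cc <- suppressWarnings(stats::cor(t(expr_sub)))
  cc[!is.finite(cc)] <- 0
  a <- if (signed) ((1 + cc) / 2)^power else abs(cc)^power
  diag(a) <- 1
  a
}

#' Scale-free topology fit of a connectivity distribution
#'
#' Bins the connectivities, regresses log10 frequency on log10 mean
#' connectivity, and returns the R-squared of the fit (0 when the slope is
#' positive, i.e. not scale-free-like).
#'
#' @param k numeric vector of node connectivities.
#' @param n_breaks number of bins.
#' @return R-squared in `[0, 1]`.
#' @export
scale_free_fit <- function(k, n_breaks = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 3L) return(0)
  bins <- cut(k, breaks = n_breaks)
  freq <- tapply(k, bins, length)
  mean_k <- tapply(k, bins, mean)
  ok <- !is.na(freq) & freq > 0
  if (sum(ok) < 3L) return(0)
  fit <- stats::lm(log10(freq[ok] / sum(freq[ok])) ~ log10(mean_k[ok]))
  r2 <- summary(fit)$r.squared
  if (stats::coef(fit)[2L] >= 0) 0 else r2
}

#' Choose the soft-threshold power
#'
#' Smallest candidate power whose network connectivity distribution reaches
#' the scale-free fit target; falls back to 6 (with a warning) when none does.
#' Powers that shrink the network's mean connectivity below `min_mean_k` are
#' not eligible: a high enough power makes any network trivially sparse
#' (which can masquerade as scale-free) while leaving nothing to cluster.
#'
#' @param expr_sub features x samples matrix.
#' @param candidate_powers powers to try, in increasing order.
#' @param target_r2 scale-free fit R-squared to reach (default 0.8).
#' @param min_mean_k minimum mean connectivity an eligible power must retain
#'   (default 1).
#' @param signed passed to [build_adjacency()].
#' @return list with `power`, `fit_r2` (per candidate) and `reached_target`.
#' @export
pick_soft_power <- function(expr_sub, candidate_powers = 1:20,
                            target_r2 = 0.8, min_mean_k = 1, signed = FALSE) {
  stopifnot(length(candidate_powers) >= 1)
  cc <- suppressWarnings(stats::cor(t(expr_sub)))
  cc[!is.finite(cc)] <- 0
  base <- if (signed) (1 + cc) / 2 else abs(cc)
  diag(base) <- 0
  ks <- lapply(candidate_powers, function(p) rowSums(base^p))
  fits <- vapply(ks, scale_free_fit, numeric(1))
  names(fits) <- candidate_powers
  mean_k <- vapply(ks, mean, numeric(1))
  hit <- which(fits >= target_r2 & mean_k >= min_mean_k)
  if (length(hit)) {
    list(power = candidate_powers[hit[1L]], fit_r2 = fits, reached_target = TRUE)
  } else {
    warning("no candidate power reached scale-free fit R^2 >= ", target_r2,
            "; falling back to power 6")
    list(power = 6, fit_r2 = fits, reached_target = FALSE)
  }
}

#' Topological overlap similarity
#'
#' Unsigned TOM of an adjacency matrix:
#' `TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with `L = A^2`
#' restricted to off-diagonal terms and `k` the connectivity. Diagonal is 1.
#'
#' @param adjacency symmetric matrix in `[0, 1]` with unit diagonal.
#' @return TOM similarity matrix in `[0, 1]`.
#' @export
tom_similarity <- function(adjacency) {
  stopifnot(is.matrix(adjacency), nrow(adjacency) == ncol(adjacency))
  a <- adjacency
  diag(a) <- 0
  k <- rowSums(a)
  l <- a %*% a
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  tom
}

#' Detect co-expression modules from an adjacency matrix
#'
#' Computes TOM similarity, clusters 1 - TOM by average-linkage hierarchical
#' clustering, and cuts the dendrogram at a height placed a fraction
#' `cut_height` of the way between the lowest and highest merge heights.
#' Clusters smaller than `min_module_size` are pooled into the unassigned
#' "grey" set, as is everything when the merge heights carry no structure
#' (all equal).
#'
#' @param adjacency symmetric adjacency matrix with feature dimnames.
#' @param min_module_size smallest retained module (default 10).
#' @param cut_height relative cut position in `(0, 1)` between the first and
#'   last merge height (default 0.5, the midpoint of the dendrogram's merge
#'   range; module-internal merges happen low, between-module merges at the
#'   top, so a mid-range cut separates distinct blocks).
#' @return list of modules; each a list with `id` (`"M1"`, ... or `"grey"`)
#'   and `members` (character vector). The grey pool, if any, is last.
#' @export
detect_modules <- function(adjacency, min_module_size = 10, cut_height = 0.5) {
  stopifnot(is.matrix(adjacency), isTRUE(all.equal(adjacency, t(adjacency))))
  feats <- rownames(adjacency)
  if (is.null(feats)) feats <- paste0("f", seq_len(nrow(adjacency)))
  if (nrow(adjacency) < min_module_size)
    return(list(list(id = "grey", members = feats)))
  tom <- tom_similarity(adjacency)
  d <- stats::as.dist(1 - tom)
  hc <- stats::hclust(d, method = "average")
  h <- hc$height
  if (max(h) - min(h) < 1e-10) {
    labels <- rep(1L, length(feats))  # no structure in the tree
  } else {
    cut_at <- min(h) + cut_height * (max(h) - min(h))
    labels <- stats::cutree(hc, h = cut_at)
  }
  sizes <- table(labels)
  keep <- as.integer(names(sizes)[sizes >= min_module_size])
  # a single all-encompassing cluster carries no module structure either
  if (length(keep) == 1L && sizes[as.character(keep)] == length(feats) &&
      length(sizes) == 1L && max(h) - min(h) < 1e-10)
    keep <- integer(0)
  modules <- list()
  for (i in seq_along(keep))
    modules[[i]] <- list(id = paste0("M", i),
                         members = feats[labels == keep[i]])
  grey <- feats[!labels %in% keep]
  if (length(grey))
    modules[[length(modules) + 1L]] <- list(id = "grey", members = grey)
  modules
}

#' Module eigengenes and trait correlation
#'
#' The eigengene is the first principal component of the per-feature
#' standardized member submatrix, sign-oriented to correlate positively with
#' the mean standardized member expression. Each eigengene is correlated with
#' the phenotype (tumor = 1, normal = 0) by Pearson correlation with the
#' usual t-test p-value. The grey pool is passed through unscored.
#'
#' @param modules output of [detect_modules()].
#' @param expr_sub features x samples matrix covering all module members.
#' @param phenotype per-sample labels (`"tumor"`/`"normal"`), aligned with
#'   the columns of `expr_sub`.
#' @return the modules, each augmented with `eigengene`, `trait_r`, `trait_p`
#'   (grey: NA scores).
#' @export
module_trait <- function(modules, expr_sub, phenotype) {
  stopifnot(ncol(expr_sub) == length(phenotype))
  ph01 <- as.numeric(phenotype == "tumor")
  lapply(modules, function(mod) {
    if (identical(mod$id, "grey")) {
      mod$eigengene <- NULL; mod$trait_r <- NA_real_; mod$trait_p <- NA_real_
      return(mod)
    }
    sub <- expr_sub[mod$members, , drop = FALSE]
    z <- t(scale(t(sub)))
    z[!is.finite(z)] <- 0
    if (nrow(z) == 1L) {
      eg <- as.numeric(z)
    } else {
      sv <- La.svd(z, nu = 0, nv = 1)
      eg <- as.numeric(sv$vt[1L, ])
      if (stats::cor(eg, colMeans(z)) < 0) eg <- -eg
    }
    ct <- pearson_p(eg, ph01)
    mod$eigengene <- stats::setNames(eg, colnames(expr_sub))
    mod$trait_r <- ct$r
    mod$trait_p <- ct$p
    mod
  })
}

#' Extract risk mRNAs and miRNAs from trait-scored modules
#'
#' Keeps the module with the largest `|trait_r|` among those with
#' `trait_p < alpha` (mode `"top"`), or the union of all passing modules
#' (mode `"all-significant"`), and splits its members into mRNAs and miRNAs.
#'
#' @param modules output of [module_trait()].
#' @param feature_kind named vector mapping feature id to `"mRNA"`/`"miRNA"`
#'   (see [bundle_feature_kind()]).
#' @param alpha significance cutoff on the module-trait p-value (default 0.05).
#' @param mode `"top"` or `"all-significant"`.
#' @return list of class `RiskFactorSet` with `risk_mrnas`, `risk_mirnas`
#'   (sorted character vectors) and `selected_modules` (ids).
#' @export
extract_risk_factors <- function(modules, feature_kind, alpha = 0.05,
                                 mode = c("top", "all-significant")) {
  mode <- match.arg(mode)
  scored <- Filter(function(m) !identical(m$id, "grey") && is.finite(m$trait_r),
                   modules)
  passing <- Filter(function(m) m$trait_p < alpha, scored)
  if (length(passing) == 0L) {
    warning("no module significantly correlated with the phenotype")
    return(structure(list(risk_mrnas = character(0), risk_mirnas = character(0),
                          selected_modules = character(0)),
                     class = "RiskFactorSet"))
  }
  if (mode == "top") {
    r <- vapply(passing, function(m) abs(m$trait_r), numeric(1))
    passing <- passing[which.max(r)]
  }
  members <- sort(unique(unlist(lapply(passing, `[[`, "members"))))
  structure(list(
    risk_mrnas = members[feature_kind[members] == "mRNA"],
    risk_mirnas = members[feature_kind[members] == "miRNA"],
    selected_modules = vapply(passing, `[[`, character(1), "id")),
    class = "RiskFactorSet")
}
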