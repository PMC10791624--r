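#' Correlation strength of an interacting feature pair
#'
#' Combines the two features' differential-expression p-values and their
#' expression-correlation p-value into
#' `CS = -(ln p_a + ln p_b + ln p_ab)`. Inputs are clamped to
#' `[eps, 1]` so the score is finite and non-negative.
#'
#' @param p_a,p_b differential p-values of the two features.
#' @param p_ab p-value of their Pearson expression correlation.
#' @param eps lower clamp (default 1e-300).
#' @return non-negative correlation strength (vectorized).
#' @export
correlation_strength <- function(p_a, p_b, p_ab, eps = 1e-300) {
  vals <- cbind(p_a, p_b, p_ab)
  if (any(vals < 0 | vals > 1))
    stop("p-values must lie in [0, 1]")
  vals[vals < eps] <- eps
  unname(-(log(vals[, 1L]) + log(vals[, 2L]) + log(vals[, 3L])))
}

#' Pearson correlation with its t-test p-value
#'
#' `r` is the Pearson product-moment correlation; the two-sided p-value comes
#' from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#' A constant vector yields `r = 0, p = 1` by convention.
#'
#' @param x,y paired numeric vectors with at least 3 observations.
#' @return list with elements `r` and `p`.
#' @export
pearson_p <- function(x, y) {
  n <- length(x)
  stopifnot(n == length(y), n >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = 0, p = 1))
  r <- stats::cor(x, y)
  r <- max(-1, min(1, r))
  if (abs(r) == 1) return(list(r = r, p = 0))
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(abs(t_stat), n - 2, lower.tail = FALSE))
}

# normalize RiskPathway / ReconstructedPathway inputs to a named list of
# ReconstructedPathway objects
.as_recon_list <- function(pathways) {
  out <- lapply(pathways, function(p) {
    if (inherits(p, "RiskPathway")) p$pathway else p
  })
  names(out) <- vapply(out, function(p) p$base$id, character(1))
  out
}

# unique unordered cross-pathway interacting pairs between two reconstructed
# pathways: mRNA-mRNA pairs backed by a PPI edge, miRNA-mRNA pairs backed by
# a miRNA-target edge; self-pairs excluded. Returns data frame (a, b, kind).
.interacting_pairs <- function(rp_i, rp_j, network) {
  mr_i <- rp_i$base$mrna_nodes; mr_j <- rp_j$base$mrna_nodes
  mi_i <- rp_i$mirna_nodes; mi_j <- rp_j$mirna_nodes
  ppi <- network$ppi
  rows_mm <- NULL
  if (nrow(ppi)) {
    hit <- (ppi[, 1L] %in% mr_i & ppi[, 2L] %in% mr_j) |
           (ppi[, 1L] %in% mr_j & ppi[, 2L] %in% mr_i)
    if (any(hit))
      rows_mm <- cbind(ppi[hit, , drop = FALSE], "mRNA-mRNA")
  }
  mt <- network$mirna_targets
  rows_mt <- NULL
  if (nrow(mt)) {
    hit <- (mt[, 1L] %in% mi_i & mt[, 2L] %in% mr_j) |
           (mt[, 1L] %in% mi_j & mt[, 2L] %in% mr_i)
    if (any(hit))
      rows_mt <- cbind(mt[hit, , drop = FALSE], "miRNA-mRNA")
  }
  rows <- rbind(rows_mm, rows_mt)
  if (is.null(rows))
    return(data.frame(a = character(0), b = character(0), kind = character(0),
                      stringsAsFactors = FALSE))
  data.frame(a = rows[, 1L], b = rows[, 2L], kind = rows[, 3L],
             stringsAsFactors = FALSE)
}

#' Crosstalk between one pair of reconstructed pathways
#'
#' Enumerates the unique unordered feature pairs that span the two pathways
#' (one endpoint a member of each; self-pairs excluded) and carry an
#' interaction edge — a PPI edge for mRNA-mRNA pairs, a miRNA-target edge for
#' miRNA-mRNA pairs — and sums their correlation strengths
#' ([correlation_strength()]). The expression-correlation p-value of each
#' pair is computed with [pearson_p()] on the expression rows.
#'
#' @param rp_i,rp_j `ReconstructedPathway` (or `RiskPathway`) objects.
#' @param network an `InteractionNetwork`.
#' @param diff_p named vector of raw differential p-values
#'   ([differential_p_lookup()]).
#' @param expr combined features x samples expression matrix restricted to
#'   the samples over which correlations are computed.
#' @param cor_cache optional environment used to memoize per-pair Pearson
#'   p-values across calls.
#' @return list with `score` (the crosstalk sum), `pairs` (data frame with
#'   columns `a`, `b`, `kind`, `p_a`, `p_b`, `p_ab`, `cs`) and `n_skipped`
#'   (pairs dropped because a feature is absent from `expr` or `diff_p`).
#' @export
pathway_pair_crosstalk <- function(rp_i, rp_j, network, diff_p, expr,
                                   cor_cache = NULL) {
  pr <- .interacting_pairs(rp_i, rp_j, network)
  n_skip <- 0L
  if (nrow(pr)) {
    ok <- pr$a %in% rownames(expr) & pr$b %in% rownames(expr) &
      pr$a %in% names(diff_p) & pr$b %in% names(diff_p)
    n_skip <- sum(!ok)
    pr <- pr[ok, , drop = FALSE]
  }
  if (nrow(pr) == 0L) {
    empty <- data.frame(a = character(0), b = character(0), kind = character(0),
                        p_a = numeric(0), p_b = numeric(0), p_ab = numeric(0),
                        cs = numeric(0), stringsAsFactors = FALSE)
    return(list(score = 0, pairs = empty, n_skipped = n_skip))
  }
  p_ab <- vapply(seq_len(nrow(pr)), function(k) {
    key <- paste(sort(c(pr$a[k], pr$b[k])), collapse = "\r")
    if (!is.null(cor_cache) && !is.null(cor_cache[[key]]))
      return(cor_cache[[key]])
    p <- pearson_p(expr[pr$a[k], ], expr[pr$b[k], ])$p
    if (!is.null(cor_cache)) cor_cache[[key]] <- p
    p
  }, numeric(1))
  pr$p_a <- unname(diff_p[pr$a])
  pr$p_b <- unname(diff_p[pr$b])
  pr$p_ab <- p_ab
  pr$cs <- correlation_strength(pr$p_a, pr$p_b, pr$p_ab)
  list(score = sum(pr$cs), pairs = pr, n_skipped = n_skip)
}

#' Crosstalk network over all risk-pathway pairs
#'
#' Scores every unordered pair of risk pathways with
#' [pathway_pair_crosstalk()]; pairs without interacting features are kept
#' with score 0 and an empty contribution list.
#'
#' @param risk_pathways list of `RiskPathway` or `ReconstructedPathway`
#'   objects (at least 2 for a non-empty network).
#' @param network an `InteractionNetwork`.
#' @param diff_p named vector of raw differential p-values.
#' @param expr combined features x samples expression matrix (already
#'   restricted to the sample set correlations should use).
#' @return object of class `CrosstalkNetwork`: list with `pairs` (data frame
#'   `pathway_i`, `pathway_j`, `score`, `n_pairs`), `contributions` (data
#'   frame with per interacting pair columns `pathway_i`, `pathway_j`, `a`,
#'   `b`, `kind`, `p_a`, `p_b`, `p_ab`, `cs`), `pathways` (the reconstructed
#'   pathways) and `total_crosstalk`.
#' @export
build_crosstalk_network <- function(risk_pathways, network, diff_p, expr) {
  recon <- .as_recon_list(risk_pathways)
  ids <- names(recon)
  if (length(recon) < 2L) {
    warning("fewer than 2 risk pathways: empty crosstalk network")
    return(structure(list(
      pairs = data.frame(pathway_i = character(0), pathway_j = character(0),
                         score = numeric(0), n_pairs = integer(0)),
      contributions = data.frame(), pathways = recon, total_crosstalk = 0),
      class = "CrosstalkNetwork"))
  }
  cache <- new.env(parent = emptyenv())
  combos <- utils::combn(ids, 2L)
  pair_rows <- vector("list", ncol(combos))
  contrib <- vector("list", ncol(combos))
  for (k in seq_len(ncol(combos))) {
    i <- combos[1L, k]; j <- combos[2L, k]
    res <- pathway_pair_crosstalk(recon[[i]], recon[[j]], network, diff_p,
                                  expr, cor_cache = cache)
    pair_rows[[k]] <- data.frame(pathway_i = i, pathway_j = j,
                                 score = res$score, n_pairs = nrow(res$pairs),
                                 stringsAsFactors = FALSE)
    if (nrow(res$pairs))
      contrib[[k]] <- cbind(data.frame(pathway_i = i, pathway_j = j,
                                       stringsAsFactors = FALSE), res$pairs)
  }
  pairs <- do.call(rbind, pair_rows)
  contrib <- contrib[!vapply(contrib, is.null, logical(1))]
  contributions <- if (length(contrib)) do.call(rbind, contrib) else
    data.frame(pathway_i = character(0), pathway_j = character(0),
               a = character(0), b = character(0), kind = character(0),
               p_a = numeric(0), p_b = numeric(0), p_ab = numeric(0),
               cs = numeric(0), stringsAsFactors = FALSE)
  rownames(pairs) <- rownames(contributions) <- NULL
  structure(list(pairs = pairs, contributions = contributions,
                 pathways = recon, total_crosstalk = sum(pairs$score)),
            class = "CrosstalkNetwork")
}

#' @export
print.CrosstalkNetwork <- function(x, ...) {
  cat(sprintf("CrosstalkNetwork: %d pathways, %d pathway pairs, %d interacting feature pairs, total crosstalk %.4g\n",
              length(x$pathways), nrow(x$pairs), nrow(x$contributions),
              x$total_crosstalk))
  invisible(x)
}
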