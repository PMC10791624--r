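#' Upper-tail hypergeometric probability
#'
#' Over-representation p-value for drawing `m` or more marked items when `n`
#' items are drawn without replacement from a universe of `N` containing `M`
#' marked ones: `P(X >= m)` (tail `"ge"`, the default over-representation
#' convention) or the strict tail `P(X > m)` (`"gt"`). Computed through the
#' hypergeometric CDF in log space.
#'
#' @param N universe size.
#' @param M number of marked items in the universe.
#' @param n number of items drawn.
#' @param m observed overlap.
#' @param tail `"ge"` for `P(X >= m)` or `"gt"` for `P(X > m)`.
#' @return probability in `[0, 1]`.
#' @export
hypergeom_upper <- function(N, M, n, m, tail = c("ge", "gt")) {
  tail <- match.arg(tail)
  if (any(c(N, M, n, m) < 0) || M > N || n > N || m > min(M, n))
    stop("invalid hypergeometric parameters: N=", N, " M=", M, " n=", n, " m=", m)
  q <- if (tail == "ge") m - 1 else m
  # P(X >= q+1), exponentiated from the log CDF for numerical stability
  exp(stats::phyper(q, M, N - M, n, lower.tail = FALSE, log.p = TRUE))
}

#' Attach miRNAs to pathways by target over-representation
#'
#' For each (miRNA, pathway) pair, tests whether the miRNA's target mRNAs are
#' over-represented among the pathway's mRNAs with [hypergeom_upper()], using
#' `m` = targets inside the pathway, `n` = targets in the background,
#' `M` = pathway size and `N` = background size (all genome-wide mRNAs).
#' miRNAs with p below `alpha` are attached to the pathway, linked by edges
#' to their in-pathway target mRNAs only.
#'
#' @param pathways named list of [pathway_graph()] objects.
#' @param mirna_targets 2-column matrix of (miRNA id, target mRNA id) edges,
#'   or an `InteractionNetwork` (its `mirna_targets` slot is used).
#' @param background_mrnas character vector of all background mRNA ids
#'   (targets outside it are ignored).
#' @param alpha attachment threshold on the enrichment p-value (default 0.05).
#' @param tail passed to [hypergeom_upper()].
#' @return named list of `ReconstructedPathway` objects: each has `base`
#'   (the input `PathwayGraph`), `mirna_nodes`, `mirna_edges` (2-column
#'   matrix miRNA, target) and `enrichment_p` (named by miRNA).
#' @export
attach_mirnas <- function(pathways, mirna_targets, background_mrnas,
                          alpha = 0.05, tail = "ge") {
  if (inherits(mirna_targets, "InteractionNetwork"))
    mirna_targets <- mirna_targets$mirna_targets
  mirna_targets <- .as_edge_matrix(mirna_targets)
  background_mrnas <- unique(as.character(background_mrnas))
  N <- length(background_mrnas)
  if (any(vapply(pathways, function(p)
    length(intersect(p$mrna_nodes, background_mrnas)), integer(1)) > N))
    stop("background smaller than a pathway")
  by_mirna <- split(mirna_targets[, 2L], mirna_targets[, 1L])
  by_mirna <- lapply(by_mirna, function(tg) unique(intersect(tg, background_mrnas)))
  n_bg <- lengths(by_mirna)
  if (any(n_bg == 0L)) {
    message(sum(n_bg == 0L), " miRNA(s) with no background targets skipped")
    by_mirna <- by_mirna[n_bg > 0L]
  }
  mirna_ids <- sort(names(by_mirna))
  out <- lapply(pathways, function(p) {
    path_mrnas <- intersect(p$mrna_nodes, background_mrnas)
    M <- length(path_mrnas)
    attached <- character(0); pvals <- numeric(0)
    edges <- matrix(character(0), ncol = 2L)
    for (mi in mirna_ids) {
      tg <- by_mirna[[mi]]
      hits <- intersect(tg, path_mrnas)
      p_enr <- hypergeom_upper(N, M, length(tg), length(hits), tail = tail)
      if (p_enr < alpha && length(hits) > 0L) {
        attached <- c(attached, mi)
        pvals <- c(pvals, p_enr)
        edges <- rbind(edges, cbind(mi, sort(hits)))
      }
    }
    structure(list(base = p, mirna_nodes = attached,
                   mirna_edges = unname(edges),
                   enrichment_p = stats::setNames(pvals, attached)),
              class = "ReconstructedPathway")
  })
  names(out) <- names(pathways)
  out
}

#' All member features of a reconstructed pathway
#' @param rp a `ReconstructedPathway`.
#' @return character vector: member mRNAs followed by attached miRNAs.
#' @export
pathway_features <- function(rp) c(rp$base$mrna_nodes, rp$mirna_nodes)

#' @export
print.ReconstructedPathway <- function(x, ...) {
  cat(sprintf("ReconstructedPathway %s: %d mRNAs, %d attached miRNAs, %d miRNA-target edges\n",
              x$base$id, length(x$base$mrna_nodes), length(x$mirna_nodes),
              nrow(x$mirna_edges)))
  invisible(x)
}
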