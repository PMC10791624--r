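#' Identify risk pathways by risk-factor over-representation
#'
#' Tests every reconstructed pathway for over-representation of a cancer's
#' risk mRNAs and miRNAs with the cumulative hypergeometric test:
#' `M` = pathway mRNAs plus attached miRNAs, `n` = risk mRNAs plus risk
#' miRNAs, `m` = their overlap, `N` = background size (mRNAs + miRNAs of the
#' expression universe, since both kinds enter `M` and `n`). Pathways with
#' p below `alpha` are returned sorted by increasing p. No multiple-testing
#' correction is applied by default (raw p < 0.05 screening); set
#' `correct = TRUE` for BH on the pathway p-values.
#'
#' @param recon_pathways named list from [attach_mirnas()].
#' @param risk a `RiskFactorSet` from [extract_risk_factors()].
#' @param background_n background universe size; defaults to the number of
#'   distinct features across the pathways and risk set if `NULL` (callers
#'   should pass the expression universe size).
#' @param alpha retention threshold (default 0.05).
#' @param tail passed to [hypergeom_upper()].
#' @param correct apply BH to pathway p-values before thresholding.
#' @return list of `RiskPathway` objects, each with `pathway` (the
#'   `ReconstructedPathway`), `enrichment_p` and `overlap_features`; sorted
#'   ascending by p.
#' @export
identify_risk_pathways <- function(recon_pathways, risk, background_n = NULL,
                                   alpha = 0.05, tail = "ge", correct = FALSE) {
  stopifnot(length(recon_pathways) > 0)
  risk_features <- c(risk$risk_mrnas, risk$risk_mirnas)
  if (length(risk_features) == 0L) {
    warning("empty risk factor set: no risk pathways")
    return(list())
  }
  if (is.null(background_n))
    background_n <- length(unique(c(unlist(lapply(recon_pathways, pathway_features)),
                                    risk_features)))
  n <- length(risk_features)
  res <- lapply(recon_pathways, function(rp) {
    members <- pathway_features(rp)
    overlap <- intersect(members, risk_features)
    M <- length(members)
    p <- hypergeom_upper(background_n, M, n, length(overlap), tail = tail)
    list(pathway = rp, enrichment_p = p, overlap_features = sort(overlap))
  })
  pvals <- vapply(res, `[[`, numeric(1), "enrichment_p")
  if (correct) pvals <- stats::p.adjust(pvals, method = "BH")
  keep <- which(pvals < alpha)
  res <- res[keep][order(pvals[keep])]
  lapply(res, function(x) structure(x, class = "RiskPathway"))
}
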