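#' Remove drug-target features from reconstructed pathways
#'
#' Deletes the given mRNA/miRNA ids from every pathway's node sets and prunes
#' miRNA-target edges accordingly. With `cascade = TRUE`, an attached miRNA
#' whose in-pathway target mRNAs have all been removed is removed from that
#' pathway as well (applied to fixpoint; unknown ids are ignored).
#'
#' @param risk_pathways list of `RiskPathway` or `ReconstructedPathway`
#'   objects.
#' @param targets character vector of feature ids to remove.
#' @param cascade remove orphaned attached miRNAs (default `TRUE`).
#' @return named list of reduced `ReconstructedPathway` objects.
#' @export
remove_targets <- function(risk_pathways, targets, cascade = TRUE) {
  recon <- .as_recon_list(risk_pathways)
  targets <- unique(as.character(targets))
  lapply(recon, function(rp) {
    rp$base$mrna_nodes <- setdiff(rp$base$mrna_nodes, targets)
    if (!is.null(rp$base$internal_edges) && nrow(rp$base$internal_edges)) {
      keep <- rp$base$internal_edges[, 1L] %in% rp$base$mrna_nodes &
              rp$base$internal_edges[, 2L] %in% rp$base$mrna_nodes
      rp$base$internal_edges <- rp$base$internal_edges[keep, , drop = FALSE]
    }
    removed_mirna <- intersect(rp$mirna_nodes, targets)
    rp$mirna_nodes <- setdiff(rp$mirna_nodes, targets)
    if (nrow(rp$mirna_edges)) {
      keep <- rp$mirna_edges[, 1L] %in% rp$mirna_nodes &
              rp$mirna_edges[, 2L] %in% rp$base$mrna_nodes
      rp$mirna_edges <- rp$mirna_edges[keep, , drop = FALSE]
    }
    if (cascade && length(rp$mirna_nodes)) {
      # one pass reaches the fixpoint: removing a miRNA deletes no mRNA,
      # so no further miRNA can become orphaned
      orphaned <- setdiff(rp$mirna_nodes, rp$mirna_edges[, 1L])
      rp$mirna_nodes <- setdiff(rp$mirna_nodes, orphaned)
      removed_mirna <- union(removed_mirna, orphaned)
    }
    rp$enrichment_p <- rp$enrichment_p[rp$mirna_nodes]
    rp
  })
}

# per-pathway surviving feature sets (mRNAs and attached miRNAs combined)
# after target removal; mirrors remove_targets but returns only id sets
.surviving_features <- function(recon, targets, cascade) {
  lapply(recon, function(rp) {
    mr <- setdiff(rp$base$mrna_nodes, targets)
    mi <- setdiff(rp$mirna_nodes, targets)
    if (cascade && length(mi) && nrow(rp$mirna_edges)) {
      live <- rp$mirna_edges[rp$mirna_edges[, 2L] %in% mr, 1L]
      mi <- intersect(mi, live)
    } else if (cascade) {
      mi <- character(0)
    }
    c(mr, mi)
  })
}

#' Crosstalk network totals after removing a target set
#'
#' Recomputes every pathway-pair crosstalk score after deleting the targets
#' (and, with `cascade`, orphaned attached miRNAs). Because correlation
#' strengths of surviving pairs are unchanged by removal, the cached
#' contributions of the full network are reused: a contributing pair survives
#' iff its endpoints still span the two pathways.
#'
#' @param ct a `CrosstalkNetwork` from [build_crosstalk_network()].
#' @param targets feature ids removed by the drug(s).
#' @param cascade remove orphaned attached miRNAs.
#' @return list with `total` (crosstalk after removal) and `pairs` (the
#'   pair table with columns `score_before` and `score_after`).
#' @export
crosstalk_after_removal <- function(ct, targets, cascade = TRUE) {
  stopifnot(inherits(ct, "CrosstalkNetwork"))
  surv <- .surviving_features(ct$pathways, unique(as.character(targets)), cascade)
  co <- ct$contributions
  pairs <- ct$pairs
  after <- stats::setNames(numeric(nrow(pairs)),
                           paste(pairs$pathway_i, pairs$pathway_j, sep = "\r"))
  if (nrow(co)) {
    keep <- vapply(seq_len(nrow(co)), function(k) {
      si <- surv[[co$pathway_i[k]]]; sj <- surv[[co$pathway_j[k]]]
      (co$a[k] %in% si && co$b[k] %in% sj) ||
        (co$a[k] %in% sj && co$b[k] %in% si)
    }, logical(1))
    if (any(keep)) {
      kept <- co[keep, , drop = FALSE]
      agg <- tapply(kept$cs, paste(kept$pathway_i, kept$pathway_j, sep = "\r"), sum)
      after[names(agg)] <- agg
    }
  }
  out <- data.frame(pathway_i = pairs$pathway_i, pathway_j = pairs$pathway_j,
                    score_before = pairs$score, score_after = unname(after),
                    stringsAsFactors = FALSE)
  list(total = sum(out$score_after), pairs = out)
}

#' Destruction score of a target set
#'
#' `DS = 1 - Crosstalk_after / Crosstalk_before`: the fraction of total
#' risk-pathway crosstalk destroyed by removing the targets. Clipped to
#' `[0, 1]`.
#'
#' @param ct a `CrosstalkNetwork` with positive total crosstalk.
#' @param targets feature ids (mRNA and/or miRNA) removed.
#' @param cascade remove orphaned attached miRNAs (default `TRUE`).
#' @return list with `ds`, `crosstalk_before`, `crosstalk_after` and
#'   `affected_pairs` (pathway pairs whose score changed, with before/after).
#' @export
destruction_score <- function(ct, targets, cascade = TRUE) {
  if (ct$total_crosstalk <= 0)
    stop("no crosstalk to destroy: total crosstalk is 0")
  res <- crosstalk_after_removal(ct, targets, cascade)
  ds <- 1 - res$total / ct$total_crosstalk
  ds <- max(0, min(1, ds))
  changed <- res$pairs[res$pairs$score_after != res$pairs$score_before, ,
                       drop = FALSE]
  list(ds = ds, crosstalk_before = ct$total_crosstalk, crosstalk_after = res$total,
       affected_pairs = changed)
}

#' Screen single drugs by crosstalk destruction
#'
#' Computes the destruction score of every drug (all its mRNA and miRNA
#' targets removed at once) against the full crosstalk network and flags
#' drugs with `DS > ds_threshold` as single-therapy candidates.
#'
#' @param drug_map a `DrugTargetMap`.
#' @param ct a `CrosstalkNetwork`.
#' @param ds_threshold pass threshold on DS (default 0.01).
#' @param cascade remove orphaned attached miRNAs (default `TRUE`).
#' @return data frame sorted by decreasing `ds` with columns `drug`, `ds`,
#'   `n_targets`, `passes_single`.
#' @export
screen_single_drugs <- function(drug_map, ct, ds_threshold = 0.01,
                                cascade = TRUE) {
  stopifnot(inherits(drug_map, "DrugTargetMap"), length(drug_map) > 0)
  ids <- names(drug_map)
  ds <- vapply(ids, function(d)
    destruction_score(ct, drug_targets(drug_map, d), cascade)$ds, numeric(1))
  out <- data.frame(drug = ids,
                    ds = unname(ds),
                    n_targets = vapply(ids, function(d)
                      length(drug_targets(drug_map, d)), integer(1)),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$passes_single <- out$ds > ds_threshold
  out[order(-out$ds, out$drug), , drop = FALSE]
}

#' Screen drug pairs for superadditive crosstalk destruction
#'
#' Scores every unordered pair of passing drugs on the union of their target
#' sets and selects combinations whose joint destruction score is at least
#' (criterion `"ge"`, default) or strictly greater than (`"gt"`) the sum of
#' the single-drug scores. Note that without cascade removal the joint score
#' can never exceed the sum (crosstalk is a sum of non-negative pair terms),
#' so strict superadditivity arises only through orphaned-miRNA cascades.
#'
#' @param drug_scores output of [screen_single_drugs()] (only rows with
#'   `passes_single` are combined).
#' @param drug_map the `DrugTargetMap`.
#' @param ct the full `CrosstalkNetwork`.
#' @param criterion `"ge"` (joint >= sum, within `tol`) or `"gt"` (strict).
#' @param tol numerical tolerance on the comparison (default 1e-9).
#' @param cascade remove orphaned attached miRNAs (default `TRUE`).
#' @return data frame sorted by decreasing `ds_combo` with columns `drug1`,
#'   `drug2`, `ds1`, `ds2`, `ds_combo`, `synergy_margin`, `selected`, plus an
#'   attribute `"affected"`: a named list (`"drug1|drug2"`) of affected
#'   pathway-pair tables (crosstalk before/after the combined removal).
#' @export
optimize_combinations <- function(drug_scores, drug_map, ct,
                                  criterion = c("ge", "gt"), tol = 1e-9,
                                  cascade = TRUE) {
  criterion <- match.arg(criterion)
  passing <- drug_scores[drug_scores$passes_single, , drop = FALSE]
  if (nrow(passing) < 2L) {
    warning("fewer than 2 passing drugs: no combinations")
    out <- data.frame(drug1 = character(0), drug2 = character(0),
                      ds1 = numeric(0), ds2 = numeric(0),
                      ds_combo = numeric(0), synergy_margin = numeric(0),
                      selected = logical(0))
    attr(out, "affected") <- list()
    return(out)
  }
  ds_by_drug <- stats::setNames(passing$ds, passing$drug)
  combos <- utils::combn(sort(passing$drug), 2L)
  affected <- list()
  rows <- vector("list", ncol(combos))
  for (k in seq_len(ncol(combos))) {
    d1 <- combos[1L, k]; d2 <- combos[2L, k]
    union_targets <- unique(c(drug_targets(drug_map, d1),
                              drug_targets(drug_map, d2)))
    res <- destruction_score(ct, union_targets, cascade)
    margin <- res$ds - (ds_by_drug[[d1]] + ds_by_drug[[d2]])
    rows[[k]] <- data.frame(drug1 = d1, drug2 = d2,
                            ds1 = ds_by_drug[[d1]], ds2 = ds_by_drug[[d2]],
                            ds_combo = res$ds, synergy_margin = margin,
                            stringsAsFactors = FALSE)
    affected[[paste(d1, d2, sep = "|")]] <- res$affected_pairs
  }
  out <- do.call(rbind, rows)
  out$selected <- if (criterion == "ge") out$synergy_margin >= -tol else
    out$synergy_margin > tol
  out <- out[order(-out$ds_combo, out$drug1, out$drug2), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "affected") <- affected
  out
}
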