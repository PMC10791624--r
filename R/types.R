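#' Construct an expression bundle
#'
#' Container for matched mRNA and miRNA expression matrices over the same
#' samples, together with tumor/normal phenotype labels. Abundances are
#' linear-scale and non-negative unless `is_log2 = TRUE`.
#'
#' @param mrna numeric matrix, mRNA features x samples, rownames = feature ids,
#'   colnames = sample ids.
#' @param mirna numeric matrix, miRNA features x samples, same sample columns
#'   as `mrna` in the same order.
#' @param phenotype named character vector mapping sample id to
#'   `"tumor"`/`"normal"`; must cover all samples.
#' @param is_log2 logical; set to `TRUE` when the matrices are already on the
#'   log2 scale (disables the non-negativity requirement and downstream
#'   re-logging of fold changes).
#' @return An object of class `ExpressionBundle`: a list with elements
#'   `mrna`, `mirna`, `phenotype`, `is_log2`.
#' @export
expression_bundle <- function(mrna, mirna, phenotype, is_log2 = FALSE) {
  stopifnot(is.matrix(mrna), is.matrix(mirna))
  if (is.null(rownames(mrna)) || is.null(rownames(mirna)) ||
      is.null(colnames(mrna)) || is.null(colnames(mirna)))
    stop("expression matrices need feature rownames and sample colnames")
  if (!identical(colnames(mrna), colnames(mirna)))
    stop("mRNA and miRNA matrices must share identical, identically ordered sample columns")
  if (anyDuplicated(rownames(mrna)))
    stop("duplicate mRNA feature id: ", rownames(mrna)[duplicated(rownames(mrna))][1L])
  if (anyDuplicated(rownames(mirna)))
    stop("duplicate miRNA feature id: ", rownames(mirna)[duplicated(rownames(mirna))][1L])
  samples <- colnames(mrna)
  if (!all(samples %in% names(phenotype)))
    stop("phenotype missing for sample: ", setdiff(samples, names(phenotype))[1L])
  phenotype <- phenotype[samples]
  if (!all(phenotype %in% c("tumor", "normal")))
    stop("phenotype labels must be 'tumor' or 'normal'")
  if (sum(phenotype == "tumor") < 2L || sum(phenotype == "normal") < 2L)
    stop("need at least 2 samples per phenotype group")
  if (!is_log2 && (min(mrna) < 0 || min(mirna) < 0))
    stop("negative abundance in linear-scale expression matrix")
  structure(list(mrna = mrna, mirna = mirna, phenotype = phenotype,
                 is_log2 = is_log2),
            class = "ExpressionBundle")
}

#' @export
print.ExpressionBundle <- function(x, ...) {
  cat(sprintf("ExpressionBundle: %d mRNAs, %d miRNAs, %d samples (%d tumor / %d normal)%s\n",
              nrow(x$mrna), nrow(x$mirna), ncol(x$mrna),
              sum(x$phenotype == "tumor"), sum(x$phenotype == "normal"),
              if (x$is_log2) ", log2 scale" else ""))
  invisible(x)
}

#' Samples of an expression bundle
#' @param bundle an `ExpressionBundle`.
#' @return character vector of sample ids.
#' @export
bundle_samples <- function(bundle) colnames(bundle$mrna)

#' Combined feature matrix of a bundle
#'
#' Stacks the mRNA and miRNA matrices into one features x samples matrix.
#' @param bundle an `ExpressionBundle`.
#' @return numeric matrix with all features as rows.
#' @export
bundle_matrix <- function(bundle) rbind(bundle$mrna, bundle$mirna)

#' Feature kinds of a bundle
#' @param bundle an `ExpressionBundle`.
#' @return named character vector (`"mRNA"`/`"miRNA"`) over all feature ids.
#' @export
bundle_feature_kind <- function(bundle) {
  kinds <- c(rep("mRNA", nrow(bundle$mrna)), rep("miRNA", nrow(bundle$mirna)))
  names(kinds) <- c(rownames(bundle$mrna), rownames(bundle$mirna))
  kinds
}

# canonicalize an undirected 2-column edge matrix: sort endpoints within each
# row, drop self-loops and duplicates; returns character matrix with 2 columns
.canon_undirected <- function(edges, warn_self = TRUE) {
  edges <- .as_edge_matrix(edges)
  if (nrow(edges) == 0L) return(edges)
  self <- edges[, 1L] == edges[, 2L]
  if (any(self)) {
    if (warn_self) warning(sum(self), " self-loop edge(s) skipped")
    edges <- edges[!self, , drop = FALSE]
  }
  if (nrow(edges) == 0L) return(edges)
  flip <- edges[, 1L] > edges[, 2L]
  edges[flip, ] <- edges[flip, c(2L, 1L), drop = FALSE]
  edges[!duplicated(paste(edges[, 1L], edges[, 2L], sep = "\r")), , drop = FALSE]
}

.as_edge_matrix <- function(edges) {
  if (is.data.frame(edges)) edges <- as.matrix(edges[, 1:2])
  if (is.null(edges) || length(edges) == 0L)
    return(matrix(character(0), ncol = 2L))
  storage.mode(edges) <- "character"
  unname(edges[, 1:2, drop = FALSE])
}

#' Construct an interaction network
#'
#' Holds undirected protein-protein (mRNA-mRNA) edges and directed
#' miRNA-to-target-mRNA edges. PPI edges are stored orientation-free with
#' endpoints sorted; self-loops are dropped with a warning; both sets are
#' deduplicated.
#'
#' @param ppi_edges 2-column character matrix or data frame of mRNA id pairs.
#' @param mirna_target_edges 2-column character matrix or data frame,
#'   first column miRNA id, second column target mRNA id.
#' @return An object of class `InteractionNetwork` with elements `ppi`
#'   (2-column matrix, endpoints sorted) and `mirna_targets` (2-column matrix).
#' @export
interaction_network <- function(ppi_edges = NULL, mirna_target_edges = NULL) {
  ppi <- .canon_undirected(ppi_edges)
  mt <- .as_edge_matrix(mirna_target_edges)
  if (nrow(mt) > 0L) {
    self <- mt[, 1L] == mt[, 2L]
    if (any(self)) {
      warning(sum(self), " self-loop miRNA-target edge(s) skipped")
      mt <- mt[!self, , drop = FALSE]
    }
    mt <- mt[!duplicated(paste(mt[, 1L], mt[, 2L], sep = "\r")), , drop = FALSE]
  }
  structure(list(ppi = ppi, mirna_targets = mt), class = "InteractionNetwork")
}

#' @export
print.InteractionNetwork <- function(x, ...) {
  cat(sprintf("InteractionNetwork: %d PPI edges, %d miRNA-target edges\n",
              nrow(x$ppi), nrow(x$mirna_targets)))
  invisible(x)
}

#' Construct a pathway graph
#'
#' A pathway as an undirected graph: a set of member mRNAs and, optionally,
#' internal mRNA-mRNA edges among them.
#'
#' @param id pathway identifier, unique within a collection.
#' @param name human-readable pathway name.
#' @param mrna_nodes character vector of member mRNA ids.
#' @param internal_edges optional 2-column matrix of unordered mRNA pairs,
#'   endpoints must be members.
#' @return An object of class `PathwayGraph`.
#' @export
pathway_graph <- function(id, name = id, mrna_nodes, internal_edges = NULL) {
  mrna_nodes <- unique(as.character(mrna_nodes))
  if (!is.null(internal_edges)) {
    internal_edges <- .canon_undirected(internal_edges, warn_self = FALSE)
    bad <- setdiff(c(internal_edges), mrna_nodes)
    if (length(bad))
      stop("internal edge endpoint not a pathway member: ", bad[1L])
  }
  structure(list(id = as.character(id), name = as.character(name),
                 mrna_nodes = mrna_nodes, internal_edges = internal_edges),
            class = "PathwayGraph")
}

#' Construct a drug-target map
#'
#' @param drugs named list; each element a list with character vectors
#'   `mrna_targets` and `mirna_targets` (either may be empty, not both).
#' @return An object of class `DrugTargetMap` (named list).
#' @export
drug_target_map <- function(drugs) {
  stopifnot(is.list(drugs), !is.null(names(drugs)), !anyDuplicated(names(drugs)))
  out <- lapply(drugs, function(d) {
    mr <- unique(as.character(d$mrna_targets %||% character(0)))
    mi <- unique(as.character(d$mirna_targets %||% character(0)))
    if (length(mr) + length(mi) == 0L)
      stop("drug with no targets")
    list(mrna_targets = mr, mirna_targets = mi)
  })
  structure(out, class = "DrugTargetMap")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' All targets of a drug
#' @param drug_map a `DrugTargetMap`.
#' @param drug_id drug identifier (or several).
#' @return character vector: union of mRNA and miRNA targets of the drugs.
#' @export
drug_targets <- function(drug_map, drug_id) {
  unique(unlist(lapply(drug_map[drug_id], function(d)
    c(d$mrna_targets, d$mirna_targets)), use.names = FALSE))
}

#' Construct a survival table
#'
#' @param sample character vector of sample ids.
#' @param time non-negative follow-up times (days).
#' @param event event indicator, 1 = death observed, 0 = censored.
#' @return data frame of class `SurvivalTable` with columns
#'   `sample`, `time`, `event`.
#' @export
survival_table <- function(sample, time, event) {
  stopifnot(length(sample) == length(time), length(time) == length(event))
  if (any(time < 0)) stop("negative survival time")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  if (anyDuplicated(sample)) stop("duplicate sample in survival table")
  structure(data.frame(sample = as.character(sample), time = as.numeric(time),
                       event = as.integer(event), stringsAsFactors = FALSE),
            class = c("SurvivalTable", "data.frame"))
}
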