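#' Read matched expression matrices and phenotype labels
#'
#' Expression files are TSV with feature ids in the first column and a header
#' row of sample ids. The phenotype file is a 2-column TSV (sample, label)
#' with labels `tumor`/`normal`, with or without a header. The working cohort
#' is the intersection of the two matrices' samples (sorted); both matrices
#' are subset to it.
#'
#' @param path_mrna path to the mRNA expression TSV.
#' @param path_mirna path to the miRNA expression TSV.
#' @param path_phenotype path to the sample-to-label TSV.
#' @param is_log2 passed to [expression_bundle()].
#' @return An `ExpressionBundle`.
#' @export
read_expression <- function(path_mrna, path_mirna, path_phenotype,
                            is_log2 = FALSE) {
  mrna <- .read_matrix_tsv(path_mrna)
  mirna <- .read_matrix_tsv(path_mirna)
  common <- sort(intersect(colnames(mrna), colnames(mirna)))
  if (length(common) == 0L)
    stop("no common samples between mRNA and miRNA matrices (first mRNA sample: ",
         colnames(mrna)[1L], ")")
  ph <- utils::read.table(path_phenotype, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, col.names = c("sample", "label"))
  if (identical(tolower(ph$sample[1L]), "sample")) ph <- ph[-1L, , drop = FALSE]
  phenotype <- stats::setNames(ph$label, ph$sample)
  missing <- setdiff(common, names(phenotype))
  if (length(missing))
    stop("phenotype missing for sample: ", missing[1L])
  expression_bundle(mrna[, common, drop = FALSE], mirna[, common, drop = FALSE],
                    phenotype[common], is_log2 = is_log2)
}

.read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "", comment.char = "")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate feature id in ", path, ": ", ids[duplicated(ids)][1L])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1L, drop = FALSE], 2, as.numeric))),
                 arr.ind = TRUE)
    stop("non-numeric expression value in ", path, " at row ", bad[1L, 1L],
         ", column ", bad[1L, 2L] + 1L)
  }
  rownames(m) <- ids
  m
}

#' Write an expression matrix as TSV
#' @param m numeric matrix with feature rownames and sample colnames.
#' @param path output path.
#' @param id_col name of the leading id column in the header.
#' @export
write_matrix_tsv <- function(m, path, id_col = "feature") {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a GMT pathway file
#'
#' Standard GMT: one pathway per line, `name TAB description TAB member...`.
#'
#' @param path path to a GMT file.
#' @param internal_edges optional path to a 3-column TSV
#'   (pathway_id, node_a, node_b) of within-pathway edges.
#' @return named list of [pathway_graph()] objects, keyed by id.
#' @export
read_gmt <- function(path, internal_edges = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  edge_tab <- NULL
  if (!is.null(internal_edges)) {
    edge_tab <- utils::read.table(internal_edges, sep = "\t", header = FALSE,
                                  stringsAsFactors = FALSE,
                                  col.names = c("pathway", "a", "b"))
  }
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("GMT line ", i, " has fewer than 3 fields")
    ed <- NULL
    if (!is.null(edge_tab)) {
      sub <- edge_tab[edge_tab$pathway == f[1L], c("a", "b"), drop = FALSE]
      if (nrow(sub)) ed <- as.matrix(sub)
    }
    out[[f[1L]]] <- pathway_graph(f[1L], f[2L], f[-(1:2)], internal_edges = ed)
  }
  if (anyDuplicated(names(out))) stop("duplicate pathway id in GMT")
  out
}

#' Write pathways to a GMT file
#' @param pathways named list of `PathwayGraph` objects.
#' @param path output path.
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(pathways, function(p)
    paste(c(p$id, p$name, p$mrna_nodes), collapse = "\t"), character(1))
  writeLines(lines, path)
}

#' Read an edge list TSV
#'
#' @param path 2-column TSV (no header, or header starting with `#`).
#' @param kind one of `"ppi"` (undirected, deduplicated orientation-free,
#'   self-loops skipped with a warning), `"mirna_target"` or `"drug_target"`
#'   (directed, deduplicated).
#' @return 2-column character matrix.
#' @export
read_edges <- function(path, kind = c("ppi", "mirna_target", "drug_target")) {
  kind <- match.arg(kind)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  edges <- .as_edge_matrix(df)
  if (kind == "ppi") return(.canon_undirected(edges))
  self <- edges[, 1L] == edges[, 2L]
  if (any(self)) {
    warning(sum(self), " self-loop edge(s) skipped in ", path)
    edges <- edges[!self, , drop = FALSE]
  }
  edges[!duplicated(paste(edges[, 1L], edges[, 2L], sep = "\r")), , drop = FALSE]
}

#' Write an edge list TSV
#' @param edges 2-column character matrix.
#' @param path output path.
#' @export
write_edges <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read a drug-target table
#'
#' TSV with columns drug id, target id, target kind (`mRNA`/`miRNA`).
#' @param path input path.
#' @return a `DrugTargetMap`.
#' @export
read_drug_targets <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#",
                          col.names = c("drug", "target", "kind"))
  drugs <- lapply(split(df, df$drug), function(d)
    list(mrna_targets = d$target[d$kind == "mRNA"],
         mirna_targets = d$target[d$kind == "miRNA"]))
  drug_target_map(drugs)
}

#' Write a drug-target table
#' @param drug_map a `DrugTargetMap`.
#' @param path output path.
#' @export
write_drug_targets <- function(drug_map, path) {
  rows <- do.call(rbind, lapply(names(drug_map), function(id) {
    d <- drug_map[[id]]
    rbind(
      if (length(d$mrna_targets))
        cbind(id, d$mrna_targets, "mRNA") else NULL,
      if (length(d$mirna_targets))
        cbind(id, d$mirna_targets, "miRNA") else NULL)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read a survival table
#' @param path TSV with columns sample, time_days, event (header optional).
#' @return a `SurvivalTable`.
#' @export
read_survival <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (is.na(suppressWarnings(as.numeric(df[1L, 2L])))) df <- df[-1L, , drop = FALSE]
  survival_table(df[[1L]], as.numeric(df[[2L]]), as.integer(df[[3L]]))
}

#' Write a survival table
#' @param surv a `SurvivalTable`.
#' @param path output path.
#' @export
write_survival <- function(surv, path) {
  utils::write.table(data.frame(sample = surv$sample, time_days = surv$time,
                                event = surv$event),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}
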