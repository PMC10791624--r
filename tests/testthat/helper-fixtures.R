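# Small in-code fixtures shared across test files.

# bare reconstructed pathway (what attach_mirnas produces), built directly
make_recon <- function(id, mrnas, mirnas = character(0),
                       mirna_edges = NULL) {
  if (is.null(mirna_edges)) mirna_edges <- matrix(character(0), ncol = 2)
  structure(list(
    base = pathway_graph(id, id, mrnas),
    mirna_nodes = mirnas,
    mirna_edges = mirna_edges,
    enrichment_p = stats::setNames(rep(0.01, length(mirnas)), mirnas)),
    class = "ReconstructedPathway")
}

# random crosstalk fixture: <= `max_feats` features per pathway, random PPI /
# miRNA-target edges, random expression and differential p-values
make_random_fixture <- function(seed, n_pathways = 3, max_feats = 8,
                                n_samples = 12) {
  set.seed(seed)
  n_mrna <- 14; n_mirna <- 5
  mrnas <- sprintf("g%02d", 1:n_mrna)
  mirnas <- sprintf("mi%02d", 1:n_mirna)
  recon <- list()
  for (k in seq_len(n_pathways)) {
    nm <- sample(2:(max_feats - 1), 1)
    path_m <- mrnas[sample.int(n_mrna, nm)]
    n_mi <- sample(0:min(2, max_feats - nm), 1)
    path_mi <- if (n_mi > 0) mirnas[sample.int(n_mirna, n_mi)] else character(0)
    edges <- NULL
    for (mi in path_mi)
      edges <- rbind(edges, cbind(mi, sample(path_m, min(2, length(path_m)))))
    recon[[sprintf("pw%d", k)]] <- make_recon(sprintf("pw%d", k), path_m,
                                              path_mi, edges)
  }
  ppi <- cbind(mrnas[sample.int(n_mrna, 25, replace = TRUE)],
               mrnas[sample.int(n_mrna, 25, replace = TRUE)])
  mt <- cbind(mirnas[sample.int(n_mirna, 10, replace = TRUE)],
              mrnas[sample.int(n_mrna, 10, replace = TRUE)])
  network <- suppressWarnings(interaction_network(ppi, mt))
  feats <- c(mrnas, mirnas)
  expr <- matrix(rnorm(length(feats) * n_samples), length(feats),
                 dimnames = list(feats, sprintf("s%02d", 1:n_samples)))
  diff_p <- stats::setNames(runif(length(feats)), feats)
  list(recon = recon, network = network, expr = expr, diff_p = diff_p)
}

# minimal 2-pathway fixture with a known cascade: pathway P holds mRNAs
# x1, x2 and attached miRNA u (targets x1, x2 in P); pathway Q holds y.
# PPI: x1-y, x2-y; miRNA-target: u -> y. Removing {x1} or {x2} kills one
# bridge pair each; removing both orphans u and kills the (u, y) pair too.
make_cascade_fixture <- function(seed = 1, n_samples = 10) {
  set.seed(seed)
  recon <- list(
    P = make_recon("P", c("x1", "x2"), "u", rbind(c("u", "x1"), c("u", "x2"))),
    Q = make_recon("Q", "y"))
  network <- interaction_network(rbind(c("x1", "y"), c("x2", "y")),
                                 rbind(c("u", "x1"), c("u", "x2"),
                                       c("u", "y")))
  feats <- c("x1", "x2", "y", "u")
  expr <- matrix(rnorm(4 * n_samples), 4,
                 dimnames = list(feats, sprintf("s%d", 1:n_samples)))
  diff_p <- stats::setNames(rep(0.01, 4), feats)
  list(recon = recon, network = network, expr = expr, diff_p = diff_p)
}

# hand-built crosstalk network whose contribution CS values are exact
# round numbers (for closed-form destruction-score checks)
make_manual_ct <- function() {
  recon <- list(P = make_recon("P", c("a1", "a2")),
                Q = make_recon("Q", c("b1", "b2")))
  pairs <- data.frame(pathway_i = "P", pathway_j = "Q", score = 9,
                      n_pairs = 2L, stringsAsFactors = FALSE)
  contributions <- data.frame(
    pathway_i = "P", pathway_j = "Q",
    a = c("a1", "a2"), b = c("b1", "b2"), kind = "mRNA-mRNA",
    p_a = 1, p_b = 1, p_ab = exp(-c(6, 3)), cs = c(6, 3),
    stringsAsFactors = FALSE)
  structure(list(pairs = pairs, contributions = contributions,
                 pathways = recon, total_crosstalk = 9),
            class = "CrosstalkNetwork")
}
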