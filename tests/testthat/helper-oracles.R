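# Independent oracle implementations used to cross-check the package.
# Deliberately written with different algorithms/primitives than the
# implementation they verify.

# upper-tail hypergeometric by direct PMF enumeration
oracle_hyper_ge <- function(N, M, n, m) {
  ks <- m:min(M, n)
  ks <- ks[ks >= max(0, n - (N - M))]
  if (length(ks) == 0) return(0)
  sum(choose(M, ks) * choose(N - M, n - ks)) / choose(N, n)
}

# Benjamini-Hochberg step-up, written out longhand
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running_min <- 1
  for (i in n:1) {
    val <- p[o[i]] * n / i
    running_min <- min(running_min, val)
    adj[o[i]] <- min(running_min, 1)
  }
  adj
}

# triple-loop brute-force crosstalk between two reconstructed pathways:
# loops over every ordered feature pair, checks edge membership by string
# scan, collects unordered qualifying pairs, and uses cor.test() for the
# correlation p-value (independent of pearson_p's closed form)
oracle_pair_crosstalk <- function(rp_i, rp_j, network, diff_p, expr,
                                  eps = 1e-300) {
  ppi_keys <- character(0)
  if (nrow(network$ppi))
    ppi_keys <- c(paste(network$ppi[, 1], network$ppi[, 2]),
                  paste(network$ppi[, 2], network$ppi[, 1]))
  mt_keys <- character(0)
  if (nrow(network$mirna_targets))
    mt_keys <- c(paste(network$mirna_targets[, 1], network$mirna_targets[, 2]),
                 paste(network$mirna_targets[, 2], network$mirna_targets[, 1]))
  feats_i <- c(rp_i$base$mrna_nodes, rp_i$mirna_nodes)
  feats_j <- c(rp_j$base$mrna_nodes, rp_j$mirna_nodes)
  is_mirna_i <- c(rep(FALSE, length(rp_i$base$mrna_nodes)),
                  rep(TRUE, length(rp_i$mirna_nodes)))
  is_mirna_j <- c(rep(FALSE, length(rp_j$base$mrna_nodes)),
                  rep(TRUE, length(rp_j$mirna_nodes)))
  seen <- character(0)
  score <- 0
  for (ai in seq_along(feats_i)) {
    for (bj in seq_along(feats_j)) {
      a <- feats_i[ai]; b <- feats_j[bj]
      if (a == b) next
      if (!(a %in% rownames(expr)) || !(b %in% rownames(expr))) next
      if (!(a %in% names(diff_p)) || !(b %in% names(diff_p))) next
      key <- paste(sort(c(a, b)), collapse = " ")
      if (key %in% seen) next
      mm <- !is_mirna_i[ai] && !is_mirna_j[bj]
      mixed <- xor(is_mirna_i[ai], is_mirna_j[bj])
      has_edge <- (mm && paste(a, b) %in% ppi_keys) ||
        (mixed && paste(a, b) %in% mt_keys)
      if (!has_edge) next
      seen <- c(seen, key)
      x <- expr[a, ]; y <- expr[b, ]
      p_ab <- if (stats::sd(x) == 0 || stats::sd(y) == 0) 1 else {
        r <- stats::cor(x, y)
        if (abs(r) >= 1) 0 else stats::cor.test(x, y)$p.value
      }
      clamp <- function(p) max(eps, min(1, p))
      score <- score - (log(clamp(diff_p[[a]])) + log(clamp(diff_p[[b]])) +
                          log(clamp(p_ab)))
    }
  }
  score
}

# two-group log-rank by hand: O - E / V tabulation over distinct event times
oracle_logrank <- function(times, events, groups) {
  groups <- as.character(groups)
  gl <- sort(unique(groups))
  stopifnot(length(gl) == 2)
  ts <- sort(unique(times[events == 1]))
  O1 <- E1 <- V <- 0
  for (t in ts) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & groups == gl[1])
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & groups == gl[1])
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- if (V > 0) (O1 - E1)^2 / V else 0
  list(statistic = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE))
}

# adjusted Rand index between two labelings (contingency-table formula)
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_comb - expected) / (max_index - expected)
}
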