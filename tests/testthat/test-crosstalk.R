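test_that("correlation strength combines log p-values with clamping", {
  expect_equal(correlation_strength(exp(-1), exp(-2), exp(-3)), 6)
  expect_equal(correlation_strength(1, 1, 1), 0)
  expect_equal(correlation_strength(0, 1, 1), -log(1e-300))
  expect_equal(correlation_strength(exp(-1), exp(-1), exp(-1)) * 3, 9)
  expect_error(correlation_strength(1.2, 0.5, 0.5), "\\[0, 1\\]")
  expect_error(correlation_strength(-0.1, 0.5, 0.5), "\\[0, 1\\]")
  expect_true(all(correlation_strength(runif(10), runif(10), runif(10)) >= 0))
})

test_that("pearson_p matches cor.test and handles degenerate input", {
  x <- as.numeric(1:10)
  expect_equal(pearson_p(x, x)$r, 1)
  expect_equal(pearson_p(x, x)$p, 0)
  expect_equal(pearson_p(x, -x)$r, -1)
  # 5-point fixture against the closed-form t and cor.test
  y <- c(2.3, -1.1, 0.4, 1.7, -0.6)
  x5 <- c(1, 2, 3, 4, 5)
  got <- pearson_p(x5, y)
  ref <- stats::cor.test(x5, y)
  expect_equal(got$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  expect_gt(got$p, 0.5)  # near-orthogonal small sample
  const <- pearson_p(rep(1, 5), y)
  expect_equal(const$r, 0)
  expect_equal(const$p, 1)
})

test_that("pathway-pair crosstalk handles empty, singleton and shared cases", {
  fx <- make_cascade_fixture(7)
  # no cross edges between two unrelated pathways
  lonely <- list(A = make_recon("A", "x1"), B = make_recon("B", "x2"))
  net0 <- interaction_network(NULL, NULL)
  res0 <- pathway_pair_crosstalk(lonely$A, lonely$B, net0, fx$diff_p, fx$expr)
  expect_equal(res0$score, 0)
  expect_equal(nrow(res0$pairs), 0)

  # singleton: one PPI pair
  net1 <- interaction_network(rbind(c("x1", "x2")), NULL)
  res1 <- pathway_pair_crosstalk(lonely$A, lonely$B, net1, fx$diff_p, fx$expr)
  expect_equal(nrow(res1$pairs), 1)
  expect_equal(res1$score, res1$pairs$cs)
  expect_equal(res1$score,
               correlation_strength(res1$pairs$p_a, res1$pairs$p_b,
                                    res1$pairs$p_ab))

  # a feature shared by both pathways contributes no self-pair
  shared <- list(A = make_recon("A", c("x1", "x2")),
                 B = make_recon("B", c("x1", "x2")))
  res2 <- pathway_pair_crosstalk(shared$A, shared$B, net1, fx$diff_p, fx$expr)
  expect_false(any(res2$pairs$a == res2$pairs$b))
  expect_equal(nrow(res2$pairs), 1)  # the x1-x2 pair, counted once

  # features absent from the expression matrix are skipped and counted
  ghost <- list(A = make_recon("A", c("x1", "zz")), B = make_recon("B", "x2"))
  net2 <- interaction_network(rbind(c("x1", "x2"), c("zz", "x2")), NULL)
  res3 <- pathway_pair_crosstalk(ghost$A, ghost$B, net2, fx$diff_p, fx$expr)
  expect_equal(res3$n_skipped, 1)
  expect_equal(nrow(res3$pairs), 1)
})

test_that("crosstalk network covers all pathway pairs and is order invariant", {
  fx <- make_random_fixture(11, n_pathways = 4)
  ct <- build_crosstalk_network(fx$recon, fx$network, fx$diff_p, fx$expr)
  expect_equal(nrow(ct$pairs), choose(4, 2))
  expect_equal(ct$total_crosstalk, sum(ct$pairs$score))
  expect_equal(sum(ct$contributions$cs), ct$total_crosstalk, tolerance = 1e-9)
  expect_true(all(ct$pairs$score >= 0))
  ct2 <- build_crosstalk_network(rev(fx$recon), fx$network, fx$diff_p, fx$expr)
  key <- function(p) {
    k <- apply(cbind(pmin(p$pathway_i, p$pathway_j),
                     pmax(p$pathway_i, p$pathway_j)), 1, paste, collapse = "|")
    stats::setNames(p$score, k)[order(k)]
  }
  expect_equal(key(ct$pairs), key(ct2$pairs), tolerance = 1e-12)
  expect_warning(empty <- build_crosstalk_network(fx$recon[1], fx$network,
                                                  fx$diff_p, fx$expr),
                 "fewer than 2")
  expect_equal(empty$total_crosstalk, 0)
})

test_that("removing a network edge never increases any pair score", {
  fx <- make_random_fixture(13, n_pathways = 3)
  ct <- build_crosstalk_network(fx$recon, fx$network, fx$diff_p, fx$expr)
  net2 <- fx$network
  # drop the first PPI edge and the first miRNA-target edge
  net2$ppi <- net2$ppi[-1, , drop = FALSE]
  net2$mirna_targets <- net2$mirna_targets[-1, , drop = FALSE]
  ct2 <- build_crosstalk_network(fx$recon, net2, fx$diff_p, fx$expr)
  expect_true(all(ct2$pairs$score <= ct$pairs$score + 1e-9))
})

test_that("pair scores agree with the independent brute-force oracle", {
  for (seed in c(21, 22, 23)) {
    fx <- make_random_fixture(seed, n_pathways = 3)
    ct <- build_crosstalk_network(fx$recon, fx$network, fx$diff_p, fx$expr)
    for (k in seq_len(nrow(ct$pairs))) {
      i <- ct$pairs$pathway_i[k]; j <- ct$pairs$pathway_j[k]
      expect_equal(ct$pairs$score[k],
                   oracle_pair_crosstalk(fx$recon[[i]], fx$recon[[j]],
                                         fx$network, fx$diff_p, fx$expr),
                   tolerance = 1e-9)
    }
  }
})
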