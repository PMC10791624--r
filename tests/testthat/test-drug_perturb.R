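test_that("target removal deletes members and cascades orphaned miRNAs", {
  fx <- make_cascade_fixture(1)
  # empty target set: identity
  same <- remove_targets(fx$recon, character(0))
  expect_identical(lapply(same, pathway_features),
                   lapply(fx$recon, pathway_features))
  # all features: everything emptied
  gone <- remove_targets(fx$recon, c("x1", "x2", "y", "u"))
  expect_true(all(lengths(lapply(gone, pathway_features)) == 0))
  # removing both in-pathway targets cascades the attached miRNA out
  casc <- remove_targets(fx$recon, c("x1", "x2"), cascade = TRUE)
  expect_false("u" %in% casc$P$mirna_nodes)
  nocasc <- remove_targets(fx$recon, c("x1", "x2"), cascade = FALSE)
  expect_true("u" %in% nocasc$P$mirna_nodes)
  # removing one target keeps the miRNA attached
  part <- remove_targets(fx$recon, "x1", cascade = TRUE)
  expect_true("u" %in% part$P$mirna_nodes)
})

test_that("destruction score closed forms hold on a hand-built network", {
  ct <- make_manual_ct()
  expect_equal(destruction_score(ct, character(0))$ds, 0)
  expect_equal(destruction_score(ct, c("a1", "a2", "b1", "b2"))$ds, 1)
  # removing only the cs = 6 pair's endpoint leaves 3 of 9: DS = 2/3
  res <- destruction_score(ct, "a1")
  expect_equal(res$ds, 2 / 3, tolerance = 1e-12)
  expect_equal(res$crosstalk_after, 3)
  expect_equal(nrow(res$affected_pairs), 1)
  # degenerate network refuses to score
  ct0 <- ct; ct0$total_crosstalk <- 0
  expect_error(destruction_score(ct0, "a1"), "no crosstalk")
})

test_that("cached destruction equals a full rebuild after removal", {
  for (seed in c(5, 6)) {
    fx <- make_random_fixture(seed, n_pathways = 4)
    ct <- build_crosstalk_network(fx$recon, fx$network, fx$diff_p, fx$expr)
    if (ct$total_crosstalk == 0) next
    feats <- unique(unlist(lapply(fx$recon, pathway_features)))
    set.seed(seed)
    targets <- sample(feats, 3)
    for (cascade in c(TRUE, FALSE)) {
      fast <- destruction_score(ct, targets, cascade = cascade)$ds
      reduced <- remove_targets(fx$recon, targets, cascade = cascade)
      ct2 <- build_crosstalk_network(reduced, fx$network, fx$diff_p, fx$expr)
      expect_equal(fast, 1 - ct2$total_crosstalk / ct$total_crosstalk,
                   tolerance = 1e-9)
    }
  }
})

test_that("DS is monotone in the target set and bounded in [0, 1]", {
  fx <- make_random_fixture(8, n_pathways = 4)
  ct <- build_crosstalk_network(fx$recon, fx$network, fx$diff_p, fx$expr)
  feats <- unique(unlist(lapply(fx$recon, pathway_features)))
  set.seed(8)
  for (rep in 1:10) {
    t2 <- sample(feats, sample(2:length(feats), 1))
    t1 <- sample(t2, sample(seq_along(t2), 1))
    for (cascade in c(TRUE, FALSE)) {
      d1 <- destruction_score(ct, t1, cascade)$ds
      d2 <- destruction_score(ct, t2, cascade)$ds
      expect_lte(d1, d2 + 1e-12)
      expect_gte(d1, 0); expect_lte(d2, 1)
    }
  }
})

test_that("single-drug screening ranks by DS and applies the pass threshold", {
  ct <- make_manual_ct()
  dm <- drug_target_map(list(
    strong = list(mrna_targets = "a1"),          # DS = 2/3
    weak = list(mrna_targets = "b2"),            # DS = 1/3
    dud = list(mrna_targets = "zz")))            # DS = 0
  sc <- screen_single_drugs(dm, ct, ds_threshold = 0.01)
  expect_identical(sc$drug, c("strong", "weak", "dud"))
  expect_equal(sc$ds, c(2 / 3, 1 / 3, 0), tolerance = 1e-12)
  expect_identical(sc$passes_single, c(TRUE, TRUE, FALSE))
  sc0 <- screen_single_drugs(dm, ct, ds_threshold = 0)
  expect_identical(sc0$passes_single, c(TRUE, TRUE, FALSE))  # ds > 0 passes
})

test_that("combination screening: equality selects, shared targets do not", {
  ct <- make_manual_ct()
  dm <- drug_target_map(list(
    d1 = list(mrna_targets = "a1"),
    d2 = list(mrna_targets = "b2"),
    twin1 = list(mrna_targets = "a1"),
    twin2 = list(mrna_targets = c("a1", "b1"))))
  sc <- screen_single_drugs(dm, ct, ds_threshold = 0.01)
  combos <- optimize_combinations(sc, dm, ct)
  key <- paste(combos$drug1, combos$drug2, sep = "|")
  # disjoint target sets destroying disjoint pairs: exact additivity, selected
  row_add <- combos[key == "d1|d2", ]
  expect_equal(row_add$ds_combo, row_add$ds1 + row_add$ds2, tolerance = 1e-12)
  expect_true(row_add$selected)
  # identical targets: union = either set, strictly subadditive, rejected
  row_twin <- combos[key == "d1|twin1", ]
  expect_equal(row_twin$ds_combo, row_twin$ds1, tolerance = 1e-12)
  expect_false(row_twin$selected)
  # sorting is by decreasing joint destruction
  expect_true(all(diff(combos$ds_combo) <= 1e-12))
  # strict criterion drops the equality case
  combos_gt <- optimize_combinations(sc, dm, ct, criterion = "gt")
  expect_false(combos_gt$selected[paste(combos_gt$drug1, combos_gt$drug2,
                                        sep = "|") == "d1|d2"])
})

test_that("cascade removal produces strict superadditivity on the cascade fixture", {
  fx <- make_cascade_fixture(3)
  ct <- build_crosstalk_network(fx$recon, fx$network, fx$diff_p, fx$expr)
  ds1 <- destruction_score(ct, "x1", cascade = TRUE)$ds
  ds2 <- destruction_score(ct, "x2", cascade = TRUE)$ds
  ds12 <- destruction_score(ct, c("x1", "x2"), cascade = TRUE)$ds
  expect_gt(ds12, ds1 + ds2 + 1e-6)
  # without the cascade the same union is exactly additive here
  ds12_nc <- destruction_score(ct, c("x1", "x2"), cascade = FALSE)$ds
  ds1_nc <- destruction_score(ct, "x1", cascade = FALSE)$ds
  ds2_nc <- destruction_score(ct, "x2", cascade = FALSE)$ds
  expect_equal(ds12_nc, ds1_nc + ds2_nc, tolerance = 1e-12)
})

test_that("combination results are invariant to drug enumeration order", {
  fx <- make_random_fixture(17, n_pathways = 3)
  ct <- build_crosstalk_network(fx$recon, fx$network, fx$diff_p, fx$expr)
  feats <- unique(unlist(lapply(fx$recon, pathway_features)))
  dm <- drug_target_map(list(a = list(mrna_targets = feats[1:2]),
                             b = list(mrna_targets = feats[3]),
                             c = list(mrna_targets = feats[4:5])))
  sc <- screen_single_drugs(dm, ct, ds_threshold = 0)
  c1 <- optimize_combinations(sc, dm, ct)
  c2 <- optimize_combinations(sc[rev(seq_len(nrow(sc))), ], dm, ct)
  expect_equal(c1[order(c1$drug1, c1$drug2), ],
               c2[order(c2$drug1, c2$drug2), ], tolerance = 1e-12,
               ignore_attr = TRUE)
})
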