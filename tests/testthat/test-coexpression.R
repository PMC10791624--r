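test_that("soft-threshold adjacency follows the unsigned/signed transforms", {
  s <- seq_len(8)
  m <- rbind(f1 = s, f2 = 2 * s + 3, f3 = -s)  # f2 = f1, f3 = -f1 (cor +-1)
  m <- m + 0  # numeric
  a_uns <- build_adjacency(m, power = 6)
  expect_equal(unname(a_uns["f1", "f2"]), 1)
  expect_equal(unname(a_uns["f1", "f3"]), 1)   # |cor| in unsigned nets
  a_sgn <- build_adjacency(m, power = 2, signed = TRUE)
  expect_equal(unname(a_sgn["f1", "f3"]), 0)   # ((1-1)/2)^2
  expect_equal(unname(a_sgn["f1", "f2"]), 1)
  # uncorrelated features: adjacency ~ |cor|^power ~ 0
  set.seed(1)
  m2 <- matrix(rnorm(3 * 2000), 3)
  rownames(m2) <- paste0("r", 1:3)
  a2 <- build_adjacency(m2, power = 6)
  expect_lt(max(a2[upper.tri(a2)]), 1e-3)
  # constant feature: zeroed with a warning
  m3 <- rbind(c1 = rep(1, 8), f1 = s)
  expect_warning(a3 <- build_adjacency(m3 + 0, power = 6), "constant")
  expect_equal(unname(a3["c1", "f1"]), 0)
})

test_that("TOM similarity is a unit-diagonal symmetric measure in [0, 1]", {
  set.seed(2)
  m <- matrix(rnorm(20 * 15), 20, dimnames = list(paste0("f", 1:20), NULL))
  tom <- tom_similarity(build_adjacency(m, 6))
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  expect_equal(tom, t(tom), tolerance = 1e-12)
  expect_equal(unname(diag(tom)), rep(1, 20))
})

test_that("module detection recovers perfect blocks and greys out noise", {
  # two disjoint perfect blocks
  blocks <- c(rep(1, 12), rep(2, 12))
  adj <- outer(blocks, blocks, "==") * 1
  dimnames(adj) <- list(paste0("f", 1:24), paste0("f", 1:24))
  mods <- detect_modules(adj, min_module_size = 10)
  ids <- vapply(mods, `[[`, character(1), "id")
  expect_setequal(ids, c("M1", "M2"))
  got <- lapply(mods, `[[`, "members")
  expect_true(setequal(got[[1]], paste0("f", 1:12)) ||
                setequal(got[[1]], paste0("f", 13:24)))

  # identity adjacency: no structure, everything grey
  id_adj <- diag(24)
  dimnames(id_adj) <- dimnames(adj)
  mods2 <- detect_modules(id_adj, min_module_size = 10)
  expect_identical(vapply(mods2, `[[`, character(1), "id"), "grey")

  # one block below the minimum size goes grey
  blocks3 <- c(rep(1, 5), rep(2, 12))
  adj3 <- outer(blocks3, blocks3, "==") * 1
  dimnames(adj3) <- list(paste0("g", 1:17), paste0("g", 1:17))
  mods3 <- detect_modules(adj3, min_module_size = 10)
  ids3 <- vapply(mods3, `[[`, character(1), "id")
  expect_setequal(ids3, c("M1", "grey"))
  grey <- mods3[[which(ids3 == "grey")]]$members
  expect_setequal(grey, paste0("g", 1:5))
})

test_that("soft power selection reaches the target on graded structure and falls back otherwise", {
  # graded hub-like loadings give a smoothly decaying connectivity profile
  set.seed(3)
  n <- 80; ns <- 50
  w <- (seq_len(n) / n)^1.5
  f <- rnorm(ns)
  m <- t(sapply(w, function(wi) wi * f + sqrt(1 - wi^2) * rnorm(ns)))
  rownames(m) <- paste0("f", 1:n)
  sp <- pick_soft_power(m)
  expect_true(sp$reached_target)
  expect_lte(sp$power, 20)
  expect_gte(max(sp$fit_r2), 0.8)

  # two equal perfect blocks: connectivity takes a single value, the
  # scale-free fit is undefined, so the fallback engages
  blocks <- c(rep(1, 10), rep(2, 10))
  bm <- rbind(matrix(rep(rnorm(30), 10), 10, byrow = TRUE),
              matrix(rep(rnorm(30), 10), 10, byrow = TRUE))
  rownames(bm) <- paste0("b", 1:20)
  expect_warning(sp2 <- pick_soft_power(bm), "falling back")
  expect_equal(sp2$power, 6)
  expect_false(sp2$reached_target)

  # a single candidate power that cannot reach the target still returns 6
  expect_warning(sp3 <- pick_soft_power(bm, candidate_powers = 6))
  expect_equal(sp3$power, 6)
})

test_that("module-trait scoring orients eigengenes and flags phenotype modules", {
  set.seed(4)
  ph <- rep(c("tumor", "normal"), each = 20)
  ph01 <- as.numeric(ph == "tumor")
  # module tracking the phenotype almost perfectly
  m_sig <- t(sapply(1:12, function(i) ph01 * 3 + rnorm(40, 0, 0.1)))
  # module independent of phenotype
  f <- rnorm(40)
  m_null <- t(sapply(1:12, function(i) f + rnorm(40, 0, 0.3)))
  m <- rbind(m_sig, m_null)
  rownames(m) <- paste0("f", 1:24)
  colnames(m) <- paste0("s", 1:40)
  mods <- list(list(id = "M1", members = paste0("f", 1:12)),
               list(id = "M2", members = paste0("f", 13:24)))
  scored <- module_trait(mods, m, ph)
  expect_gt(abs(scored[[1]]$trait_r), 0.95)
  expect_lt(scored[[1]]$trait_p, 1e-6)
  expect_gt(scored[[2]]$trait_p, 0.05)
  # identical members: eigengene equals the standardized series up to sign
  m_id <- matrix(rep(m[1, ], 3), 3, byrow = TRUE,
                 dimnames = list(paste0("r", 1:3), colnames(m)))
  scored_id <- module_trait(list(list(id = "M1", members = paste0("r", 1:3))),
                            m_id, ph)
  z <- as.numeric(scale(m[1, ]))
  eg <- unname(scored_id[[1]]$eigengene)
  expect_gt(abs(stats::cor(eg, z)), 1 - 1e-9)
})

test_that("risk factor extraction honors mode, alpha and ordering", {
  mods <- list(
    list(id = "M1", members = c("g1", "g2", "mi1"), trait_r = 0.9,
         trait_p = 1e-5),
    list(id = "M2", members = c("g3", "g4"), trait_r = -0.5, trait_p = 0.01),
    list(id = "M3", members = c("g5"), trait_r = 0.1, trait_p = 0.6),
    list(id = "grey", members = "g6", trait_r = NA_real_, trait_p = NA_real_))
  kind <- stats::setNames(c(rep("mRNA", 6), "miRNA"),
                          c(paste0("g", 1:6), "mi1"))
  top <- extract_risk_factors(mods, kind, mode = "top")
  expect_identical(top$risk_mrnas, c("g1", "g2"))
  expect_identical(top$risk_mirnas, "mi1")
  allm <- extract_risk_factors(mods, kind, mode = "all-significant")
  expect_setequal(allm$risk_mrnas, c("g1", "g2", "g3", "g4"))
  expect_warning(none <- extract_risk_factors(mods, kind, alpha = 1e-9),
                 "no module")
  expect_length(none$risk_mrnas, 0)
  # invariant to module order
  allm2 <- extract_risk_factors(rev(mods), kind, mode = "all-significant")
  expect_identical(allm$risk_mrnas, allm2$risk_mrnas)
})

test_that("planted modules are recovered on synthetic cohorts", {
  for (seed in 1:2) {
    co <- generate_cohort(synthetic_config(seed = seed))
    lm2 <- log2(bundle_matrix(co$bundle) + 1e-9)
    feats <- names(co$truth$modules)
    adj <- build_adjacency(lm2[feats, ], 6)
    mods <- detect_modules(adj)
    det <- rep("grey", length(feats)); names(det) <- feats
    for (m in mods) det[intersect(m$members, feats)] <- m$id
    expect_gte(oracle_ari(det, co$truth$modules[feats]), 0.8)
  }
})
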