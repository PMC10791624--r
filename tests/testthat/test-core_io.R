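test_that("expression reading harmonizes samples and validates the bundle", {
  dir <- withr::local_tempdir()
  mrna <- matrix(1:12, 3, 4, dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  mirna <- matrix(1:8, 2, 4, dimnames = list(paste0("mi", 1:2), paste0("s", 4:1)))
  write_matrix_tsv(mrna, file.path(dir, "m.tsv"))
  write_matrix_tsv(mirna, file.path(dir, "mi.tsv"))
  writeLines(paste(paste0("s", 1:4), c("tumor", "tumor", "normal", "normal"),
                   sep = "\t"), file.path(dir, "ph.tsv"))
  b <- read_expression(file.path(dir, "m.tsv"), file.path(dir, "mi.tsv"),
                       file.path(dir, "ph.tsv"))
  expect_s3_class(b, "ExpressionBundle")
  expect_identical(colnames(b$mrna), paste0("s", 1:4))
  expect_identical(colnames(b$mrna), colnames(b$mirna))
  # columns re-aligned, values preserved
  expect_equal(b$mirna[, "s2"], mirna[, "s2"])

  # disjoint samples
  colnames(mirna) <- paste0("t", 1:4)
  write_matrix_tsv(mirna, file.path(dir, "mi2.tsv"))
  expect_error(read_expression(file.path(dir, "m.tsv"),
                               file.path(dir, "mi2.tsv"),
                               file.path(dir, "ph.tsv")),
               "no common samples")

  # duplicate feature id
  dup <- rbind(mrna, mrna[1, , drop = FALSE])
  writeLines(c(paste(c("feature", paste0("s", 1:4)), collapse = "\t"),
               apply(cbind(c("g1", "g2", "g3", "g1"), dup), 1, paste,
                     collapse = "\t")),
             file.path(dir, "dup.tsv"))
  expect_error(read_expression(file.path(dir, "dup.tsv"),
                               file.path(dir, "mi.tsv"),
                               file.path(dir, "ph.tsv")),
               "g1")

  # non-numeric cell
  txt <- readLines(file.path(dir, "m.tsv"))
  txt[2] <- sub("\t1\t", "\tNOPE\t", txt[2])
  writeLines(txt, file.path(dir, "bad.tsv"))
  expect_error(read_expression(file.path(dir, "bad.tsv"),
                               file.path(dir, "mi.tsv"),
                               file.path(dir, "ph.tsv")),
               "non-numeric")
})

test_that("bundle constructor enforces its invariants", {
  m <- matrix(1:8, 2, 4, dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  mi <- matrix(1:4, 1, 4, dimnames = list("mi1", paste0("s", 1:4)))
  ph <- stats::setNames(c("tumor", "tumor", "normal", "normal"), paste0("s", 1:4))
  expect_silent(expression_bundle(m, mi, ph))
  expect_error(expression_bundle(-m, mi, ph), "negative")
  expect_silent(expression_bundle(-m, mi, ph, is_log2 = TRUE))
  expect_error(expression_bundle(m, mi, ph[1:3]), "missing")
  ph1 <- ph; ph1[] <- "tumor"
  expect_error(expression_bundle(m, mi, ph1), "2 samples per phenotype")
})

test_that("GMT round-trips and rejects malformed lines", {
  dir <- withr::local_tempdir()
  p <- list(a = pathway_graph("a", "first", c("g1", "g2", "g3")),
            b = pathway_graph("b", "second", c("g2", "g4")))
  f <- file.path(dir, "p.gmt")
  write_gmt(p, f)
  p2 <- read_gmt(f)
  expect_identical(names(p2), c("a", "b"))
  expect_identical(p2$a$mrna_nodes, c("g1", "g2", "g3"))
  expect_identical(p2$b$name, "second")

  writeLines(character(0), file.path(dir, "empty.gmt"))
  expect_length(read_gmt(file.path(dir, "empty.gmt")), 0)

  writeLines(c("ok\tdesc\tg1", "bad\tonlydesc"), file.path(dir, "bad.gmt"))
  expect_error(read_gmt(file.path(dir, "bad.gmt")), "line 2")
})

test_that("edge reading deduplicates and handles self-loops by kind", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "e.tsv")
  writeLines(c("A\tB", "B\tA", "C\tD"), f)
  e <- read_edges(f, "ppi")
  expect_equal(nrow(e), 2)          # (A,B) and (B,A) collapse
  expect_true(all(e[, 1] <= e[, 2]))

  writeLines(c("A\tA"), f)
  expect_warning(e2 <- read_edges(f, "ppi"), "self-loop")
  expect_equal(nrow(e2), 0)

  writeLines(c("mi1\tg1", "mi1\tg2", "mi2\tg1", "mi1\tg1"), f)
  e3 <- read_edges(f, "mirna_target")
  expect_equal(nrow(e3), 3)
})

test_that("drug-target and survival tables round-trip", {
  dir <- withr::local_tempdir()
  dm <- drug_target_map(list(d1 = list(mrna_targets = c("g1", "g2"),
                                       mirna_targets = "mi1"),
                             d2 = list(mrna_targets = "g3")))
  f <- file.path(dir, "d.tsv")
  write_drug_targets(dm, f)
  dm2 <- read_drug_targets(f)
  expect_identical(sort(names(dm2)), c("d1", "d2"))
  expect_setequal(dm2$d1$mrna_targets, c("g1", "g2"))
  expect_identical(dm2$d1$mirna_targets, "mi1")
  expect_identical(drug_targets(dm2, c("d1", "d2")),
                   unique(c(dm2$d1$mrna_targets, dm2$d1$mirna_targets, "g3")))

  sv <- survival_table(paste0("s", 1:3), c(10, 0, 250.5), c(1, 0, 1))
  f2 <- file.path(dir, "s.tsv")
  write_survival(sv, f2)
  sv2 <- read_survival(f2)
  expect_equal(sv2$time, sv$time)
  expect_equal(sv2$event, sv$event)
  expect_error(survival_table("a", -1, 1), "negative")
  expect_error(survival_table(c("a", "a"), c(1, 2), c(1, 1)), "duplicate")
})
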