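test_that("lipid shorthand names parse at summed and chain level", {
  a <- parse_lipid_name("PC 34:1")
  expect_equal(a$lipid_class, "PC")
  expect_equal(a$summed_carbons, 34L)
  expect_equal(a$summed_double_bonds, 1L)
  expect_null(a$chains)
  b <- parse_lipid_name("PC 16:0/18:1")
  expect_equal(b$summed_carbons, 34L)       # sum rule
  expect_equal(b$summed_double_bonds, 1L)
  expect_equal(b$chains$carbons, c(16L, 18L))
  expect_equal(b$chains$double_bonds, c(0L, 1L))
  tg <- parse_lipid_name("TG 16:0/18:1/18:2")
  expect_equal(tg$summed_carbons, 52L)
  expect_equal(tg$summed_double_bonds, 3L)
  sm <- parse_lipid_name("SM d18:1/16:0")
  expect_equal(sm$lipid_class, "SM")
  expect_equal(sm$summed_carbons, 34L)
  expect_equal(sm$chains$prefix, c("d", ""))
  # chain order is canonical: the two namings are the same annotation
  expect_equal(parse_lipid_name("PC 18:1/16:0")$chains,
               parse_lipid_name("PC 16:0/18:1")$chains)
  # unknown grammar: class-only with the parse flag down
  u <- parse_lipid_name("Cholesterol ester (mystery)")
  expect_false(u$parsed)
  expect_equal(u$lipid_class, "Cholesterol")
  expect_error(parse_lipid_name("  "), "empty")
})

test_that("agreement classification walks the hierarchy", {
  expect_equal(classify_agreement("PC 16:0/18:1", "PC 16:0/18:1",
                                  "[M+H]+", "[M+H]+"), "full_agreement")
  expect_equal(classify_agreement("PC 16:0/18:1", "PC 18:1/16:0",
                                  "[M+H]+", "[M+H]+"), "full_agreement")
  expect_equal(classify_agreement("PC 16:0/18:1", "PC 16:1/18:0",
                                  "[M+H]+", "[M+H]+"), "summed_adduct")
  expect_equal(classify_agreement("PC 34:1", "PC 16:0/18:1",
                                  "[M+H]+", "[M+H]+"), "summed_adduct")
  expect_equal(classify_agreement("PC 34:1", "PC 36:2",
                                  "[M+H]+", "[M+H]+"), "class_adduct")
  expect_equal(classify_agreement("PC 34:1", "PC 36:2",
                                  "[M+H]+", "[M+Na]+"), "class")
  expect_equal(classify_agreement("PC 34:1", "PC 34:1",
                                  "[M+H]+", "[M+Na]+"), "class")  # strict adduct
  expect_equal(classify_agreement("PC 34:1", "TG 52:3",
                                  "[M+H]+", "[M+NH4]+"), "full_disagreement")
})

test_that("agreement levels weaken monotonically as fields diverge", {
  lv <- function(x) match(x, lcmsmatch:::AGREEMENT_LEVELS)
  full <- classify_agreement("PC 16:0/18:1", "PC 16:0/18:1", "[M+H]+", "[M+H]+")
  summed <- classify_agreement("PC 16:0/18:1", "PC 16:1/18:0", "[M+H]+", "[M+H]+")
  class_ad <- classify_agreement("PC 16:0/18:1", "PC 14:0/18:1", "[M+H]+", "[M+H]+")
  cls <- classify_agreement("PC 16:0/18:1", "PC 14:0/18:1", "[M+H]+", "[M+Na]+")
  expect_true(lv(full) > lv(summed))
  expect_true(lv(summed) > lv(class_ad))
  expect_true(lv(class_ad) > lv(cls))
})

test_that("compute_rbp matches the worked example and simple cases", {
  r <- compute_rbp(c(10, 20, 30), c(5, 15))
  expect_equal(r$threshold, 20)
  expect_equal(r$objective, 2 / 3, tolerance = 1e-12)
  # perfect separation: threshold = min agreement score, objective 1
  r2 <- compute_rbp(c(50, 60, 70), c(1, 2, 3))
  expect_equal(r2$threshold, 50)
  expect_equal(r2$objective, 1.0)
  # identical lists: objective 0 everywhere, lowest score returned
  r3 <- compute_rbp(c(5, 10, 15), c(5, 10, 15))
  expect_equal(r3$threshold, 5)
  expect_equal(r3$objective, 0)
  expect_error(compute_rbp(numeric(), 1), "non-empty")
  expect_error(compute_rbp(1, numeric()), "non-empty")
})

test_that("compute_rbp equals an exhaustive sweep on random score sets", {
  set.seed(17)
  for (rep in 1:1000) {
    agree <- runif(sample(3:300, 1), 0, 40)
    disagree <- runif(sample(3:300, 1), 0, 40)
    got <- compute_rbp(agree, disagree)
    want <- rbp_sweep_oracle(agree, disagree, extra_grid = FALSE)
    expect_identical(got$threshold, want$threshold)
    expect_identical(got$objective, want$objective)
  }
})

test_that("the RBP objective is a step function: dense grids never beat it", {
  set.seed(18)
  for (rep in 1:50) {
    agree <- rnorm(50, 30, 6)
    disagree <- rnorm(50, 15, 6)
    got <- compute_rbp(agree, disagree)
    dense <- rbp_sweep_oracle(agree, disagree, extra_grid = TRUE)
    expect_lte(dense$objective, got$objective + 1e-12)
  }
})

test_that("reconcile applies library-specific RBP thresholds per feature", {
  ann <- rbind(
    data.frame(group_id = 1L, mz = 760.58, rt = 10, library = "A",
               compound = "PC 16:0/18:1", adduct = "[M+H]+", score = 30,
               k = 5L, m = 6L, n = 6L),
    data.frame(group_id = 1L, mz = 760.58, rt = 10, library = "B",
               compound = "PC 16:0/18:1", adduct = "[M+H]+", score = 8,
               k = 3L, m = 6L, n = 4L),   # below B's RBP -> only A retained
    data.frame(group_id = 2L, mz = 700.55, rt = 12, library = "A",
               compound = "PC 32:0", adduct = "[M+H]+", score = 4,
               k = 2L, m = 5L, n = 5L),   # below both -> unannotated
    data.frame(group_id = 2L, mz = 700.55, rt = 12, library = "B",
               compound = "PC 32:0", adduct = "[M+H]+", score = 5,
               k = 2L, m = 5L, n = 4L),
    data.frame(group_id = 3L, mz = 650.4, rt = 5, library = "A",
               compound = "PE 16:0/18:1", adduct = "[M+H]+", score = 25,
               k = 5L, m = 6L, n = 6L),
    data.frame(group_id = 3L, mz = 650.4, rt = 5, library = "B",
               compound = "PE 34:1", adduct = "[M+H]+", score = 22,
               k = 4L, m = 6L, n = 5L))   # both pass -> summed_adduct
  out <- reconcile(ann, c(A = 10, B = 12))
  f <- out$features
  expect_equal(f$category, c("only_a", "unannotated", "both"))
  expect_equal(f$agreement_level[3L], "summed_adduct")
  # partition: category counts sum to the number of features
  s <- out$summary
  expect_equal(s$n_features[s$category == "all_features"],
               sum(s$n_features[s$category != "all_features"]))
  expect_equal(sum(s$n_features[s$category != "all_features"]), 3L)
})

test_that("reconcile recovers a planted A-only/B-only/shared structure", {
  # 12 shared, 5 A-only, 4 B-only, 3 unannotated; scores all above RBPs
  mkrow <- function(gid, lib, comp, score) {
    data.frame(group_id = gid, mz = 500 + gid, rt = gid, library = lib,
               compound = comp, adduct = "[M+H]+", score = score,
               k = 3L, m = 4L, n = 4L)
  }
  rows <- list()
  for (g in 1:12) {
    rows <- c(rows, list(mkrow(g, "A", sprintf("PC %d:1", 30 + g), 30),
                         mkrow(g, "B", sprintf("PC %d:1", 30 + g), 30)))
  }
  for (g in 13:17) {
    rows <- c(rows, list(mkrow(g, "A", "PE 34:1", 30), mkrow(g, "B", NA, NA)))
  }
  for (g in 18:21) {
    rows <- c(rows, list(mkrow(g, "A", NA, NA), mkrow(g, "B", "TG 52:3", 30)))
  }
  for (g in 22:24) {
    rows <- c(rows, list(mkrow(g, "A", NA, NA), mkrow(g, "B", NA, NA)))
  }
  out <- reconcile(do.call(rbind, rows), c(A = 10, B = 10))
  expect_equal(sum(out$features$category == "both"), 12L)
  expect_equal(sum(out$features$category == "only_a"), 5L)
  expect_equal(sum(out$features$category == "only_b"), 4L)
  expect_equal(sum(out$features$category == "unannotated"), 3L)
  expect_true(all(out$features$agreement_level[out$features$category == "both"]
                  == "full_agreement"))
  # compound-level counts collapse adduct forms: same compound, two adducts
  ann2 <- rbind(mkrow(1L, "A", "PC 34:1", 30), mkrow(1L, "B", "PC 34:1", 30),
                mkrow(2L, "A", "PC 34:1", 30), mkrow(2L, "B", "PC 34:1", 30))
  ann2$adduct[3:4] <- "[M+Na]+"
  out2 <- reconcile(ann2, c(A = 10, B = 10))
  s2 <- out2$summary
  expect_equal(s2$n_features[s2$category == "both_full_agreement"], 2L)
  expect_equal(s2$n_compounds[s2$category == "both_full_agreement"], 1L)
})
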