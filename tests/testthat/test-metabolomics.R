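make_pt <- function(X, group, is_qc) peak_table(X, group, is_qc)

test_that("missingness filter removes >80% missing features, imputes means", {
  X <- rbind(F1 = c(2, NA, 4, 1, 1, 3, 2, 4, 1, 2),
             F2 = c(NA, NA, NA, NA, 5, NA, NA, NA, NA, NA),
             F3 = 1:10)
  pt <- make_pt(X, rep(c("Con", "Mod"), 5), rep(FALSE, 10))
  out <- filter_missing(pt, 0.8)
  # F2 is missing in 9/10 samples (0.9 > 0.8): removed; F1 at 0.1 stays
  expect_equal(rownames(out$intensity), c("F1", "F3"))
  expect_equal(unname(out$intensity["F1", 2]),
               mean(c(2, 4, 1, 1, 3, 2, 4, 1, 2)))
  # a fully observed table is untouched
  pt3 <- make_pt(X[3, , drop = FALSE], pt$group, pt$is_qc)
  expect_equal(filter_missing(pt3)$intensity, pt3$intensity)
})

test_that("QC RSD filter drops irreproducible and degenerate features", {
  X <- rbind(F1 = c(5, 6, 10, 10, 10),
             F2 = c(5, 6, 1, 3, 2),
             F3 = c(5, 6, 0, 0, 0))
  pt <- make_pt(X, c("Con", "Mod", "QC", "QC", "QC"),
                c(FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_warning(out <- filter_qc_rsd(pt, 0.20), "non-positive QC mean")
  expect_equal(rownames(out$intensity), "F1")   # {1,3,2}: RSD = 0.5, dropped
  # RSD of {1,3} is ~70.7%
  expect_equal(stats::sd(c(1, 3)) / mean(c(1, 3)), 0.7071, tolerance = 1e-4)
  pt_single_qc <- make_pt(X, c("Con", "Mod", "QC", "Mod", "Con"),
                          c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_error(filter_qc_rsd(pt_single_qc), "two QC")
})

test_that("SD filter keeps ceiling(0.6 F) features with deterministic ties", {
  set.seed(30)
  X <- matrix(stats::rnorm(10 * 8, 100, c(1:10)), 10, 8,
              dimnames = list(sprintf("F%02d", 1:10), NULL))
  pt <- make_pt(abs(X), rep(c("Con", "Mod"), 4), rep(FALSE, 8))
  out <- filter_low_sd(pt, 0.40)
  expect_equal(nrow(out$intensity), 6)
  # all-equal SDs: the drop is id-ordered (larger ids dropped first)
  Xe <- matrix(rep(c(1, 2), each = 5), 5, 2,
               dimnames = list(sprintf("F%d", 1:5), NULL))
  pte <- make_pt(Xe, c("Con", "Mod"), c(FALSE, FALSE))
  oute <- filter_low_sd(pte, 0.40)
  expect_equal(rownames(oute$intensity), c("F1", "F2", "F3"))
  expect_equal(filter_low_sd(pte, 0)$intensity, pte$intensity)
})

test_that("normalization equalizes totals, centres features, guards zeros", {
  set.seed(31)
  X <- matrix(stats::runif(20 * 6, 10, 1000), 20, 6)
  X[1, 1] <- 0
  pt <- make_pt(X, rep(c("Con", "Mod", "QC"), each = 2),
                rep(c(FALSE, FALSE, TRUE), each = 2))
  out <- normalize_table(pt)
  expect_equal(stats::sd(colSums(out$prelog)), 0, tolerance = 1e-9)
  expect_equal(max(abs(rowMeans(out$normalized))), 0, tolerance = 1e-12)
  expect_true(all(is.finite(out$normalized)))
  auto <- normalize_table(pt, autoscale = TRUE)
  expect_equal(unname(apply(auto$normalized, 1, stats::sd)), rep(1, 20),
               tolerance = 1e-9)
})

test_that("VIP satisfies its normalization identity", {
  set.seed(32)
  X <- matrix(stats::rnorm(30 * 25), 30, 25,
              dimnames = list(NULL, paste0("F", 1:25)))
  g <- rep(c("Con", "Mod"), length.out = 30)
  vip <- pls_da_vip(X, g)
  expect_equal(mean(vip^2), 1, tolerance = 1e-9)
  # single feature is forced to VIP 1
  expect_equal(unname(pls_da_vip(X[, 1, drop = FALSE], g)), 1,
               tolerance = 1e-9)
  expect_error(pls_da_vip(X, rep("Con", 30)), "two groups")
  # zero-variance feature gets VIP 0
  X0 <- cbind(X, const = 1)
  expect_warning(v0 <- pls_da_vip(X0, g), "zero-variance")
  expect_equal(unname(v0["const"]), 0)
})

test_that("an informative feature dominates the VIP ranking", {
  hits <- 0
  for (s in 1:50) {
    set.seed(400 + s)
    X <- matrix(stats::rnorm(40 * 50), 40, 50,
                dimnames = list(NULL, paste0("F", 1:50)))
    g <- rep(c("Con", "Mod"), each = 20)
    X[g == "Mod", 1] <- X[g == "Mod", 1] + 3
    vip <- pls_da_vip(X, g)
    if (which.max(vip) == 1) hits <- hits + 1
  }
  expect_gte(hits, 48)
})

test_that("differential screen agrees with a hand-computed oracle", {
  # 8 features, n=5/group, constructed then screened both ways
  set.seed(33)
  n <- 5
  # F9 dominates every sample's total so sum-normalization closure barely
  # perturbs the flat features
  means_con <- c(100, 100, 100, 50, 80, 60, 200, 150, 50000)
  means_mod <- c(300, 100, 102, 150, 80, 62, 600, 150, 50000)
  X <- matrix(0, 9, 2 * n, dimnames = list(paste0("F", 1:9), NULL))
  for (f in 1:9) {
    X[f, 1:n] <- means_con[f] * (1 + stats::rnorm(n, 0, 0.05))
    X[f, (n + 1):(2 * n)] <- means_mod[f] * (1 + stats::rnorm(n, 0, 0.05))
  }
  g <- rep(c("Con", "Mod"), each = n)
  pt <- normalize_table(make_pt(X, g, rep(FALSE, 2 * n)))
  scr <- differential_screen(pt)

  # oracle: recompute all three criteria from the stored matrices
  vip <- pls_da_vip(t(pt$normalized), g)
  for (f in rownames(pt$normalized)) {
    p_or <- stats::t.test(pt$normalized[f, g == "Mod"],
                          pt$normalized[f, g == "Con"])$p.value
    fc_or <- mean(pt$prelog[f, g == "Mod"]) / mean(pt$prelog[f, g == "Con"])
    row <- scr[scr$feature_id == f, ]
    expect_equal(row$p, p_or, tolerance = 1e-12)
    expect_equal(row$fc, fc_or, tolerance = 1e-12)
    expect_equal(row$passes,
                 vip[[f]] > 1 && p_or < 0.05 && max(fc_or, 1 / fc_or) > 1)
  }
  # strongly shifted features pass, flat ones fail
  expect_true(all(scr$passes[scr$feature_id %in% c("F1", "F7")]))
  expect_false(any(scr$passes[scr$feature_id %in% c("F2", "F5", "F8")]))
})

test_that("equal means fail the strict bidirectional fold-change bound", {
  # mirrored values: group means are exactly equal, sample totals constant,
  # so FC is exactly 1 and the strict > 1 criterion fails
  X <- rbind(F1 = c(9, 11, 11, 9),
             F2 = c(21, 19, 19, 21))
  pt <- normalize_table(make_pt(X, rep(c("Con", "Mod"), each = 2),
                                rep(FALSE, 4)))
  scr <- differential_screen(pt)
  expect_equal(scr$fc, c(1, 1))
  expect_false(any(scr$passes))
})

test_that("the screen is invariant to per-sample global scaling", {
  gen <- gen_peak_table(sim_spec(seed = 44, n_features = 40, n_per_group = 6,
                                 missing_rate = 0))
  pt1 <- normalize_table(gen$peaks)
  pt2raw <- gen$peaks
  pt2raw$intensity[, 3] <- pt2raw$intensity[, 3] * 7.5
  pt2 <- normalize_table(pt2raw)
  s1 <- differential_screen(pt1)
  s2 <- differential_screen(pt2)
  expect_equal(s1$p, s2$p, tolerance = 1e-9)
  expect_equal(s1$fc, s2$fc, tolerance = 1e-9)
  expect_identical(s1$passes, s2$passes)
})

test_that("random-forest panel is deterministic and recovers planted features", {
  gen <- gen_peak_table(sim_spec(seed = 55, n_features = 50, n_per_group = 15,
                                 n_planted = 3, effect_size = 4,
                                 missing_rate = 0))
  pt <- normalize_table(gen$peaks)
  p1 <- rf_biomarker_panel(pt, k = 10, seed = 9, ntree = 200)
  p2 <- rf_biomarker_panel(pt, k = 10, seed = 9, ntree = 200)
  expect_identical(p1$panel, p2$panel)
  expect_true(all(gen$truth$planted_features %in% p1$panel))
  expect_true(p1$cv_accuracy >= 0 && p1$cv_accuracy <= 1)
  expect_true(p1$cv_auc >= 0 && p1$cv_auc <= 1)
})

test_that("panel intersection preserves the first panel's order", {
  expect_equal(intersect_panels(c("a", "b", "c"), c("c", "b", "d")),
               c("b", "c"))
  expect_equal(intersect_panels(c("a", "b"), c("x", "y")), character(0))
  expect_equal(intersect_panels(c("a", "b"), c("b", "a")), c("a", "b"))
})

test_that("peak tables round-trip through TSV with annotations", {
  gen <- gen_peak_table(sim_spec(seed = 66, n_features = 12, n_per_group = 3,
                                 n_qc = 2))
  dir <- withr::local_tempdir()
  f <- file.path(dir, "peaks.tsv")
  write_peak_table(gen$peaks, f)
  back <- read_peak_table(f)
  expect_equal(unname(back$intensity), unname(gen$peaks$intensity))
  expect_equal(back$group, gen$peaks$group)
  expect_equal(back$is_qc, gen$peaks$is_qc)
})
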