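mk_table <- function(values, samples = paste0("s", seq_len(ncol(values)))) {
  dimnames(values) <- list(paste0("P", seq_len(nrow(values))), samples)
  values
}

test_that("TAS equalizes sample totals at the across-sample mean", {
  m <- mk_table(matrix(c(40, 60, 80, 120), 2))
  n <- normalize_intensities(m, "tas")
  expect_equal(unname(colSums(n)), c(150, 150))
  # idempotence
  n2 <- normalize_intensities(n, "tas")
  expect_equal(unname(n2), unname(n), tolerance = 1e-12)
})

test_that("manual normalization divides by per-sample concentration", {
  m <- mk_table(matrix(c(10, 20, 30, 40), 2))
  f <- c(s1 = 2, s2 = 1)
  n <- normalize_intensities(m, "manual", factors = f)
  expect_equal(unname(n[, "s1"]), c(5, 10))
  expect_equal(unname(n[, "s2"]), c(30, 40))
  expect_error(normalize_intensities(m, "manual"), "requires factors")
  expect_error(normalize_intensities(m, "manual", factors = c(s1 = 2)),
               "missing manual factor")
  expect_error(normalize_intensities(m, "manual", factors = c(s1 = 2, s2 = 0)),
               "positive")
})

test_that("'none' returns the input unchanged", {
  m <- mk_table(matrix(1:4, 2))
  expect_equal(unname(normalize_intensities(m, "none")), unname(m),
               ignore_attr = TRUE)
})

test_that("paired t-test reproduces the closed-form toy example", {
  m <- mk_table(matrix(c(1, 2, 3, 2, 4, 6), nrow = 1,
                       dimnames = NULL), samples = paste0("s", 1:6))
  md <- data.frame(sample = paste0("s", 1:6),
                   individual = rep(c("a", "b", "c"), 2),
                   time_point = rep(c("t1", "t2"), each = 3))
  r <- paired_test(m, md)
  expect_equal(r$fold_change, 2.0)
  expect_equal(r$t, 3.464, tolerance = 1e-3)
  expect_equal(r$df, 2)
  expect_equal(r$p_raw, 0.0742, tolerance = 1e-3)
})

test_that("degenerate pairs are flagged, sparse proteoforms excluded", {
  m <- mk_table(matrix(c(1, 2, 3, 1, 2, 3,
                         5, NA, NA, 6, NA, NA), nrow = 2, byrow = TRUE),
                samples = paste0("s", 1:6))
  md <- data.frame(sample = paste0("s", 1:6),
                   individual = rep(c("a", "b", "c"), 2),
                   time_point = rep(c("t1", "t2"), each = 3))
  r <- paired_test(m, md)
  expect_equal(r$flag[1], "zero variance")
  expect_equal(r$fold_change[1], 1)
  expect_true(is.na(r$p_raw[1]))
  expect_match(r$flag[2], "excluded")
})

test_that("Bonferroni-Dunn divides alpha by the test count", {
  expect_equal(bonferroni_dunn(rep(0.01, 10))$alpha_adjusted, 0.005)
  expect_equal(bonferroni_dunn(0.01, k = 1)$alpha_adjusted, 0.05)
  expect_equal(bonferroni_dunn(rep(0.01, 15))$alpha_adjusted, 1 / 300)
  expect_error(bonferroni_dunn(numeric(0)), "k must be")
})

test_that("significance filter applies the two-fold and adjusted-p rules", {
  res <- data.frame(proteoform = c("A", "B", "C"),
                    fold_change = c(2.5, 1.8, 3.0),
                    p_raw = c(0.001, 0.0001, 0.02))
  out <- significance_filter(res, alpha = 0.05, k = 10)
  expect_equal(out$alpha_adjusted, rep(0.005, 3))
  expect_equal(out$significant, c(TRUE, FALSE, FALSE))
  expect_equal(out$direction, c("up", "none", "none"))
  down <- significance_filter(data.frame(proteoform = "D", fold_change = 0.3,
                                         p_raw = 1e-5), k = 10)
  expect_equal(down$direction, "down")
})

test_that("fold changes and p-values are invariant under global rescaling", {
  db <- toy_study_db(seed = 42)
  sim <- simulate_study(db, study_design(seed = 6))
  lib <- build_library(sim$peptides)
  q <- quantify_ms1(sim$ms1, lib)
  r1 <- paired_test(normalize_intensities(q, "none"), sim$metadata)
  q2 <- q * 57.3
  r2 <- paired_test(normalize_intensities(q2, "none"), sim$metadata)
  expect_equal(r1$fold_change, r2$fold_change)
  expect_equal(r1$p_raw, r2$p_raw)
})

test_that("concentration-driven regulation vanishes under manual normalization", {
  db <- toy_study_db(seed = 42)
  fam_acc <- db$accession[db$is_family_member]
  freq <- stats::setNames(rep(1, nrow(db)), db$accession)
  sim <- simulate_study(db, study_design(seed = 17, frequency = freq,
                                         family_share = 0.95))
  lib <- build_library(sim$peptides)
  q <- quantify_ms1(sim$ms1, lib)
  conc <- stats::setNames(sim$metadata$concentration, sim$metadata$sample)
  r_none <- paired_test(normalize_intensities(q, "none"), sim$metadata)
  r_man <- paired_test(normalize_intensities(q, "manual", factors = conc),
                       sim$metadata)
  fam_rows <- r_none$proteoform %in% fam_acc
  expect_true(all(r_none$fold_change[fam_rows] > 1.5))
  expect_true(all(abs(log2(r_man$fold_change[fam_rows])) < 0.5))
  sf <- significance_filter(r_man)
  expect_false(any(sf$significant[fam_rows]))
})

test_that("single-simulation recovery of a true 3-fold upregulation", {
  db <- toy_study_db(seed = 42)
  acc <- db$accession
  fam_acc <- db$accession[db$is_family_member]
  fc <- stats::setNames(rep(1, length(acc)), acc)
  fc[fam_acc[1]] <- 3
  freq <- stats::setNames(rep(1, length(acc)), acc)
  sim <- simulate_study(db, study_design(seed = 10, fold_changes = fc,
                                         frequency = freq, noise_cv = 0.1))
  lib <- build_library(sim$peptides)
  q <- quantify_ms1(sim$ms1, lib)
  r <- paired_test(normalize_intensities(q, "none"), sim$metadata)
  est <- r$fold_change[r$proteoform == fam_acc[1]]
  expect_gt(est, 2.5); expect_lt(est, 3.5)
  bd <- bonferroni_dunn(r$p_raw)
  expect_lt(r$p_raw[r$proteoform == fam_acc[1]], bd$alpha_adjusted)
})

test_that("detection frequencies are binned as published", {
  det <- matrix(c(rep(TRUE, 36), rep(c(TRUE, FALSE), c(13, 23)),
                  rep(FALSE, 36)), nrow = 3, byrow = TRUE,
                dimnames = list(c("A", "B", "C"), NULL))
  f <- detection_frequency(det, 36)
  expect_equal(f$frequency, c(100L, 36L, 0L))
  expect_equal(f$class, c("ubiquitous", "uncommon", "rare"))
  expect_warning(classify_frequency(85), "unclassified")
  expect_error(detection_frequency(det, 2), "more individuals")
})

test_that("concordance reports correlation and discordant proteoforms", {
  f <- c(A = 2, B = 3, C = 1.5, D = 4)
  expect_equal(concordance(f, f)$r, 1)
  g <- f; g["B"] <- f["B"] * 2.5
  cc <- concordance(f, g)
  expect_true(cc$report$discordant[cc$report$proteoform == "B"])
  expect_equal(sum(cc$report$discordant), 1L)
  expect_error(concordance(f[1:2], f[1:2]), ">= 3")
})
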