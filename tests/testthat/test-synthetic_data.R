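db <- toy_study_db(seed = 42)
fam <- protein_db(as.data.frame(db)[db$is_family_member, ], name = "family_only")

test_that("generated family respects identity bands and uniqueness", {
  spec <- family_spec(n_central = 4, n_peripheral = 2)
  fam <- generate_family(spec, seed = 42)   # carries the role annotation
  ids <- identity_summary(fam)
  role <- fam$role
  L <- spec$base_length
  central_floor <- 100 * (L - ceiling(L * (1 - spec$central_identity_min / 100))) / L
  for (k in seq_len(nrow(ids$pair_identities))) {
    p <- ids$pair_identities[k, ]
    ra <- role[fam$accession == p$a]; rb <- role[fam$accession == p$b]
    if (ra == "central" && rb == "central") {
      expect_gte(p$identity, central_floor)
    } else {
      expect_gte(p$identity, spec$peripheral_identity_range[1])
      expect_lte(p$identity, spec$peripheral_identity_range[2])
    }
  }
  map <- map_proteotypic(fam)
  counts <- table(unlist(map$parents[map$proteotypic]))
  expect_true(all(fam$accession %in% names(counts)))
})

test_that("two centrals at 99% identity differ at few positions, each distinguishable", {
  f2 <- generate_family(family_spec(n_central = 2, n_peripheral = 0,
                                    central_identity_min = 99), seed = 5)
  d <- sum(strsplit(f2$sequence[1], "")[[1]] != strsplit(f2$sequence[2], "")[[1]])
  expect_lte(d, 2L)
  map <- map_proteotypic(f2)
  expect_setequal(unlist(map$parents[map$proteotypic]), f2$accession)
})

test_that("a family of one is trivially all-proteotypic", {
  f1 <- generate_family(family_spec(n_central = 1, n_peripheral = 0), seed = 9)
  expect_equal(nrow(f1), 1L)
  expect_true(all(map_proteotypic(f1)$proteotypic))
})

test_that("background proteins share no tryptic peptide with the family", {
  bg <- protein_db(as.data.frame(db)[!db$is_family_member, ], name = "bg")
  expect_equal(anyDuplicated(bg$accession), 0L)
  fam_keys <- unlist(lapply(fam$sequence, function(s)
    tryptic_digest(s, 2)$peptide))
  bg_keys <- unlist(lapply(bg$sequence, function(s)
    tryptic_digest(s, 2)$peptide))
  long_enough <- nchar(intersect(fam_keys, bg_keys)) >= 6
  expect_false(any(long_enough))
  expect_equal(nrow(generate_background(0, seed = 1)), 0L)
})

test_that("identical seed and design reproduce the matrices bit for bit", {
  d <- study_design(seed = 7)
  s1 <- simulate_study(db, d)
  s2 <- simulate_study(db, d)
  expect_identical(s1$ms1, s2$ms1)
  expect_identical(s1$ms2, s2$ms2)
  expect_identical(s1$metadata, s2$metadata)
  s3 <- simulate_study(db, study_design(seed = 8))
  expect_false(identical(s1$ms1, s3$ms1))
})

test_that("noise-free unit-fold simulation is constant across samples", {
  acc <- db$accession
  d <- noise_free_design(db, fold_changes = stats::setNames(rep(1, length(acc)), acc))
  sim <- simulate_study(db, d)
  expect_true(all(apply(sim$ms1, 1, function(v) max(v) - min(v) == 0)))
  expect_equal(stats::sd(sim$metadata$concentration), 0)
})

test_that("a noise-free 3-fold proteoform triples exactly at t2", {
  acc <- db$accession
  target <- fam$accession[1]
  fc <- stats::setNames(rep(1, length(acc)), acc)
  fc[target] <- 3
  sim <- simulate_study(db, noise_free_design(db, fold_changes = fc))
  map <- sim$peptides
  uniq <- map$key[map$proteotypic &
                    vapply(map$parents, identical, logical(1), target)]
  md <- sim$metadata
  t1 <- sim$ms1[uniq, md$sample[md$time_point == "t1"], drop = FALSE]
  t2 <- sim$ms1[uniq, md$sample[md$time_point == "t2"], drop = FALSE]
  expect_equal(unname(t2), unname(3 * t1), tolerance = 1e-12)
  bgpep <- map$key[vapply(map$parents, function(p)
    all(p %in% db$accession[!db$is_family_member]), logical(1))]
  expect_equal(unname(sim$ms1[bgpep, md$time_point == "t1"]),
               unname(sim$ms1[bgpep, md$time_point == "t2"]),
               tolerance = 1e-12)
})

test_that("fragment rows sum back to the peptide area when fragment noise is off", {
  d <- study_design(seed = 3, fragment_cv = 0)
  sim <- simulate_study(db, d)
  pep_of <- sub("\\.f[0-9]+$", "", rownames(sim$ms2))
  sums <- rowsum(ifelse(is.na(sim$ms2), 0, sim$ms2), group = pep_of)
  sums <- sums[rownames(sim$ms1), , drop = FALSE]
  m1 <- ifelse(is.na(sim$ms1), 0, sim$ms1)
  expect_equal(unname(sums), unname(m1), tolerance = 1e-10)
})

test_that("simulated concentration rises with family upregulation, monotonically", {
  sim <- simulate_study(db, study_design(seed = 21))
  md <- sim$metadata
  m1 <- mean(md$concentration[md$time_point == "t1"])
  m2 <- mean(md$concentration[md$time_point == "t2"])
  expect_gt(m2, m1)
  expect_equal(m1, 1.4, tolerance = 0.15)
  expect_equal(m2, 2.6, tolerance = 0.45)

  acc <- db$accession
  fam_acc <- fam$accession
  deltas <- vapply(c(1, 2, 3), function(f) {
    fc <- stats::setNames(rep(1, length(acc)), acc)
    fc[fam_acc] <- f
    s <- simulate_study(db, study_design(seed = 21, fold_changes = fc))
    with(s$metadata, mean(concentration[time_point == "t2"]) -
                     mean(concentration[time_point == "t1"]))
  }, numeric(1))
  expect_true(all(diff(deltas) > 0))
})

test_that("empirical detection frequency converges to the class probability", {
  acc <- db$accession
  freq <- stats::setNames(rep(1, length(acc)), acc)
  freq[fam$accession[3]] <- 0.6
  sim <- simulate_study(db, study_design(n_individuals = 500, seed = 4,
                                         frequency = freq))
  emp <- mean(sim$truth$detect[fam$accession[3], ])
  expect_lt(abs(emp - 0.6), 3.5 * sqrt(0.6 * 0.4 / 500))
})
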