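test_that("FASTA reading collapses redundant sequences and keeps order", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">sp|AAA1|first", "GGGGGKAAAATKEEEEER",
               ">sp|AAA2|same sequence, different header",
               "GGGGGKAAAATKEEE", "EER",
               ">sp|BBB1|distinct", "MMMMMKTTTTTTR"), fa)
  db <- read_fasta(fa)
  expect_equal(nrow(db), 2L)
  expect_equal(db$accession, c("AAA1", "BBB1"))
  expect_equal(db$merged_accessions[[1]], c("AAA1", "AAA2"))

  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_equal(nrow(read_fasta(empty)), 0L)

  fa3 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">C3 x", "AAAK", ">A1 y", "CCCK", ">B2 z", "DDDK"), fa3)
  expect_equal(read_fasta(fa3)$accession, c("C3", "A1", "B2"))
})

test_that("non-standard residues are rejected with their position", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P1", "AAXK"), fa)
  expect_error(read_fasta(fa), "residue 'X' at position 3")
})

test_that("annotations attach locus and flags, signal trimming merges variants", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P1", "MKWLLLAAAATKEEEEER",   # signal MKWLLL + mature
               ">P2", "AAAATKEEEEER"), fa)    # mature only
  ann <- data.frame(accession = c("P1", "P2"), gene_locus = c("g1", "g1"),
                    is_family_member = c(TRUE, TRUE),
                    signal_length = c(6L, 0L))
  db <- read_fasta(fa, annotations = ann, trim_signal = TRUE)
  expect_equal(nrow(db), 1L)
  expect_equal(db$merged_accessions[[1]], c("P1", "P2"))
  expect_equal(db$gene_locus, "g1")
})

test_that("tryptic digestion follows the K/R-not-before-P rule", {
  expect_equal(tryptic_digest("AKRPGK", 0)$peptide, c("AK", "RPGK"))
  expect_equal(tryptic_digest("AAA", 0)$peptide, "AAA")
  expect_setequal(tryptic_digest("AKEK", 1)$peptide, c("AK", "EK", "AKEK"))
  expect_error(tryptic_digest("", 0), "non-empty")
})

test_that("digestion agrees with the brute-force oracle on random sequences", {
  set.seed(11)
  for (i in 1:150) {
    s <- random_aa_seq(sample(5:60, 1))
    mm <- sample(0:2, 1)
    got <- sort(tryptic_digest(s, mm)$peptide)
    expect_identical(got, oracle_digest(s, mm))
  }
})

test_that("0-missed digestion products reconstruct the parent sequence", {
  set.seed(12)
  for (i in 1:40) {
    s <- random_aa_seq(sample(10:80, 1))
    d <- tryptic_digest(s, 0)
    expect_identical(paste(d$peptide, collapse = ""), s)
  }
})

test_that("peptide masses are monoisotopic with fixed carbamidomethyl-C", {
  expect_equal(peptide_mass("ACK"), 377.17328, tolerance = 1e-4)
  expect_equal(peptide_mass("G"), 75.03203, tolerance = 1e-4)
  expect_error(peptide_mass(""), "empty")
  expect_error(peptide_mass("AZB"), "residue 'Z' at position 2")
})

test_that("mass is additive up to one water per bond", {
  set.seed(13)
  for (i in 1:25) {
    s1 <- random_aa_seq(sample(1:20, 1))
    s2 <- random_aa_seq(sample(1:20, 1))
    expect_equal(peptide_mass(paste0(s1, s2)),
                 peptide_mass(s1) + peptide_mass(s2) - 18.010565,
                 tolerance = 1e-5)
  }
})

test_that("m/z admissibility follows the scan window", {
  expect_equal(mz_admissible(377.17328, charges = c(1, 2)), 1L)
  expect_equal(mz_admissible(1499 - 1.00728, charges = 1), 1L)
  expect_equal(mz_admissible(100, charges = 1), integer(0))
  expect_error(mz_admissible(-5, charges = 1), "positive")
})

test_that("proteotypic mapping isolates the distinguishing peptide pair", {
  map <- map_proteotypic(toy_pair_db(), digest_params(max_missed = 0))
  uniq <- map[map$proteotypic, ]
  expect_setequal(uniq$peptide, c("AAAATK", "AAAVTK"))
  shared <- map[!map$proteotypic, ]
  expect_true(all(vapply(shared$parents, length, integer(1)) == 2L))
})

test_that("a single-protein database makes every admissible peptide proteotypic", {
  db <- protein_db(data.frame(accession = "solo",
                              sequence = "GGGGGKAAAATKEEEEERMMMMMMK"),
                   name = "solo")
  map <- map_proteotypic(db)
  expect_true(all(map$proteotypic))
})

test_that("proteotypic count never grows in a superset context", {
  dbA <- toy_pair_db()
  extra <- data.frame(accession = "BG1",
                      sequence = "CCCCCKAAAATKDDDDDK",
                      is_family_member = FALSE)
  dbB <- protein_db(rbind(as.data.frame(dbA)[, c("accession", "sequence",
                                                 "is_family_member")],
                          extra), name = "superset")
  cc <- compare_contexts(dbA, dbB, digest_params(max_missed = 0))
  expect_true(all(cc$n_proteotypic_b <= cc$n_proteotypic_a))
  # P1's only unique peptide AAAATK is shared into the background copy
  expect_true(cc$unidentifiable_in_b[cc$accession == "P1"])
  expect_equal(attr(cc, "lost_peptides")$P1, "AAAATK")
})

test_that("identical contexts show zero differences", {
  dbA <- toy_pair_db()
  cc <- compare_contexts(dbA, dbA)
  expect_true(all(cc$n_lost == 0L))
  expect_false(any(cc$unidentifiable_in_b))
})

test_that("mismatched family sequences are an error", {
  dbA <- toy_pair_db()
  dbC <- protein_db(data.frame(accession = c("P1", "P2"),
                               sequence = c("GGGGGKAAAATKEEEEER",
                                            "GGGGGKAAAVTKEEEEEK")),
                    name = "other")
  expect_error(compare_contexts(dbA, dbC), "differ")
})

test_that("I/L-equivalent proteins are indistinguishable by default", {
  db <- protein_db(data.frame(
    accession = c("P1", "P2"),
    sequence = c("GGGGGKAAIATKEEEEER", "GGGGGKAALATKEEEEER")), name = "il")
  map <- map_proteotypic(db, digest_params(max_missed = 0))
  expect_false(any(map$proteotypic))
  map2 <- map_proteotypic(db, digest_params(max_missed = 0,
                                            il_equivalent = FALSE))
  expect_equal(sum(map2$proteotypic), 2L)
})

test_that("long-form screening reports support, absence and undecidability", {
  mature <- "GGGGGKAAAATKEEEEER"
  db <- protein_db(data.frame(
    accession = c("M1", "L1", "L2"),
    sequence = c(mature,
                 paste0(mature, "TTTTTTWK"),   # admissible unique extension
                 paste0(mature, "GGK")),       # extension too short to observe
    is_long_form = c(FALSE, TRUE, TRUE)), name = "lf")
  p0 <- digest_params(max_missed = 0)
  rep1 <- screen_long_forms(db, observed_peptides = character(0), params = p0)
  expect_equal(rep1$verdict[rep1$accession == "L1"],
               "not supported at protein level")
  expect_equal(rep1$verdict[rep1$accession == "L2"], "undecidable")
  rep2 <- screen_long_forms(db, observed_peptides = "TTTTTTWK", params = p0)
  expect_equal(rep2$verdict[rep2$accession == "L1"], "supported")
  no_lf <- protein_db(data.frame(accession = "M1", sequence = mature),
                      name = "none")
  expect_equal(nrow(screen_long_forms(no_lf, character(0))), 0L)
})

test_that("pairwise identity matches column-counting on gapless alignments", {
  expect_equal(pairwise_identity("ACDEFGHIK", "ACDEFGHIK"), 100)
  expect_equal(pairwise_identity("ACD", "ACE"), 66.7, tolerance = 0.01)
  db <- toy_pair_db()
  ids <- identity_summary(db)
  expect_equal(ids$mean_identity, 100 * 17 / 18, tolerance = 0.01)
})
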