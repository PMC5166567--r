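# Independent brute-force oracle for tryptic digestion: enumerate every
# substring of the sequence and keep those whose boundaries are valid
# cleavage points (C-terminal to K/R except before P, or a sequence end)
# and whose internal cleavage-site count does not exceed max_missed.
oracle_digest <- function(sequence, max_missed) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(aa)
  sites <- which(aa %in% c("K", "R"))
  sites <- sites[sites < n & aa[sites + 1L] != "P"]
  starts <- c(1L, sites + 1L)
  ends <- c(sites, n)
  out <- character(0)
  for (s in starts) {
    for (e in ends[ends >= s]) {
      internal <- sum(sites >= s & sites < e)
      if (internal <= max_missed)
        out <- c(out, substr(sequence, s, e))
    }
  }
  sort(out)
}

random_aa_seq <- function(n) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
               n, replace = TRUE), collapse = "")
}

# two-proteoform toy database: identical except one residue inside the
# middle tryptic peptide (AAAATK vs AAAVTK)
toy_pair_db <- function() {
  protein_db(data.frame(
    accession = c("P1", "P2"),
    sequence = c("GGGGGKAAAATKEEEEER", "GGGGGKAAAVTKEEEEER"),
    stringsAsFactors = FALSE), name = "toy")
}

# small simulation setup reused across tests; built once per test file
toy_study_db <- function(seed = 42) {
  fam <- generate_family(family_spec(n_central = 4, n_peripheral = 2),
                         seed = seed)
  bg <- generate_background(8, seed = seed + 1, family_db = fam)
  combine_dbs(fam, bg)
}

noise_free_design <- function(db, ...) {
  acc <- db$accession
  study_design(frequency = stats::setNames(rep(1, length(acc)), acc),
               noise_cv = 0, tech_cv = 0, fragment_cv = 0, conc_cv = 0,
               ion_cv = 0, ...)
}
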