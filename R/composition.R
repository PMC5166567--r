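#' Relative proteoform composition (100% method)
#'
#' Estimates the relative composition of the family from unique-peptide
#' areas, assuming equal ionization efficiencies of family-derived peptides
#' (defensible for highly homologous proteoforms). Per proteoform, a score
#' is the sum of its unique-peptide areas across samples divided by its
#' number of unique peptides quantified; scores are then normalized to sum
#' to 100%. Proteoforms below the share threshold are merged into an
#' "Others" bin.
#'
#' @param ms2_table Numeric peptide x sample or fragment x sample matrix
#'   (fragment rows named `<peptide>.f<i>` are collapsed first).
#' @param library An [build_library()] ion library of unique peptides.
#' @param unique_counts Named count of unique peptides per proteoform;
#'   defaults to the per-proteoform peptide counts of the library.
#' @param threshold Share (percent) below which proteoforms are pooled
#'   into `"Others"` (default 5).
#' @param per_sample If `TRUE`, additionally return a per-sample share
#'   matrix instead of pooling areas across samples first.
#' @return A list of class `composition_report` with `shares` (named
#'   percentages of proteoforms at or above threshold), `others_bin`
#'   (percent), `all_shares` (unmerged), `threshold`, and optionally
#'   `per_sample_shares`.
#' @export
relative_composition <- function(ms2_table, library, unique_counts = NULL,
                                 threshold = 5, per_sample = FALSE) {
  stopifnot(is.matrix(ms2_table), inherits(library, "ion_library"))
  pep_of <- sub("\\.f[0-9]+$", "", rownames(ms2_table))
  known <- pep_of %in% library$key
  mat <- ms2_table[known, , drop = FALSE]
  pep_of <- pep_of[known]
  if (nrow(mat) == 0L) stop("no library peptides found in the matrix")
  prot_of <- library$proteoform[match(pep_of, library$key)]

  if (is.null(unique_counts)) {
    unique_counts <- table(library$proteoform)
  }
  prots <- unique(library$proteoform)
  if (any(is.na(unique_counts[prots]) | unique_counts[prots] <= 0))
    stop("unique_counts must be positive for every library proteoform")

  area <- rowsum(rowSums(mat, na.rm = TRUE), group = prot_of)
  score <- stats::setNames(rep(0, length(prots)), prots)
  score[rownames(area)] <- area[, 1]
  score <- score / as.numeric(unique_counts[prots])
  if (sum(score) <= 0) stop("zero total score; nothing to compose")
  shares <- 100 * score / sum(score)

  low <- shares < threshold
  kept <- sort(shares[!low], decreasing = TRUE)
  out <- list(shares = kept, others_bin = sum(shares[low]),
              all_shares = shares, threshold = threshold)
  if (per_sample) {
    ps <- apply(mat, 2, function(v) {
      a <- rowsum(ifelse(is.na(v), 0, v), group = prot_of)
      s <- stats::setNames(rep(0, length(prots)), prots)
      s[rownames(a)] <- a[, 1]
      s <- s / as.numeric(unique_counts[prots])
      if (sum(s) > 0) 100 * s / sum(s) else s * NA_real_
    })
    out$per_sample_shares <- ps
  }
  structure(out, class = "composition_report")
}

#' @export
print.composition_report <- function(x, ...) {
  cat("Relative proteoform composition (100% method):\n")
  for (p in names(x$shares))
    cat(sprintf("  %-12s %6.2f%%\n", p, x$shares[p]))
  cat(sprintf("  %-12s %6.2f%%  (< %g%% each)\n", "Others", x$others_bin,
              x$threshold))
  invisible(x)
}

#' Family fraction of total MS intensity
#'
#' Sums the areas of all family-derived peptides (unique and shared between
#' family proteoforms) and divides by the total intensity of all quantified
#' peptides, per sample.
#'
#' @param all_peptide_areas Numeric peptide x sample matrix covering family
#'   and background peptides.
#' @param family_peptides Character vector of family peptide row names
#'   (unique and shared).
#' @return List with `per_sample` (percent per sample), `mean` and `sd`
#'   across samples.
#' @export
family_fraction <- function(all_peptide_areas, family_peptides) {
  stopifnot(is.matrix(all_peptide_areas))
  fam <- intersect(rownames(all_peptide_areas), family_peptides)
  total <- colSums(all_peptide_areas, na.rm = TRUE)
  if (any(total <= 0)) stop("sample with zero total intensity")
  fam_sum <- if (length(fam))
    colSums(all_peptide_areas[fam, , drop = FALSE], na.rm = TRUE)
  else rep(0, ncol(all_peptide_areas))
  pct <- 100 * fam_sum / total
  list(per_sample = pct, mean = mean(pct), sd = stats::sd(pct))
}

#' Family peptide row names of a peptide map
#'
#' Helper returning the keys of peptides whose parents are all family
#' members (unique and shared within the family), given the database.
#'
#' @param peptides A `peptide_map`.
#' @param db The [protein_db()] the map was computed from.
#' @return Character vector of peptide keys.
#' @export
family_peptide_keys <- function(peptides, db) {
  fam <- db$accession[db$is_family_member]
  peptides$key[vapply(peptides$parents, function(p) all(p %in% fam),
                      logical(1))]
}
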