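#' Construct a proteoform database context
#'
#' A database context is a curated set of protein entries against which
#' peptide uniqueness is judged. Two contexts are typically compared: a
#' designated family-only database (the homologous proteoforms alone) and a
#' comprehensive database that adds a constant background proteome. Whether
#' a peptide is proteotypic depends on the context: the same family peptide
#' can lose uniqueness once background proteins enter the database.
#'
#' @param entries A data.frame with columns `accession`, `sequence` and
#'   optionally `gene_locus`, `is_family_member`, `reviewed`, `is_long_form`,
#'   `merged_accessions` (missing optional columns are filled with defaults).
#' @param name Context name, e.g. `"family_only"` or `"comprehensive"`.
#' @return A `protein_db` object (a validated data.frame with a `name`
#'   attribute).
#' @export
protein_db <- function(entries, name = "db") {
  stopifnot(is.data.frame(entries))
  req <- c("accession", "sequence")
  miss <- setdiff(req, names(entries))
  if (length(miss)) stop("entries lack columns: ", paste(miss, collapse = ", "))
  defaults <- list(gene_locus = NA_character_, is_family_member = TRUE,
                   reviewed = FALSE, is_long_form = FALSE)
  for (nm in names(defaults)) {
    if (is.null(entries[[nm]])) entries[[nm]] <- rep(defaults[[nm]], nrow(entries))
  }
  if (is.null(entries$merged_accessions)) {
    entries$merged_accessions <- I(as.list(entries$accession))
  }
  if (anyDuplicated(entries$accession))
    stop("duplicate accession in database: ",
         entries$accession[duplicated(entries$accession)][1])
  if (any(!nzchar(entries$sequence) | is.na(entries$sequence)))
    stop("empty sequence in database")
  for (i in seq_len(nrow(entries))) {
    aa <- strsplit(entries$sequence[i], "", fixed = TRUE)[[1]]
    bad <- which(!aa %in% AA_ALPHABET)
    if (length(bad))
      stop(sprintf("non-standard residue '%s' at position %d in %s",
                   aa[bad[1]], bad[1], entries$accession[i]))
  }
  rownames(entries) <- NULL
  structure(entries, name = name, class = c("protein_db", "data.frame"))
}

#' @export
print.protein_db <- function(x, ...) {
  cat(sprintf("protein_db '%s': %d entries (%d family, %d background, %d long-form)\n",
              attr(x, "name"), nrow(x), sum(x$is_family_member),
              sum(!x$is_family_member), sum(x$is_long_form)))
  invisible(x)
}

#' Read a proteoform FASTA database
#'
#' Reads protein sequences from FASTA, attaches locus/family annotation and
#' clears redundancies: records with identical (optionally signal-trimmed)
#' sequences are collapsed to a single entry whose `merged_accessions` field
#' records all contributing accessions. Such redundancies typically arise
#' from database entries differing only in the signal peptide that is
#' cleaved before secretion.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped).
#' @param annotations Optional annotation table (data.frame or TSV path)
#'   with column `accession` and any of `gene_locus`, `is_family_member`,
#'   `reviewed`, `is_long_form`, `signal_length`.
#' @param trim_signal If `TRUE`, trim the first `signal_length` residues of
#'   each annotated entry before redundancy comparison (mature-sequence
#'   keying).
#' @param name Context name passed to [protein_db()].
#' @return A [protein_db()] with one entry per distinct sequence, input
#'   order preserved.
#' @export
read_fasta <- function(path, annotations = NULL, trim_signal = FALSE,
                       name = "db") {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(seqs) == 0L) {
    return(protein_db(data.frame(accession = character(0),
                                 sequence = character(0)), name = name))
  }
  # first whitespace-delimited token of the header; strip db prefixes (tr|X|Y)
  acc <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  acc <- vapply(strsplit(acc, "|", fixed = TRUE), function(p) {
    if (length(p) >= 2L) p[2L] else p[1L]
  }, character(1))
  sq <- as.character(seqs)
  for (i in seq_along(sq)) {
    aa <- strsplit(sq[i], "", fixed = TRUE)[[1]]
    bad <- which(!aa %in% AA_ALPHABET)
    if (length(bad))
      stop(sprintf("non-standard residue '%s' at position %d in record '%s'",
                   aa[bad[1]], bad[1], acc[i]))
  }

  ann <- annotations
  if (is.character(ann)) {
    ann <- utils::read.delim(ann, stringsAsFactors = FALSE)
  }
  entries <- data.frame(accession = acc, sequence = unname(sq),
                        stringsAsFactors = FALSE)
  entries$gene_locus <- NA_character_
  entries$is_family_member <- TRUE
  entries$reviewed <- FALSE
  entries$is_long_form <- FALSE
  sig_len <- rep(0L, nrow(entries))
  if (!is.null(ann)) {
    stopifnot("accession" %in% names(ann))
    idx <- match(entries$accession, ann$accession)
    for (col in c("gene_locus", "is_family_member", "reviewed", "is_long_form")) {
      if (!is.null(ann[[col]])) {
        v <- ann[[col]][idx]
        entries[[col]] <- ifelse(is.na(idx), entries[[col]], v)
      }
    }
    if (!is.null(ann$signal_length)) {
      v <- ann$signal_length[idx]
      sig_len <- ifelse(is.na(v), 0L, as.integer(v))
    }
  }

  key <- entries$sequence
  if (trim_signal) {
    key <- substring(entries$sequence, sig_len + 1L)
  }
  first <- !duplicated(key)
  merged <- split(entries$accession, match(key, key[first]))
  out <- entries[first, , drop = FALSE]
  if (trim_signal) out$sequence <- key[first]
  out$merged_accessions <- I(unname(merged[as.character(seq_len(sum(first)))]))
  protein_db(out, name = name)
}

#' In-silico tryptic digestion
#'
#' Cleaves a protein sequence C-terminal to lysine (K) or arginine (R),
#' suppressed when the following residue is proline, and enumerates all
#' products carrying 0 to `max_missed` internal missed cleavages.
#'
#' @param sequence A single amino-acid string.
#' @param max_missed Maximum number of internal missed cleavage sites.
#' @return A data.frame with columns `peptide`, `start`, `end`,
#'   `missed_cleavages`, ordered by start position then missed cleavages.
#' @examples
#' tryptic_digest("AKRPGK", max_missed = 0)
#' tryptic_digest("AKEK", max_missed = 1)
#' @export
tryptic_digest <- function(sequence, max_missed = 2L) {
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence))
    stop("sequence must be a single non-empty string")
  if (max_missed < 0L) stop("max_missed must be >= 0")
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(aa)
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & aa[pmin(cut_after + 1L, n)] != "P"]
  bounds <- c(0L, cut_after, n)          # fragment k spans bounds[k]+1..bounds[k+1]
  nfrag <- length(bounds) - 1L
  res <- vector("list", nfrag)
  for (i in seq_len(nfrag)) {
    jmax <- min(nfrag, i + max_missed)
    js <- i:jmax
    res[[i]] <- data.frame(
      peptide = vapply(js, function(j) substr(sequence, bounds[i] + 1L, bounds[j + 1L]),
                       character(1)),
      start = bounds[i] + 1L,
      end = bounds[js + 1L],
      missed_cleavages = js - i,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  out <- out[order(out$start, out$missed_cleavages), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Digestion and admissibility parameters
#'
#' Bundles the settings that decide which digestion products can serve as
#' quantifiable ions: missed-cleavage allowance, peptide length bounds, the
#' charge states considered, and the scan window. Charge 1 is additionally
#' considered for short peptides (at or below `short_charge1_len` residues),
#' which otherwise fall below the lower m/z bound at charge 2.
#'
#' @param max_missed Maximum internal missed cleavages (default 2).
#' @param length_range Inclusive peptide length bounds (default 6-30).
#' @param charges Charge states considered for every peptide (default 2-4).
#' @param short_charge1_len Peptides at or below this length also consider
#'   charge 1 (default 7).
#' @param window Inclusive m/z window (default 250-1500).
#' @param il_equivalent Treat isoleucine and leucine as indistinguishable
#'   (equal residue mass) when judging peptide uniqueness (default `TRUE`).
#' @return A list of class `digest_params`.
#' @export
digest_params <- function(max_missed = 2L, length_range = c(6L, 30L),
                          charges = 2:4, short_charge1_len = 7L,
                          window = c(250, 1500), il_equivalent = TRUE) {
  stopifnot(max_missed >= 0, length(length_range) == 2L,
            length_range[1] >= 1, length(window) == 2L, window[1] < window[2])
  structure(list(max_missed = as.integer(max_missed),
                 length_range = as.integer(length_range),
                 charges = as.integer(charges),
                 short_charge1_len = as.integer(short_charge1_len),
                 window = as.numeric(window),
                 il_equivalent = isTRUE(il_equivalent)),
            class = "digest_params")
}

il_normalize <- function(x) gsub("I", "L", x, fixed = TRUE)

admissible_charges <- function(mass, peptide_length, params) {
  ch <- params$charges
  if (peptide_length <= params$short_charge1_len) ch <- union(1L, ch)
  mz_admissible(mass, charges = ch, window = params$window)
}

#' Map peptides to proteoforms and flag proteotypic peptides
#'
#' Digests every entry of a database context, merges identical peptide
#' sequences (with I/L treated as equivalent when configured), records the
#' full parent set of each peptide, applies the admissibility filter
#' (length bounds and m/z window), and flags as proteotypic those peptides
#' mapping to exactly one proteoform in this context. With highly
#' homologous families only these proteoform-specific peptides can support
#' identification and quantification, and their number shrinks as database
#' complexity grows.
#'
#' @param db A [protein_db()].
#' @param params A [digest_params()] object.
#' @return A data.frame of class `peptide_map` with columns `peptide`,
#'   `key` (I/L-normalized uniqueness key), `parents` (list of accessions),
#'   `n_parents`, `missed_cleavages` (minimum over occurrences),
#'   `mono_mass`, `charges` (list), `proteotypic`. Attribute `context`
#'   carries the database name.
#' @export
map_proteotypic <- function(db, params = digest_params()) {
  stopifnot(inherits(db, "protein_db"))
  if (nrow(db) == 0L) stop("empty database context")
  pieces <- lapply(seq_len(nrow(db)), function(i) {
    d <- tryptic_digest(db$sequence[i], params$max_missed)
    d$accession <- db$accession[i]
    d
  })
  all <- do.call(rbind, pieces)
  len <- nchar(all$peptide)
  all <- all[len >= params$length_range[1] & len <= params$length_range[2], ,
             drop = FALSE]
  if (nrow(all) == 0L) {
    out <- data.frame(peptide = character(0), key = character(0),
                      n_parents = integer(0), missed_cleavages = integer(0),
                      mono_mass = numeric(0), proteotypic = logical(0))
    out$parents <- list(); out$charges <- list()
    return(structure(out, context = attr(db, "name"),
                     class = c("peptide_map", "data.frame")))
  }
  all$key <- if (params$il_equivalent) il_normalize(all$peptide) else all$peptide
  keys <- unique(all$key)
  grp <- match(all$key, keys)
  parents <- lapply(split(all$accession, grp), function(a) sort(unique(a)))
  missed <- vapply(split(all$missed_cleavages, grp), min, numeric(1))
  rep_pep <- vapply(split(all$peptide, grp), `[`, character(1), 1L)
  ord <- order(as.integer(names(parents)))
  parents <- parents[ord]; missed <- missed[ord]; rep_pep <- rep_pep[ord]

  mono <- peptide_mass(rep_pep)
  charges <- lapply(seq_along(rep_pep), function(i)
    admissible_charges(mono[i], nchar(rep_pep[i]), params))
  keep <- lengths(charges) > 0L
  out <- data.frame(peptide = rep_pep, key = keys,
                    n_parents = lengths(parents),
                    missed_cleavages = as.integer(missed),
                    mono_mass = mono, stringsAsFactors = FALSE)
  out$parents <- unname(parents)
  out$charges <- unname(charges)
  out$proteotypic <- out$n_parents == 1L
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, context = attr(db, "name"),
            class = c("peptide_map", "data.frame"))
}

#' Per-proteoform proteotypic counts under two database contexts
#'
#' Compares how many proteotypic peptides each family proteoform retains in
#' two database contexts sharing identical family sequences (e.g. a
#' family-only database versus a comprehensive database with background
#' proteins), and flags proteoforms that lose all proteotypic peptides and
#' hence become unidentifiable in the larger context.
#'
#' @param dbA,dbB Two [protein_db()] contexts with identical family entries.
#' @param params A [digest_params()].
#' @return A data.frame with columns `accession`, `n_proteotypic_a`,
#'   `n_proteotypic_b`, `n_lost`, `unidentifiable_in_b`; attribute
#'   `lost_peptides` holds the per-proteoform peptide keys that lost
#'   proteotypic status in `dbB`.
#' @export
compare_contexts <- function(dbA, dbB, params = digest_params()) {
  famA <- dbA[dbA$is_family_member, c("accession", "sequence")]
  famB <- dbB[dbB$is_family_member, c("accession", "sequence")]
  famA <- famA[order(famA$accession), ]; famB <- famB[order(famB$accession), ]
  if (!identical(famA$accession, famB$accession) ||
      !identical(famA$sequence, famB$sequence))
    stop("family proteoforms differ between the two contexts")
  mapA <- map_proteotypic(dbA, params)
  mapB <- map_proteotypic(dbB, params)
  proteo_keys <- function(map, acc)
    map$key[map$proteotypic & vapply(map$parents, function(p)
      identical(p, acc), logical(1))]
  acc <- famA$accession
  lost <- stats::setNames(vector("list", length(acc)), acc)
  nA <- nB <- integer(length(acc))
  for (i in seq_along(acc)) {
    kA <- proteo_keys(mapA, acc[i]); kB <- proteo_keys(mapB, acc[i])
    nA[i] <- length(kA); nB[i] <- length(kB)
    lost[[i]] <- setdiff(kA, kB)
  }
  out <- data.frame(accession = acc, n_proteotypic_a = nA,
                    n_proteotypic_b = nB, n_lost = lengths(lost),
                    unidentifiable_in_b = nA > 0L & nB == 0L,
                    stringsAsFactors = FALSE)
  attr(out, "lost_peptides") <- lost
  out
}

#' Screen putative long-form proteoforms for protein-level evidence
#'
#' Some family members are annotated only from cDNA as longer transcripts
#' (e.g. 235-residue forms) whose expression at protein level is uncertain.
#' For each long-form entry this screen lists the admissible peptides unique
#' to that entry within the database (necessarily arising from its
#' distinguishing region) and checks whether any were observed.
#'
#' @param db A [protein_db()] containing long-form entries
#'   (`is_long_form = TRUE`).
#' @param observed_peptides Character vector of observed peptide sequences.
#' @param params A [digest_params()].
#' @return A data.frame with one row per long form: `accession`,
#'   `n_unique_peptides`, `n_observed`, `verdict` (one of `"supported"`,
#'   `"not supported at protein level"`, `"undecidable"`); attribute
#'   `unique_peptides` carries the peptide lists.
#' @export
screen_long_forms <- function(db, observed_peptides, params = digest_params()) {
  long_acc <- db$accession[db$is_long_form]
  if (length(long_acc) == 0L) {
    return(data.frame(accession = character(0), n_unique_peptides = integer(0),
                      n_observed = integer(0), verdict = character(0)))
  }
  map <- map_proteotypic(db, params)
  obs_keys <- if (params$il_equivalent) il_normalize(observed_peptides)
              else observed_peptides
  peps <- stats::setNames(vector("list", length(long_acc)), long_acc)
  n_obs <- integer(length(long_acc))
  verdict <- character(length(long_acc))
  for (i in seq_along(long_acc)) {
    sel <- map$proteotypic &
      vapply(map$parents, function(p) identical(p, long_acc[i]), logical(1))
    peps[[i]] <- map$key[sel]
    n_obs[i] <- sum(peps[[i]] %in% obs_keys)
    verdict[i] <- if (length(peps[[i]]) == 0L) "undecidable"
      else if (n_obs[i] > 0L) "supported"
      else "not supported at protein level"
  }
  out <- data.frame(accession = long_acc, n_unique_peptides = lengths(peps),
                    n_observed = n_obs, verdict = verdict,
                    stringsAsFactors = FALSE)
  attr(out, "unique_peptides") <- peps
  out
}

#' Percent identity of two protein sequences
#'
#' Global (Needleman-Wunsch) alignment with BLOSUM62, gap open 10 and gap
#' extension 0.5; identity is the fraction of identical aligned columns
#' over the alignment length, in percent.
#'
#' @param a,b Amino-acid strings (or single-row `protein_db` subsets).
#' @return Percent identity in `[0, 100]`.
#' @examples
#' pairwise_identity("ACD", "ACE")
#' @export
pairwise_identity <- function(a, b) {
  seq_of <- function(x) {
    if (is.data.frame(x)) x <- x$sequence
    stopifnot(is.character(x), length(x) == 1L, nzchar(x))
    x
  }
  a <- seq_of(a); b <- seq_of(b)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  as.numeric(Biostrings::pid(al, type = "PID1"))
}

#' Pairwise identity summary of a set of proteoforms
#'
#' @param db A [protein_db()] (or data.frame with `accession`, `sequence`).
#' @return A list with `pair_identities` (data.frame `a`, `b`,
#'   `identity`), `matrix` (symmetric percent-identity matrix) and
#'   `mean_identity` (arithmetic mean over distinct pairs).
#' @export
identity_summary <- function(db) {
  n <- nrow(db)
  if (n < 2L) stop("need at least two entries")
  m <- matrix(100, n, n, dimnames = list(db$accession, db$accession))
  pairs <- utils::combn(n, 2)
  ids <- apply(pairs, 2, function(ij)
    pairwise_identity(db$sequence[ij[1]], db$sequence[ij[2]]))
  for (k in seq_len(ncol(pairs))) {
    m[pairs[1, k], pairs[2, k]] <- m[pairs[2, k], pairs[1, k]] <- ids[k]
  }
  list(pair_identities = data.frame(a = db$accession[pairs[1, ]],
                                    b = db$accession[pairs[2, ]],
                                    identity = ids, stringsAsFactors = FALSE),
       matrix = m, mean_identity = mean(ids))
}
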