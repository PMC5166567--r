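# Background amino-acid composition used for random sequence generation
# (approximate vertebrate frequencies; K+R ~ 11% so tryptic peptides
# average ~9 residues).
AA_FREQ <- c(
  A = 0.074, R = 0.052, N = 0.045, D = 0.053, C = 0.018, E = 0.062,
  Q = 0.040, G = 0.074, H = 0.026, I = 0.053, L = 0.091, K = 0.058,
  M = 0.023, F = 0.040, P = 0.050, S = 0.073, T = 0.059, W = 0.013,
  Y = 0.033, V = 0.066
)

# substitution targets that can never create or destroy a tryptic cleavage
# site (no K/R, no P) and never collide under I/L equivalence
SUB_TARGETS <- c("A", "S", "T", "V", "N", "D", "Q", "E", "G", "H", "F",
                 "Y", "W", "M")

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

random_protein <- function(length) {
  paste(sample(names(AA_FREQ), length, replace = TRUE, prob = AA_FREQ),
        collapse = "")
}

#' Specification of a synthetic homologous proteoform family
#'
#' Describes the family structure the generator emulates: a cluster of
#' central proteoforms of very high mutual identity plus peripheral members
#' of intermediate identity, all of a common mature-protein length.
#'
#' @param n_central Number of central proteoforms (default 15).
#' @param n_peripheral Number of peripheral proteoforms (default 5).
#' @param central_identity_min Minimum percent identity among central pairs
#'   (default 97).
#' @param peripheral_identity_range Percent-identity band for pairs
#'   involving a peripheral member (default `c(82, 94)`).
#' @param base_length Mature sequence length in residues (default 157).
#' @return A list of class `family_spec`.
#' @export
family_spec <- function(n_central = 15L, n_peripheral = 5L,
                        central_identity_min = 97,
                        peripheral_identity_range = c(82, 94),
                        base_length = 157L) {
  stopifnot(n_central >= 1L, n_peripheral >= 0L,
            central_identity_min > 0, central_identity_min <= 100,
            length(peripheral_identity_range) == 2L,
            peripheral_identity_range[1] < peripheral_identity_range[2],
            central_identity_min > peripheral_identity_range[2],
            base_length >= 30L)
  structure(list(n_central = as.integer(n_central),
                 n_peripheral = as.integer(n_peripheral),
                 central_identity_min = central_identity_min,
                 peripheral_identity_range = peripheral_identity_range,
                 base_length = as.integer(base_length)),
            class = "family_spec")
}

# positions of the base sequence lying inside an admissible 0-missed tryptic
# peptide where a substitution cannot alter the cleavage pattern
substitutable_positions <- function(sequence, params) {
  frags <- tryptic_digest(sequence, 0L)
  len <- nchar(frags$peptide)
  ok <- len >= params$length_range[1] & len <= params$length_range[2]
  ok <- ok & vapply(seq_len(nrow(frags)), function(i)
    length(admissible_charges(peptide_mass(frags$peptide[i]), len[i],
                              params)) > 0L, logical(1))
  pos <- unlist(lapply(which(ok), function(i) frags$start[i]:frags$end[i]))
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  prev <- c("", aa[-length(aa)])
  keep <- !(aa[pos] %in% c("K", "R")) & !(aa[pos] == "P" & prev[pos] %in% c("K", "R"))
  sort(pos[keep])
}

substitute_at <- function(sequence, pos, targets) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  for (k in seq_along(pos)) aa[pos[k]] <- targets[k]
  paste(aa, collapse = "")
}

draw_targets <- function(sequence, pos) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  vapply(pos, function(p) sample(setdiff(SUB_TARGETS, aa[p]), 1L), character(1))
}

#' Generate a homologous proteoform family
#'
#' Derives a family of proteoforms from one random base sequence by point
#' substitutions placed inside admissible tryptic peptides, so that (i)
#' central pairs stay above the requested identity, (ii) pairs involving a
#' peripheral member fall in the peripheral identity band, and (iii) every
#' proteoform retains at least one admissible proteotypic peptide in the
#' family-only context. Substitutions never touch K/R positions or
#' cleavage-suppressing prolines, so all family members share an identical
#' tryptic cleavage pattern. The construction is audited with
#' [map_proteotypic()] and re-drawn (bounded retries) if uniqueness fails.
#'
#' @param spec A [family_spec()].
#' @param seed Integer seed; identical seed and spec give identical output.
#' @param params A [digest_params()] used for admissibility auditing.
#' @param max_tries Bounded retries before declaring the spec infeasible.
#' @return A [protein_db()] named `"family_only"` with columns including
#'   `role` (`"central"`/`"peripheral"`).
#' @export
generate_family <- function(spec, seed, params = digest_params(),
                            max_tries = 25L) {
  stopifnot(inherits(spec, "family_spec"))
  with_seed(seed, {
    L <- spec$base_length
    k_c <- max(1L, floor(L * (1 - spec$central_identity_min / 100) / 2))
    hi <- spec$peripheral_identity_range[2]
    lo <- spec$peripheral_identity_range[1]
    p_priv <- max(1L, ceiling(L * (1 - hi / 100) / 2))
    mid <- (lo + hi) / 2
    core <- max(0L, round(L * (1 - mid / 100)) - p_priv - k_c)
    n <- spec$n_central + spec$n_peripheral
    need <- spec$n_central * k_c + spec$n_peripheral * p_priv + core

    for (try in seq_len(max_tries)) {
      base <- random_protein(L)
      pool <- substitutable_positions(base, params)
      if (length(pool) < need) next
      picks <- sample(pool, need)
      core_pos <- if (core > 0L) picks[seq_len(core)] else integer(0)
      core_tgt <- draw_targets(base, core_pos)
      rest <- picks[setdiff(seq_along(picks), seq_len(core))]
      splits <- split(rest, rep(seq_len(n),
                                times = c(rep(k_c, spec$n_central),
                                          rep(p_priv, spec$n_peripheral))))
      seqs <- character(n)
      for (i in seq_len(n)) {
        pos <- sort(splits[[i]])
        tgt <- draw_targets(base, pos)
        if (i > spec$n_central) {       # peripheral: add the shared core
          pos <- c(pos, core_pos); tgt <- c(tgt, core_tgt)
        }
        seqs[i] <- substitute_at(base, pos, tgt)
      }
      role <- rep(c("central", "peripheral"),
                  c(spec$n_central, spec$n_peripheral))
      db <- protein_db(data.frame(
        accession = sprintf("FAM%03d", seq_len(n)),
        gene_locus = sprintf("fam%d", seq_len(n)),
        sequence = seqs, is_family_member = TRUE, reviewed = FALSE,
        is_long_form = FALSE, role = role, stringsAsFactors = FALSE),
        name = "family_only")
      map <- map_proteotypic(db, params)
      npt <- proteotypic_counts(map, db$accession)
      if (all(npt >= 1L)) {
        attr(db, "base_sequence") <- base
        return(db)
      }
    }
    stop("family_spec infeasible: could not place substitutions ",
         "satisfying identity bands and uniqueness after ", max_tries,
         " tries")
  })
}

proteotypic_counts <- function(map, accessions) {
  single <- map$proteotypic
  parent1 <- vapply(map$parents, `[`, character(1), 1L)
  tab <- table(factor(parent1[single], levels = accessions))
  as.integer(tab)
}

#' Generate a constant background proteome
#'
#' Draws random, non-homologous proteins (constant across time points in
#' downstream simulation) and audits that none of their tryptic peptides
#' collides with a family peptide (colliding entries are re-drawn).
#'
#' @param n Number of background proteins.
#' @param seed Integer seed.
#' @param family_db Optional [protein_db()] whose peptides must be avoided.
#' @param length_range Sequence length bounds (default 80-300 residues).
#' @param params A [digest_params()].
#' @return A [protein_db()] named `"background"` with
#'   `is_family_member = FALSE`.
#' @export
generate_background <- function(n, seed, family_db = NULL,
                                length_range = c(80L, 300L),
                                params = digest_params()) {
  stopifnot(n >= 0L)
  if (n == 0L) {
    return(protein_db(data.frame(accession = character(0),
                                 sequence = character(0),
                                 is_family_member = logical(0)),
                      name = "background"))
  }
  fam_keys <- if (!is.null(family_db) && nrow(family_db)) {
    unlist(lapply(family_db$sequence, function(s)
      il_normalize(tryptic_digest(s, params$max_missed)$peptide)))
  } else character(0)
  with_seed(seed, {
    seqs <- character(n)
    for (i in seq_len(n)) {
      repeat {
        s <- random_protein(sample(length_range[1]:length_range[2], 1L))
        keys <- il_normalize(tryptic_digest(s, params$max_missed)$peptide)
        keys <- keys[nchar(keys) >= params$length_range[1]]
        if (!any(keys %in% fam_keys)) { seqs[i] <- s; break }
      }
    }
    protein_db(data.frame(accession = sprintf("BG%03d", seq_len(n)),
                          gene_locus = sprintf("bg%d", seq_len(n)),
                          sequence = seqs, is_family_member = FALSE,
                          reviewed = TRUE, is_long_form = FALSE,
                          stringsAsFactors = FALSE),
               name = "background")
  })
}

#' Combine database contexts
#'
#' Binds a family database and a background database into a comprehensive
#' context (family sequences identical to the family-only context).
#'
#' @param ... `protein_db` objects.
#' @param name Name of the combined context (default `"comprehensive"`).
#' @return A [protein_db()].
#' @export
combine_dbs <- function(..., name = "comprehensive") {
  dbs <- list(...)
  cols <- c("accession", "gene_locus", "sequence", "is_family_member",
            "reviewed", "is_long_form")
  rows <- lapply(dbs, function(d) as.data.frame(d)[, cols, drop = FALSE])
  protein_db(do.call(rbind, rows), name = name)
}

#' Paired two-time-point study design
#'
#' Captures the study conditions the simulator reproduces: a within-subject
#' design with every individual sampled before (t1) and during (t2) a
#' treatment period, proteoform-specific true fold changes, genotype-like
#' per-individual detection probabilities, and total protein concentration
#' that rises when the family is upregulated (1.4 to 2.6 ug/uL on average
#' at defaults).
#'
#' @param n_individuals Number of paired individuals (default 13).
#' @param fold_changes Named vector of true t2/t1 fold changes per
#'   proteoform; unnamed entries default to 1. `NULL` (default) assigns a
#'   uniform family fold computed so the expected concentration ratio
#'   equals `conc_t2_mean / conc_t1_mean`.
#' @param frequency Named vector of per-individual detection probabilities;
#'   `NULL` assigns defaults spanning ubiquitous (1.0), common (0.6),
#'   uncommon (0.4) and rare (0.05) classes across the family, background
#'   always 1.
#' @param conc_t1_mean,conc_t2_mean Mean urinary protein concentration in
#'   ug/uL at t1/t2 (defaults 1.4 and 2.6).
#' @param family_share Expected family fraction of total MS intensity at t1
#'   (default 0.85).
#' @param noise_cv Biological coefficient of variation (lognormal,
#'   per proteoform and sample; default 0.2).
#' @param tech_cv Technical CV per peptide measurement (default 0.1).
#' @param fragment_cv CV per fragment measurement (default 0.05; set 0 to
#'   make fragment sums reproduce peptide areas exactly).
#' @param conc_cv CV of the concentration measurement (default 0.05,
#'   within the Bradford triplicate tolerance).
#' @param ion_cv CV of per-peptide ionization efficiency factors, drawn
#'   once per peptide and shared across samples (default 0.5).
#' @param n_fragments Fragment rows per peptide in the MS2 matrix
#'   (default 6).
#' @param n_pool Replicate samplings averaged per time point (pooling;
#'   default 2 at t1, 3 at t2).
#' @param seed Integer seed.
#' @return A list of class `study_design`.
#' @export
study_design <- function(n_individuals = 13L, fold_changes = NULL,
                         frequency = NULL, conc_t1_mean = 1.4,
                         conc_t2_mean = 2.6, family_share = 0.85,
                         noise_cv = 0.2, tech_cv = 0.1, fragment_cv = 0.05,
                         conc_cv = 0.05, ion_cv = 0.5, n_fragments = 6L,
                         n_pool = c(t1 = 2L, t2 = 3L), seed = 1L) {
  stopifnot(n_individuals >= 2L, conc_t1_mean > 0, conc_t2_mean > 0,
            family_share > 0, family_share < 1,
            noise_cv >= 0, tech_cv >= 0, fragment_cv >= 0, conc_cv >= 0,
            ion_cv >= 0, n_fragments >= 1L)
  if (!is.null(fold_changes) && (is.null(names(fold_changes)) ||
                                 any(fold_changes <= 0)))
    stop("fold_changes must be a named vector of positive ratios")
  if (!is.null(frequency) && (is.null(names(frequency)) ||
                              any(frequency < 0 | frequency > 1)))
    stop("frequency must be named detection probabilities in [0,1]")
  structure(list(n_individuals = as.integer(n_individuals),
                 fold_changes = fold_changes, frequency = frequency,
                 conc_t1_mean = conc_t1_mean, conc_t2_mean = conc_t2_mean,
                 family_share = family_share, noise_cv = noise_cv,
                 tech_cv = tech_cv, fragment_cv = fragment_cv,
                 conc_cv = conc_cv, ion_cv = ion_cv,
                 n_fragments = as.integer(n_fragments),
                 n_pool = n_pool, seed = as.integer(seed)),
            class = "study_design")
}

default_frequencies <- function(fam_acc) {
  n <- length(fam_acc)
  probs <- rep(1, n)
  if (n > 2L) {
    rest <- n - 2L
    # remaining proteoforms spread over common/uncommon/rare classes in
    # roughly the 4:7:6 proportion observed for a wild population
    n_common <- round(rest * 4 / 17)
    n_rare <- round(rest * 6 / 17)
    n_uncommon <- rest - n_common - n_rare
    probs <- c(1, 1, rep(0.6, n_common), rep(0.4, n_uncommon),
               rep(0.05, n_rare))
  }
  stats::setNames(probs[seq_len(n)], fam_acc)
}

#' Simulate a paired label-free quantification study
#'
#' Generates MS1 (peptide x sample) and MS2 (fragment x sample) peak-area
#' matrices with known ground truth for a database of family and background
#' proteins. Per sample, a proteoform's amount is its baseline times its
#' true fold change (at t2) times averaged lognormal biological noise;
#' detection is a per-individual Bernoulli draw (an undetected proteoform
#' contributes no peptides at either time point and is stored as absent,
#' not zero). Peptide areas multiply the summed parent amounts by a
#' per-peptide ionization factor and technical noise; the MS2 matrix
#' distributes each peptide area over fragment rows with Dirichlet weights.
#' Total protein concentration is proportional to the total simulated
#' protein amount (scaled so the t1 average equals `conc_t1_mean`), so
#' family upregulation raises concentration.
#'
#' @param db A [protein_db()] with family and (optionally) background
#'   entries.
#' @param design A [study_design()].
#' @param params A [digest_params()].
#' @param peptide_map Optional precomputed [map_proteotypic()] result for
#'   `db` (avoids re-digesting in repeated simulations).
#' @return A list of class `mup_simulation` with elements `ms1`, `ms2`
#'   (matrices; rownames are peptide keys / `key.f<i>` fragment ids),
#'   `metadata` (sample, individual, time_point, concentration),
#'   `peptides` (the peptide map) and `truth` (ground-truth list).
#' @export
simulate_study <- function(db, design, params = digest_params(),
                           peptide_map = NULL) {
  stopifnot(inherits(db, "protein_db"), inherits(design, "study_design"))
  map <- if (is.null(peptide_map)) map_proteotypic(db, params) else peptide_map
  if (nrow(map) == 0L) stop("database yields no admissible peptides")
  acc <- db$accession
  fam <- db$is_family_member
  if (!any(fam)) stop("database contains no family members")

  freq <- default_frequencies(acc[fam])
  if (!is.null(design$frequency)) {
    unknown <- setdiff(names(design$frequency), acc)
    if (length(unknown)) stop("frequency names unknown: ",
                              paste(unknown, collapse = ", "))
    freq[intersect(names(design$frequency), names(freq))] <-
      design$frequency[intersect(names(design$frequency), names(freq))]
  }
  freq_all <- stats::setNames(rep(1, length(acc)), acc)
  freq_all[names(freq)] <- freq

  with_seed(design$seed, {
    nE <- length(acc)
    # baselines: family lognormal spread; background scaled so the expected
    # family share of total peptide-level MS intensity at t1 equals
    # design$family_share (peptides shared among several family proteoforms
    # accumulate all their parents' amounts, so the share is computed on
    # the peptide map, not on protein amounts)
    baseline <- stats::setNames(stats::rlnorm(nE, 0, 1), acc)
    expected <- baseline * freq_all
    fam_acc <- acc[fam]
    fam_int <- sum(vapply(map$parents, function(p)
      sum(expected[intersect(p, fam_acc)]), numeric(1)))
    bg_int <- sum(vapply(map$parents, function(p)
      sum(expected[setdiff(p, fam_acc)]), numeric(1)))
    if (any(!fam) && bg_int > 0) {
      target_bg <- fam_int * (1 - design$family_share) / design$family_share
      baseline[!fam] <- baseline[!fam] * target_bg / bg_int
    }

    fold <- stats::setNames(rep(1, nE), acc)
    if (is.null(design$fold_changes)) {
      r <- design$conc_t2_mean / design$conc_t1_mean
      B <- sum(baseline[!fam])
      FA <- sum(baseline[fam] * freq_all[fam])
      f <- (r * (B + FA) - B) / FA
      if (f <= 0) stop("infeasible concentration ratio for this database")
      fold[fam] <- f
    } else {
      unknown <- setdiff(names(design$fold_changes), acc)
      if (length(unknown)) stop("fold_changes names unknown: ",
                                paste(unknown, collapse = ", "))
      fold[names(design$fold_changes)] <- design$fold_changes
    }

    nI <- design$n_individuals
    detect <- matrix(stats::rbinom(nE * nI, 1L, rep(freq_all, nI)) == 1L,
                     nrow = nE, dimnames = list(acc, NULL))
    individuals <- sprintf("I%02d", seq_len(nI))
    colnames(detect) <- individuals

    samples <- c(paste0(individuals, "_t1"), paste0(individuals, "_t2"))
    time_point <- rep(c("t1", "t2"), each = nI)
    indiv_of <- rep(individuals, 2)
    nS <- length(samples)

    pool_n <- c(t1 = design$n_pool[["t1"]], t2 = design$n_pool[["t2"]])
    bio <- matrix(1, nE, nS, dimnames = list(acc, samples))
    for (s in seq_len(nS)) {
      reps <- pool_n[[time_point[s]]]
      draws <- matrix(rlnorm_cv(nE * reps, design$noise_cv), nE, reps)
      bio[, s] <- rowMeans(draws)
    }
    amount <- baseline * bio *
      ifelse(rep(time_point, each = nE) == "t2", fold, 1)
    present <- detect[, indiv_of, drop = FALSE]
    amount[!present] <- NA_real_
    dimnames(amount) <- list(acc, samples)

    total <- colSums(amount, na.rm = TRUE)
    kappa <- design$conc_t1_mean / mean(total[time_point == "t1"])
    concentration <- kappa * total * rlnorm_cv(nS, design$conc_cv)

    # peptide-level MS1 areas
    nP <- nrow(map)
    P <- matrix(0, nP, nE, dimnames = list(map$key, acc))
    for (i in seq_len(nP)) P[i, map$parents[[i]]] <- 1
    amount0 <- amount; amount0[is.na(amount0)] <- 0
    pep_amount <- P %*% amount0
    none_present <- (P %*% (!present)) == rowSums(P)
    ion <- stats::setNames(rlnorm_cv(nP, design$ion_cv), map$key)
    ms1 <- pep_amount * ion *
      matrix(rlnorm_cv(nP * nS, design$tech_cv), nP, nS)
    ms1[none_present] <- NA_real_
    dimnames(ms1) <- list(map$key, samples)

    # MS2: Dirichlet fragment weights per peptide, drawn once
    nF <- design$n_fragments
    w <- matrix(stats::rgamma(nP * nF, shape = 2), nP, nF)
    w <- w / rowSums(w)
    rownames(w) <- map$key
    frag_ids <- paste0(rep(map$key, each = nF), ".f", rep(seq_len(nF), nP))
    ms2 <- ms1[rep(seq_len(nP), each = nF), , drop = FALSE] *
      as.vector(t(w)) *
      matrix(rlnorm_cv(nP * nF * nS, design$fragment_cv), nP * nF, nS)
    dimnames(ms2) <- list(frag_ids, samples)

    metadata <- data.frame(sample = samples, individual = indiv_of,
                           time_point = time_point,
                           concentration = as.numeric(concentration),
                           stringsAsFactors = FALSE)
    truth <- list(baseline = baseline, fold_changes = fold,
                  frequency = freq_all, detect = detect,
                  ionization = ion, fragment_weights = w,
                  family_share = design$family_share, kappa = kappa,
                  family_members = acc[fam])
    structure(list(ms1 = ms1, ms2 = ms2, metadata = metadata,
                   peptides = map, truth = truth, design = design),
              class = "mup_simulation")
  })
}

#' @export
print.mup_simulation <- function(x, ...) {
  cat(sprintf("mup_simulation: %d peptides x %d samples (MS1), %d fragment rows (MS2), %d individuals\n",
              nrow(x$ms1), ncol(x$ms1), nrow(x$ms2),
              x$design$n_individuals))
  invisible(x)
}
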