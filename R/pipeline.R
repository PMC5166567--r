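# stable FNV-1a hash over a serialized R object; used to fingerprint
# configurations in run reports
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", h)
}

#' Read a peptide quantification matrix from TSV
#'
#' Tab-delimited, UTF-8, `.` decimal; first column = peptide (or fragment)
#' identifier, header row = sample identifiers. Missing detections are
#' encoded as `NA` (absent, not zero).
#'
#' @param path TSV file path.
#' @return Numeric matrix with peptide rownames and sample colnames.
#' @export
read_quant_matrix <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 1L) stop("empty matrix file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  ncol_expect <- length(header)
  samples <- header[-1]
  n <- length(lines) - 1L
  if (n == 0L)
    return(matrix(numeric(0), 0, length(samples),
                  dimnames = list(character(0), samples)))
  ids <- character(n)
  vals <- matrix(NA_real_, n, length(samples))
  for (i in seq_len(n)) {
    f <- fields[[i + 1L]]
    if (length(f) != ncol_expect)
      stop(sprintf("ragged row at line %d of %s: %d fields, expected %d",
                   i + 1L, path, length(f), ncol_expect))
    ids[i] <- f[1]
    v <- suppressWarnings(as.numeric(f[-1]))
    bad <- which(is.na(v) & !(f[-1] %in% c("NA", "", "nan", "NaN")))
    if (length(bad))
      stop(sprintf("non-numeric cell '%s' at line %d, column %d of %s",
                   f[-1][bad[1]], i + 1L, bad[1] + 1L, path))
    vals[i, ] <- v
  }
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate peptide id in ", path, ": ", dup[1])
  dimnames(vals) <- list(ids, samples)
  vals
}

#' Write a peptide quantification matrix to TSV
#'
#' @param mat Numeric matrix with rownames and colnames.
#' @param path Output TSV path.
#' @param id_name Header of the identifier column (default `"peptide"`).
#' @return `path`, invisibly.
#' @export
write_quant_matrix <- function(mat, path, id_name = "peptide") {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Write a simulated study to disk
#'
#' Writes the generated database (FASTA), MS1/MS2 matrices (TSV), sample
#' metadata (TSV) and ground truth (JSON) of a [simulate_study()] result.
#'
#' @param sim A `mup_simulation`.
#' @param db The [protein_db()] the simulation was generated from.
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_simulation <- function(sim, db, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(fasta = file.path(dir, "database.fasta"),
             ms1 = file.path(dir, "ms1_matrix.tsv"),
             ms2 = file.path(dir, "ms2_matrix.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             truth = file.path(dir, "ground_truth.json"))
  ss <- Biostrings::AAStringSet(stats::setNames(db$sequence, db$accession))
  Biostrings::writeXStringSet(ss, paths["fasta"])
  write_quant_matrix(sim$ms1, paths["ms1"])
  write_quant_matrix(sim$ms2, paths["ms2"], id_name = "fragment")
  utils::write.table(sim$metadata, paths["metadata"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth$detect <- as.data.frame(truth$detect)
  truth$fragment_weights <- NULL
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. Either `simulate = TRUE`
#' (default), in which case the family/background database and quantification
#' matrices are generated with known ground truth, or paths to a FASTA
#' database, MS1/MS2 matrices and sample metadata are supplied. Unknown
#' arguments are rejected.
#'
#' @param simulate Generate inputs with the synthetic-data module.
#' @param family A [family_spec()] (simulated runs).
#' @param n_background Number of background proteins (simulated runs).
#' @param design A [study_design()] (simulated runs).
#' @param db_fasta,annotations,ms1_path,ms2_path,metadata_path Input file
#'   paths for non-simulated runs; `metadata_path` must provide a
#'   `concentration` column when manual normalization is requested.
#' @param params A [digest_params()].
#' @param normalizations Subset of `c("none", "tas", "manual")`.
#' @param alpha Family-wise error rate (default 0.05).
#' @param min_pairs Minimum complete pairs per tested proteoform.
#' @param log2_transform Test on log2 scale (default FALSE).
#' @param composition_threshold Others-bin threshold in percent.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param seed Integer seed for database generation.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = TRUE, family = family_spec(),
                            n_background = 30L, design = study_design(),
                            db_fasta = NULL, annotations = NULL,
                            ms1_path = NULL, ms2_path = NULL,
                            metadata_path = NULL,
                            params = digest_params(),
                            normalizations = c("none", "tas", "manual"),
                            alpha = 0.05, min_pairs = 3L,
                            log2_transform = FALSE,
                            composition_threshold = 5, out_dir = NULL,
                            seed = 1L) {
  normalizations <- match.arg(normalizations, c("none", "tas", "manual"),
                              several.ok = TRUE)
  stopifnot(alpha > 0, alpha < 1, min_pairs >= 2L)
  if (!simulate) {
    for (p in c(db_fasta, ms1_path, ms2_path, metadata_path)) {
      if (is.null(p) || !file.exists(p))
        stop("non-simulated run requires existing db_fasta, ms1_path, ",
             "ms2_path and metadata_path; missing: ",
             if (is.null(p)) "unset path" else p)
    }
    md <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
    need <- c("sample", "individual", "time_point")
    if (!all(need %in% names(md)))
      stop("metadata must have columns: ", paste(need, collapse = ", "))
    if ("manual" %in% normalizations && is.null(md$concentration))
      stop("manual normalization requested but metadata has no ",
           "'concentration' column")
  }
  structure(list(simulate = simulate, family = family,
                 n_background = as.integer(n_background), design = design,
                 db_fasta = db_fasta, annotations = annotations,
                 ms1_path = ms1_path, ms2_path = ms2_path,
                 metadata_path = metadata_path, params = params,
                 normalizations = normalizations, alpha = alpha,
                 min_pairs = as.integer(min_pairs),
                 log2_transform = log2_transform,
                 composition_threshold = composition_threshold,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full quantification pipeline
#'
#' Executes digestion, ion-library construction, MS1 and MS2 roll-up,
#' every requested normalization strategy, paired testing with the
#' Bonferroni-Dunn corrected two-fold filter, MS1/MS2 concordance,
#' detection-frequency classification and relative composition, for both
#' the family-only and (when background proteins exist) the comprehensive
#' database context. Deterministic given the configured seeds.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `run_report`; see Details. When
#'   `config$out_dir` is set, all tables are also written there via
#'   [write_results()].
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  params <- config$params

  if (config$simulate) {
    fam_db <- generate_family(config$family, seed = config$seed,
                              params = params)
    bg_db <- generate_background(config$n_background,
                                 seed = config$seed + 1L,
                                 family_db = fam_db, params = params)
    db <- if (nrow(bg_db)) combine_dbs(fam_db, bg_db) else fam_db
    sim <- simulate_study(db, config$design, params = params)
    ms1 <- sim$ms1; ms2 <- sim$ms2; metadata <- sim$metadata
    truth <- sim$truth
  } else {
    db <- read_fasta(config$db_fasta, annotations = config$annotations,
                     name = "comprehensive")
    fam_db <- protein_db(as.data.frame(db)[db$is_family_member, ],
                         name = "family_only")
    ms1 <- read_quant_matrix(config$ms1_path)
    ms2 <- read_quant_matrix(config$ms2_path)
    metadata <- utils::read.delim(config$metadata_path,
                                  stringsAsFactors = FALSE)
    sim <- NULL; truth <- NULL
  }

  contexts <- list(family_only = fam_db)
  if (any(!db$is_family_member)) contexts$comprehensive <- db

  manual_factors <- if ("manual" %in% config$normalizations) {
    stats::setNames(metadata$concentration, metadata$sample)
  } else NULL

  results <- list(); counts <- list(); libraries <- list()
  concord <- list(); freq <- list()
  for (ctx in names(contexts)) {
    map <- map_proteotypic(contexts[[ctx]], params)
    lib <- build_library(map)
    # restrict to family proteoforms: background is the normalization
    # matrix, not a quantification target
    lib_fam <- lib[lib$proteoform %in% db$accession[db$is_family_member], ,
                   drop = FALSE]
    class(lib_fam) <- class(lib); attr(lib_fam, "context") <- ctx
    libraries[[ctx]] <- lib_fam
    q1 <- quantify_ms1(ms1, lib_fam)
    q2 <- quantify_ms2(ms2, lib_fam)
    counts[[ctx]] <- list(n_proteins = nrow(contexts[[ctx]]),
                          n_peptides = nrow(map),
                          n_proteotypic = sum(map$proteotypic),
                          n_library = nrow(lib_fam))
    folds <- list()
    for (lvl in c("MS1", "MS2")) {
      tab <- if (lvl == "MS1") q1 else q2
      for (nrm in config$normalizations) {
        nt <- normalize_intensities(tab, nrm, factors = manual_factors)
        pt <- paired_test(nt, metadata, min_pairs = config$min_pairs,
                          log2_transform = config$log2_transform)
        sf <- significance_filter(pt, alpha = config$alpha)
        sf$context <- ctx; sf$level <- lvl; sf$normalization <- nrm
        results[[paste(ctx, lvl, nrm, sep = ".")]] <- sf
        folds[[paste(lvl, nrm, sep = ".")]] <-
          stats::setNames(sf$fold_change, sf$proteoform)
      }
    }
    nrm0 <- config$normalizations[length(config$normalizations)]
    concord[[ctx]] <- concordance(folds[[paste0("MS1.", nrm0)]],
                                  folds[[paste0("MS2.", nrm0)]])
    det <- detection_matrix(q1, metadata)
    freq[[ctx]] <- detection_frequency(det)
  }

  comp_ctx <- names(contexts)[length(contexts)]
  composition <- relative_composition(ms2, libraries[[comp_ctx]],
                                      threshold = config$composition_threshold)
  map_full <- map_proteotypic(contexts[[comp_ctx]], params)
  famfrac <- family_fraction(ms1, family_peptide_keys(map_full, db))

  report <- structure(list(
    config = config, config_hash = config_hash(unclass(config)),
    version = as.character(utils::packageVersion("mupquant")),
    counts = counts, results = do.call(rbind, c(results,
                                                make.row.names = FALSE)),
    concordance = concord, frequency = freq, composition = composition,
    family_fraction = famfrac, libraries = libraries,
    metadata = metadata, truth = truth), class = "run_report")
  if (!is.null(config$out_dir)) write_results(report, config$out_dir)
  report
}

#' Per-individual detection matrix from a proteoform intensity table
#'
#' A proteoform counts as detected in an individual if it is present
#' (non-absent) in at least one of that individual's samples.
#'
#' @param table A `proteoform_intensity` matrix.
#' @param metadata Sample metadata with `sample` and `individual`.
#' @return Logical proteoform x individual matrix.
#' @export
detection_matrix <- function(table, metadata) {
  indiv <- unique(metadata$individual)
  out <- matrix(FALSE, nrow(table), length(indiv),
                dimnames = list(rownames(table), indiv))
  for (iv in indiv) {
    cols <- metadata$sample[metadata$individual == iv]
    cols <- intersect(cols, colnames(table))
    out[, iv] <- rowSums(!is.na(table[, cols, drop = FALSE])) > 0
  }
  out
}

#' Write run-report tables to a directory
#'
#' Writes the differential-expression results, frequency classification,
#' concordance report, composition (TSV and pie-chart-ready JSON) and a
#' JSON run summary.
#'
#' @param report A `run_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_results <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(results = file.path(dir, "results.tsv"),
             frequency = file.path(dir, "frequency.tsv"),
             concordance = file.path(dir, "concordance.tsv"),
             composition = file.path(dir, "composition.tsv"),
             composition_json = file.path(dir, "composition.json"),
             summary = file.path(dir, "run_summary.json"))
  utils::write.table(report$results, paths["results"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  freq <- do.call(rbind, lapply(names(report$frequency), function(ctx) {
    f <- report$frequency[[ctx]]; f$context <- ctx; f
  }))
  utils::write.table(freq, paths["frequency"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  conc <- do.call(rbind, lapply(names(report$concordance), function(ctx) {
    r <- report$concordance[[ctx]]$report; r$context <- ctx
    r$r_overall <- report$concordance[[ctx]]$r; r
  }))
  utils::write.table(conc, paths["concordance"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  comp <- report$composition
  comp_df <- data.frame(label = c(names(comp$shares), "Others"),
                        percent = c(unname(comp$shares), comp$others_bin),
                        stringsAsFactors = FALSE)
  utils::write.table(comp_df, paths["composition"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(comp_df, paths["composition_json"], digits = NA)
  summary <- list(version = report$version, config_hash = report$config_hash,
                  counts = report$counts,
                  family_fraction = report$family_fraction[c("mean", "sd")],
                  k_tests = unique(report$results$k_tests))
  jsonlite::write_json(summary, paths["summary"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' @export
print.run_report <- function(x, ...) {
  cat("mupquant run report (config", x$config_hash, ")\n")
  for (ctx in names(x$counts)) {
    ct <- x$counts[[ctx]]
    cat(sprintf("  %s: %d proteins, %d peptides, %d proteotypic, %d in library\n",
                ctx, ct$n_proteins, ct$n_peptides, ct$n_proteotypic,
                ct$n_library))
  }
  sig <- x$results[x$results$significant, , drop = FALSE]
  cat(sprintf("  significant proteoform calls: %d of %d rows\n",
              nrow(sig), nrow(x$results)))
  cat(sprintf("  family fraction of MS intensity: %.1f +/- %.1f %%\n",
              x$family_fraction$mean, x$family_fraction$sd))
  invisible(x)
}
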