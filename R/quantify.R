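#' Build an ion library of proteotypic peptides
#'
#' The ion library fixes which peptides carry quantitative signal: the
#' proteotypic peptides of a database context, optionally restricted to
#' those observed in at least one identification run, each mapped to its
#' single parent proteoform.
#'
#' @param peptides A `peptide_map` from [map_proteotypic()].
#' @param observed_in Optional character vector (or list per run) of
#'   observed peptide sequences; the library keeps peptides observed in at
#'   least one run (union over runs). `NULL` keeps all proteotypic
#'   peptides.
#' @return A data.frame of class `ion_library` with columns `peptide`,
#'   `key`, `proteoform`, `charges` (list); attribute `context` carries the
#'   database context name.
#' @export
build_library <- function(peptides, observed_in = NULL) {
  stopifnot(inherits(peptides, "peptide_map"))
  sel <- peptides$proteotypic
  if (!is.null(observed_in)) {
    obs <- il_normalize(unique(unlist(observed_in)))
    sel <- sel & peptides$key %in% obs
  }
  lib <- peptides[sel, , drop = FALSE]
  if (nrow(lib) == 0L) {
    all_parents <- unique(unlist(peptides$parents))
    stop("empty ion library: no proteotypic peptide observed; ",
         "unidentifiable proteoforms: ", paste(all_parents, collapse = ", "))
  }
  out <- data.frame(peptide = lib$peptide, key = lib$key,
                    proteoform = vapply(lib$parents, `[`, character(1), 1L),
                    stringsAsFactors = FALSE)
  out$charges <- lib$charges
  rownames(out) <- NULL
  structure(out, context = attr(peptides, "context"),
            class = c("ion_library", "data.frame"))
}

rollup_matrix <- function(mat, library, rollup) {
  keep <- library$key %in% rownames(mat)
  lib <- library[keep, , drop = FALSE]
  prots <- unique(library$proteoform)
  out <- matrix(NA_real_, length(prots), ncol(mat),
                dimnames = list(prots, colnames(mat)))
  agg <- if (rollup == "sum") function(v) sum(v, na.rm = TRUE)
         else function(v) mean(v, na.rm = TRUE)
  for (p in prots) {
    rows <- lib$key[lib$proteoform == p]
    if (length(rows) == 0L) next                 # absent from matrix
    sub <- mat[rows, , drop = FALSE]
    vals <- apply(sub, 2, function(v)
      if (all(is.na(v))) NA_real_ else agg(v))
    out[p, ] <- vals
  }
  out
}

new_intensity_table <- function(values, level, rollup, library) {
  structure(values, level = level, rollup = rollup,
            context = attr(library, "context"),
            class = c("proteoform_intensity", class(values)))
}

#' Roll peptide-level MS1 areas up to proteoforms
#'
#' Aggregates the precursor (MS1) peak areas of each proteoform's
#' proteotypic peptides per sample. A proteoform whose library peptides are
#' all absent in a sample is stored as absent (`NA`), not zero, and is
#' excluded from downstream means.
#'
#' @param matrix Numeric peptide x sample matrix (rownames = peptide
#'   sequences or I/L-normalized keys).
#' @param library An [build_library()] ion library.
#' @param rollup `"sum"` (default) or `"mean"` over a proteoform's
#'   peptides.
#' @return A `proteoform_intensity` matrix (proteoform x sample) with
#'   attributes `level = "MS1"` and `rollup`.
#' @export
quantify_ms1 <- function(matrix, library, rollup = c("sum", "mean")) {
  rollup <- match.arg(rollup)
  stopifnot(inherits(library, "ion_library"), is.matrix(matrix))
  if (is.null(rownames(matrix)) || is.null(colnames(matrix)))
    stop("quantification matrix needs peptide rownames and sample colnames")
  new_intensity_table(rollup_matrix(matrix, library, rollup),
                      "MS1", rollup, library)
}

#' Roll fragment-level MS2 areas up to proteoforms
#'
#' Fragment rows (named `<peptide>.f<i>`) are first summed to peptide
#' areas (absent when all fragments are absent), then rolled up exactly as
#' at MS1 level. Fragment rows matching no library peptide are ignored;
#' their count is reported via attribute `n_ignored_fragments`.
#'
#' @inheritParams quantify_ms1
#' @param fragment_matrix Numeric fragment x sample matrix.
#' @return A `proteoform_intensity` matrix with attribute `level = "MS2"`.
#' @export
quantify_ms2 <- function(fragment_matrix, library, rollup = c("sum", "mean")) {
  rollup <- match.arg(rollup)
  stopifnot(inherits(library, "ion_library"), is.matrix(fragment_matrix))
  pep_of <- sub("\\.f[0-9]+$", "", rownames(fragment_matrix))
  known <- pep_of %in% library$key
  n_ignored <- sum(!known)
  sub <- fragment_matrix[known, , drop = FALSE]
  pep_ids <- unique(pep_of[known])
  pep_mat <- matrix(NA_real_, length(pep_ids), ncol(fragment_matrix),
                    dimnames = list(pep_ids, colnames(fragment_matrix)))
  grp <- match(pep_of[known], pep_ids)
  for (j in seq_len(ncol(sub))) {
    v <- sub[, j]
    s <- tapply(v, grp, function(x)
      if (all(is.na(x))) NA_real_ else sum(x, na.rm = TRUE))
    pep_mat[as.integer(names(s)), j] <- as.numeric(s)
  }
  out <- new_intensity_table(rollup_matrix(pep_mat, library, rollup),
                             "MS2", rollup, library)
  attr(out, "n_ignored_fragments") <- n_ignored
  out
}
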