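#' Normalize a proteoform intensity table
#'
#' Three strategies are supported, mirroring the choices available when the
#' quantification targets themselves drive total protein concentration:
#' * `"none"` - intensities unchanged; retains concentration changes on the
#'   MS level.
#' * `"tas"` - total area sums: each sample is scaled so its summed area
#'   equals the across-sample mean total, equalizing MS intensity.
#' * `"manual"` - manual scale factors: each sample's values are divided by
#'   an externally measured factor, canonically the total protein
#'   concentration in ug/uL (Bradford), accounting for the family-driven
#'   concentration change itself.
#'
#' @param table A `proteoform_intensity` matrix (or plain numeric matrix).
#' @param method One of `"none"`, `"tas"`, `"manual"`.
#' @param factors Named per-sample positive factors, required for
#'   `"manual"` (names must cover all samples).
#' @return The normalized table (same class and attributes, plus
#'   `normalization`).
#' @export
normalize_intensities <- function(table, method = c("none", "tas", "manual"),
                                  factors = NULL) {
  method <- match.arg(method)
  stopifnot(is.matrix(table))
  out <- table
  if (method == "tas") {
    totals <- colSums(table, na.rm = TRUE)
    if (any(totals <= 0)) stop("sample with non-positive total area")
    out <- sweep(table, 2, mean(totals) / totals, `*`)
  } else if (method == "manual") {
    if (is.null(factors)) stop("manual normalization requires factors")
    if (is.null(names(factors)) || !all(colnames(table) %in% names(factors)))
      stop("missing manual factor for sample(s): ",
           paste(setdiff(colnames(table), names(factors)), collapse = ", "))
    f <- factors[colnames(table)]
    if (any(!is.finite(f) | f <= 0))
      stop("manual factors must be positive and finite")
    out <- sweep(table, 2, f, `/`)
  }
  attributes(out) <- attributes(table)
  attr(out, "normalization") <- method
  out
}

#' Paired differential-expression test per proteoform
#'
#' For each proteoform, pairs each individual's t1 and t2 intensities
#' (using only individuals where the proteoform is present at both time
#' points), applies a two-sided paired t-test, and reports the fold change
#' as the ratio of group means (t2/t1) over the paired individuals.
#' Proteoforms with fewer than `min_pairs` complete pairs are excluded
#' (reported with `NA` and a reason); zero variance of the paired
#' differences is flagged.
#'
#' @param table A (normalized) `proteoform_intensity` matrix.
#' @param metadata Data.frame with columns `sample`, `individual`,
#'   `time_point` (values `"t1"`/`"t2"`).
#' @param min_pairs Minimum complete pairs required to test (default 3).
#' @param log2_transform Test log2-transformed intensities instead of raw
#'   areas (default `FALSE`; fold change is always reported on the raw
#'   ratio scale).
#' @return Data.frame with columns `proteoform`, `n_pairs`, `fold_change`,
#'   `t`, `df`, `p_raw`, `flag` (`""`, `"excluded: <min_pairs"`, or
#'   `"zero variance"`).
#' @export
paired_test <- function(table, metadata, min_pairs = 3L,
                        log2_transform = FALSE) {
  stopifnot(is.matrix(table),
            all(c("sample", "individual", "time_point") %in% names(metadata)))
  if (!all(colnames(table) %in% metadata$sample))
    stop("metadata missing for sample(s): ",
         paste(setdiff(colnames(table), metadata$sample), collapse = ", "))
  md <- metadata[match(colnames(table), metadata$sample), ]
  res <- lapply(rownames(table), function(p) {
    v <- table[p, ]
    indiv <- unique(md$individual)
    s1 <- md$sample[match(paste0(indiv, "t1"),
                          paste0(md$individual, md$time_point))]
    s2 <- md$sample[match(paste0(indiv, "t2"),
                          paste0(md$individual, md$time_point))]
    x1 <- v[s1]; x2 <- v[s2]
    ok <- !is.na(x1) & !is.na(x2)
    n <- sum(ok)
    if (n < min_pairs) {
      return(data.frame(proteoform = p, n_pairs = n, fold_change = NA_real_,
                        t = NA_real_, df = NA_real_, p_raw = NA_real_,
                        flag = sprintf("excluded: <%d pairs", min_pairs),
                        stringsAsFactors = FALSE))
    }
    a <- x1[ok]; b <- x2[ok]
    fc <- mean(b) / mean(a)
    ta <- if (log2_transform) log2(a) else a
    tb <- if (log2_transform) log2(b) else b
    d <- tb - ta
    if (stats::sd(d) == 0) {
      return(data.frame(proteoform = p, n_pairs = n, fold_change = fc,
                        t = NA_real_, df = n - 1, p_raw = NA_real_,
                        flag = "zero variance", stringsAsFactors = FALSE))
    }
    tt <- stats::t.test(tb, ta, paired = TRUE)
    data.frame(proteoform = p, n_pairs = n, fold_change = fc,
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value, flag = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Bonferroni-Dunn adjusted significance threshold
#'
#' Family-wise error control by comparing raw p-values against
#' `alpha / k`, where `k` is the number of proteoforms tested. With
#' alpha = 0.05 this reproduces thresholds 0.005 (k = 10), 0.0033 (k = 15),
#' 0.006 (k = 9) and 0.0036 (k = 14).
#'
#' @param p_raw Numeric vector of raw p-values (NAs allowed, never called
#'   significant).
#' @param alpha Family-wise error rate (default 0.05).
#' @param k Number of tests; defaults to the number of non-missing
#'   p-values.
#' @return List with `alpha_adjusted`, `k`, and logical `significant`.
#' @export
bonferroni_dunn <- function(p_raw, alpha = 0.05, k = NULL) {
  if (is.null(k)) k <- sum(!is.na(p_raw))
  if (k < 1L) stop("k must be >= 1 (no tests performed)")
  thr <- alpha / k
  list(alpha_adjusted = thr, k = as.integer(k),
       significant = !is.na(p_raw) & p_raw < thr)
}

#' Two-fold and adjusted-p significance filter
#'
#' Retains proteoforms regulated more than two-fold in either direction
#' (|log2 fold| > 1) with a raw p-value below the Bonferroni-Dunn adjusted
#' threshold; annotates the direction of regulation.
#'
#' @param results Data.frame with columns `proteoform`, `fold_change`,
#'   `p_raw` (as from [paired_test()]).
#' @param alpha Family-wise error rate (default 0.05).
#' @param k Number of tests for the correction; defaults to the number of
#'   testable rows.
#' @param fold_threshold Fold-change cut-off (default 2).
#' @return The input with added columns `k_tests`, `alpha_adjusted`,
#'   `significant`, `direction`; attribute `retained` holds the filtered
#'   subset.
#' @export
significance_filter <- function(results, alpha = 0.05, k = NULL,
                                fold_threshold = 2) {
  stopifnot(all(c("proteoform", "fold_change", "p_raw") %in% names(results)))
  bd <- bonferroni_dunn(results$p_raw, alpha = alpha, k = k)
  lfc <- log2(results$fold_change)
  sig <- bd$significant & !is.na(lfc) & abs(lfc) > log2(fold_threshold)
  direction <- ifelse(!sig, "none", ifelse(lfc > 0, "up", "down"))
  out <- results
  out$k_tests <- bd$k
  out$alpha_adjusted <- bd$alpha_adjusted
  out$significant <- sig
  out$direction <- direction
  attr(out, "retained") <- out[sig, , drop = FALSE]
  out
}

#' Classify a detection frequency into abundance classes
#'
#' Frequencies are rounded to integer percent and binned exactly as
#' reported for a wild population: ubiquitous = 100%, common = 50-70%,
#' uncommon = 30-49%, rare < 10%. Values falling in the unreported gaps
#' (10-29% and 71-99%) are classed `"unclassified"` with a warning.
#'
#' @param frequency Numeric vector of percentages in `[0, 100]`.
#' @return Character vector of classes.
#' @export
classify_frequency <- function(frequency) {
  stopifnot(all(frequency >= 0 & frequency <= 100))
  f <- round(frequency)
  cls <- ifelse(f == 100, "ubiquitous",
         ifelse(f >= 50 & f <= 70, "common",
         ifelse(f >= 30 & f <= 49, "uncommon",
         ifelse(f < 10, "rare", "unclassified"))))
  if (any(cls == "unclassified"))
    warning("frequencies in unreported ranges (10-29% or 71-99%) ",
            "classified as 'unclassified'")
  cls
}

#' Detection frequency and abundance class per proteoform
#'
#' Frequency is the number of individuals expressing a proteoform divided
#' by the total sample size, in integer percent.
#'
#' @param detections Logical proteoform x individual matrix (or data.frame)
#'   of per-individual detection indicators.
#' @param n_total Total number of individuals (defaults to
#'   `ncol(detections)`).
#' @return Data.frame with columns `proteoform`, `n_detected`, `frequency`
#'   (integer percent), `class`.
#' @export
detection_frequency <- function(detections, n_total = ncol(detections)) {
  detections <- as.matrix(detections)
  stopifnot(is.logical(detections) || all(detections %in% c(0, 1)),
            n_total > 0)
  if (ncol(detections) > n_total)
    stop("detections reference more individuals than n_total")
  n_det <- rowSums(detections == TRUE | detections == 1)
  freq <- as.integer(round(100 * n_det / n_total))
  data.frame(proteoform = rownames(detections), n_detected = as.integer(n_det),
             frequency = freq, class = classify_frequency(freq),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Concordance of MS1 and MS2 fold changes
#'
#' Pearson correlation of log2 fold changes over the proteoforms shared by
#' the two quantification strategies, plus a per-proteoform report listing
#' discordant cases (fold-change ratio beyond a threshold in either
#' direction).
#'
#' @param fold_ms1,fold_ms2 Named numeric vectors of fold changes.
#' @param ratio_threshold Flag proteoforms whose MS1/MS2 fold-change ratio
#'   (larger over smaller) exceeds this (default 2).
#' @return List with `r` (Pearson correlation of log2 folds), `n_shared`,
#'   and `report` (data.frame `proteoform`, `fold_ms1`, `fold_ms2`,
#'   `ratio`, `discordant`).
#' @export
concordance <- function(fold_ms1, fold_ms2, ratio_threshold = 2) {
  shared <- intersect(names(fold_ms1), names(fold_ms2))
  shared <- shared[!is.na(fold_ms1[shared]) & !is.na(fold_ms2[shared])]
  if (length(shared) < 3L)
    stop("need >= 3 shared proteoforms with fold changes, got ",
         length(shared))
  l1 <- log2(fold_ms1[shared]); l2 <- log2(fold_ms2[shared])
  r <- if (stats::sd(l1) == 0 && stats::sd(l2) == 0 &&
           all(l1 == l2)) 1 else stats::cor(l1, l2)
  ratio <- pmax(fold_ms1[shared] / fold_ms2[shared],
                fold_ms2[shared] / fold_ms1[shared])
  report <- data.frame(proteoform = shared,
                       fold_ms1 = unname(fold_ms1[shared]),
                       fold_ms2 = unname(fold_ms2[shared]),
                       ratio = unname(ratio),
                       discordant = unname(ratio > ratio_threshold),
                       stringsAsFactors = FALSE)
  list(r = unname(r), n_shared = length(shared), report = report)
}
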