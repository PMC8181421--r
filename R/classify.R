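# DHS category assignment per contrast and cross-timepoint summaries.
#
# A peak is called differentially accessible ("up" in a contrast, e.g. an
# mDHS for memory-vs-naive or an iDHS for restimulated-vs-resting) when it
# shows a greater than `fold`-fold change, an adjusted p-value below `padj`,
# and a normalized read count above `min_reads` in both replicates of the
# condition in which it is claimed present (the higher group); "down"
# symmetrically. Defaults: 3-fold, 0.05, 20 reads.

#' Classify peaks into up/down/none for one contrast
#'
#' @param diff [nb_wald_test()] result table (fold change group2/group1).
#' @param normalized normalized count matrix (features x samples).
#' @param samples sample sheet.
#' @param condition1,condition2 the contrasted condition labels
#'   (group1, group2).
#' @param fold fold-change threshold (default 3).
#' @param padj adjusted-p threshold (default 0.05).
#' @param min_reads normalized-count presence threshold, applied to every
#'   replicate of the higher group (default 20).
#' @param inclusive if `TRUE`, use `>=` for the fold threshold instead of
#'   the default strict `>`.
#' @return `DHSCategoryTable` data.frame: feature, category
#'   (`up`/`down`/`none`), log2fc, padj, and mean normalized count per
#'   condition.
#' @export
classify_dhs <- function(diff, normalized, samples, condition1, condition2,
                         fold = 3, padj = 0.05, min_reads = 20,
                         inclusive = FALSE) {
  stopifnot(fold > 0, padj > 0, min_reads >= 0)
  s1 <- samples$sample[samples$condition == condition1]
  s2 <- samples$sample[samples$condition == condition2]
  if (!length(s1) || !length(s2)) stop("unknown condition label")
  if (!all(c(s1, s2) %in% colnames(normalized)))
    stop("normalized matrix is missing replicate columns")
  y1 <- normalized[diff$feature, s1, drop = FALSE]
  y2 <- normalized[diff$feature, s2, drop = FALSE]
  fc <- 2^diff$log2fc
  gt <- if (inclusive) `>=` else `>`
  present2 <- apply(y2 > min_reads, 1, all)
  present1 <- apply(y1 > min_reads, 1, all)
  up <- gt(fc, fold) & diff$padj < padj & present2
  down <- gt(1 / fc, fold) & diff$padj < padj & present1
  stopifnot(!any(up & down))
  out <- data.frame(feature = diff$feature,
                    category = ifelse(up, "up", ifelse(down, "down", "none")),
                    log2fc = diff$log2fc, padj = diff$padj,
                    stringsAsFactors = FALSE)
  out[[paste0("mean_", condition1)]] <- rowMeans(y1)
  out[[paste0("mean_", condition2)]] <- rowMeans(y2)
  out
}

#' Per-sample peak presence sets
#'
#' The presence filter used to define "~30,000 peaks/sample" sets: a peak
#' belongs to a sample's set when its normalized count exceeds `min_reads`.
#'
#' @param normalized normalized count matrix.
#' @param min_reads threshold (default 20).
#' @return named list (sample -> character vector of feature ids).
#' @export
presence_filter <- function(normalized, min_reads = 20) {
  lapply(setNames(seq_len(ncol(normalized)), colnames(normalized)),
         function(j) rownames(normalized)[normalized[, j] > min_reads])
}

# Percentage rounding used in stability reports: round to one decimal; keep
# the decimal only when the tenths digit is 5, otherwise round to integer
# (83.33 -> 83, 97.46 -> 97.5).
round_percentage <- function(pct) {
  p1 <- round(pct, 1)
  ifelse(round(p1 * 10) %% 10 == 5, p1, round(pct))
}

#' Stability of a reference DHS set at a later timepoint
#'
#' For each fold threshold, counts how many peaks of a reference set (e.g.
#' the mDHSs gained by day 28) still show at least that fold change over the
#' baseline at a later timepoint, and reports the percentage of the
#' reference-set size.
#'
#' Either supply the later-timepoint fold changes of the reference peaks
#' (`later_fc`), or pre-tabulated passing counts (`pass_counts`) when working
#' from published tables.
#'
#' @param n_reference reference set size (> 0).
#' @param later_fc numeric vector of later-timepoint fold changes (linear
#'   scale) for the reference peaks.
#' @param thresholds fold thresholds to evaluate (default `c(3, 2)`).
#' @param pass_counts optional integer vector, one per threshold, used
#'   instead of `later_fc`.
#' @return data.frame: threshold, count, percentage (rounded), raw_pct.
#' @export
stability_summary <- function(n_reference, later_fc = NULL,
                              thresholds = c(3, 2), pass_counts = NULL) {
  if (n_reference <= 0) stop("reference set must be non-empty")
  if (is.null(pass_counts)) {
    if (is.null(later_fc)) stop("supply later_fc or pass_counts")
    pass_counts <- vapply(thresholds, function(t) sum(later_fc >= t), 0L)
  }
  stopifnot(length(pass_counts) == length(thresholds))
  raw <- 100 * pass_counts / n_reference
  data.frame(threshold = thresholds, count = as.integer(pass_counts),
             percentage = round_percentage(raw), raw_pct = raw)
}

#' Peaks meeting the same category criteria at every timepoint
#'
#' Intersection of the peaks labelled `category` in every supplied contrast
#' table — e.g. the mDHSs defined by the strict criteria in all three memory
#' timepoints.
#'
#' @param tables list of [classify_dhs()] tables over the same master set.
#' @param category `"up"` or `"down"`.
#' @return character vector of feature ids.
#' @export
consistent_set <- function(tables, category = c("up", "down")) {
  category <- match.arg(category)
  stopifnot(length(tables) >= 2)
  feats <- lapply(tables, function(t) sort(t$feature))
  if (!all(vapply(feats[-1], identical, TRUE, feats[[1]])))
    stop("category tables cover different master sets")
  sets <- lapply(tables, function(t) t$feature[t$category == category])
  Reduce(intersect, sets)
}

#' Fraction of early-suppressed peaks that recover later
#'
#' Of the peaks suppressed at an early timepoint (an early "down" set), the
#' transient fraction is the share whose later-timepoint fold change no
#' longer meets the suppression criterion (later FC over baseline >
#' `1 / recovery_fold`).
#'
#' Either supply the later fold changes of the early set (`later_fc`), or a
#' pre-tabulated `n_recovered` when working from published tables.
#'
#' @param n_early size of the early-suppressed set (> 0).
#' @param later_fc later-timepoint fold changes (linear, later/baseline) for
#'   the early set.
#' @param recovery_fold suppression fold criterion (default 3).
#' @param n_recovered optional pre-tabulated recovered count.
#' @return list: count, n, percentage (integer-rounded).
#' @export
transient_fraction <- function(n_early, later_fc = NULL, recovery_fold = 3,
                               n_recovered = NULL) {
  if (n_early <= 0) stop("early-suppressed set must be non-empty")
  if (is.null(n_recovered)) {
    if (is.null(later_fc)) stop("supply later_fc or n_recovered")
    n_recovered <- sum(later_fc >= 1 / recovery_fold)
  }
  list(count = as.integer(n_recovered), n = as.integer(n_early),
       percentage = round(100 * n_recovered / n_early))
}
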