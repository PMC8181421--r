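# Peak calling from cut tracks and master peak-set construction.
#
# The caller slides a fixed window over the combined-strand cut counts and
# scores each window against a Poisson background whose rate is the larger of
# the chromosome-wide rate and a local rate (10 kb by default), in the spirit
# of MACS-style local-lambda calling. Significant windows are merged;
# each merged region's summit is the bp of maximal combined cut count.

# windowed sums at given 0-based starts via cumulative sums
window_sums <- function(cum, starts0, width, L) {
  a <- pmax(starts0, 0L); b <- pmin(starts0 + width, L)
  cum[b + 1L] - cum[a + 1L]
}

#' Call peaks on one chromosome's cut track
#'
#' @param track [cut_track()] object.
#' @param window sliding window width in bp (default 150, >= 50).
#' @param min_pvalue Poisson upper-tail p-value threshold (default 1e-5).
#' @param local_background width in bp of the local-rate window (default
#'   10000; must exceed `window`).
#' @param step window step in bp (default `window %/% 3`).
#' @return peak data.frame; `score` is -log10 of the Poisson p of the window
#'   centred on the summit; intervals are non-overlapping and sorted.
#' @export
call_peaks <- function(track, window = 150L, min_pvalue = 1e-5,
                       local_background = 10000L, step = window %/% 3L) {
  stopifnot(window >= 50, local_background > window, step >= 1)
  x <- combined_cuts(track)
  L <- length(x)
  total <- sum(x)
  empty <- peak_table(character(0), integer(0), integer(0))
  if (total == 0 || L < window) return(empty)
  cum <- c(0, cumsum(as.numeric(x)))
  global_rate <- total / L

  starts0 <- seq.int(0L, L - window, by = step)
  cnt <- window_sums(cum, starts0, window, L)
  ctr <- starts0 + window %/% 2L
  lb0 <- ctr - local_background %/% 2L
  lhi <- pmin(lb0 + local_background, L); llo <- pmax(lb0, 0L)
  local_rate <- (cum[lhi + 1L] - cum[llo + 1L]) / (lhi - llo)
  lambda <- pmax(global_rate, local_rate) * window
  logp <- ppois(cnt - 1, lambda, lower.tail = FALSE, log.p = TRUE)
  sig <- which(logp < log(min_pvalue))
  if (length(sig) == 0) return(empty)

  regions <- merge_intervals(data.frame(chrom = track$chrom,
                                        start = starts0[sig],
                                        end = starts0[sig] + window))
  n <- nrow(regions)
  summit <- integer(n); score <- numeric(n)
  for (i in seq_len(n)) {
    sl <- x[(regions$start[i] + 1L):regions$end[i]]
    summit[i] <- regions$start[i] + which.max(sl) - 1L   # ties: leftmost
    s0 <- summit[i] - window %/% 2L
    k <- window_sums(cum, s0, window, L)
    lo <- pmax(summit[i] - local_background %/% 2L, 0L)
    hi <- pmin(lo + local_background, L)
    lam <- max(global_rate, (cum[hi + 1L] - cum[lo + 1L]) / (hi - lo)) * window
    score[i] <- -ppois(k - 1, lam, lower.tail = FALSE, log.p = TRUE) / log(10)
  }
  peak_table(regions$chrom, regions$start, regions$end,
             name = paste0(track$chrom, "_peak_", seq_len(n)),
             score = score, summit = summit)
}

#' Call peaks across a whole track set
#'
#' Applies [call_peaks()] per chromosome and concatenates.
#'
#' @param tracks track set (named list of [cut_track()]).
#' @inheritParams call_peaks
#' @return peak data.frame.
#' @export
call_peaks_all <- function(tracks, window = 150L, min_pvalue = 1e-5,
                           local_background = 10000L) {
  out <- lapply(tracks, call_peaks, window = window,
                min_pvalue = min_pvalue, local_background = local_background)
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Top k peaks by score
#'
#' Ties at the cutoff are broken by (chrom, start); if fewer than `k` peaks
#' are available, all are returned.
#'
#' @param peaks peak data.frame.
#' @param k number to keep (>= 0).
#' @return subset of `peaks`.
#' @export
top_k <- function(peaks, k) {
  stopifnot(k >= 0)
  if (k == 0) return(peaks[integer(0), , drop = FALSE])
  ord <- order(-peaks$score, peaks$chrom, peaks$start)
  peaks[sort(head(ord, k)), , drop = FALSE]
}

#' Replicate-concordant peak set
#'
#' Intersects the top `k` peaks of two replicates, keeping replicate 1's
#' coordinates and summits — the high-confidence summit set used downstream.
#'
#' @param rep1,rep2 peak data.frames for the two replicates.
#' @param k peaks to take from each replicate before intersecting
#'   (default 35000).
#' @return subset of `top_k(rep1, k)` overlapping `top_k(rep2, k)`.
#' @export
concordant_peaks <- function(rep1, rep2, k = 35000L) {
  intersect_peaks(top_k(rep1, k), top_k(rep2, k))
}

#' Merge per-condition peak sets into the master set
#'
#' Merges the union of all condition sets (book-ended regions fuse); each
#' merged region inherits the summit of its highest-score contributing peak
#' (ties by coordinate), so summit-window counting stays anchored on the
#' strongest observed signal.
#'
#' @param condition_sets list of peak data.frames (>= 1).
#' @return master peak data.frame, sorted, named `master_1..n`.
#' @export
build_master_set <- function(condition_sets) {
  stopifnot(length(condition_sets) >= 1)
  all_pk <- do.call(rbind, condition_sets)
  rownames(all_pk) <- NULL
  if (nrow(all_pk) == 0)
    return(peak_table(character(0), integer(0), integer(0)))
  merged <- merge_intervals(all_pk)
  merged$name <- paste0("master_", seq_len(nrow(merged)))
  merged$summit <- NA_integer_
  merged$score <- NA_real_
  ord <- order(-all_pk$score, all_pk$chrom, all_pk$start)
  cand <- all_pk[ord, , drop = FALSE]
  for (ch in unique(merged$chrom)) {
    im <- which(merged$chrom == ch)
    ic <- which(cand$chrom == ch)
    if (!length(ic)) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(merged$start[im] + 1L, merged$end[im]),
      IRanges::IRanges(cand$start[ic] + 1L, cand$end[ic]),
      select = "first")   # candidates sorted by score: first = best
    merged$summit[im] <- cand$summit[ic][hits]
    merged$score[im] <- cand$score[ic][hits]
  }
  merged$strand <- "."
  merged <- merged[, c("chrom", "start", "end", "name", "score", "strand",
                       "summit")]
  validate_peaks(merged)
  merged
}

#' Count cuts in summit-centred windows for each sample
#'
#' Counts both strands' cuts in `[summit - halfwidth, summit + halfwidth)`
#' per master peak and sample, clipping windows at chromosome ends — the
#' summit-window tag counting that feeds normalization and testing.
#'
#' @param track_sets named list (sample id -> track set).
#' @param peaks master peak data.frame with summits.
#' @param samples sample sheet (sample, condition, replicate).
#' @param halfwidth window half-width in bp (default 200).
#' @return [count_matrix()] of peaks x samples.
#' @export
count_in_windows <- function(track_sets, peaks, samples, halfwidth = 200L) {
  stopifnot(halfwidth > 0)
  cnt <- matrix(0L, nrow(peaks), length(track_sets),
                dimnames = list(peaks$name, names(track_sets)))
  for (s in names(track_sets)) {
    tr <- track_sets[[s]]
    for (ch in unique(peaks$chrom)) {
      if (!ch %in% names(tr)) stop("track missing chromosome ", ch)
      L <- track_length(tr[[ch]])
      ip <- which(peaks$chrom == ch)
      if (any(peaks$summit[ip] < 0 | peaks$summit[ip] >= L))
        stop("summit outside chromosome ", ch)
      cum <- c(0, cumsum(as.numeric(combined_cuts(tr[[ch]]))))
      cnt[ip, s] <- as.integer(
        window_sums(cum, peaks$summit[ip] - halfwidth, 2L * halfwidth, L))
    }
  }
  count_matrix(cnt, samples)
}
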