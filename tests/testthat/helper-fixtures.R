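# Shared fixtures: a reduced-scale simulation config for fast end-to-end
# tests, and random-instance builders for oracle comparisons.

small_config <- function(seed = 11,
                         n_peaks = c(mDHS = 30, nDHS = 30, iDHS = 30,
                                     dDHS = 30, constitutive = 80),
                         ...) {
  sim_config(n_peaks = n_peaks, genome = c(chr1 = 1e6, chr2 = 1e6),
             seed = seed, ...)
}

# the standard study-scale config (2,000 peaks, 8-fold effects, depth 100)
standard_config <- function(seed = 11, ...) sim_config(seed = seed, ...)

random_intervals <- function(n, chroms = c("chrA", "chrB"), max_pos = 2000,
                             max_len = 120) {
  start <- sample.int(max_pos, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + sample.int(max_len, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

random_peaks <- function(n, chroms = c("chrA", "chrB"), max_pos = 2000,
                         max_len = 120) {
  iv <- random_intervals(n, chroms, max_pos, max_len)
  peak_table(iv$chrom, iv$start, iv$end, name = paste0("p", seq_len(n)),
             score = round(runif(n, 0, 100), 1))
}

# tiny track set with cuts at given 0-based positions
tiny_tracks <- function(L = 1000, fwd_pos = integer(0), rev_pos = integer(0),
                        chrom = "chrT") {
  setNames(list(cut_track(chrom, tabulate(fwd_pos + 1L, L),
                          tabulate(rev_pos + 1L, L))), chrom)
}
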