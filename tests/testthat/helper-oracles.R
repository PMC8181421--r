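# Independent brute-force oracles used to validate the fast implementations.

# per-bp coverage mask reconstruction of interval merging
oracle_merge <- function(intervals) {
  out <- list()
  for (ch in sort(unique(intervals$chrom))) {
    d <- intervals[intervals$chrom == ch, , drop = FALSE]
    mask <- logical(max(d$end) + 1)
    for (i in seq_len(nrow(d))) mask[(d$start[i] + 1):d$end[i]] <- TRUE
    r <- rle(mask)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths
    keep <- r$values
    out[[ch]] <- data.frame(chrom = ch, start = starts[keep],
                            end = ends[keep], stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

# O(n*m) pairwise half-open overlap
oracle_intersect <- function(a, b) {
  keep <- vapply(seq_len(nrow(a)), function(i)
    any(b$chrom == a$chrom[i] & b$start < a$end[i] & b$end > a$start[i]),
    TRUE)
  a[keep, , drop = FALSE]
}

# exhaustive all-pairs closest gene with the documented tie rules
oracle_closest <- function(peaks, genes) {
  vapply(seq_len(nrow(peaks)), function(i) {
    g <- genes[genes$chrom == peaks$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) return(NA_character_)
    d <- abs(g$tss - peaks$summit[i])
    g <- g[d == min(d), , drop = FALSE]
    g <- g[order(g$tss, g$gene_id), , drop = FALSE]
    g$gene_id[1]
  }, "")
}

# naive O(n^2) step-up BH: padj_i = min over p_j >= p_i of p_j * n / rank_j
oracle_bh <- function(p) {
  n <- length(p)
  vapply(seq_len(n), function(i) {
    min(1, min(vapply(which(p >= p[i]), function(j)
      p[j] * n / sum(p <= p[j]), 0)))
  }, 0)
}

# naive per-position IUPAC scan of one window sequence (forward strand)
iupac_match_at <- function(seq_chars, pos, consensus) {
  map <- Biostrings::IUPAC_CODE_MAP
  all(vapply(seq_along(consensus), function(k) {
    b <- seq_chars[pos + k - 1]
    grepl(b, map[[consensus[k]]], fixed = TRUE)
  }, TRUE))
}

oracle_scan_window <- function(window_seq, consensus) {
  chars <- strsplit(window_seq, "")[[1]]
  cons <- strsplit(consensus, "")[[1]]
  L <- length(chars); m <- length(cons)
  if (L < m) return(integer(0))
  which(vapply(seq_len(L - m + 1), iupac_match_at, TRUE,
               seq_chars = chars, consensus = cons))
}

revcomp_str <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# brute-force NB likelihood-ratio p by grid optimization (small instances)
oracle_nb_lr_p <- function(k1, k2, sf1, sf2, alpha) {
  ll <- function(k, sf, mu)
    sum(stats::dnbinom(k, mu = mu * sf, size = 1 / alpha, log = TRUE))
  grid <- exp(seq(log(0.05), log(max(c(k1, k2, 1)) * 20), length.out = 4000))
  l_null <- max(vapply(grid, function(m) ll(k1, sf1, m) + ll(k2, sf2, m), 0))
  l_alt <- max(vapply(grid, function(m) ll(k1, sf1, m), 0)) +
    max(vapply(grid, function(m) ll(k2, sf2, m), 0))
  stats::pchisq(2 * (l_alt - l_null), df = 1, lower.tail = FALSE)
}
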