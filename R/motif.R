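# Consensus motif scanning in summit windows, enrichment against background
# peaks, strand-aware footprint scoring of motif instances, and aggregate
# cut/tag-density profiles.

#' Built-in consensus motif panel
#'
#' Literature IUPAC consensus strings for the transcription-factor families
#' recurrently found in T-cell accessible chromatin (ETS, RUNX, AP-1,
#' TCF/LEF, NFAT, T-box, EGR). A custom panel can be read with
#' [read_motif_panel()].
#'
#' @return data.frame: name, consensus.
#' @export
default_motif_panel <- function() {
  read_motif_panel(system.file("extdata", "motif_panel.tsv",
                               package = "atacmem"))
}

#' Read a motif panel TSV (columns: name, consensus)
#'
#' @param path TSV path.
#' @return data.frame: name, consensus (validated IUPAC, length >= 5).
#' @export
read_motif_panel <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "consensus") %in% names(df)))
  ok <- grepl("^[ACGTRYSWKMBDHVN]+$", toupper(df$consensus))
  if (!all(ok)) stop("invalid IUPAC consensus: ", df$consensus[!ok][1])
  if (any(nchar(df$consensus) < 5)) stop("consensus strings must be >= 5 bp")
  df$consensus <- toupper(df$consensus)
  df
}

#' Scan a consensus motif in summit-proximal windows
#'
#' Finds all exact IUPAC matches on both strands within
#' `[summit - halfwidth, summit + halfwidth)` of each peak (windows clipped
#' at chromosome ends). Reverse-strand hits are reported with forward
#' coordinates and a `-` strand flag; duplicate (position, strand) pairs
#' arising from overlapping windows are removed.
#'
#' @param genome named [Biostrings::DNAStringSet] (or coercible character
#'   vector) of chromosome sequences.
#' @param peaks peak data.frame with summits.
#' @param consensus IUPAC consensus string.
#' @param halfwidth window half-width around the summit (default 100).
#' @return data.frame: chrom, start, end (0-based half-open), strand, peak
#'   (name of the window's peak).
#' @export
scan_motifs <- function(genome, peaks, consensus, halfwidth = 100L) {
  if (!methods::is(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(genome)
  pat <- Biostrings::DNAString(consensus)
  rcpat <- Biostrings::reverseComplement(pat)
  hits <- list(); hi <- 0L
  for (i in seq_len(nrow(peaks))) {
    ch <- peaks$chrom[i]
    if (!ch %in% names(genome)) stop("genome is missing chromosome ", ch)
    L <- Biostrings::width(genome[ch])
    w0 <- max(peaks$summit[i] - halfwidth, 0L)
    w1 <- min(peaks$summit[i] + halfwidth, L)
    if (w1 - w0 < length(pat)) next
    subj <- Biostrings::subseq(genome[[ch]], w0 + 1L, w1)
    for (str in c("+", "-")) {
      p <- if (str == "+") pat else rcpat
      m <- Biostrings::matchPattern(p, subj, fixed = "subject")
      if (length(m) == 0) next
      hits[[hi <- hi + 1L]] <- data.frame(
        chrom = ch, start = w0 + IRanges::start(m) - 1L,
        end = w0 + IRanges::end(m), strand = str,
        peak = peaks$name[i], stringsAsFactors = FALSE)
    }
  }
  if (hi == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      peak = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out <- out[!duplicated(out[, c("chrom", "start", "strand")]), , drop = FALSE]
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Motif enrichment in target versus background peaks
#'
#' Counts peaks containing at least one consensus hit in their summit window
#' and compares target against background with a hypergeometric upper-tail
#' test; fold enrichment is the ratio of hit fractions.
#'
#' @param genome chromosome sequences (see [scan_motifs()]).
#' @param target,background peak data.frames (both non-empty).
#' @param consensus IUPAC consensus string.
#' @param halfwidth summit window half-width (default 100).
#' @return list: n_target, n_background, hits_target, hits_background,
#'   fold (possibly `Inf`), pvalue.
#' @export
motif_enrichment <- function(genome, target, background, consensus,
                             halfwidth = 100L) {
  stopifnot(nrow(target) > 0, nrow(background) > 0)
  ht <- length(unique(scan_motifs(genome, target, consensus, halfwidth)$peak))
  hb <- length(unique(scan_motifs(genome, background, consensus,
                                  halfwidth)$peak))
  nt <- nrow(target); nb <- nrow(background)
  fold <- (ht / nt) / (hb / nb)
  p <- phyper(ht - 1, ht + hb, nt + nb - ht - hb, nt, lower.tail = FALSE)
  list(n_target = nt, n_background = nb, hits_target = ht,
       hits_background = hb, fold = fold, pvalue = p)
}

#' Rank a motif panel by enrichment
#'
#' Applies [motif_enrichment()] to every motif of a panel and returns the
#' table sorted by p-value (ties by descending fold).
#'
#' @inheritParams motif_enrichment
#' @param panel motif panel data.frame (name, consensus).
#' @return data.frame: name, consensus, hits_target, hits_background, fold,
#'   pvalue, sorted by evidence.
#' @export
motif_enrichment_panel <- function(genome, target, background, panel,
                                   halfwidth = 100L) {
  rows <- lapply(seq_len(nrow(panel)), function(i) {
    e <- motif_enrichment(genome, target, background, panel$consensus[i],
                          halfwidth)
    data.frame(name = panel$name[i], consensus = panel$consensus[i],
               hits_target = e$hits_target,
               hits_background = e$hits_background, fold = e$fold,
               pvalue = e$pvalue, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$pvalue, -out$fold), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Strand-aware footprint score for one motif instance
#'
#' Tests for local protection of the motif interval against its shoulder:
#' the forward strand is compared with the upstream shoulder, the reverse
#' strand with the downstream shoulder (bound factors shield the strand
#' facing the flank). Per strand, the p-value is the lower binomial tail of
#' observing at most the footprint's cuts among footprint+shoulder cuts when
#' each cut lands in the footprint with probability
#' `len_fp / (len_fp + len_shoulder)`. The combined score is the sum of the
#' two `-log10 p` values; an instance passes at `score >= threshold`
#' (default 10).
#'
#' @param tracks track set (named list of [cut_track()]), typically pooled
#'   replicates.
#' @param instance one-row data.frame with chrom, start, end (0-based
#'   half-open motif interval).
#' @param shoulder shoulder width in bp (default 35; must be >= the motif
#'   length).
#' @param threshold combined-score pass threshold (default 10).
#' @return list: score_fwd, score_rev, score (combined), pass.
#' @export
footprint_score <- function(tracks, instance, shoulder = 35L,
                            threshold = 10) {
  ch <- instance$chrom[1]
  if (!ch %in% names(tracks)) stop("track missing chromosome ", ch)
  tr <- tracks[[ch]]
  L <- track_length(tr)
  fp0 <- instance$start[1]; fp1 <- instance$end[1]
  len_fp <- fp1 - fp0
  if (shoulder < len_fp) stop("shoulder must be >= footprint length")
  strand_p <- function(counts, sh0, sh1) {
    sh0 <- max(sh0, 0L); sh1 <- min(sh1, L)
    k_fp <- sum(counts[(fp0 + 1L):fp1])
    k_sh <- if (sh1 > sh0) sum(counts[(sh0 + 1L):sh1]) else 0L
    n <- k_fp + k_sh
    if (n == 0) return(1)
    q <- len_fp / (len_fp + (sh1 - sh0))
    pbinom(k_fp, n, q)
  }
  p_f <- strand_p(tr$fwd, fp0 - shoulder, fp0)
  p_r <- strand_p(tr$rev, fp1, fp1 + shoulder)
  s_f <- -log10(p_f); s_r <- -log10(p_r)
  score <- s_f + s_r
  list(score_fwd = s_f, score_rev = s_r, score = score,
       pass = score >= threshold)
}

#' Score every motif instance of a table
#'
#' @inheritParams footprint_score
#' @param instances data.frame of motif intervals (chrom, start, end).
#' @return `instances` with score_fwd, score_rev, score, pass columns added.
#' @export
footprint_scores <- function(tracks, instances, shoulder = 35L,
                             threshold = 10) {
  sc <- lapply(seq_len(nrow(instances)), function(i)
    footprint_score(tracks, instances[i, , drop = FALSE], shoulder,
                    threshold))
  instances$score_fwd <- vapply(sc, `[[`, 0, "score_fwd")
  instances$score_rev <- vapply(sc, `[[`, 0, "score_rev")
  instances$score <- vapply(sc, `[[`, 0, "score")
  instances$pass <- vapply(sc, `[[`, TRUE, "pass")
  instances
}

#' Average strand-resolved cut profile around motif instances
#'
#' Aligns instances on their motif centre; reverse-strand instances are
#' orientation-flipped (profile reversed and strands swapped) so that all
#' instances read in motif orientation. Returns per-bp mean forward and
#' reverse cut counts across instances.
#'
#' @param tracks track set (pooled sample group).
#' @param instances data.frame: chrom, start, end, strand.
#' @param window total profile width in bp (even; default 200).
#' @return list: `position` (offsets relative to motif centre), `fwd`,
#'   `rev` (per-bp means), `n` instances used.
#' @export
average_cut_profile <- function(tracks, instances, window = 200L) {
  stopifnot(window %% 2 == 0)
  if (nrow(instances) == 0) stop("no motif instances supplied")
  half <- window %/% 2L
  acc_f <- numeric(window); acc_r <- numeric(window); used <- 0L
  for (i in seq_len(nrow(instances))) {
    ch <- instances$chrom[i]
    tr <- tracks[[ch]]
    if (is.null(tr)) stop("track missing chromosome ", ch)
    L <- track_length(tr)
    ctr <- (instances$start[i] + instances$end[i]) %/% 2L
    a <- ctr - half; b <- ctr + half
    if (a < 0 || b > L) next   # instances too close to the edge are skipped
    f <- tr$fwd[(a + 1L):b]; r <- tr$rev[(a + 1L):b]
    if (identical(instances$strand[i], "-")) {
      tmp <- rev(f); f <- rev(r); r <- tmp
    }
    acc_f <- acc_f + f; acc_r <- acc_r + r
    used <- used + 1L
  }
  if (used == 0) stop("no motif instances fit within the chromosomes")
  list(position = seq.int(-half, half - 1L), fwd = acc_f / used,
       rev = acc_r / used, n = used)
}

#' Tag-density matrix around summits
#'
#' Bins both strands' cuts over `[summit - window/2, summit + window/2)` at
#' `bin` bp resolution for every peak (rows), scaled by the sample's size
#' factor; column means give the average density profile. Windows extending
#' beyond a chromosome contribute zeros there.
#'
#' @param tracks track set for one sample.
#' @param peaks peak data.frame with summits.
#' @param window total window width in bp (default 2000).
#' @param bin bin width in bp (default 10; must divide `window`).
#' @param size_factor the sample's size factor (counts are divided by it).
#' @return matrix peaks x bins with `colmeans` attribute holding the average
#'   profile.
#' @export
tag_density_profile <- function(tracks, peaks, window = 2000L, bin = 10L,
                                size_factor = 1) {
  stopifnot(window %% bin == 0)
  nb <- window %/% bin
  half <- window %/% 2L
  out <- matrix(0, nrow(peaks), nb,
                dimnames = list(peaks$name, as.character(
                  seq.int(-half, half - bin, by = bin))))
  for (ch in unique(peaks$chrom)) {
    tr <- tracks[[ch]]
    if (is.null(tr)) stop("track missing chromosome ", ch)
    L <- track_length(tr)
    cum <- c(0, cumsum(as.numeric(combined_cuts(tr))))
    ip <- which(peaks$chrom == ch)
    for (b in seq_len(nb)) {
      s0 <- peaks$summit[ip] - half + (b - 1L) * bin
      out[ip, b] <- window_sums(cum, pmax(pmin(s0, L), -bin), bin, L)
    }
  }
  out <- out / size_factor
  attr(out, "colmeans") <- colMeans(out)
  out
}
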