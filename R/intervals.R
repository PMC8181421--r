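#' @importFrom stats median optimize pnorm ppois pbinom phyper quantile rbinom
#'   rnbinom rpois runif setNames var rlnorm
#' @importFrom utils read.table write.table head
NULL

# Peaks and genomic intervals are plain data.frames using BED conventions:
# 0-based half-open [start, end), columns chrom/start/end(/name/score/strand)
# plus an absolute 0-based `summit` column for peaks.

#' Construct a peak table
#'
#' Builds and validates the data.frame of genomic intervals used throughout the
#' package. Coordinates are 0-based half-open (BED convention); `summit` is an
#' absolute 0-based position inside `[start, end)`.
#'
#' @param chrom character chromosome names.
#' @param start,end integer 0-based half-open interval bounds.
#' @param name feature identifiers (defaults to `peak_1..n`).
#' @param score non-negative numeric enrichment scores.
#' @param strand one of `"+"`, `"-"`, `"."` per interval.
#' @param summit absolute summit positions; defaults to the interval midpoint
#'   (rounded down).
#' @return data.frame with columns chrom, start, end, name, score, strand,
#'   summit.
#' @export
peak_table <- function(chrom, start, end, name = NULL, score = 0,
                       strand = ".", summit = NULL) {
  n <- length(chrom)
  start <- as.integer(start); end <- as.integer(end)
  if (is.null(name)) name <- if (n) paste0("peak_", seq_len(n)) else character(0)
  if (is.null(summit)) summit <- start + (end - start) %/% 2L
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   name = as.character(name),
                   score = rep_len(as.numeric(score), n),
                   strand = rep_len(as.character(strand), n),
                   summit = as.integer(summit),
                   stringsAsFactors = FALSE)
  validate_peaks(df)
  df
}

validate_peaks <- function(df) {
  if (nrow(df) == 0) return(invisible(df))
  if (any(df$start < 0)) stop("interval start must be >= 0")
  if (any(df$start >= df$end)) stop("interval start must be < end")
  if (any(!nzchar(df$chrom))) stop("chromosome names must be non-empty")
  if (!is.null(df$summit) &&
      any(df$summit < df$start | df$summit >= df$end))
    stop("summit must lie within [start, end)")
  if (!is.null(df$score) && any(df$score < 0)) stop("scores must be >= 0")
  invisible(df)
}

#' Read a BED file of peaks
#'
#' Accepts BED3/BED5/BED6 plus an optional seventh "summit" column, which may
#' hold either an absolute 0-based position or an offset from `start`
#' (`summit_col` selects the dialect). Records are returned in file order with
#' coordinates unchanged; a missing summit defaults to the interval midpoint.
#'
#' @param path BED file path.
#' @param summit_col `"none"`, `"absolute"` or `"offset"`.
#' @return peak data.frame (see [peak_table()]).
#' @export
read_bed <- function(path, summit_col = c("none", "absolute", "offset")) {
  summit_col <- match.arg(summit_col)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  if (length(lines) == 0)
    return(peak_table(character(0), integer(0), integer(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("malformed BED line ", which(nf < 3)[1], ": fewer than 3 columns")
  get <- function(i) vapply(fields, function(f)
    if (length(f) >= i) f[i] else NA_character_, "")
  start <- suppressWarnings(as.integer(get(2)))
  end <- suppressWarnings(as.integer(get(3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stop("malformed BED line ", bad[1], ": non-integer coordinate")
  bad <- which(start >= end)
  if (length(bad)) stop("invalid interval on line ", bad[1], ": start >= end")
  name <- get(4); score <- suppressWarnings(as.numeric(get(5)))
  strand <- get(6)
  name[is.na(name)] <- paste0("peak_", which(is.na(name)))
  score[is.na(score)] <- 0
  strand[is.na(strand) | !strand %in% c("+", "-", ".")] <- "."
  summit <- NULL
  if (summit_col != "none") {
    s7 <- suppressWarnings(as.integer(get(7)))
    bad <- which(is.na(s7))
    if (length(bad)) stop("malformed BED line ", bad[1], ": missing summit column")
    summit <- if (summit_col == "absolute") s7 else start + s7
  }
  peak_table(get(1), start, end, name, score, strand, summit)
}

#' Write peaks as BED
#'
#' Inverse of [read_bed()]; with `summit_col != "none"` a seventh column
#' carrying the summit (absolute or offset from start) is written.
#'
#' @inheritParams read_bed
#' @param peaks peak data.frame.
#' @export
write_bed <- function(peaks, path, summit_col = c("none", "absolute", "offset")) {
  summit_col <- match.arg(summit_col)
  out <- peaks[, c("chrom", "start", "end", "name", "score", "strand")]
  if (summit_col == "absolute") out$summit <- peaks$summit
  if (summit_col == "offset") out$summit <- peaks$summit - peaks$start
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a TSV gene model table
#'
#' Expects columns gene_id, chrom, tss (0-based), strand; header optional.
#'
#' @param path TSV path.
#' @return data.frame with gene_id, chrom, tss, strand.
#' @export
read_gene_table <- function(path) {
  first <- readLines(path, n = 1)
  header <- grepl("gene_id", first, fixed = TRUE)
  df <- read.table(path, sep = "\t", header = header,
                   col.names = if (header) NULL else
                     c("gene_id", "chrom", "tss", "strand"),
                   stringsAsFactors = FALSE)
  names(df) <- c("gene_id", "chrom", "tss", "strand")[seq_along(df)]
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in gene table")
  df
}

#' Merge overlapping or book-ended intervals
#'
#' Sorts by (chrom, start) and merges intervals that overlap or touch
#' (distance 0 merges), preserving the union of covered bases — the standard
#' `sort | merge` behaviour used when building union peak sets.
#'
#' @param intervals data.frame with chrom, start, end (0-based half-open).
#' @return merged data.frame with chrom, start, end, sorted.
#' @export
merge_intervals <- function(intervals) {
  if (nrow(intervals) == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  out <- lapply(split(intervals, intervals$chrom), function(d) {
    r <- IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end))
    data.frame(chrom = d$chrom[1], start = IRanges::start(r) - 1L,
               end = IRanges::end(r), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[order(names(out))])
  rownames(out) <- NULL
  out
}

#' Keep peaks of one set that overlap another
#'
#' Returns the members of `a` that overlap any member of `b` by at least 1 bp
#' (half-open coordinates, so book-ended intervals do not count). `a`'s order,
#' coordinates and summits are preserved — this is the replicate-concordance
#' primitive.
#'
#' @param a,b peak data.frames.
#' @return subset of `a`.
#' @export
intersect_peaks <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(a[integer(0), , drop = FALSE])
  keep <- logical(nrow(a))
  for (ch in unique(a$chrom)) {
    ia <- which(a$chrom == ch)
    ib <- which(b$chrom == ch)
    if (length(ib) == 0) next
    ra <- IRanges::IRanges(a$start[ia] + 1L, a$end[ia])
    rb <- IRanges::IRanges(b$start[ib] + 1L, b$end[ib])
    keep[ia] <- IRanges::overlapsAny(ra, rb)
  }
  a[keep, , drop = FALSE]
}

#' Assign each peak its closest gene
#'
#' Distance is measured summit-to-TSS on the same chromosome and signed as
#' `tss - summit`. Ties are broken by smaller tss, then lexicographic gene_id.
#' Peaks on chromosomes with no gene get `NA` (and a warning) rather than a
#' cross-chromosome assignment.
#'
#' @param peaks peak data.frame with summit column.
#' @param genes gene table (gene_id, chrom, tss).
#' @return data.frame peak name, gene_id, distance (tss - summit).
#' @export
closest_gene <- function(peaks, genes) {
  if (nrow(genes) == 0) stop("gene table is empty")
  res <- data.frame(name = peaks$name, gene_id = NA_character_,
                    distance = NA_integer_, stringsAsFactors = FALSE)
  for (ch in unique(peaks$chrom)) {
    ip <- which(peaks$chrom == ch)
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0) next
    g <- g[order(g$tss, g$gene_id), , drop = FALSE]
    for (i in ip) {
      s <- peaks$summit[i]
      d <- abs(g$tss - s)
      j <- which(d == min(d))          # sorted by (tss, gene_id): first wins
      res$gene_id[i] <- g$gene_id[j[1]]
      res$distance[i] <- g$tss[j[1]] - s
    }
  }
  if (anyNA(res$gene_id))
    warning("no gene on chromosome for ",
            sum(is.na(res$gene_id)), " peak(s); NA assigned")
  res
}

#' Three-way overlap counts between two sets
#'
#' For character vectors, exact set algebra on identifiers. For peak
#' data.frames, membership is by >= 1 bp interval overlap in each direction
#' (the two sets may come from different master coordinate systems), as used
#' for Venn-style comparisons of DHS sets.
#'
#' @param a,b character vectors of ids, or peak data.frames.
#' @return named integer vector: `both`, `a_only`, `b_only`.
#' @export
overlap_counts <- function(a, b) {
  if (is.data.frame(a) && is.data.frame(b)) {
    ab <- nrow(intersect_peaks(a, b))
    ba <- nrow(intersect_peaks(b, a))
    c(both = ab, a_only = nrow(a) - ab, b_only = nrow(b) - ba)
  } else {
    a <- unique(as.character(a)); b <- unique(as.character(b))
    inter <- length(intersect(a, b))
    c(both = inter, a_only = length(a) - inter, b_only = length(b) - inter)
  }
}
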