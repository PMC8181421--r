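# Lightweight containers. A CountMatrix couples an integer feature x sample
# matrix with its sample sheet; a CutTrack holds per-base, per-strand Tn5
# insertion counts for one chromosome.

#' Construct a count matrix with sample metadata
#'
#' @param counts integer matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids).
#' @param samples data.frame with columns `sample`, `condition`, `replicate`;
#'   one row per column of `counts`, matched by `sample`.
#' @return object of class `CountMatrix`: list with `counts` and `samples`.
#' @export
count_matrix <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) stop("counts must have sample column names")
  if (is.null(rownames(counts))) stop("counts must have feature row names")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (anyDuplicated(colnames(counts))) stop("sample ids must be unique")
  req <- c("sample", "condition", "replicate")
  if (!all(req %in% names(samples)))
    stop("samples needs columns: ", paste(req, collapse = ", "))
  if (!setequal(samples$sample, colnames(counts)))
    stop("samples$sample must match colnames(counts)")
  samples <- samples[match(colnames(counts), samples$sample), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(counts = counts, samples = samples), class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat("CountMatrix:", nrow(x$counts), "features x", ncol(x$counts),
      "samples\n")
  cat("conditions:", paste(unique(x$samples$condition), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' Sample ids belonging to a condition
#' @param cm CountMatrix.
#' @param condition condition label.
#' @return character vector of sample ids.
#' @export
condition_samples <- function(cm, condition) {
  cm$samples$sample[cm$samples$condition == condition]
}

#' Construct a per-chromosome cut track
#'
#' Per-base integer counts of Tn5 insertion (cut) sites, forward and reverse
#' strand kept separate as footprinting requires.
#'
#' @param chrom chromosome name.
#' @param fwd,rev integer vectors of per-base cut counts, equal length; index
#'   i holds the count at 0-based position i - 1.
#' @return object of class `CutTrack`.
#' @export
cut_track <- function(chrom, fwd, rev) {
  if (length(fwd) != length(rev)) stop("strand vectors must have equal length")
  if (any(fwd < 0) || any(rev < 0)) stop("cut counts must be >= 0")
  structure(list(chrom = chrom, fwd = as.integer(fwd), rev = as.integer(rev)),
            class = "CutTrack")
}

#' @export
print.CutTrack <- function(x, ...) {
  cat("CutTrack", x$chrom, ":", length(x$fwd), "bp,",
      sum(x$fwd) + sum(x$rev), "cuts\n")
  invisible(x)
}

track_length <- function(track) length(track$fwd)

combined_cuts <- function(track) track$fwd + track$rev

# A "track set" is a named list of CutTrack, one per chromosome, for one
# sample. Summing track sets pools replicates (as done before footprinting).

#' Pool cut-track sets across samples
#'
#' Element-wise sum of per-base counts over samples covering the same
#' chromosomes, used to combine replicates before footprint scoring.
#'
#' @param track_sets list of track sets (each a named list of [cut_track()]).
#' @return one pooled track set.
#' @export
pool_tracks <- function(track_sets) {
  stopifnot(length(track_sets) >= 1)
  out <- track_sets[[1]]
  for (ts in track_sets[-1]) {
    if (!identical(names(ts), names(out)))
      stop("track sets cover different chromosomes")
    for (ch in names(out)) {
      out[[ch]]$fwd <- out[[ch]]$fwd + ts[[ch]]$fwd
      out[[ch]]$rev <- out[[ch]]$rev + ts[[ch]]$rev
    }
  }
  out
}

#' Write a cut-track set as strand-separated bedGraph
#'
#' Emits `<prefix>_fwd.bedGraph` and `<prefix>_rev.bedGraph` with one line per
#' run of equal non-zero coverage (0-based half-open intervals).
#'
#' @param tracks track set (named list of [cut_track()]).
#' @param prefix output path prefix.
#' @return paths written, invisibly.
#' @export
write_cut_tracks <- function(tracks, prefix) {
  paths <- character(0)
  for (strand in c("fwd", "rev")) {
    path <- paste0(prefix, "_", strand, ".bedGraph")
    con <- file(path, "w")
    for (ch in names(tracks)) {
      v <- tracks[[ch]][[strand]]
      r <- rle(v)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths
      keep <- r$values != 0
      if (any(keep)) {
        writeLines(paste(tracks[[ch]]$chrom, starts[keep], ends[keep],
                         r$values[keep], sep = "\t"), con)
      }
    }
    close(con)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read a strand-separated bedGraph pair into a cut-track set
#'
#' @param prefix path prefix used by [write_cut_tracks()].
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @return track set (named list of [cut_track()]).
#' @export
read_cut_tracks <- function(prefix, chrom_lengths) {
  vecs <- lapply(c(fwd = "fwd", rev = "rev"), function(strand) {
    path <- paste0(prefix, "_", strand, ".bedGraph")
    if (!file.exists(path)) stop("file not found: ", path)
    out <- lapply(chrom_lengths, function(L) integer(L))
    if (file.size(path) > 0) {
      bg <- read.table(path, sep = "\t", stringsAsFactors = FALSE,
                       col.names = c("chrom", "start", "end", "value"))
      for (i in seq_len(nrow(bg))) {
        ch <- bg$chrom[i]
        out[[ch]][(bg$start[i] + 1L):bg$end[i]] <-
          out[[ch]][(bg$start[i] + 1L):bg$end[i]] + bg$value[i]
      }
    }
    out
  })
  setNames(lapply(names(chrom_lengths), function(ch)
    cut_track(ch, vecs$fwd[[ch]], vecs$rev[[ch]])), names(chrom_lengths))
}

#' Write a count matrix as TSV
#'
#' Two files: `<prefix>_counts.tsv` (feature column + one column per sample)
#' and `<prefix>_samples.tsv` (the sample sheet).
#'
#' @param cm CountMatrix.
#' @param prefix output path prefix.
#' @export
write_count_matrix <- function(cm, prefix) {
  df <- data.frame(feature = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, paste0(prefix, "_counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cm$samples, paste0(prefix, "_samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Read a count matrix written by [write_count_matrix()]
#' @param prefix path prefix.
#' @return CountMatrix.
#' @export
read_count_matrix <- function(prefix) {
  df <- read.table(paste0(prefix, "_counts.tsv"), sep = "\t", header = TRUE,
                   check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df$feature
  samples <- read.table(paste0(prefix, "_samples.tsv"), sep = "\t",
                        header = TRUE, stringsAsFactors = FALSE)
  count_matrix(counts, samples)
}
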