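# Synthetic multi-condition ATAC experiment with planted ground truth.
#
# The generator emulates the data structure the downstream analysis assumes:
# negative-binomially distributed summit-window counts with per-sample depth
# factors, replicate pairs per condition, planted category-specific fold
# changes, per-base strand-separated Tn5 cut tracks with protected footprints
# at planted motifs, and a matched expression matrix whose fold changes track
# the categories of nearby peaks.

#' Simulation configuration
#'
#' Defaults describe the standard synthetic experiment: a naive condition
#' (`N`), three resting memory timepoints (`M7`, `M28`, `M56`) and two
#' antigen-restimulated memory conditions (`M28Ag`, `M56Ag`), two replicates
#' each, on a 2 x 5 Mb genome carrying 2,000 peaks.
#'
#' @param n_peaks named integer vector: peaks per category
#'   (mDHS/nDHS/iDHS/dDHS/constitutive).
#' @param conditions ordered condition labels.
#' @param memory_conditions conditions counting as memory (mDHS-high).
#' @param stimulated_conditions conditions counting as antigen-stimulated
#'   (iDHS-high).
#' @param replicates replicates per condition (>= 2).
#' @param depth expected fragments per constitutive peak per sample.
#' @param dispersion NB dispersion alpha (variance = mu + alpha * mu^2).
#' @param effect_size planted accessibility fold change for
#'   category-specific peaks (>= 3).
#' @param constitutive_jitter max accessibility ratio across conditions for
#'   constitutive peaks.
#' @param peak_width planted peak width in bp.
#' @param summit_sd Gaussian spread (bp) of cut positions around the summit.
#' @param bg_rate background cut rate per bp per strand.
#' @param protection multiplicative per-bp cut rate inside protected motifs.
#' @param flank_boost multiplicative rate over the `flank_bp` flanks of
#'   protected motifs.
#' @param flank_bp width of the boosted flank on each side of a motif.
#' @param shared_gene_fraction fraction of iDHS peaks paired with an mDHS
#'   peak at a shared gene (creates mDHS+iDHS genes).
#' @param coupling_log2fc expression log2 fold change coupled to peak
#'   categories.
#' @param synergy_log2fc extra stimulated log2 fold change for genes linked
#'   to both an mDHS and an iDHS.
#' @param decoupled_fraction fraction of genes whose expression ignores their
#'   peak's category.
#' @param expr_base_mean expected expression counts per gene per sample.
#' @param genome named numeric vector of chromosome lengths.
#' @param seed integer RNG seed; every generator is deterministic given it.
#' @return list of class `SimulationConfig`.
#' @export
sim_config <- function(n_peaks = c(mDHS = 300, nDHS = 300, iDHS = 300,
                                   dDHS = 300, constitutive = 800),
                       conditions = c("N", "M7", "M28", "M56", "M28Ag", "M56Ag"),
                       memory_conditions = c("M7", "M28", "M56", "M28Ag", "M56Ag"),
                       stimulated_conditions = c("M28Ag", "M56Ag"),
                       replicates = 2L,
                       depth = 100,
                       dispersion = 0.1,
                       effect_size = 8,
                       constitutive_jitter = 1.25,
                       peak_width = 400L,
                       summit_sd = 40,
                       bg_rate = 0.005,
                       protection = 0.1,
                       flank_boost = 1.5,
                       flank_bp = 10L,
                       shared_gene_fraction = 0.15,
                       coupling_log2fc = 2,
                       synergy_log2fc = 1,
                       decoupled_fraction = 0.1,
                       expr_base_mean = 200,
                       genome = c(chr1 = 5e6, chr2 = 5e6),
                       seed = 1L) {
  stopifnot(length(conditions) >= 2, replicates >= 2, depth > 0,
            dispersion >= 0, effect_size > 0, all(n_peaks >= 0),
            all(genome > 0), all(memory_conditions %in% conditions),
            all(stimulated_conditions %in% conditions))
  cats <- c("mDHS", "nDHS", "iDHS", "dDHS", "constitutive")
  np <- setNames(rep(0L, length(cats)), cats)
  np[names(n_peaks)] <- as.integer(n_peaks)
  structure(list(n_peaks = np, conditions = conditions,
                 memory_conditions = memory_conditions,
                 stimulated_conditions = stimulated_conditions,
                 replicates = as.integer(replicates), depth = depth,
                 dispersion = dispersion, effect_size = effect_size,
                 constitutive_jitter = constitutive_jitter,
                 peak_width = as.integer(peak_width), summit_sd = summit_sd,
                 bg_rate = bg_rate, protection = protection,
                 flank_boost = flank_boost, flank_bp = as.integer(flank_bp),
                 shared_gene_fraction = shared_gene_fraction,
                 coupling_log2fc = coupling_log2fc,
                 synergy_log2fc = synergy_log2fc,
                 decoupled_fraction = decoupled_fraction,
                 expr_base_mean = expr_base_mean,
                 genome = genome, seed = as.integer(seed)),
            class = "SimulationConfig")
}

# Independent deterministic substream per generator: each public generator
# re-seeds from the config seed plus a fixed offset, so calls are
# order-independent and reproducible. Kept well below 2^31.
sim_seed <- function(config, offset) {
  set.seed((abs(config$seed) %% 1000003L) * 1009L + offset)
}

#' Sample sheet for a simulated experiment
#'
#' One row per sample (`<condition>_r<replicate>`), with the per-sample
#' library-size factor drawn log-uniformly in `[0.7, 1.4]` under the config
#' seed.
#'
#' @param config [sim_config()] object.
#' @return data.frame: sample, condition, replicate, size_factor.
#' @export
sim_samples <- function(config) {
  sim_seed(config, 3L)
  df <- expand.grid(replicate = seq_len(config$replicates),
                    condition = config$conditions,
                    stringsAsFactors = FALSE)
  df <- df[order(match(df$condition, config$conditions), df$replicate), ]
  df <- data.frame(sample = paste0(df$condition, "_r", df$replicate),
                   condition = df$condition, replicate = df$replicate,
                   stringsAsFactors = FALSE)
  df$size_factor <- exp(runif(nrow(df), log(0.7), log(1.4)))
  rownames(df) <- NULL
  df
}

# Condition multiplier row for one peak of a given category.
category_multipliers <- function(category, config) {
  cond <- config$conditions
  mem <- cond %in% config$memory_conditions
  stim <- cond %in% config$stimulated_conditions
  e <- config$effect_size
  m <- switch(category,
    mDHS = ifelse(mem, e, 1),
    nDHS = ifelse(mem, 1, e),
    iDHS = ifelse(stim, e, 1),
    dDHS = ifelse(stim, 1, e),
    constitutive = exp(runif(length(cond),
                             -log(config$constitutive_jitter) / 2,
                             log(config$constitutive_jitter) / 2)))
  setNames(m, cond)
}

#' Generate the planted truth: peaks, genes and motif instances
#'
#' Peaks are laid out on a regular grid (one "unit" per slot, jittered) so
#' that every peak is >= 2 kb from its neighbours and each gene's TSS is
#' closer to its own peak(s) than to any other gene's. A configurable
#' fraction of iDHS peaks is placed as a pair with an mDHS peak flanking a
#' shared gene, producing genes linked to both categories. Every mDHS peak
#' carries protected ETS and RUNX consensus instances near its summit; every
#' dDHS peak carries an unprotected ETS instance (matched-depth null
#' footprints).
#'
#' @param config [sim_config()] object.
#' @return list of class `SimTruth`: `peaks` (peak table plus `category`,
#'   `gene_id` and per-condition `mult_*` columns), `genes` (gene table),
#'   `motifs` (planted instances with `protected` flag), `config`.
#' @export
simulate_truth <- function(config) {
  sim_seed(config, 1L)
  np <- config$n_peaks
  n_total <- sum(np)
  if (n_total == 0) {
    return(structure(list(
      peaks = cbind(peak_table(character(0), integer(0), integer(0)),
                    category = character(0), gene_id = character(0)),
      genes = data.frame(gene_id = character(0), chrom = character(0),
                         tss = integer(0), strand = character(0)),
      motifs = data.frame(), config = config), class = "SimTruth"))
  }
  n_shared <- min(round(config$shared_gene_fraction * np[["iDHS"]]),
                  np[["mDHS"]], np[["iDHS"]])
  # unit = one genomic slot: either a single peak or an mDHS/iDHS pair
  unit_cat <- c(rep("pair", n_shared),
                rep("mDHS", np[["mDHS"]] - n_shared),
                rep("iDHS", np[["iDHS"]] - n_shared),
                rep("nDHS", np[["nDHS"]]),
                rep("dDHS", np[["dDHS"]]),
                rep("constitutive", np[["constitutive"]]))
  unit_cat <- sample(unit_cat)
  n_units <- length(unit_cat)

  genome <- config$genome
  alloc <- round(n_units * genome / sum(genome))
  alloc[1] <- n_units - sum(alloc[-1])
  w <- config$peak_width
  # slot spacing must guarantee >= 2 kb between neighbouring peaks and make
  # each planted gene strictly nearest to its own peak(s): with +/-200 bp
  # slot jitter and +/-1000 bp pair offsets that needs 4400 bp (3400 without
  # pairs)
  min_spacing <- (if (n_shared > 0) 2400 else 1400) + 2000 + max(w - 400, 0)
  for (ch in names(genome)) {
    if (alloc[[ch]] > 0 && genome[[ch]] / (alloc[[ch]] + 1) < min_spacing)
      stop("genome too small to place ", alloc[[ch]], " peak units on ",
           ch, " with the required spacing")
  }

  rows <- vector("list", n_units)
  motif_rows <- list()
  panel <- default_motif_panel()
  ets <- panel$consensus[panel$name == "ETS"]
  runx <- panel$consensus[panel$name == "RUNX"]
  unit_i <- 0L
  for (ch in names(genome)) {
    n_c <- alloc[[ch]]
    if (n_c == 0) next
    spacing <- floor(genome[[ch]] / (n_c + 1))
    centers <- (seq_len(n_c)) * spacing + round(runif(n_c, -200, 200))
    for (k in seq_len(n_c)) {
      unit_i <- unit_i + 1L
      cat_k <- unit_cat[unit_i]
      ctr <- centers[k]
      gid <- sprintf("gene_%05d", unit_i)
      if (cat_k == "pair") {
        tss <- ctr + round(runif(1, -200, 200))
        rows[[unit_i]] <- data.frame(
          chrom = ch, summit = c(ctr - 1000L, ctr + 1000L),
          category = c("mDHS", "iDHS"), gene_id = gid, tss = tss,
          stringsAsFactors = FALSE)
      } else {
        tss <- ctr + sample(c(-1L, 1L), 1) * round(runif(1, 200, 1000))
        rows[[unit_i]] <- data.frame(
          chrom = ch, summit = ctr, category = cat_k, gene_id = gid,
          tss = tss, stringsAsFactors = FALSE)
      }
    }
  }
  pk <- do.call(rbind, rows)
  rownames(pk) <- NULL
  pk$start <- as.integer(pk$summit - w %/% 2)
  pk$end <- as.integer(pk$start + w)
  pk <- pk[order(pk$chrom, pk$start), ]
  pk$name <- sprintf("peak_%05d", seq_len(nrow(pk)))
  rownames(pk) <- NULL

  mult <- t(vapply(pk$category, category_multipliers, config = config,
                   numeric(length(config$conditions))))
  colnames(mult) <- paste0("mult_", config$conditions)

  peaks <- data.frame(chrom = pk$chrom, start = pk$start, end = pk$end,
                      name = pk$name, score = 0, strand = ".",
                      summit = as.integer(pk$summit),
                      category = pk$category, gene_id = pk$gene_id,
                      stringsAsFactors = FALSE)
  peaks <- cbind(peaks, mult)
  validate_peaks(peaks)

  genes <- unique(data.frame(gene_id = pk$gene_id, chrom = pk$chrom,
                             tss = as.integer(pk$tss), strand = "+",
                             stringsAsFactors = FALSE))
  genes <- genes[order(genes$gene_id), ]
  rownames(genes) <- NULL

  # planted motif instances: protected in mDHS, unprotected (null) in dDHS
  mi <- 0L
  for (i in seq_len(nrow(peaks))) {
    if (peaks$category[i] == "mDHS") {
      off_e <- -sample(30:80, 1); off_r <- sample(20:70, 1)
      motif_rows[[mi <- mi + 1L]] <- data.frame(
        peak = peaks$name[i], motif = c("ETS", "RUNX"),
        consensus = c(ets, runx), chrom = peaks$chrom[i],
        start = peaks$summit[i] + c(off_e, off_r),
        protected = TRUE, stringsAsFactors = FALSE)
    } else if (peaks$category[i] == "dDHS") {
      off_e <- sample(c(-1, 1), 1) * sample(20:80, 1)
      motif_rows[[mi <- mi + 1L]] <- data.frame(
        peak = peaks$name[i], motif = "ETS", consensus = ets,
        chrom = peaks$chrom[i], start = peaks$summit[i] + off_e,
        protected = FALSE, stringsAsFactors = FALSE)
    }
  }
  motifs <- if (mi) do.call(rbind, motif_rows) else
    data.frame(peak = character(0), motif = character(0),
               consensus = character(0), chrom = character(0),
               start = integer(0), protected = logical(0))
  if (nrow(motifs)) {
    motifs$start <- as.integer(motifs$start)
    motifs$end <- motifs$start + nchar(motifs$consensus)
    motifs$strand <- "+"
    rownames(motifs) <- NULL
  }
  structure(list(peaks = peaks, genes = genes, motifs = motifs,
                 config = config), class = "SimTruth")
}

#' @export
print.SimTruth <- function(x, ...) {
  cat("SimTruth:", nrow(x$peaks), "peaks,", nrow(x$genes), "genes,",
      nrow(x$motifs), "planted motif instances\n")
  print(table(x$peaks$category))
  invisible(x)
}

# NB draw with Poisson limit at zero dispersion.
rnb <- function(n, mu, alpha) {
  if (alpha < 1e-12) rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / alpha)
}

#' Simulate the peak x sample fragment count matrix
#'
#' Count for peak i in sample j is drawn
#' `NB(mean = depth * multiplier(i, condition(j)) * size_factor(j),
#' variance = mean + dispersion * mean^2)`.
#'
#' @param truth [simulate_truth()] output.
#' @param config [sim_config()] object (defaults to the truth's own).
#' @return [count_matrix()] of peaks x samples.
#' @export
simulate_counts <- function(truth, config = truth$config) {
  samples <- sim_samples(config)
  sim_seed(config, 2L)
  mult <- as.matrix(truth$peaks[, paste0("mult_", config$conditions),
                                drop = FALSE])
  mu <- config$depth * mult[, match(samples$condition, config$conditions),
                            drop = FALSE]
  mu <- sweep(mu, 2, samples$size_factor, `*`)
  cnt <- matrix(rnb(length(mu), as.vector(mu), config$dispersion),
                nrow = nrow(mu),
                dimnames = list(truth$peaks$name, samples$sample))
  count_matrix(cnt, samples[, c("sample", "condition", "replicate")])
}

# per-bp cut-placement weights for one peak window [start, end)
peak_cut_weights <- function(peak_start, peak_end, summit, motifs, config) {
  pos <- peak_start:(peak_end - 1L)
  wgt <- exp(-((pos - summit)^2) / (2 * config$summit_sd^2))
  if (!is.null(motifs) && nrow(motifs)) {
    for (m in seq_len(nrow(motifs))) {
      if (isTRUE(motifs$protected[m])) {
        core <- pos >= motifs$start[m] & pos < motifs$end[m]
        fl <- (pos >= motifs$start[m] - config$flank_bp & pos < motifs$start[m]) |
              (pos >= motifs$end[m] & pos < motifs$end[m] + config$flank_bp)
        wgt[core] <- wgt[core] * config$protection
        wgt[fl] <- wgt[fl] * config$flank_boost
      }
    }
  }
  wgt
}

#' Simulate one sample's strand-separated Tn5 cut tracks
#'
#' Each peak receives an NB-distributed cut total (matching the count model),
#' placed with a Gaussian spread around the summit; within protected planted
#' motifs the per-bp rate is multiplied by `protection` and the 10 bp flanks
#' by `flank_boost`. Background cuts arrive uniformly at `bg_rate` per bp per
#' strand, scaled by the sample's size factor. Every drawn cut is placed
#' (track totals are exact bookkeeping). Deterministic given seed and sample.
#'
#' @param truth [simulate_truth()] output.
#' @param sample sample id from [sim_samples()].
#' @param config [sim_config()] object.
#' @return track set: named list of [cut_track()], one per chromosome.
#' @export
simulate_cut_track <- function(truth, sample, config = truth$config) {
  samples <- sim_samples(config)
  j <- match(sample, samples$sample)
  if (is.na(j)) stop("unknown sample: ", sample)
  sim_seed(config, 100L + j)
  sf <- samples$size_factor[j]
  cond <- samples$condition[j]
  mult <- truth$peaks[[paste0("mult_", cond)]]
  out <- list()
  for (ch in names(config$genome)) {
    L <- as.integer(config$genome[[ch]])
    fwd_pos <- integer(0); rev_pos <- integer(0)
    idx <- which(truth$peaks$chrom == ch)
    for (i in idx) {
      mu <- config$depth * mult[i] * sf
      n_cuts <- rnb(1, mu, config$dispersion)
      if (n_cuts == 0) next
      pmot <- truth$motifs[truth$motifs$peak == truth$peaks$name[i], ,
                           drop = FALSE]
      wgt <- peak_cut_weights(truth$peaks$start[i], truth$peaks$end[i],
                              truth$peaks$summit[i], pmot, config)
      pos <- truth$peaks$start[i] +
        sample.int(length(wgt), n_cuts, replace = TRUE, prob = wgt) - 1L
      is_fwd <- runif(n_cuts) < 0.5
      fwd_pos <- c(fwd_pos, pos[is_fwd])
      rev_pos <- c(rev_pos, pos[!is_fwd])
    }
    n_bg_f <- rpois(1, config$bg_rate * L * sf)
    n_bg_r <- rpois(1, config$bg_rate * L * sf)
    fwd_pos <- c(fwd_pos, sample.int(L, n_bg_f, replace = TRUE) - 1L)
    rev_pos <- c(rev_pos, sample.int(L, n_bg_r, replace = TRUE) - 1L)
    out[[ch]] <- cut_track(ch, tabulate(fwd_pos + 1L, L),
                           tabulate(rev_pos + 1L, L))
  }
  out
}

#' Simulate a genome sequence with planted motif instances
#'
#' Uniform random bases, with each planted motif instance overwritten by a
#' concrete instantiation of its IUPAC consensus (degenerate positions
#' resolved at random under the seed).
#'
#' @param truth [simulate_truth()] output.
#' @param config [sim_config()] object.
#' @return named [Biostrings::DNAStringSet] of chromosomes.
#' @export
simulate_genome <- function(truth, config = truth$config) {
  sim_seed(config, 4L)
  seqs <- lapply(names(config$genome), function(ch) {
    L <- as.integer(config$genome[[ch]])
    s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
               collapse = "")
    mm <- truth$motifs[truth$motifs$chrom == ch, , drop = FALSE]
    if (nrow(mm)) {
      for (m in seq_len(nrow(mm))) {
        concrete <- concretize_iupac(mm$consensus[m])
        substr(s, mm$start[m] + 1L, mm$end[m]) <- concrete
      }
    }
    s
  })
  Biostrings::DNAStringSet(setNames(unlist(seqs), names(config$genome)))
}

# One concrete realization of an IUPAC consensus string.
concretize_iupac <- function(consensus) {
  map <- Biostrings::IUPAC_CODE_MAP
  paste(vapply(strsplit(toupper(consensus), "")[[1]], function(b) {
    opts <- strsplit(map[[b]], "")[[1]]
    if (length(opts) == 1) opts else sample(opts, 1)
  }, ""), collapse = "")
}

#' Simulate the gene x sample expression count matrix
#'
#' Gene means follow the categories of the gene's linked peaks: mDHS-linked
#' genes are up in memory conditions by `coupling_log2fc`, nDHS-linked down;
#' iDHS-linked genes up under stimulation, dDHS-linked down; genes linked to
#' both an mDHS and an iDHS receive a further `synergy_log2fc` boost under
#' stimulation. A `decoupled_fraction` of genes ignores its peaks. Counts are
#' NB with the config dispersion and fresh log-uniform size factors.
#'
#' @param truth [simulate_truth()] output.
#' @param config [sim_config()] object.
#' @return [count_matrix()] of genes x samples, with an extra `gene_truth`
#'   element recording each gene's linked categories, condition multipliers
#'   and decoupled flag.
#' @export
simulate_expression <- function(truth, config = truth$config) {
  sim_seed(config, 5L)
  genes <- truth$genes
  cond <- config$conditions
  mem <- cond %in% config$memory_conditions
  stim <- cond %in% config$stimulated_conditions
  cats <- lapply(genes$gene_id, function(g)
    unique(truth$peaks$category[truth$peaks$gene_id == g]))
  decoupled <- runif(nrow(genes)) < config$decoupled_fraction
  c2 <- 2^config$coupling_log2fc
  mult <- matrix(1, nrow(genes), length(cond),
                 dimnames = list(genes$gene_id, cond))
  for (i in seq_len(nrow(genes))) {
    if (decoupled[i]) next
    cs <- cats[[i]]
    m <- rep(1, length(cond))
    if ("mDHS" %in% cs) m[mem] <- m[mem] * c2
    if ("nDHS" %in% cs) m[mem] <- m[mem] / c2
    if ("iDHS" %in% cs) m[stim] <- m[stim] * c2
    if ("dDHS" %in% cs) m[stim] <- m[stim] / c2
    if (all(c("mDHS", "iDHS") %in% cs))
      m[stim] <- m[stim] * 2^config$synergy_log2fc
    mult[i, ] <- m
  }
  samples <- sim_samples(config)
  expr_sf <- exp(runif(nrow(samples), log(0.7), log(1.4)))
  mu <- config$expr_base_mean *
    mult[, match(samples$condition, cond), drop = FALSE]
  mu <- sweep(mu, 2, expr_sf, `*`)
  cnt <- matrix(rnb(length(mu), as.vector(mu), config$dispersion),
                nrow = nrow(mu),
                dimnames = list(genes$gene_id, samples$sample))
  cm <- count_matrix(cnt, samples[, c("sample", "condition", "replicate")])
  cm$gene_truth <- data.frame(
    gene_id = genes$gene_id,
    categories = vapply(cats, paste, "", collapse = ","),
    decoupled = decoupled, stringsAsFactors = FALSE)
  cm$gene_truth <- cbind(cm$gene_truth,
                         setNames(as.data.frame(mult), paste0("mult_", cond)))
  cm
}

#' Write the truth tables of a simulated experiment as plain text
#'
#' Emits the truth peak BED (+ category/gene columns as a TSV), the gene
#' table, planted motifs, and the sample sheet, so downstream runs can score
#' sensitivity and specificity against the planted truth.
#'
#' @param truth [simulate_truth()] output.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    peaks = file.path(dir, "truth_peaks.tsv"),
    genes = file.path(dir, "truth_genes.tsv"),
    motifs = file.path(dir, "truth_motifs.tsv"),
    samples = file.path(dir, "samples.tsv"))
  write.table(truth$peaks, paths["peaks"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(truth$genes, paths["genes"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(truth$motifs, paths["motifs"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim_samples(truth$config), paths["samples"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(paths)
}
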