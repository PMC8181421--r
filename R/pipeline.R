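# End-to-end orchestration: simulate -> call peaks -> concordance -> master
# set -> summit-window counts -> normalize -> NB tests -> DHS categories ->
# stability -> gene integration -> motif enrichment -> footprints, with a
# machine-readable manifest. Stage outputs are plain TSV/BED/JSON files so
# any stage can be re-run standalone on user-provided data.

#' Default contrast table for the standard simulated design
#'
#' Memory timepoints against naive (mDHS/nDHS calls, stability, transience)
#' and restimulated against resting memory (iDHS/dDHS calls).
#'
#' @param fold per-contrast fold threshold (default 3).
#' @return data.frame: name, condition1, condition2, fold.
#' @export
default_contrasts <- function(fold = 3) {
  data.frame(name = c("M7-vs-N", "M28-vs-N", "M56-vs-N", "M28Ag-vs-M28"),
             condition1 = c("N", "N", "N", "M28"),
             condition2 = c("M7", "M28", "M56", "M28Ag"),
             fold = fold, stringsAsFactors = FALSE)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full synthetic-to-report pipeline
#'
#' Executes every stage in dependency order on a simulated experiment and
#' writes all intermediate and final tables, a JSON report, and a manifest
#' with parameters, seed and file checksums. Fully deterministic given the
#' config seed.
#'
#' @param config [sim_config()] object.
#' @param outdir output directory (created; must not already contain a
#'   manifest unless `overwrite = TRUE`).
#' @param contrasts contrast table (see [default_contrasts()]); every
#'   condition referenced must exist in the config.
#' @param top_n_concordant top-k peaks per replicate before intersection
#'   (default 35000).
#' @param halfwidth summit-window half-width for counting (default 200).
#' @param n_top top-N for size factors (default 30000).
#' @param padj_cut adjusted-p threshold (default 0.05).
#' @param min_reads normalized-count presence threshold (default 20).
#' @param min_pvalue peak-caller p threshold (default 1e-5).
#' @param motif_halfwidth motif-scan window half-width (default 100).
#' @param footprint_threshold combined footprint score threshold
#'   (default 10).
#' @param overwrite allow writing into an existing run directory.
#' @return invisibly, the parsed report list (also at
#'   `<outdir>/report.json`).
#' @export
run_pipeline <- function(config = sim_config(), outdir,
                         contrasts = default_contrasts(),
                         top_n_concordant = 35000L, halfwidth = 200L,
                         n_top = 30000L, padj_cut = 0.05, min_reads = 20,
                         min_pvalue = 1e-5, motif_halfwidth = 100L,
                         footprint_threshold = 10, overwrite = FALSE) {
  if (!all(c(contrasts$condition1, contrasts$condition2) %in%
             config$conditions))
    stop("contrast references an unknown condition")
  if (file.exists(file.path(outdir, "manifest.json")) && !overwrite)
    stop("run directory already holds a manifest; use overwrite = TRUE")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) message("[atacmem] ", ...)

  log_msg("simulating truth (seed ", config$seed, ")")
  truth <- simulate_truth(config)
  write_truth(truth, outdir)
  samples <- sim_samples(config)

  # pass 1: per-sample peak calling (tracks regenerated later for counting,
  # so at most one sample's dense tracks are held in memory at a time)
  log_msg("calling peaks per sample")
  sample_peaks <- list()
  for (s in samples$sample) {
    tr <- simulate_cut_track(truth, s, config)
    pk <- call_peaks_all(tr, min_pvalue = min_pvalue)
    sample_peaks[[s]] <- pk
    write_bed(pk, file.path(outdir, paste0("peaks_", s, ".bed")),
              summit_col = "absolute")
    rm(tr)
  }

  log_msg("building replicate-concordant and master sets")
  cond_sets <- list()
  for (cond in config$conditions) {
    reps <- samples$sample[samples$condition == cond]
    cs <- concordant_peaks(sample_peaks[[reps[1]]], sample_peaks[[reps[2]]],
                           k = top_n_concordant)
    for (r in reps[-(1:2)])
      cs <- intersect_peaks(cs, top_k(sample_peaks[[r]], top_n_concordant))
    cond_sets[[cond]] <- cs
  }
  master <- build_master_set(cond_sets)
  write_bed(master, file.path(outdir, "master_peaks.bed"),
            summit_col = "absolute")

  # pass 2: summit-window counting
  log_msg("counting cuts in summit windows (±", halfwidth, " bp)")
  cnt <- matrix(0L, nrow(master), nrow(samples),
                dimnames = list(master$name, samples$sample))
  for (s in samples$sample) {
    tr <- simulate_cut_track(truth, s, config)
    cnt[, s] <- count_in_windows(setNames(list(tr), s), master,
                                 samples[samples$sample == s, ],
                                 halfwidth)$counts[, 1]
    rm(tr)
  }
  cm <- count_matrix(cnt, samples[, c("sample", "condition", "replicate")])
  write_count_matrix(cm, file.path(outdir, "window"))

  log_msg("normalizing (top-", n_top, "-median factors)")
  factors <- size_factors_topn(cm, n_top)
  normalized <- normalize_counts(cm, factors)
  write_tsv(data.frame(sample = names(factors), size_factor = factors),
            file.path(outdir, "size_factors.tsv"))

  log_msg("differential accessibility and DHS classification")
  tables <- list()
  diffs <- list()
  for (i in seq_len(nrow(contrasts))) {
    con <- contrasts[i, ]
    g <- list(condition_samples(cm, con$condition1),
              condition_samples(cm, con$condition2))
    alpha <- estimate_dispersion(cm, factors, g)
    d <- nb_wald_test(cm, factors, g, alpha)
    tab <- classify_dhs(d, normalized, samples, con$condition1,
                        con$condition2, fold = con$fold, padj = padj_cut,
                        min_reads = min_reads)
    diffs[[con$name]] <- d
    tables[[con$name]] <- tab
    write_tsv(merge(d, tab[, c("feature", "category")], by = "feature"),
              file.path(outdir, paste0("diff_", con$name, ".tsv")))
  }

  gained <- tables[["M28-vs-N"]]
  induced <- tables[["M28Ag-vs-M28"]]
  category_sets <- list(
    mDHS = gained$feature[gained$category == "up"],
    nDHS = gained$feature[gained$category == "down"],
    iDHS = induced$feature[induced$category == "up"],
    dDHS = induced$feature[induced$category == "down"])

  # stability of M28 mDHSs at M56; transience of M7 nDHSs by M28
  later <- diffs[["M56-vs-N"]]
  ref <- category_sets$mDHS
  stab <- stability_summary(length(ref),
                            2^later$log2fc[match(ref, later$feature)],
                            thresholds = c(3, 2))
  early_down <- tables[["M7-vs-N"]]
  early_set <- early_down$feature[early_down$category == "down"]
  m28fc <- 2^diffs[["M28-vs-N"]]$log2fc[
    match(early_set, diffs[["M28-vs-N"]]$feature)]
  trans <- transient_fraction(length(early_set), m28fc, recovery_fold = 3)
  write_tsv(stab, file.path(outdir, "stability_mDHS.tsv"))

  log_msg("peak-to-gene integration")
  pg <- closest_gene(master, truth$genes)
  gene_assign <- assign_genes(category_sets, pg)
  write_tsv(gene_assign, file.path(outdir, "gene_classes.tsv"))
  expr <- simulate_expression(truth, config)
  write_count_matrix(expr, file.path(outdir, "expression"))
  expr_mem <- diff_test(expr, "N", "M28", normalization = "mor")
  expr_stim <- diff_test(expr, "M28", "M28Ag", normalization = "mor")
  gene_sets <- split(gene_assign$gene_id, gene_assign$class)
  gene_sets <- gene_sets[setdiff(names(gene_sets), "none")]
  set_means <- mean_expression_fc(gene_sets, expr_stim$result,
                                  seed = config$seed)
  primed <- primed_inducible_genes(expr_mem$result, expr_stim$result,
                                   fold = 3)
  write_tsv(set_means, file.path(outdir, "gene_set_expression.tsv"))

  log_msg("motif enrichment and footprinting")
  genome <- simulate_genome(truth, config)
  panel <- default_motif_panel()
  master_cat <- rep("none", nrow(master))
  for (nm in names(category_sets))
    master_cat[master$name %in% category_sets[[nm]]] <- nm
  target <- master[master$name %in% category_sets$mDHS, , drop = FALSE]
  background <- master[master_cat == "none", , drop = FALSE]
  enrich <- motif_enrichment_panel(genome, target, background, panel,
                                   motif_halfwidth)
  write_tsv(enrich, file.path(outdir, "motif_enrichment.tsv"))

  mem_reps <- samples$sample[samples$condition == "M28"]
  pooled <- pool_tracks(lapply(mem_reps, simulate_cut_track, truth = truth,
                               config = config))
  ets <- panel$consensus[panel$name == "ETS"]
  instances <- scan_motifs(genome, target, ets, motif_halfwidth)
  fp <- if (nrow(instances))
    footprint_scores(pooled, instances, threshold = footprint_threshold)
  else cbind(instances, score = numeric(0), pass = logical(0))
  write_tsv(fp, file.path(outdir, "footprints_ETS.tsv"))
  profile <- if (any(fp$pass))
    average_cut_profile(pooled, fp[fp$pass, , drop = FALSE]) else NULL
  if (!is.null(profile))
    write_tsv(data.frame(position = profile$position, fwd = profile$fwd,
                         rev = profile$rev),
              file.path(outdir, "cut_profile_ETS.tsv"))
  rm(pooled)

  truth_metrics <- truth_recovery(master, master_cat, truth)

  report <- list(
    seed = config$seed,
    n_master_peaks = nrow(master),
    category_counts = lapply(category_sets, length),
    contrast_category_counts = lapply(tables, function(t)
      as.list(table(t$category))),
    stability = stab,
    transient = trans,
    gene_set_expression = set_means,
    primed_inducible = primed[c("count", "n", "percentage")],
    motif_enrichment = enrich,
    footprint = list(n_instances = nrow(fp), n_pass = sum(fp$pass),
                     pass_rate = if (nrow(fp)) mean(fp$pass) else NA),
    truth = truth_metrics)
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")

  files <- setdiff(list.files(outdir), "manifest.json")
  manifest <- list(
    package = "atacmem",
    seed = config$seed,
    parameters = list(top_n_concordant = top_n_concordant,
                      halfwidth = halfwidth, n_top = n_top,
                      fold = contrasts$fold, padj = padj_cut,
                      min_reads = min_reads, min_pvalue = min_pvalue,
                      motif_halfwidth = motif_halfwidth,
                      footprint_threshold = footprint_threshold),
    files = as.list(tools::md5sum(file.path(outdir, files))))
  names(manifest$files) <- files
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  log_msg("done: ", outdir)
  invisible(report)
}

# Sensitivity/specificity of DHS classification against the planted truth,
# matching master peaks to truth peaks by >= 1 bp overlap.
truth_recovery <- function(master, master_cat, truth) {
  out <- list()
  for (cat in c("mDHS", "nDHS", "iDHS", "dDHS")) {
    tp <- truth$peaks[truth$peaks$category == cat, , drop = FALSE]
    if (nrow(tp) == 0) next
    called <- master[master_cat == cat, , drop = FALSE]
    hit <- nrow(intersect_peaks(tp, called))
    out[[cat]] <- list(n_truth = nrow(tp), recovered = hit,
                       sensitivity = hit / nrow(tp))
  }
  const <- truth$peaks[truth$peaks$category == "constitutive", , drop = FALSE]
  if (nrow(const)) {
    any_called <- master[master_cat != "none", , drop = FALSE]
    fp <- nrow(intersect_peaks(const, any_called))
    out$constitutive <- list(n_truth = nrow(const), mislabelled = fp,
                             false_rate = fp / nrow(const))
  }
  out$master_recovery <- list(
    n_truth = nrow(truth$peaks),
    recovered = nrow(intersect_peaks(truth$peaks, master)),
    sensitivity = nrow(intersect_peaks(truth$peaks, master)) /
      max(nrow(truth$peaks), 1))
  out
}

#' Summarize a finished pipeline run
#'
#' Reads `report.json` (and the manifest) from a run directory and prints a
#' human-readable summary: category counts per contrast, stability and
#' transience, gene-set expression means, top motif enrichments, footprint
#' pass rates, and — when truth tables are present — sensitivity/specificity
#' against the planted truth.
#'
#' @param outdir run directory produced by [run_pipeline()].
#' @return invisibly, the parsed report list.
#' @export
pipeline_report <- function(outdir) {
  path <- file.path(outdir, "report.json")
  if (!file.exists(path)) stop("no report.json in ", outdir)
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  cat("atacmem run (seed ", rep$seed, "): ", rep$n_master_peaks,
      " master peaks\n", sep = "")
  cat("DHS categories:",
      paste(names(rep$category_counts), unlist(rep$category_counts),
            sep = "=", collapse = ", "), "\n")
  st <- rep$stability
  for (i in seq_along(st$threshold))
    cat(sprintf("mDHS stability at %g-fold: %d (%s%%)\n", st$threshold[i],
                st$count[i], format(st$percentage[i])))
  cat(sprintf("transient early-suppressed fraction: %d/%d (%d%%)\n",
              rep$transient$count, rep$transient$n,
              rep$transient$percentage))
  cat(sprintf("primed-inducible genes: %d/%d (%d%%)\n",
              rep$primed_inducible$count, rep$primed_inducible$n,
              rep$primed_inducible$percentage))
  ge <- rep$gene_set_expression
  for (i in seq_along(ge$set))
    cat(sprintf("mean log2FC [%s]: %.2f (95%% CI %.2f..%.2f, n=%d)\n",
                ge$set[i], ge$mean_log2fc[i], ge$ci_lo[i], ge$ci_hi[i],
                ge$n[i]))
  me <- rep$motif_enrichment
  cat("top motif enrichments:",
      paste(head(me$name, 3), collapse = ", "), "\n")
  cat(sprintf("ETS footprints passing: %d/%d\n", rep$footprint$n_pass,
              rep$footprint$n_instances))
  if (!is.null(rep$truth)) {
    cat("truth recovery:\n")
    for (nm in setdiff(names(rep$truth), c("constitutive",
                                           "master_recovery")))
      cat(sprintf("  %s sensitivity: %.3f (%d/%d)\n", nm,
                  rep$truth[[nm]]$sensitivity, rep$truth[[nm]]$recovered,
                  rep$truth[[nm]]$n_truth))
    if (!is.null(rep$truth$constitutive))
      cat(sprintf("  constitutive false-labelling: %.3f\n",
                  rep$truth$constitutive$false_rate))
  } else cat("truth tables absent; recovery section omitted\n")
  invisible(rep)
}
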