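# Peak-to-gene integration: category-defined gene sets and their expression
# fold changes, and primed-inducible gene identification.

#' Assign DHS categories to genes via their peaks
#'
#' Each gene's category set is the union of the DHS categories of its
#' assigned peaks (nearest-gene assignment: one gene per peak, possibly many
#' peaks per gene). The exclusive class follows the set: a gene with both an
#' mDHS and an iDHS is `mDHS+iDHS` and never counted in the "only" classes;
#' `dDHS-only` requires no mDHS or iDHS peak.
#'
#' @param categories named list of character vectors of peak ids per DHS
#'   label, e.g. `list(mDHS = ..., nDHS = ..., iDHS = ..., dDHS = ...)` —
#'   typically the up/down sets of [classify_dhs()] tables.
#' @param peak_gene data.frame mapping `name` (peak id) to `gene_id`
#'   (e.g. from [closest_gene()]).
#' @return data.frame: gene_id, categories (comma-joined), class
#'   (`mDHS-only`, `iDHS-only`, `mDHS+iDHS`, `dDHS-only`, `none`).
#' @export
assign_genes <- function(categories, peak_gene) {
  genes <- unique(peak_gene$gene_id)
  gene_cats <- lapply(setNames(genes, genes), function(g) {
    pk <- peak_gene$name[peak_gene$gene_id == g]
    names(categories)[vapply(categories, function(s) any(pk %in% s), TRUE)]
  })
  cls <- vapply(gene_cats, function(cs) {
    if (all(c("mDHS", "iDHS") %in% cs)) "mDHS+iDHS"
    else if ("mDHS" %in% cs) "mDHS-only"
    else if ("iDHS" %in% cs) "iDHS-only"
    else if ("dDHS" %in% cs) "dDHS-only"
    else "none"
  }, "")
  data.frame(gene_id = genes,
             categories = vapply(gene_cats, paste, "", collapse = ","),
             class = cls, stringsAsFactors = FALSE)
}

#' Mean expression fold change per gene set with bootstrap CI
#'
#' Arithmetic mean of log2 expression fold changes over each gene set, with a
#' 95% percentile bootstrap confidence interval (seeded). Genes missing from
#' the expression table are dropped and counted.
#'
#' @param gene_sets named list of gene-id vectors.
#' @param expr_diff expression [nb_wald_test()] table (feature = gene_id).
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return data.frame: set, n, n_missing, mean_log2fc, ci_lo, ci_hi.
#' @export
mean_expression_fc <- function(gene_sets, expr_diff, n_boot = 1000L,
                               seed = 1L) {
  set.seed(seed)
  rows <- lapply(names(gene_sets), function(nm) {
    g <- gene_sets[[nm]]
    lfc <- expr_diff$log2fc[match(g, expr_diff$feature)]
    miss <- sum(is.na(lfc))
    lfc <- lfc[!is.na(lfc)]
    if (length(lfc) == 0) stop("gene set '", nm, "' is empty after dropping")
    boots <- vapply(seq_len(n_boot), function(i)
      mean(lfc[sample.int(length(lfc), replace = TRUE)]), 0)
    data.frame(set = nm, n = length(lfc), n_missing = miss,
               mean_log2fc = mean(lfc),
               ci_lo = unname(quantile(boots, 0.025)),
               ci_hi = unname(quantile(boots, 0.975)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Primed-inducible genes
#'
#' Among the genes at least `fold`-fold upregulated by antigen restimulation
#' (the inducible set, stimulated-vs-memory contrast), returns the subset
#' already at least `fold`-fold upregulated in resting memory relative to
#' naive — the genes whose induction is epigenetically primed.
#'
#' Either supply the two expression result tables, or pre-tabulated
#' `n_inducible`/`n_primed` counts when working from published tables.
#'
#' @param memory_vs_naive,stim_vs_memory expression [nb_wald_test()] tables
#'   over the same genes (fold change group2/group1).
#' @param fold threshold (default 3); "at least" semantics (`>=`).
#' @param n_inducible,n_primed optional pre-tabulated counts.
#' @return list: genes (ids, when tables supplied), count, n (inducible set
#'   size), percentage (integer-rounded).
#' @export
primed_inducible_genes <- function(memory_vs_naive = NULL,
                                   stim_vs_memory = NULL, fold = 3,
                                   n_inducible = NULL, n_primed = NULL) {
  if (is.null(n_inducible)) {
    stopifnot(!is.null(memory_vs_naive), !is.null(stim_vs_memory))
    if (!setequal(memory_vs_naive$feature, stim_vs_memory$feature))
      stop("the two contrasts must cover the same genes")
    thr <- log2(fold)
    inducible <- stim_vs_memory$feature[stim_vs_memory$log2fc >= thr]
    if (length(inducible) == 0) stop("inducible gene set is empty")
    mem_up <- memory_vs_naive$feature[memory_vs_naive$log2fc >= thr]
    primed <- intersect(inducible, mem_up)
    n_inducible <- length(inducible); n_primed <- length(primed)
  } else {
    primed <- NULL
    if (n_inducible <= 0) stop("inducible gene set is empty")
  }
  list(genes = primed, count = as.integer(n_primed),
       n = as.integer(n_inducible),
       percentage = round(100 * n_primed / n_inducible))
}
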