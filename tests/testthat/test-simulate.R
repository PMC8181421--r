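test_that("truth generation is deterministic, placed and labelled correctly", {
  cfg <- small_config(seed = 5)
  tr1 <- simulate_truth(cfg)
  tr2 <- simulate_truth(cfg)
  expect_identical(tr1$peaks, tr2$peaks)
  expect_identical(tr1$genes, tr2$genes)

  # empty config is allowed
  empty <- simulate_truth(sim_config(n_peaks = c(constitutive = 0)))
  expect_equal(nrow(empty$peaks), 0)

  # planted effect sizes hold by construction
  pk <- tr1$peaks
  mem_ratio <- pk$mult_M28 / pk$mult_N
  expect_true(all(mem_ratio[pk$category == "mDHS"] >= cfg$effect_size))
  expect_true(all(1 / mem_ratio[pk$category == "nDHS"] >= cfg$effect_size))
  stim_ratio <- pk$mult_M28Ag / pk$mult_M28
  expect_true(all(stim_ratio[pk$category == "iDHS"] >= cfg$effect_size))
  expect_true(all(1 / stim_ratio[pk$category == "dDHS"] >= cfg$effect_size))
  const <- pk[pk$category == "constitutive", grep("^mult_", names(pk))]
  expect_true(all(apply(const, 1, max) / apply(const, 1, min) <= 1.25))

  # spacing >= 2 kb and each gene within 10 kb of its peak
  for (ch in unique(pk$chrom)) {
    s <- sort(pk$start[pk$chrom == ch])
    expect_true(all(diff(s) >= 2000))
  }
  tss <- tr1$genes$tss[match(pk$gene_id, tr1$genes$gene_id)]
  expect_true(all(abs(tss - pk$summit) <= 10000))

  # the planted gene is the nearest gene to its peak
  cg <- closest_gene(pk, tr1$genes)
  expect_equal(cg$gene_id, pk$gene_id)

  expect_error(simulate_truth(sim_config(genome = c(chr1 = 1e4))),
               "too small")
})

test_that("simulated counts follow the NB model and its Poisson limit", {
  cfg <- small_config(seed = 6)
  cm1 <- simulate_counts(simulate_truth(cfg))
  cm2 <- simulate_counts(simulate_truth(cfg))
  expect_identical(cm1$counts, cm2$counts)
  expect_true(all(cm1$counts >= 0))
  expect_true(all(cm1$counts == round(cm1$counts)))

  # multiplier 1 everywhere: empirical mean within 3 SE of depth * sizefactor
  cfg0 <- small_config(seed = 8, n_peaks = c(constitutive = 200),
                       constitutive_jitter = 1)
  tr0 <- simulate_truth(cfg0)
  cm0 <- simulate_counts(tr0)
  sf <- sim_samples(cfg0)$size_factor
  for (j in c(1, 5, 12)) {
    mu <- cfg0$depth * sf[j]
    se <- sqrt((mu + cfg0$dispersion * mu^2) / 200)
    expect_lt(abs(mean(cm0$counts[, j]) - mu), 3 * se)
  }

  # dispersion -> 0: variance ~ mean across many draws (Poisson limit)
  cfgp <- small_config(seed = 9, n_peaks = c(constitutive = 500),
                       dispersion = 0, constitutive_jitter = 1)
  cmp <- simulate_counts(simulate_truth(cfgp))
  y <- cmp$counts[, 1]
  expect_lt(abs(var(y) / mean(y) - 1), 0.25)

  # planted 8-fold mDHS at depth 100: empirical memory/naive ratio in [5, 13]
  cfg8 <- small_config(seed = 10, n_peaks = c(mDHS = 50, constitutive = 50))
  tr8 <- simulate_truth(cfg8)
  cm8 <- simulate_counts(tr8)
  sf8 <- sim_samples(cfg8)$size_factor
  norm <- sweep(cm8$counts, 2, sf8, `/`)
  m <- tr8$peaks$category == "mDHS"
  ratio <- rowMeans(norm[m, condition_samples(cm8, "M28"), drop = FALSE]) /
    rowMeans(norm[m, condition_samples(cm8, "N"), drop = FALSE])
  expect_gt(mean(ratio), 5)
  expect_lt(mean(ratio), 13)
})

test_that("cut tracks keep exact totals and carve planted footprints", {
  cfg <- small_config(seed = 12)
  tr <- simulate_truth(cfg)
  tk1 <- simulate_cut_track(tr, "M28_r1")
  tk2 <- simulate_cut_track(tr, "M28_r1")
  expect_identical(tk1, tk2)
  expect_true(all(vapply(tk1, function(t) all(t$fwd >= 0 & t$rev >= 0), TRUE)))

  # protection factor 1 leaves the motif flat; 0 empties it
  flat_cfg <- small_config(seed = 12, protection = 1, flank_boost = 1)
  trf <- simulate_truth(flat_cfg)
  tkf <- simulate_cut_track(trf, "M28_r1", flat_cfg)
  zero_cfg <- small_config(seed = 12, protection = 0, bg_rate = 0)
  trz <- simulate_truth(zero_cfg)
  tkz <- simulate_cut_track(trz, "M28_r1", zero_cfg)
  motif_cuts <- function(tracks, motifs) {
    vapply(seq_len(nrow(motifs)), function(i) {
      t <- tracks[[motifs$chrom[i]]]
      idx <- (motifs$start[i] + 1):motifs$end[i]
      sum(t$fwd[idx]) + sum(t$rev[idx])
    }, 0)
  }
  prot_z <- trz$motifs[trz$motifs$protected, ]
  expect_equal(sum(motif_cuts(tkz, prot_z)), 0)

  # default protection: per-bp rate inside protected motifs well below flanks
  prot <- tr$motifs[tr$motifs$protected, ]
  inside <- motif_cuts(tk1, prot) / (prot$end - prot$start)
  flank <- vapply(seq_len(nrow(prot)), function(i) {
    t <- tk1[[prot$chrom[i]]]
    idx <- c((prot$start[i] - 10):(prot$start[i] - 1),
             (prot$end[i] + 1):(prot$end[i] + 10)) + 1L
    (sum(t$fwd[idx]) + sum(t$rev[idx])) / 20
  }, 0)
  expect_lt(mean(inside), 0.5 * mean(flank))

  # and with protection 1 there is no depletion signal
  prot_f <- trf$motifs[trf$motifs$protected, ]
  inside_f <- motif_cuts(tkf, prot_f) / (prot_f$end - prot_f$start)
  expect_gt(mean(inside_f), 0.5 * mean(flank))
})

test_that("expression coupling plants recoverable fold changes", {
  # keep the coupled fraction minor so median-of-ratios normalization of the
  # expression matrix is identifiable (mostly-unchanged genes)
  cfg <- small_config(seed = 14, n_peaks = c(mDHS = 60, constitutive = 300),
                      decoupled_fraction = 0)
  tr <- simulate_truth(cfg)
  ex <- simulate_expression(tr)
  ex2 <- simulate_expression(tr)
  expect_identical(ex$counts, ex2$counts)

  d <- diff_test(ex, "N", "M28", normalization = "mor")$result
  m_genes <- tr$peaks$gene_id[tr$peaks$category == "mDHS"]
  rec <- mean(d$log2fc[match(m_genes, d$feature)])
  expect_gt(rec, 1.6); expect_lt(rec, 2.4)   # planted coupling log2FC = 2

  # zero coupling: no systematic difference between category gene sets
  cfg0 <- small_config(seed = 15, coupling_log2fc = 0, synergy_log2fc = 0,
                       n_peaks = c(mDHS = 250, nDHS = 250))
  tr0 <- simulate_truth(cfg0)
  ex0 <- simulate_expression(tr0)
  d0 <- diff_test(ex0, "N", "M28", normalization = "mor")$result
  for (cat in c("mDHS", "nDHS")) {
    g <- tr0$peaks$gene_id[tr0$peaks$category == cat]
    expect_lt(abs(mean(d0$log2fc[match(g, d0$feature)])), 0.2)
  }
})
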