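test_that("scan_motifs finds IUPAC matches on both strands", {
  # ETS core within a tiny window
  genome <- Biostrings::DNAStringSet(c(chrT = "TTTTTTGGAATTTTTTTTTT"))
  pk <- peak_table("chrT", 0, 20, summit = 10)
  hits <- scan_motifs(genome, pk, "TGGAA", halfwidth = 10)
  expect_equal(hits$start, 5)
  expect_equal(hits$strand, "+")
  # reverse-strand hit reported in forward coordinates
  rc <- scan_motifs(Biostrings::DNAStringSet(c(chrT = "TTTTTTTCCATTTTTTTTTT")),
                    pk, "TGGAA", halfwidth = 10)
  expect_equal(rc$strand, "-")
  expect_equal(rc$start, 5)  # TTCCA occupies 0-based 5..9
  # palindromic consensus: one hit per strand at the same position
  pal <- scan_motifs(Biostrings::DNAStringSet(c(chrT = "TTTTTTGAATTCTTTTTTTT")),
                     pk, "GAATTC", halfwidth = 10)
  expect_equal(nrow(pal), 2)
  expect_equal(unique(pal$start), 6)
  expect_setequal(pal$strand, c("+", "-"))
})

test_that("scan_motifs equals the naive per-position oracle", {
  set.seed(61)
  for (consensus in c("TGASTCA", "TGYGGT", "GGAAR")) {
    seq <- paste(sample(c("A", "C", "G", "T"), 4000, replace = TRUE,
                        prob = c(0.2, 0.3, 0.3, 0.2)), collapse = "")
    genome <- Biostrings::DNAStringSet(setNames(seq, "chrO"))
    pk <- peak_table("chrO", 500, 3500, summit = 2000)
    hits <- scan_motifs(genome, pk, consensus, halfwidth = 1500)
    w0 <- 500; w1 <- 3500
    window <- substr(seq, w0 + 1, w1)
    fwd <- oracle_scan_window(window, consensus) + w0 - 1
    rev <- oracle_scan_window(window, revcomp_str(consensus)) + w0 - 1
    expect_setequal(hits$start[hits$strand == "+"], fwd)
    expect_setequal(hits$start[hits$strand == "-"], rev)
  }
  # windows are clipped at chromosome ends without error
  tiny <- Biostrings::DNAStringSet(c(chrO = "ACGTGGAAACGT"))
  pk_edge <- peak_table("chrO", 0, 12, summit = 1)
  expect_silent(scan_motifs(tiny, pk_edge, "TGGAA", halfwidth = 100))
})

test_that("motif enrichment matches the exact hypergeometric sum", {
  cfg <- small_config(seed = 62)
  tr <- simulate_truth(cfg)
  genome <- simulate_genome(tr)
  target <- tr$peaks[tr$peaks$category == "mDHS", ]
  background <- tr$peaks[tr$peaks$category == "constitutive", ]
  e <- motif_enrichment(genome, target, background, "CAGGAAGT")
  expect_equal(e$hits_target, nrow(target))  # every mDHS has a planted ETS
  # brute-force hypergeometric tail sum
  N <- e$n_target + e$n_background; K <- e$hits_target + e$hits_background
  p_oracle <- sum(vapply(e$hits_target:min(K, e$n_target), function(k)
    choose(K, k) * choose(N - K, e$n_target - k) / choose(N, e$n_target), 0))
  expect_equal(e$pvalue, p_oracle, tolerance = 1e-10)

  # identical hit fractions: fold 1, p >= 0.5
  same <- motif_enrichment(genome, target, target, "CAGGAAGT")
  expect_equal(same$fold, 1)
  expect_gte(same$pvalue, 0.5)

  # p is monotone decreasing in the target hit count at fixed totals
  ph <- function(k) phyper(k - 1, K, N - K, e$n_target, lower.tail = FALSE)
  expect_true(all(diff(ph(1:min(K, e$n_target))) < 0))

  # planted consensi rank top-2 in the panel
  enr <- motif_enrichment_panel(genome, tr$peaks[tr$peaks$category == "mDHS", ],
                                background, default_motif_panel())
  expect_setequal(enr$name[1:2], c("ETS", "RUNX"))
})

test_that("footprint scores follow the closed-form binomial", {
  # 0 footprint cuts with 40 shoulder cuts per strand
  len_fp <- 10; len_sh <- 35
  fp0 <- 500; fp1 <- fp0 + len_fp
  fwd_pos <- rep(seq(fp0 - len_sh, fp0 - 1), length.out = 40)
  rev_pos <- rep(seq(fp1, fp1 + len_sh - 1), length.out = 40)
  tracks <- tiny_tracks(2000, fwd_pos = fwd_pos, rev_pos = rev_pos)
  inst <- data.frame(chrom = "chrT", start = fp0, end = fp1)
  fc <- footprint_score(tracks, inst, shoulder = len_sh)
  q <- len_fp / (len_fp + len_sh)
  expect_equal(fc$score_fwd, -log10((1 - q)^40), tolerance = 1e-10)
  expect_equal(fc$score_rev, -log10((1 - q)^40), tolerance = 1e-10)
  expect_false(fc$pass)  # combined 2 * 4.36 < 10
  # with 60 clean shoulder cuts per strand the instance passes
  tracks60 <- tiny_tracks(2000,
                          fwd_pos = rep(seq(fp0 - len_sh, fp0 - 1),
                                        length.out = 60),
                          rev_pos = rep(seq(fp1, fp1 + len_sh - 1),
                                        length.out = 60))
  fc60 <- footprint_score(tracks60, inst, shoulder = len_sh)
  expect_equal(fc60$score, 2 * -log10((1 - q)^60), tolerance = 1e-10)
  expect_true(fc60$pass)  # combined 2 * 6.55 >= 10

  # zero cuts anywhere: score 0, no pass
  none <- footprint_score(tiny_tracks(2000), inst)
  expect_equal(none$score, 0)
  expect_false(none$pass)

  # uniform cut rate: pass rate at threshold 10 stays below 1%
  set.seed(63)
  L <- 200000
  tracks_u <- setNames(list(cut_track("chrT", rpois(L, 0.5), rpois(L, 0.5))),
                       "chrT")
  starts <- seq(1000, L - 1000, length.out = 1000)
  insts <- data.frame(chrom = "chrT", start = round(starts),
                      end = round(starts) + 10)
  sc <- footprint_scores(tracks_u, insts)
  expect_lte(mean(sc$pass), 0.01)
  expect_error(footprint_score(tracks_u,
                               data.frame(chrom = "chrT", start = 0, end = 50)),
               "shoulder")
})

test_that("planted protected motifs outscore unprotected ones", {
  cfg <- small_config(seed = 64)
  tr <- simulate_truth(cfg)
  pooled <- pool_tracks(lapply(c("M28_r1", "M28_r2"), simulate_cut_track,
                               truth = tr))
  prot <- footprint_scores(pooled, tr$motifs[tr$motifs$protected, ])
  unprot <- footprint_scores(pooled, tr$motifs[!tr$motifs$protected, ])
  expect_gt(median(prot$score), median(unprot$score))
  expect_gte(mean(prot$pass), 0.9)
  expect_lte(mean(unprot$pass), 0.01)
})

test_that("average_cut_profile aligns, flips and detects depletion", {
  # single instance returns its own profile (motif centre = position 0)
  tracks <- tiny_tracks(1000, fwd_pos = c(495, 500, 505), rev_pos = c(508))
  inst <- data.frame(chrom = "chrT", start = 498, end = 502, strand = "+")
  pr <- average_cut_profile(tracks, inst, window = 20)
  expect_equal(pr$n, 1)
  expect_equal(pr$fwd[pr$position == 0], 1)    # the cut at 500
  expect_equal(pr$fwd[pr$position == -5], 1)   # the cut at 495
  expect_equal(pr$rev[pr$position == 8], 1)    # the cut at 508
  # a minus-strand instance flips orientation and swaps strands:
  # offset p reads from old offset -p-1 of the opposite strand
  inst_m <- inst; inst_m$strand <- "-"
  prm <- average_cut_profile(tracks, inst_m, window = 20)
  expect_equal(prm$fwd[prm$position == -9], 1)  # rev cut at 508
  expect_equal(prm$rev[prm$position == -1], 1)  # fwd cut at 500
  expect_error(average_cut_profile(tracks, inst[0, ]), "instances")

  # planted protection: core depleted relative to the near flank; null flat
  cfg <- small_config(seed = 65)
  tr <- simulate_truth(cfg)
  pooled <- pool_tracks(lapply(c("M28_r1", "M28_r2"), simulate_cut_track,
                               truth = tr))
  core_flank_ratio <- function(instances) {
    p <- average_cut_profile(pooled, instances, window = 200)
    tot <- p$fwd + p$rev
    core <- tot[abs(p$position) <= 3]
    flank <- tot[abs(p$position) >= 16 & abs(p$position) <= 30]
    mean(core) / mean(flank)
  }
  prot <- tr$motifs[tr$motifs$protected & tr$motifs$motif == "ETS", ]
  unprot <- tr$motifs[!tr$motifs$protected, ]
  expect_lt(core_flank_ratio(prot), 0.5)
  r_null <- core_flank_ratio(unprot)
  expect_gt(r_null, 0.8); expect_lt(r_null, 1.2)
})

test_that("tag density bins match the block-sum oracle and count windows", {
  set.seed(66)
  L <- 6000
  pos_f <- sample.int(L, 800, replace = TRUE) - 1L
  pos_r <- sample.int(L, 700, replace = TRUE) - 1L
  tracks <- tiny_tracks(L, fwd_pos = pos_f, rev_pos = pos_r)
  pk <- peak_table("chrT", c(2800, 4000), c(3200, 4400),
                   summit = c(3000, 4200))
  mat <- tag_density_profile(tracks, pk, window = 2000, bin = 10)
  expect_equal(dim(mat), c(2, 200))
  # block-sum oracle on the raw per-bp vector
  v <- tracks$chrT$fwd + tracks$chrT$rev
  for (i in 1:2) {
    s <- pk$summit[i]
    blocks <- vapply(seq(0, 199), function(b) {
      idx <- (s - 1000 + b * 10):(s - 1000 + b * 10 + 9) + 1L
      idx <- idx[idx >= 1 & idx <= L]
      sum(v[idx])
    }, 0)
    expect_equal(unname(mat[i, ]), blocks)
  }
  # row sums equal summit-window counts at halfwidth = window/2
  samples <- data.frame(sample = "s1", condition = "c", replicate = 1)
  cw <- count_in_windows(list(s1 = tracks), pk, samples, halfwidth = 1000)
  expect_equal(unname(rowSums(mat)), unname(as.numeric(cw$counts[, 1])))
  # empty track gives a zero matrix; size factor scales values
  zero <- tag_density_profile(tiny_tracks(L), pk)
  expect_true(all(zero == 0))
  half <- tag_density_profile(tracks, pk, size_factor = 2)
  expect_equal(half, mat / 2, ignore_attr = TRUE)
  expect_equal(attr(mat, "colmeans"), colMeans(mat))
})
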