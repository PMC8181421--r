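test_that("top-N-median size factors satisfy their closed forms", {
  set.seed(31)
  k <- matrix(rnbinom(200 * 4, mu = 100, size = 10), 200, 4,
              dimnames = list(paste0("f", 1:200), paste0("s", 1:4)))
  # identical samples: all factors 1
  same <- k[, c(1, 1, 1)]; colnames(same) <- paste0("s", 1:3)
  expect_equal(unname(size_factors_topn(same, 50)), rep(1, 3))

  # scale equivariance: doubling one sample doubles its factor relative to
  # the others and leaves its normalized column equal to the original's
  f0 <- size_factors_topn(k, 50)
  k2 <- k; k2[, 2] <- 2L * k[, 2]
  f2 <- size_factors_topn(k2, 50)
  expect_equal((f2[[2]] / f2[[1]]) / (f0[[2]] / f0[[1]]), 2)
  kd <- cbind(k, s5 = 2L * k[, 1])
  fd <- size_factors_topn(kd, 50)
  expect_equal(fd[["s5"]] / fd[["s1"]], 2)
  nd <- normalize_counts(kd, fd)
  expect_equal(nd[, "s5"], nd[, "s1"], tolerance = 1e-12)

  # after normalization the per-sample top-N medians agree to 1e-9
  topn_median <- function(v, n) median(sort(v, decreasing = TRUE)[1:n])
  norm <- normalize_counts(k, f0)
  meds <- apply(norm, 2, topn_median, n = 50)
  expect_lt(max(meds) - min(meds), 1e-9)

  expect_error(size_factors_topn(cbind(k, z = 0L)), "all-zero")
})

test_that("normalize_counts divides by factors and validates them", {
  k <- matrix(c(40L, 0L, 10L, 20L), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_equal(normalize_counts(k, c(1, 1)), k + 0)
  expect_equal(normalize_counts(k, c(2, 1))["a", "s1"], 20)
  expect_equal(normalize_counts(k, c(2, 1))["b", "s1"], 0)
  expect_error(normalize_counts(k, c(1, -1)), "> 0")
  expect_error(normalize_counts(k, 1), "one factor")
})

test_that("median-of-ratios factors agree with the DESeq2 reference", {
  skip_if_not_installed("DESeq2")
  set.seed(32)
  k <- matrix(rnbinom(500 * 6, mu = 80, size = 5), 500, 6,
              dimnames = list(paste0("f", 1:500), paste0("s", 1:6)))
  k[, 3] <- k[, 3] * 3L
  ours <- size_factors_mor(k)
  ref <- DESeq2::estimateSizeFactorsForMatrix(k)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-8)
})

test_that("dispersion estimation recovers truth and respects clamps", {
  set.seed(33)
  groups <- list(paste0("a", 1:2), paste0("b", 1:2))
  make <- function(alpha, mu = 100, n_feat = 2000) {
    k <- matrix(if (alpha == 0) rpois(n_feat * 4, mu) else
      rnbinom(n_feat * 4, mu = mu, size = 1 / alpha), n_feat, 4,
      dimnames = list(paste0("f", 1:n_feat), c(groups[[1]], groups[[2]])))
    k
  }
  # Poisson data: near-zero estimates
  a0 <- estimate_dispersion(make(0), rep(1, 4), groups)
  expect_lte(mean(a0), 0.05)
  # true alpha 0.2 recovered within the documented band
  a2 <- estimate_dispersion(make(0.2), rep(1, 4), groups)
  expect_gte(mean(a2), 0.12); expect_lte(mean(a2), 0.28)
  # constant counts: lower clamp
  kc <- matrix(50L, 10, 4, dimnames = list(paste0("f", 1:10),
                                           c(groups[[1]], groups[[2]])))
  expect_equal(unname(estimate_dispersion(kc, rep(1, 4), groups)),
               rep(1e-8, 10))
})

test_that("NB Wald test handles degenerate features and is symmetric", {
  groups <- list(c("a1", "a2"), c("b1", "b2"))
  sf <- rep(1, 4)
  k <- rbind(const = c(30L, 30L, 30L, 30L),
             zero = c(0L, 0L, 0L, 0L),
             onesided = c(0L, 0L, 25L, 35L))
  colnames(k) <- c("a1", "a2", "b1", "b2")
  res <- nb_wald_test(k, sf, groups, alpha = 0.1)
  expect_equal(res["const", "log2fc"], 0)
  expect_equal(res["const", "pvalue"], 1)
  expect_equal(res["zero", "log2fc"], 0)
  expect_equal(res["zero", "pvalue"], 1)
  # group present on one side only: finite, strongly significant
  expect_true(is.finite(res["onesided", "log2fc"]))
  expect_gt(res["onesided", "log2fc"], 4)
  expect_lt(res["onesided", "pvalue"], 1e-3)

  set.seed(34)
  k2 <- matrix(rnbinom(200 * 4, mu = 60, size = 8), 200, 4,
               dimnames = list(paste0("f", 1:200), colnames(k)))
  sf2 <- c(0.8, 1.1, 1.3, 0.9)
  a <- estimate_dispersion(k2, sf2, groups)
  fwd <- nb_wald_test(k2, sf2, groups, a)
  rev <- nb_wald_test(k2, sf2, rev(groups), a)
  expect_equal(rev$log2fc, -fwd$log2fc, tolerance = 1e-8)
  expect_equal(rev$pvalue, fwd$pvalue, tolerance = 1e-10)
})

test_that("Wald p agrees with a brute-force NB likelihood-ratio oracle", {
  set.seed(35)
  groups <- list(c("a1", "a2"), c("b1", "b2"))
  sf <- c(1.0, 1.2, 0.9, 1.1)
  alpha <- 0.1
  mus <- c(10, 20, 30, 15, 25, 40, 12, 18, 35, 22)
  shift <- c(1, 1, 1, 2, 2, 0.5, 1.5, 1, 3, 0.7)
  k <- t(vapply(seq_along(mus), function(i) {
    c(rnbinom(2, mu = mus[i] * sf[1:2], size = 1 / alpha),
      rnbinom(2, mu = mus[i] * shift[i] * sf[3:4], size = 1 / alpha))
  }, numeric(4)))
  k <- pmin(k, 50)
  dimnames(k) <- list(paste0("f", seq_along(mus)), unlist(groups))
  res <- nb_wald_test(k, sf, groups, alpha)
  for (i in seq_along(mus)) {
    p_lr <- oracle_nb_lr_p(k[i, 1:2], k[i, 3:4], sf[1:2], sf[3:4], alpha)
    if (res$pvalue[i] < 0.2 || p_lr < 0.2) {
      expect_gt(res$pvalue[i] / p_lr, 0.5)
      expect_lt(res$pvalue[i] / p_lr, 2)
    }
  }
})

test_that("NB Wald test agrees with DESeq2 on a shared fixture", {
  skip_if_not_installed("DESeq2")
  set.seed(36)
  n <- 300
  mu <- exp(runif(n, log(20), log(500)))
  fc <- sample(c(1, 1, 1, 3), n, replace = TRUE)
  k <- cbind(rnbinom(n, mu = mu, size = 10), rnbinom(n, mu = mu, size = 10),
             rnbinom(n, mu = mu, size = 10),
             rnbinom(n, mu = mu * fc, size = 10),
             rnbinom(n, mu = mu * fc, size = 10),
             rnbinom(n, mu = mu * fc, size = 10))
  dimnames(k) <- list(paste0("f", 1:n),
                      c(paste0("a", 1:3), paste0("b", 1:3)))
  groups <- list(paste0("a", 1:3), paste0("b", 1:3))
  sf <- size_factors_mor(k)
  ours <- nb_wald_test(k, sf, groups, estimate_dispersion(k, sf, groups))

  dds <- DESeq2::DESeqDataSetFromMatrix(
    k, data.frame(cond = factor(rep(c("a", "b"), each = 3))), ~cond)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  ref <- DESeq2::results(dds)
  # fold changes agree closely; calls at padj < 0.05 agree for nearly all
  expect_gt(cor(ours$log2fc, ref$log2FoldChange), 0.98)
  agree <- mean((ours$padj < 0.05) == (ref$padj < 0.05), na.rm = TRUE)
  expect_gt(agree, 0.9)
})

test_that("planted fold changes are detected with the documented power", {
  set.seed(37)
  n <- 500
  groups <- list(c("a1", "a2"), c("b1", "b2"))
  sf <- rep(1, 4)
  build <- function(fold) {
    k <- cbind(rnbinom(n, mu = 100, size = 10), rnbinom(n, mu = 100, size = 10),
               rnbinom(n, mu = 100 * fold, size = 10),
               rnbinom(n, mu = 100 * fold, size = 10))
    dimnames(k) <- list(paste0("f", 1:n), unlist(groups))
    k
  }
  # at a planted fold exactly on the 3-fold boundary the |log2fc| filter
  # removes ~half the features (the estimator is centred on the boundary),
  # so significance alone carries the 3-fold power check; the full
  # significance-plus-fold criterion is checked well clear of the boundary
  sens <- function(fold, apply_fc_filter) {
    k <- build(fold)
    r <- nb_wald_test(k, sf, groups, estimate_dispersion(k, sf, groups))
    hit <- r$padj < 0.05
    if (apply_fc_filter) hit <- hit & abs(r$log2fc) >= log2(3)
    mean(hit)
  }
  expect_gte(sens(3, FALSE), 0.8)
  expect_gte(sens(8, TRUE), 0.98)
})

test_that("BH adjustment matches the naive step-up oracle", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(38)
  for (rep in 1:5) {
    p <- round(runif(40), 3)
    padj <- bh_adjust(p)
    expect_equal(padj, oracle_bh(p))
    expect_true(all(padj >= p))
    # monotone non-decreasing in p rank
    expect_true(all(diff(padj[order(p)]) >= -1e-12))
  }
})
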