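# Normalization and negative-binomial differential testing.
#
# Size factors follow the top-N-median scheme: each sample's factor is the
# median count of its own N highest-count features, divided by the geometric
# mean of those medians across samples, so dividing by the factor equalizes
# top-N medians. The differential test is a transparent NB Wald test:
# method-of-moments dispersion with shrinkage toward the mean trend, per-group
# NB mean MLEs with size-factor offsets at fixed dispersion, Wald statistic
# from observed Fisher information, and Benjamini-Hochberg adjustment.

as_counts <- function(x) if (inherits(x, "CountMatrix")) x$counts else as.matrix(x)

#' Top-N-median size factors
#'
#' For each sample, `m_j` is the median of that sample's `n_top`
#' highest-count features (all features if fewer); the factor is
#' `m_j / geometric mean(m)`.
#'
#' @param counts CountMatrix or raw matrix.
#' @param n_top number of top features (default 30000).
#' @return named numeric vector of per-sample factors (geometric mean 1).
#' @export
size_factors_topn <- function(counts, n_top = 30000L) {
  k <- as_counts(counts)
  stopifnot(n_top >= 1)
  m <- apply(k, 2, function(v) {
    if (all(v == 0)) stop("sample with all-zero counts")
    median(sort(v, decreasing = TRUE)[seq_len(min(n_top, length(v)))])
  })
  m / exp(mean(log(m)))
}

#' Median-of-ratios size factors
#'
#' The classical reference-sample scheme: each sample's factor is the median,
#' over features with a positive geometric-mean count, of the ratio of its
#' count to that geometric mean. Provided as an alternative normalization
#' mode; the default pipeline uses [size_factors_topn()].
#'
#' @param counts CountMatrix or raw matrix.
#' @return named numeric vector of per-sample factors.
#' @export
size_factors_mor <- function(counts) {
  k <- as_counts(counts)
  logk <- log(k)
  lgm <- rowMeans(logk)
  use <- is.finite(lgm)
  if (!any(use)) stop("no feature has positive counts in every sample")
  apply(k, 2, function(v) exp(median(log(v[use]) - lgm[use])))
}

#' Divide counts by size factors
#'
#' @param counts CountMatrix or raw matrix.
#' @param factors per-sample positive factors, matching the samples.
#' @return real-valued normalized matrix (zeros preserved).
#' @export
normalize_counts <- function(counts, factors) {
  k <- as_counts(counts)
  if (length(factors) != ncol(k)) stop("one factor per sample required")
  if (any(factors <= 0)) stop("size factors must be > 0")
  sweep(k, 2, factors, `/`)
}

#' Method-of-moments dispersion with shrinkage
#'
#' Per feature, the pooled within-group moments of the normalized counts give
#' `alpha_hat = max(0, (s^2 - mu) / mu^2)`; each estimate is then shrunk
#' toward the across-feature mean with weight `shrink` and clamped to
#' `[1e-8, 10]`.
#'
#' @param counts CountMatrix or raw matrix.
#' @param factors size factors.
#' @param groups list of two character vectors of sample ids (or a
#'   factor/character vector over samples).
#' @param shrink shrinkage weight toward the mean trend (default 0.5).
#' @return per-feature dispersion vector.
#' @export
estimate_dispersion <- function(counts, factors, groups, shrink = 0.5) {
  k <- as_counts(counts)
  y <- normalize_counts(k, factors)
  idx <- group_indices(k, groups)
  ss <- 0; df <- 0; n_tot <- 0; mu_sum <- 0
  for (g in idx) {
    if (length(g) < 2) stop("each group needs >= 2 samples")
    yg <- y[, g, drop = FALSE]
    m <- rowMeans(yg)
    v <- rowSums((yg - m)^2) / (length(g) - 1)
    ss <- ss + v * (length(g) - 1)
    df <- df + (length(g) - 1)
    mu_sum <- mu_sum + m * length(g)
    n_tot <- n_tot + length(g)
  }
  s2 <- ss / df
  mu <- mu_sum / n_tot
  a <- ifelse(mu > 0, pmax(0, (s2 - mu) / mu^2), 0)
  a_trend <- mean(a)
  pmin(pmax((1 - shrink) * a + shrink * a_trend, 1e-8), 10)
}

# resolve `groups` into a list of two column-index vectors
group_indices <- function(k, groups) {
  if (is.list(groups)) {
    lapply(groups, function(g) {
      i <- match(g, colnames(k))
      if (anyNA(i)) stop("unknown sample id in group")
      i
    })
  } else {
    lv <- unique(as.character(groups))
    if (length(lv) != 2) stop("exactly two groups required")
    lapply(lv, function(l) which(as.character(groups) == l))
  }
}

# Vectorized Newton solve for per-feature NB mean MLE on the log scale, with
# size-factor offsets at fixed per-feature dispersion. The NB log-likelihood
# is strictly concave in log(mu), so damped Newton converges.
nb_group_mle <- function(K, sf, alpha, iters = 50L) {
  tot <- rowSums(K)
  eta <- log(pmax(tot / sum(sf), 1e-8))
  inv_a <- 1 / alpha
  for (it in seq_len(iters)) {
    mu <- exp(eta)
    U <- numeric(length(eta)); I <- numeric(length(eta))
    for (j in seq_along(sf)) {
      t_j <- alpha * sf[j] * mu / (1 + alpha * sf[j] * mu)
      U <- U + K[, j] - (K[, j] + inv_a) * t_j
      I <- I + (K[, j] + inv_a) * t_j * (1 - t_j)
    }
    stepv <- U / pmax(I, 1e-12)
    eta <- eta + pmin(pmax(stepv, -3), 3)
  }
  mu <- exp(eta)
  mu[tot == 0] <- 0
  mu
}

# observed Fisher information for log(mu) at given mu (per feature)
nb_obs_info <- function(K, sf, alpha, mu) {
  inv_a <- 1 / alpha
  I <- numeric(length(mu))
  for (j in seq_along(sf)) {
    t_j <- alpha * sf[j] * mu / (1 + alpha * sf[j] * mu)
    I <- I + (K[, j] + inv_a) * t_j * (1 - t_j)
  }
  I
}

#' Negative-binomial Wald test for a two-group contrast
#'
#' Fits per-group NB means by maximum likelihood with size-factor offsets at
#' the supplied (fixed) dispersions; the Wald statistic is the log fold
#' change over its standard error from observed Fisher information, with a
#' two-sided normal reference. When either group's MLE mean is zero, a
#' pseudo-mean of 0.5 is added to both groups for the fold change and the
#' information is evaluated at the shifted means, keeping the result finite.
#' Degenerate cases (both groups all zero, or non-finite statistic) report
#' `log2fc = 0, p = 1`.
#'
#' @param counts CountMatrix or raw matrix.
#' @param factors size factors.
#' @param groups list of two sample-id vectors `(group1, group2)`; the fold
#'   change is group2 over group1.
#' @param alpha per-feature dispersion vector (or scalar); typically from
#'   [estimate_dispersion()].
#' @return data.frame (`DiffResult`): feature, mean1, mean2 (normalized group
#'   means), log2fc, alpha, pvalue, padj.
#' @export
nb_wald_test <- function(counts, factors, groups, alpha) {
  k <- as_counts(counts)
  idx <- group_indices(k, groups)
  if (length(idx) != 2) stop("exactly two groups required")
  if (any(lengths(idx) < 2)) stop("each group needs >= 2 samples")
  alpha <- rep_len(pmax(alpha, 1e-8), nrow(k))

  mu1 <- nb_group_mle(k[, idx[[1]], drop = FALSE], factors[idx[[1]]], alpha)
  mu2 <- nb_group_mle(k[, idx[[2]], drop = FALSE], factors[idx[[2]]], alpha)

  zero <- mu1 == 0 | mu2 == 0
  mu1a <- ifelse(zero, mu1 + 0.5, mu1)
  mu2a <- ifelse(zero, mu2 + 0.5, mu2)
  I1 <- nb_obs_info(k[, idx[[1]], drop = FALSE], factors[idx[[1]]], alpha, mu1a)
  I2 <- nb_obs_info(k[, idx[[2]], drop = FALSE], factors[idx[[2]]], alpha, mu2a)
  delta <- log(mu2a) - log(mu1a)
  se <- sqrt(1 / pmax(I1, 1e-300) + 1 / pmax(I2, 1e-300))
  z <- delta / se
  p <- 2 * pnorm(-abs(z))
  log2fc <- delta / log(2)

  both_zero <- mu1 == 0 & mu2 == 0
  bad <- both_zero | !is.finite(p) | I1 <= 0 | I2 <= 0
  p[bad] <- 1
  log2fc[both_zero] <- 0
  z_degenerate <- delta == 0
  p[z_degenerate] <- 1

  data.frame(feature = rownames(k), mean1 = mu1, mean2 = mu2,
             log2fc = log2fc, alpha = alpha, pvalue = p,
             padj = bh_adjust(p), row.names = rownames(k),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment; input order preserved.
#'
#' @param p p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Two-group differential test with the package's standard plumbing
#'
#' Convenience wrapper: top-N-median (or median-of-ratios) size factors,
#' dispersion estimation, and the NB Wald test for `condition2` vs
#' `condition1`.
#'
#' @param cm [count_matrix()].
#' @param condition1,condition2 condition labels; fold change is
#'   condition2 / condition1.
#' @param n_top top-N for size factors (default 30000).
#' @param normalization `"topn"` or `"mor"`.
#' @param shrink dispersion shrinkage weight.
#' @return list: `result` ([nb_wald_test()] table), `factors`, `normalized`
#'   (normalized matrix), `groups`.
#' @export
diff_test <- function(cm, condition1, condition2, n_top = 30000L,
                      normalization = c("topn", "mor"), shrink = 0.5) {
  normalization <- match.arg(normalization)
  factors <- if (normalization == "topn")
    size_factors_topn(cm, n_top) else size_factors_mor(cm)
  g1 <- condition_samples(cm, condition1)
  g2 <- condition_samples(cm, condition2)
  if (!length(g1) || !length(g2)) stop("unknown condition label")
  groups <- list(g1, g2)
  alpha <- estimate_dispersion(cm, factors, groups, shrink = shrink)
  res <- nb_wald_test(cm, factors, groups, alpha)
  list(result = res, factors = factors,
       normalized = normalize_counts(cm, factors), groups = groups)
}
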