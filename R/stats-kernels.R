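## Statistical kernels shared across the screening and association stages.
## They are deliberately self-contained (no calls into fisher.test / wilcox.test
## / ks.test) so the test suite can validate them against exhaustive-enumeration
## and independent-library oracles.

#' Hypergeometric (Fisher's exact) test from set sizes
#'
#' One shared kernel for every enrichment / overlap operation in the package.
#' Tests the overlap of a `k`-gene set with an `m`-gene set inside a universe
#' of `n_universe` genes.
#'
#' @param overlap observed overlap count.
#' @param size1 size of the first set (restricted to the universe).
#' @param size2 size of the second set (restricted to the universe).
#' @param n_universe universe size.
#' @param alternative `"greater"` for one-sided over-representation,
#'   `"two.sided"` for association in either direction (the `fisher.test`
#'   convention: sum of all table probabilities no larger than the observed).
#' @return p-value.
#' @export
hyper_test <- function(overlap, size1, size2, n_universe,
                       alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  assert_that(n_universe >= 1, "universe must contain at least one element")
  assert_that(size1 <= n_universe && size2 <= n_universe,
              "set sizes cannot exceed the universe size")
  lo <- max(0L, size1 + size2 - n_universe)
  hi <- min(size1, size2)
  assert_that(overlap >= lo && overlap <= hi,
              "overlap is inconsistent with the margins")
  if (alternative == "greater") {
    return(stats::phyper(overlap - 1, size1, n_universe - size1, size2,
                         lower.tail = FALSE))
  }
  support <- lo:hi
  d <- stats::dhyper(support, size1, n_universe - size1, size2)
  dobs <- stats::dhyper(overlap, size1, n_universe - size1, size2)
  min(1, sum(d[d <= dobs * (1 + 1e-7)]))
}

## Exact null distribution of the rank sum of the smaller group, by dynamic
## programming over the (doubled, hence integer) midranks.  Handles ties
## exactly; counts stay below 2^53 for any min group size <= 8.
wmw_exact_dist <- function(ranks2, k) {
  maxS <- sum(sort(ranks2, decreasing = TRUE)[seq_len(k)])
  ## dp[j + 1, s + 1] = number of j-subsets with doubled-rank sum s
  dp <- matrix(0, nrow = k + 1L, ncol = maxS + 1L)
  dp[1L, 1L] <- 1
  for (v in ranks2) {
    for (j in seq(k, 1L)) {
      src <- dp[j, seq_len(maxS + 1L - v)]
      if (any(src != 0)) {
        idx <- (v + 1L):(maxS + 1L)
        dp[j + 1L, idx] <- dp[j + 1L, idx] + src
      }
    }
  }
  counts <- dp[k + 1L, ]
  list(sums = 0:maxS, prob = counts / sum(counts))
}

#' Wilcoxon-Mann-Whitney two-sample test
#'
#' Exact (tie-aware, by enumeration of the rank-sum null distribution) when the
#' smaller group has at most `exact_max` observations; otherwise the normal
#' approximation with tie correction and continuity correction.  Two-sided
#' p-values double the smaller tail (capped at 1).
#'
#' @param x,y numeric samples.
#' @param exact_max exact branch threshold on `min(length(x), length(y))`.
#' @return list with `statistic` (Mann-Whitney U for `x`), `p.value`, `exact`.
#' @export
wmw_test <- function(x, y, exact_max = 8L) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  assert_that(n1 >= 1 && n2 >= 1, "both groups must be non-empty")
  r <- rank(c(x, y))
  w1 <- sum(r[seq_len(n1)])
  u1 <- w1 - n1 * (n1 + 1) / 2
  if (min(n1, n2) <= exact_max) {
    ranks2 <- as.integer(round(2 * r))
    if (n1 <= n2) {
      k <- n1; wk2 <- as.integer(round(2 * w1))
    } else {
      k <- n2; wk2 <- as.integer(round(2 * (sum(r) - w1)))
    }
    dist <- wmw_exact_dist(ranks2, k)
    ple <- sum(dist$prob[dist$sums <= wk2 + 1e-9])
    pge <- sum(dist$prob[dist$sums >= wk2 - 1e-9])
    p <- min(1, 2 * min(ple, pge))
    return(list(statistic = u1, p.value = p, exact = TRUE))
  }
  mu <- n1 * n2 / 2
  tie_tab <- table(r)
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(statistic = u1, p.value = 1, exact = FALSE))
  z <- u1 - mu
  z <- z - sign(z) * 0.5              # continuity correction
  p <- min(1, 2 * stats::pnorm(-abs(z) / sqrt(sigma2)))
  list(statistic = u1, p.value = p, exact = FALSE)
}

## Asymptotic Kolmogorov survival function Q(lambda) = P(K > lambda).
## Two theta-function representations, each summed to machine precision:
## the transformed series converges fast for small lambda, the alternating
## series for large lambda.
kolmogorov_q <- function(lambda) {
  if (lambda <= 0) return(1)
  if (lambda < 1) {
    j <- 1:20
    s <- sum(exp(-(2 * j - 1)^2 * pi^2 / (8 * lambda^2)))
    return(min(1, max(0, 1 - sqrt(2 * pi) / lambda * s)))
  }
  j <- 1:100
  min(1, max(0, 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Statistic computed directly from the pooled empirical CDFs (tie-aware);
#' p-value from the asymptotic Kolmogorov distribution (the convention of
#' `ks.test(..., exact = FALSE)`), which is the relevant regime for the
#' genome-scale correlation vectors this package compares.
#'
#' @param x,y numeric samples.
#' @return list with `statistic` (D), `p.value`.
#' @export
ks2_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  assert_that(n1 >= 1 && n2 >= 1, "both samples must be non-empty")
  w <- c(x, y)
  ord <- order(w)
  steps <- cumsum(ifelse(ord <= n1, 1 / n1, -1 / n2))
  ws <- w[ord]
  keep <- c(diff(ws) != 0, TRUE)      # evaluate at the last of each tie run
  d <- max(abs(steps[keep]))
  ne <- n1 * n2 / (n1 + n2)
  list(statistic = d, p.value = kolmogorov_q(sqrt(ne) * d))
}

#' Pearson correlation with a t-distributed p-value
#'
#' @param x,y numeric vectors of equal length (at least 3).
#' @return list with `r`, `p.value`, `n`; `r` is `NA` for constant input.
#' @export
pearson_test <- function(x, y) {
  n <- length(x)
  assert_that(n == length(y), "vectors must have equal length")
  assert_that(n >= 3, "need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p.value = NA_real_, n = n))
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1) return(list(r = r, p.value = 0, n = n))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p.value = 2 * stats::pt(-abs(tstat), df = n - 2), n = n)
}

## row-wise Pearson correlation of a vector against every row of a matrix;
## constant rows yield 0 (not NA) so IRLS weights stay defined.
row_cor <- function(mat, v, zero_for_constant = TRUE) {
  vc <- v - mean(v)
  mc <- mat - rowMeans(mat)
  num <- as.vector(mc %*% vc)
  den <- sqrt(rowSums(mc^2) * sum(vc^2))
  r <- ifelse(den > 0, num / den, if (zero_for_constant) 0 else NA_real_)
  pmin(1, pmax(-1, r))
}

#' Empirical false discovery rate against a pooled permutation null
#'
#' For each observed statistic `t` (orientation: larger = more significant)
#' the raw FDR is the fraction of pooled null values at or above `t` divided
#' by the fraction of observed values at or above `t`; the curve is then
#' monotonized (suffix minimum over decreasing `t`, the BH step-up
#' convention) and capped at 1.  Tied observed statistics share one FDR.
#'
#' @param observed numeric vector of observed statistics (`NA` allowed,
#'   returned as `NA`).
#' @param null pooled null statistics (all permutations, all features).
#' @return numeric vector of FDR values aligned with `observed`.
#' @export
empirical_fdr <- function(observed, null) {
  out <- rep(NA_real_, length(observed))
  ok <- which(is.finite(observed))
  if (length(ok) == 0) return(out)
  obs <- observed[ok]
  null <- null[is.finite(null)]
  nn <- length(null)
  raw <- vapply(obs, function(t) {
    fn <- if (nn > 0) mean(null >= t) else 0
    fo <- mean(obs >= t)
    min(1, fn / fo)
  }, numeric(1))
  ordd <- order(obs, decreasing = TRUE)
  fdr <- numeric(length(obs))
  fdr[ordd] <- suffix_min(raw[ordd])
  out[ok] <- fdr
  out
}

#' Permutation FDR for a vector of feature statistics
#'
#' Rebuilds the null by calling `permute(b)` for `b = 1..n_perm`; each call
#' must return one permuted statistic per feature.  The null is pooled across
#' features and permutations, as the screening procedures assume.
#'
#' @param observed observed per-feature statistics (larger = more significant).
#' @param permute function of the permutation index returning a numeric vector.
#' @param n_perm number of permutations (default 1000).
#' @param seed optional seed set before the permutation loop.
#' @return per-feature empirical FDR.
#' @export
permutation_fdr <- function(observed, permute, n_perm = 1000L, seed = NULL) {
  if (n_perm < 100) warning("n_perm < 100: empirical FDR tail is unstable")
  if (!is.null(seed)) set.seed(seed)
  null <- unlist(lapply(seq_len(n_perm), permute), use.names = FALSE)
  empirical_fdr(observed, null)
}
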