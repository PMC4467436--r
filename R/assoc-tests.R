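# Inferential toolkit: rank-sum, hypergeometric, binomial, Fisher's exact,
# Welch t and BH-FDR, implemented here (log-space combinatorics where tails
# can underflow). Base-R equivalents are used only as cross-check oracles in
# the test suite.

new_test_result <- function(statistic, p, effect = NULL, n = NULL,
                            method = "", data.name = "") {
  out <- list(statistic = statistic, p.value = p, estimate = effect,
              n = n, method = method, data.name = data.name)
  class(out) <- c("coexsig_test", "htest")
  out
}

logsumexp <- function(lx) {
  lx <- lx[is.finite(lx) | lx == -Inf]
  if (!length(lx)) return(-Inf)
  m <- max(lx)
  if (m == -Inf) return(-Inf)
  m + log(sum(exp(lx - m)))
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided. When the pooled sample size is at most 12 and there are no
#' ties, the null distribution of the Mann-Whitney U statistic is obtained
#' by exhaustive enumeration of all group assignments; otherwise a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y Numeric vectors, each non-empty.
#' @return A test-result object (class `htest`) with the Mann-Whitney U
#'   statistic (`W`), the two-sided p-value, and the group sizes.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p.value  # 0.10 exactly
#' @export
wilcoxon_rank_sum <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  if (n <= 12 && !ties) {
    combos <- utils::combn(n, nx)
    u_null <- colSums(matrix(seq_len(n)[combos], nrow = nx)) -
      nx * (nx + 1) / 2
    p <- if (U > nx * ny / 2) 2 * mean(u_null >= U) else 2 * mean(u_null <= U)
    p <- min(1, p)
    method <- "Wilcoxon rank-sum test (exact enumeration)"
  } else {
    tie_tab <- table(r)
    z <- U - nx * ny / 2
    sigma <- sqrt((nx * ny / 12) *
                    ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1))))
    z <- (z - sign(z) * 0.5) / sigma
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "Wilcoxon rank-sum test (normal approximation)"
  }
  new_test_result(c(W = U), p, effect = c(`rank-sum W` = U),
                  n = c(n_x = nx, n_y = ny), method = method)
}

#' Upper-tail hypergeometric overlap test
#'
#' `P(X >= k)` for `X` hypergeometric: `k` overlap observed between a set of
#' size `K` and a set of size `n` drawn from a universe of `N` genes. The
#' sum is accumulated in log space, so p-values far below the smallest
#' normal double (the regime of strong set overlaps) remain meaningful via
#' `log.p`.
#'
#' @param k Observed overlap.
#' @param K,n Set sizes.
#' @param N Universe size.
#' @param log.p Return the natural log of the p-value.
#' @return The (log) upper-tail probability.
#' @export
hypergeom_overlap_test <- function(k, K, n, N, log.p = FALSE) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n))
    stop("inconsistent counts: need k <= min(K, n) and K, n <= N")
  lo <- max(0, K + n - N); hi <- min(K, n)
  if (k <= lo) return(if (log.p) 0 else 1)
  i <- k:hi
  lp <- logsumexp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n))
  lp <- min(lp, 0)
  if (log.p) lp else exp(lp)
}

#' Exact binomial test (two-sided, minimum-likelihood tails)
#'
#' Two-sided p-value obtained by summing the point probabilities of all
#' outcomes no more likely than the observed one (within a 1e-7 relative
#' slack for floating-point equality), the convention of standard
#' statistical software.
#'
#' @param k Observed successes.
#' @param n Trials.
#' @param p0 Null success probability, strictly in (0, 1).
#' @return The two-sided p-value.
#' @examples
#' binomial_test(8, 10)  # 112/1024
#' @export
binomial_test <- function(k, n, p0 = 0.5) {
  if (p0 <= 0 || p0 >= 1) stop("'p0' must be strictly inside (0, 1)")
  if (k < 0 || k > n) stop("need 0 <= k <= n")
  i <- 0:n
  ld <- lchoose(n, i) + i * log(p0) + (n - i) * log1p(-p0)
  keep <- ld <= ld[k + 1] + log(1 + 1e-7)
  min(1, exp(logsumexp(ld[keep])))
}

# Mean of the noncentral hypergeometric distribution of the [1,1] cell
# given the table margins, at odds ratio psi (log scale input).
nchyper_mean <- function(log_psi, m1, m2, n1) {
  lo <- max(0, n1 - m2); hi <- min(n1, m1)
  x <- lo:hi
  lw <- lchoose(m1, x) + lchoose(m2, n1 - x) + x * log_psi
  w <- exp(lw - max(lw))
  sum(x * w) / sum(w)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by summing the conditional (hypergeometric) point
#' probabilities of all tables with the observed margins that are no more
#' probable than the observed table. Reports both the sample odds ratio
#' `ad/bc` and the conditional maximum-likelihood odds ratio (the estimate
#' conditioned on the margins).
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return Test-result object with `p.value` and `estimate` (named vector
#'   `sample_or`, `cmle_or`); a zero margin gives `p = 1` with `NA` odds
#'   ratios.
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2L))
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be nonnegative integers")
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  m1 <- a + b; m2 <- cc + d; n1 <- a + cc
  if (m1 == 0 || m2 == 0 || n1 == 0 || (b + d) == 0)
    return(new_test_result(c(k = a), 1,
                           effect = c(sample_or = NA_real_,
                                      cmle_or = NA_real_),
                           n = c(n = sum(tab)),
                           method = "Fisher's exact test (zero margin)"))
  lo <- max(0, n1 - m2); hi <- min(n1, m1)
  x <- lo:hi
  ld <- lchoose(m1, x) + lchoose(m2, n1 - x) - lchoose(m1 + m2, n1)
  ld_obs <- ld[x == a]
  p <- min(1, exp(logsumexp(ld[ld <= ld_obs + log(1 + 1e-7)])))
  sample_or <- if (b * cc > 0) (a * d) / (b * cc) else
    if (a * d > 0) Inf else NaN
  cmle_or <- if (a == lo) 0 else if (a == hi) Inf else {
    f <- function(lp) nchyper_mean(lp, m1, m2, n1) - a
    exp(stats::uniroot(f, c(-40, 40), tol = 1e-10)$root)
  }
  new_test_result(c(k = a), p,
                  effect = c(sample_or = sample_or, cmle_or = cmle_or),
                  n = c(n = sum(tab)), method = "Fisher's exact test")
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom,
#' two-sided. If both groups are degenerate (zero variance) the p-value is 1
#' for equal means and 0 otherwise.
#'
#' @param x,y Numeric vectors with at least 2 values each.
#' @return Test-result object with statistic `t`, `df`, `p.value` and the
#'   mean difference as effect.
#' @export
welch_t_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) stop("need >= 2 values per group")
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  delta <- mean(x) - mean(y)
  se2 <- vx / nx + vy / ny
  if (se2 == 0) {
    p <- if (delta == 0) 1 else 0
    tt <- if (delta == 0) 0 else sign(delta) * Inf
    df <- NA_real_
  } else {
    tt <- delta / sqrt(se2)
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
    p <- 2 * stats::pt(-abs(tt), df)
  }
  new_test_result(c(t = tt, df = df), p,
                  effect = c(mean_difference = delta),
                  n = c(n_x = nx, n_y = ny), method = "Welch two-sample t-test")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment `q_(i) = min_(j >= i) min(1, p_(j) * m / j)`, returned
#' in the input order. `NA` p-values stay `NA` and do not count toward `m`.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  pv <- p[ok]; m <- length(pv)
  if (!m) return(q)
  o <- order(pv, decreasing = TRUE)
  q[ok] <- pmin(1, cummin(pv[o] * m / seq(m, 1)))[order(o)]
  q
}
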