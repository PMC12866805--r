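# Core statistical primitives used throughout the pipeline.  Each is written
# out explicitly (rather than delegating to stats::t.test etc.) so the test
# suite can check them against independent reference implementations.

#' Pooled-variance two-sample Student's t-test
#'
#' Two-tailed test of equal means assuming equal variances, with
#' `df = length(x) + length(y) - 2`.  This is the classical "Student's"
#' test used for probe-vs-competition reporter intensities; see
#' [call_targets()] for the vectorised per-protein version.
#'
#' Degenerate inputs are resolved rather than erroring: zero pooled variance
#' with equal means gives `t = 0, p = 1`; zero pooled variance with unequal
#' means gives `p = 0` with a warning.
#'
#' @param x,y Numeric vectors, each of length >= 2, all values finite.
#' @return A list with elements `t_stat` and `p_value`.
#' @examples
#' student_t_test(c(1, 2, 3), c(4, 5, 6))
#' @export
student_t_test <- function(x, y) {
  .check(is.numeric(x) && length(x) >= 2L && all(is.finite(x)),
         "x must be a finite numeric vector of length >= 2")
  .check(is.numeric(y) && length(y) >= 2L && all(is.finite(y)),
         "y must be a finite numeric vector of length >= 2")
  nx <- length(x); ny <- length(y)
  df <- nx + ny - 2L
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / df
  delta <- mean(x) - mean(y)
  if (sp2 <= 0) {
    if (delta == 0) return(list(t_stat = 0, p_value = 1))
    warning("zero pooled variance with unequal means; p-value degenerate at 0")
    return(list(t_stat = sign(delta) * Inf, p_value = 0))
  }
  t_stat <- delta / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t_stat = t_stat, p_value = 2 * stats::pt(-abs(t_stat), df = df))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard FDR step-up adjustment with monotonicity enforcement; the output
#' preserves the input order and lies in `[0, 1]`.
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]` (NA allowed;
#'   NAs are passed through and do not count toward the number of tests).
#' @return Adjusted p-values, same length and order as the input.
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04))
#' @export
benjamini_hochberg <- function(p_values) {
  .check(is.numeric(p_values), "p_values must be numeric")
  ok <- !is.na(p_values)
  .check(all(p_values[ok] >= 0 & p_values[ok] <= 1),
         "p_values must lie in [0, 1]")
  out <- rep(NA_real_, length(p_values))
  p <- p_values[ok]
  m <- length(p)
  if (m == 0L) return(out)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  out[ok] <- adj
  out
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided test with midrank tie handling.  Small samples (fewer than 8
#' observations in either group, and a feasible enumeration) use exact
#' enumeration of all rank splits; larger samples use the normal
#' approximation with tie-corrected variance and continuity correction.
#' The statistic reported is the Mann-Whitney U for `x`.
#'
#' @param x,y Numeric vectors, each of length >= 1.
#' @param exact_limit Maximum number of rank splits to enumerate exactly;
#'   above it the normal approximation is used regardless of sample size.
#' @return A list with elements `statistic` (U) and `p_value`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
#' @export
wilcoxon_rank_sum <- function(x, y, exact_limit = 2e5) {
  .check(is.numeric(x) && length(x) >= 1L && all(is.finite(x)),
         "x must be a finite numeric vector of length >= 1")
  .check(is.numeric(y) && length(y) >= 1L && all(is.finite(y)),
         "y must be a finite numeric vector of length >= 1")
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2

  small <- (nx < 8L || ny < 8L) && choose(nx + ny, min(nx, ny)) <= exact_limit
  if (small) {
    # Exact permutation distribution of U over all C(nx+ny, nx) splits of
    # the (mid)ranks; valid with ties, unlike stats::pwilcox.
    idx <- utils::combn(nx + ny, nx)
    us <- colSums(matrix(r[idx], nrow = nx)) - nx * (nx + 1) / 2
    eps <- 1e-9
    p_lo <- mean(us <= u + eps)
    p_hi <- mean(us >= u - eps)
    p <- min(1, 2 * min(p_lo, p_hi))
    return(list(statistic = u, p_value = p))
  }

  n <- nx + ny
  ties <- table(r)
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(statistic = u, p_value = 1))
  # continuity correction toward the null
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  list(statistic = u, p_value = min(1, 2 * stats::pnorm(-abs(z))))
}

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the over-representation
#' p-value for drawing `k` annotated genes in a query of size `n` when `K`
#' of the `N` universe genes carry the annotation.  Computed by summing the
#' PMF in log space for numerical stability.
#'
#' @param k Observed overlap, `0 <= k <= min(K, n)`.
#' @param K Annotated genes in the universe.
#' @param n Query size.
#' @param N Universe size.
#' @return The tail probability, a number in `[0, 1]`.
#' @examples
#' hypergeom_tail(5, 5, 5, 10)  # 1 / choose(10, 5)
#' @export
hypergeom_tail <- function(k, K, n, N) {
  .check(.is_count(k) && .is_count(K) && .is_count(n) && .is_count(N),
         "k, K, n, N must be non-negative integers")
  .check(K <= N && n <= N, "K and n must not exceed the universe size N")
  .check(k <= min(K, n), "overlap k cannot exceed min(K, n)")
  if (k == 0L) return(1)
  kk <- k:min(K, n)
  logp <- lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n)
  m <- max(logp)
  min(1, exp(m + log(sum(exp(logp - m)))))
}
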