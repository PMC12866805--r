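# Small deterministic fixtures built in code.

# quant table where each protein's probe/competition means are set exactly,
# with a fixed tiny multiplicative jitter so variances are non-zero.
make_quant <- function(probe_means, comp_means,
                       ids = sprintf("P%03d", seq_along(probe_means))) {
  jit <- c(0.999, 1, 1.001)
  m <- cbind(outer(probe_means, jit), outer(comp_means, jit))
  colnames(m) <- c(paste0("probe_", 1:3), paste0("comp_", 1:3))
  quant_table(m, setNames(rep(c("probe", "competition"), each = 3),
                          colnames(m)), ids)
}

# dense labeled counts from an explicit matrix
make_counts <- function(m, labels) {
  rownames(m) <- sprintf("g%02d", seq_len(nrow(m)))
  colnames(m) <- sprintf("c%02d", seq_len(ncol(m)))
  suppressWarnings(labeled_counts(m, labels))
}

# brute-force upper hypergeometric tail by direct binomial coefficients
bf_hyper_tail <- function(k, K, n, N) {
  if (k == 0) return(1)
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}
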