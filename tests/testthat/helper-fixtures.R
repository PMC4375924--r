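# Small fixtures and independent brute-force oracles shared across tests.

# tiny expression matrix with known ages
tiny_em <- function(values = NULL, unit = "raw") {
  if (is.null(values)) {
    values <- tibble::tibble(
      gene = c("g1", "g2", "g3"),
      s1 = c(10, 0, 5), s2 = c(20, 1, 5), s3 = c(30, 2, 5), s4 = c(40, 3, 5))
  }
  expression_matrix(values, ages = c(s1 = 100, s2 = 1000, s3 = 5000,
                                     s4 = 20000)[names(values)[-1]],
                    unit = unit)
}

# exhaustive permutation enumeration (independent of the package's DP)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

# brute-force two-sided exact Spearman p by full enumeration
brute_spearman_p <- function(x, y) {
  n <- length(x)
  rx <- rank(x)
  ry <- rank(y)
  rho_obs <- cor(rx, ry)
  P <- all_perms(n)
  rhos <- apply(P, 1, function(p) cor(rx, ry[p]))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

# brute-force upper binomial tail by direct summation
brute_binom_upper <- function(k, n, p) {
  sum(vapply(k:n, function(i) choose(n, i) * p^i * (1 - p)^(n - i),
             numeric(1)))
}

# brute-force upper hypergeometric tail by direct summation
brute_hyper_upper <- function(k, N, K, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# hand-rolled Benjamini-Hochberg step-up
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}
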