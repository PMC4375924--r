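#' Permutation test for the overlap of two gene sets
#'
#' Compares the observed overlap `|A` \eqn{\cap} `B|` with the overlaps of
#' `n_perm` size-matched random draws from the two universes (e.g. the
#' age-dependent genes of two datasets). The empirical p-value is the
#' fraction of permuted overlaps at least as large as the observed one, and
#' the overlap is flagged significant when it exceeds the 95% quantile of
#' the permutation distribution.
#'
#' Uses the current RNG state; seed the session for reproducibility.
#'
#' @param set_a,set_b Character vectors of gene identifiers.
#' @param universe_a,universe_b Universes the sets were drawn from
#'   (`set_a` must be a subset of `universe_a`, etc.).
#' @param n_perm Number of permutations.
#' @return A list of class `overlap_test`: `observed`, `permuted` (integer
#'   vector), `q95`, `p`, `significant`.
#' @export
overlap_permutation <- function(set_a, set_b, universe_a, universe_b,
                                n_perm = 1000L) {
  dca_assert(all(set_a %in% universe_a), "set_a must be within universe_a")
  dca_assert(all(set_b %in% universe_b), "set_b must be within universe_b")
  observed <- length(intersect(set_a, set_b))
  shared <- intersect(universe_a, universe_b)
  if (length(shared) == 0) {
    warn("disjoint universes: overlap is trivially 0")
  }
  na <- length(set_a); nb <- length(set_b)
  permuted <- vapply(seq_len(n_perm), function(b) {
    a_draw <- universe_a[sample_int(length(universe_a), na)]
    b_draw <- universe_b[sample_int(length(universe_b), nb)]
    length(intersect(a_draw, b_draw))
  }, integer(1))
  q95 <- unname(quantile(permuted, 0.95, type = 1))
  structure(list(observed = observed, permuted = permuted, q95 = q95,
                 p = mean(permuted >= observed),
                 significant = observed > q95),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf(
    "<overlap_test> observed %d, permutation mean %.2f, 95%% quantile %d, p = %.4g%s\n",
    x$observed, mean(x$permuted), x$q95, x$p,
    if (x$significant) " (significant)" else ""))
  invisible(x)
}
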