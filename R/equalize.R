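#' Per-gene stratifier statistics from interval profiles
#'
#' Computes, per gene and interval, one of the statistics used to equalise
#' the developmental and aging gene sets before re-testing the coupling
#' difference: profile standard deviation, coefficient of variation, mean
#' expression, or amplitude (max - min of the interpolated profile).
#'
#' @param profiles An [interpolate_profiles()] result.
#' @param type One of `"sd"`, `"cv"`, `"mean"`, `"amplitude"`.
#' @return A tibble: `gene`, `dev`, `age`.
#' @export
gene_stratifiers <- function(profiles,
                             type = c("sd", "cv", "mean", "amplitude")) {
  type <- match.arg(type)
  f <- switch(type,
    sd = function(m) apply(m, 1, sd),
    cv = function(m) apply(m, 1, sd) / rowMeans(m),
    mean = rowMeans,
    amplitude = function(m) apply(m, 1, max) - apply(m, 1, min))
  tibble(gene = profiles$gene,
         dev = unname(f(profile_matrix(profiles, "dev"))),
         age = unname(f(profile_matrix(profiles, "age"))))
}

#' Coupling difference under equalised stratifier distributions
#'
#' Controls for differences in expression variability, level or amplitude
#' between the two intervals: the common support of the developmental and
#' aging stratifier distributions is split into equal-width bins, and in
#' each of `n_rounds` rounds genes are drawn so that both intervals
#' contribute the same per-bin counts; each round records the two-sided
#' Wilcoxon p-value comparing the sampled developmental and aging
#' correlation distributions.
#'
#' Uses the current RNG state; seed the session for reproducibility.
#'
#' @param calls A `concordance_calls` tibble.
#' @param stratifier A tibble from [gene_stratifiers()] (columns `gene`,
#'   `dev`, `age`).
#' @param n_rounds Number of subsampling rounds.
#' @param n_bins Number of equal-width bins over the common support.
#' @return A tibble with one row per round: `round`, `p`, `n`.
#' @export
equalized_subsample <- function(calls, stratifier, n_rounds = 1000L,
                                n_bins = 10L) {
  df <- inner_join(as_tibble(calls[c("gene", "rho_dev", "rho_age")]),
                   stratifier, by = "gene")
  df <- df[complete.cases(df), , drop = FALSE]
  lo <- max(min(df$dev), min(df$age))
  hi <- min(max(df$dev), max(df$age))
  if (!(hi > lo)) dca_stop("empty common support between the two intervals")
  breaks <- seq(lo, hi, length.out = n_bins + 1L)
  bin_dev <- findInterval(df$dev, breaks, rightmost.closed = TRUE)
  bin_age <- findInterval(df$age, breaks, rightmost.closed = TRUE)
  in_dev <- bin_dev >= 1 & bin_dev <= n_bins
  in_age <- bin_age >= 1 & bin_age <= n_bins
  rounds <- vector("list", n_rounds)
  for (r in seq_len(n_rounds)) {
    xs <- list(); ys <- list()
    for (b in seq_len(n_bins)) {
      id <- which(in_dev & bin_dev == b)
      ia <- which(in_age & bin_age == b)
      k <- min(length(id), length(ia))
      if (k == 0) next
      xs[[b]] <- df$rho_dev[id[sample_int(length(id), k)]]
      ys[[b]] <- df$rho_age[ia[sample_int(length(ia), k)]]
    }
    x <- unlist(xs); y <- unlist(ys)
    p <- if (length(x) < 2) NA_real_
         else if (all(x == y)) 1
         else suppressWarnings(wilcox.test(x, y)$p.value)
    rounds[[r]] <- tibble(round = r, p = p, n = length(x))
  }
  bind_rows(rounds)
}
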