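#' Keep reliably conserved miRNA target pairs
#'
#' Retains predicted miRNA-target pairs whose site is conserved in at least
#' `min_species` of the four flag species (mouse, rat, dog, chicken). Pairs
#' with missing flags are dropped with a warning.
#'
#' @param targets Data frame with columns `mirna`, `seed`, `gene`,
#'   `cons_mouse`, `cons_rat`, `cons_dog`, `cons_chicken`.
#' @param min_species Minimum number of species with a conserved site.
#' @return The filtered tibble.
#' @export
filter_conserved_targets <- function(targets, min_species = 3L) {
  flags <- c("cons_mouse", "cons_rat", "cons_dog", "cons_chicken")
  dca_assert(all(c("mirna", "seed", "gene", flags) %in% names(targets)),
             "target table is missing required columns")
  fm <- as.matrix(targets[flags])
  bad <- rowSums(is.na(fm)) > 0
  if (any(bad)) {
    warn(sprintf("dropping %d pair(s) with missing conservation flags",
                 sum(bad)))
  }
  keep <- !bad & rowSums(fm, na.rm = TRUE) >= min_species
  as_tibble(targets[keep, , drop = FALSE])
}

#' Seed-level hypergeometric enrichment of miRNA targets in discordant genes
#'
#' Tests, once per unique miRNA seed, whether the seed's conserved targets
#' are enriched among the discordant genes of a pattern relative to the
#' concordant genes: with universe `N = |discordant| + |concordant|`, `K`
#' seed targets in the universe and `n = |discordant|` draws, the p-value is
#' the upper hypergeometric tail of the observed discordant target count.
#' P-values are Bonferroni-adjusted over the number of seeds tested; seeds
#' with adjusted p below `alpha` are flagged `specific`. A permutation null
#' (random relabelling of discordant/concordant within the universe,
#' preserving set sizes) records the number of specific seeds per
#' permutation.
#'
#' Uses the current RNG state; seed the session for reproducibility.
#'
#' @param targets Conserved-filtered target table (see
#'   [filter_conserved_targets()]); restrict it to age-dependent miRNAs
#'   beforehand if desired.
#' @param discordant,concordant Disjoint gene-identifier vectors.
#' @param n_perm Number of label permutations.
#' @param n_seed_tests Bonferroni denominator (default: seeds tested).
#' @param alpha Significance level on the adjusted p.
#' @return A tibble of class `mirna_enrichment`: `seed`, `mirnas`
#'   (comma-joined members, lexicographically first is the representative),
#'   `n_targets_universe`, `n_targets_disc`, `n_targets_conc`, `p`, `p_adj`,
#'   `specific`; attribute `perm_specific_counts` holds the permutation
#'   null.
#' @export
seed_enrichment <- function(targets, discordant, concordant,
                            n_perm = 1000L, n_seed_tests = NULL,
                            alpha = 0.05) {
  dca_assert(length(intersect(discordant, concordant)) == 0,
             "gene sets must be disjoint")
  universe <- c(discordant, concordant)
  n_disc <- length(discordant)
  N <- length(universe)
  tab <- targets[targets$gene %in% universe, , drop = FALSE]
  tab <- distinct(tab[c("seed", "mirna", "gene")])
  seeds <- sort(unique(tab$seed))
  # seed x gene membership matrix
  pairs <- distinct(tab[c("seed", "gene")])
  M <- matrix(FALSE, length(seeds), N,
              dimnames = list(seeds, universe))
  M[cbind(match(pairs$seed, seeds), match(pairs$gene, universe))] <- TRUE
  K <- rowSums(M)
  keep <- K > 0
  M <- M[keep, , drop = FALSE]
  seeds <- seeds[keep]
  K <- K[keep]
  if (length(seeds) == 0) {
    warn("no seed has targets in the universe")
    return(structure(tibble(seed = character(), mirnas = character(),
                            n_targets_universe = integer(),
                            n_targets_disc = integer(),
                            n_targets_conc = integer(),
                            p = numeric(), p_adj = numeric(),
                            specific = logical()),
                     perm_specific_counts = integer(0),
                     class = c("mirna_enrichment", "tbl_df", "tbl",
                               "data.frame")))
  }
  n_seed_tests <- n_seed_tests %||% length(seeds)
  is_disc <- universe %in% discordant
  k_obs <- as.vector(M %*% is_disc)
  p <- phyper(k_obs - 1, K, N - K, n_disc, lower.tail = FALSE)
  p_adj <- pmin(1, p * n_seed_tests)
  members <- tab |>
    distinct(.data$seed, .data$mirna) |>
    group_by(.data$seed) |>
    summarise(mirnas = paste(sort(.data$mirna), collapse = ","),
              .groups = "drop")
  out <- tibble(seed = seeds,
                mirnas = members$mirnas[match(seeds, members$seed)],
                n_targets_universe = as.integer(K),
                n_targets_disc = as.integer(k_obs),
                n_targets_conc = as.integer(K - k_obs),
                p = p, p_adj = p_adj, specific = p_adj < alpha)
  perm_counts <- integer(n_perm)
  for (b in seq_len(n_perm)) {
    z <- logical(N)
    z[sample_int(N, n_disc)] <- TRUE
    kb <- as.vector(M %*% z)
    pb <- phyper(kb - 1, K, N - K, n_disc, lower.tail = FALSE)
    perm_counts[b] <- sum(pmin(1, pb * n_seed_tests) < alpha)
  }
  class(out) <- c("mirna_enrichment", class(out))
  attr(out, "perm_specific_counts") <- perm_counts
  out
}

#' Correlation-shift estimate of miRNA translational repression
#'
#' Compares the distribution of Spearman correlations between age-dependent
#' miRNA profiles and the protein profiles of their predicted targets (the
#' observed distribution) with a chance background built from `n_background`
#' draws of equally many random miRNA-gene pairs within the same discordant
#' group. The background median of the cumulative frequency curve is
#' subtracted from both observed and background curves; the group is called
#' negatively regulated (verdict `TRUE`) when the observed cumulative
#' frequency of negative correlations (at rho = 0) exceeds the 97.5%
#' quantile of the background's.
#'
#' Uses the current RNG state; seed the session for reproducibility.
#'
#' @param mirna_profiles An `interval_profiles` tibble of age-dependent
#'   miRNA expression (aging interval used).
#' @param target_profiles An `interval_profiles` tibble of protein
#'   expression for the discordant genes of the pattern.
#' @param pairs Data frame with columns `mirna`, `gene`: the predicted
#'   (conserved, seed-filtered) regulator-target pairs.
#' @param n_background Number of background replicates.
#' @param interval Which interval grid to correlate on (aging by default).
#' @return A list of class `correlation_shift`: `observed_rho`,
#'   `excess_negative` (observed minus background-median cumulative
#'   frequency at 0), `band` (background 95% band at 0), `verdict`, `p`
#'   (fraction of background replicates at least as negative-shifted), and
#'   `curves` (tibble of centred cumulative curves on a rho grid, for
#'   plotting).
#' @export
correlation_shift <- function(mirna_profiles, target_profiles, pairs,
                              n_background = 1000L,
                              interval = c("age", "dev")) {
  interval <- match.arg(interval)
  Mm <- profile_matrix(mirna_profiles, interval)
  Mt <- profile_matrix(target_profiles, interval)
  pairs <- pairs[pairs$mirna %in% rownames(Mm) &
                   pairs$gene %in% rownames(Mt), , drop = FALSE]
  n_pairs <- nrow(pairs)
  if (n_pairs < 5) {
    warn("fewer than 5 predicted pairs: verdict is NA")
    return(structure(list(observed_rho = numeric(0),
                          excess_negative = NA_real_,
                          band = c(NA_real_, NA_real_),
                          verdict = NA, p = NA_real_, curves = NULL),
                     class = "correlation_shift"))
  }
  # rank-transform once; spearman rho is then a dot product
  Rm <- t(apply(Mm, 1, rank))
  Rt <- t(apply(Mt, 1, rank))
  npt <- ncol(Rm)
  ctr <- npt * mean(seq_len(npt))^2
  den <- sum((seq_len(npt) - mean(seq_len(npt)))^2)
  rho_pairs <- function(im, it) {
    num <- rowSums(Rm[im, , drop = FALSE] * Rt[it, , drop = FALSE]) - ctr
    num / den
  }
  # midranks make the dot-product formula approximate; profiles are
  # spline-interpolated so ties are essentially absent
  obs <- rho_pairs(match(pairs$mirna, rownames(Mm)),
                   match(pairs$gene, rownames(Mt)))
  bg_f0 <- numeric(n_background)
  grid <- seq(-1, 1, by = 0.05)
  bg_curves <- matrix(0, n_background, length(grid))
  for (b in seq_len(n_background)) {
    im <- sample_int(nrow(Rm), n_pairs, replace = TRUE)
    it <- sample_int(nrow(Rt), n_pairs, replace = TRUE)
    r <- rho_pairs(im, it)
    bg_f0[b] <- mean(r < 0)
    bg_curves[b, ] <- vapply(grid, function(g) mean(r <= g), numeric(1))
  }
  obs_f0 <- mean(obs < 0)
  med0 <- median(bg_f0)
  band <- unname(quantile(bg_f0, c(0.025, 0.975)))
  verdict <- obs_f0 > band[2]
  p <- mean(bg_f0 >= obs_f0)
  med_curve <- apply(bg_curves, 2, median)
  curves <- tibble(
    rho = rep(grid, 3),
    curve = rep(c("observed", "band_lo", "band_hi"), each = length(grid)),
    value = c(vapply(grid, function(g) mean(obs <= g), numeric(1)) - med_curve,
              apply(bg_curves, 2, quantile, 0.025) - med_curve,
              apply(bg_curves, 2, quantile, 0.975) - med_curve))
  structure(list(observed_rho = obs,
                 excess_negative = obs_f0 - med0,
                 band = band - med0, verdict = verdict, p = p,
                 curves = curves, n_pairs = n_pairs),
            class = "correlation_shift")
}

#' @export
print.correlation_shift <- function(x, ...) {
  if (is.na(x$verdict)) {
    cat("<correlation_shift> verdict NA (too few pairs)\n")
  } else {
    cat(sprintf(
      "<correlation_shift> %d pairs, excess negative %.3f (band %.3f..%.3f), verdict %s (p = %.3g)\n",
      x$n_pairs, x$excess_negative, x$band[1], x$band[2], x$verdict, x$p))
  }
  invisible(x)
}

#' Age-dependent miRNAs
#'
#' Applies the polynomial age-trajectory machinery ([fit_age_models()]) to a
#' TPM miRNA matrix and returns the miRNAs whose Benjamini-Hochberg q-value
#' falls below `alpha`.
#'
#' @param mirna_expr An [expression_matrix()] of miRNA expression.
#' @param alpha q-value threshold.
#' @inheritParams fit_age_models
#' @return Character vector of age-dependent miRNA names, with the full fit
#'   table in attribute `fits`.
#' @export
age_dependent_mirnas <- function(mirna_expr, alpha = 0.05, degrees = 0:3,
                                 offset_days = 280) {
  fits <- fit_age_models(mirna_expr, degrees = degrees,
                         offset_days = offset_days)
  out <- fits$gene[fits$q < alpha]
  attr(out, "fits") <- fits
  out
}
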