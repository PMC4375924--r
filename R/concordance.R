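#' Spearman correlation between one gene's mRNA and protein profiles
#'
#' Computes the exact-permutation Spearman correlation between the two
#' interpolated interval profiles of a single gene (see [spearman_test()]).
#'
#' @param mrna_profile,protein_profile Numeric vectors of interpolated
#'   values on the same interval grid (length 10 by default).
#' @return A one-row tibble: `rho`, `p`, `n`, `method` (`"degenerate"` flags
#'   a zero-variance profile, with `rho = NA`).
#' @export
interval_correlation <- function(mrna_profile, protein_profile) {
  spearman_test(mrna_profile, protein_profile)
}

#' Per-gene interval correlations for matched profile sets
#'
#' Joins two [interpolate_profiles()] results on `gene` and computes the
#' developmental and aging Spearman correlations for every shared gene.
#'
#' @param mrna_profiles,protein_profiles `interval_profiles` tibbles.
#' @return A tibble: `gene`, `rho_dev`, `p_dev`, `rho_age`, `p_age`.
#' @export
correlate_profiles <- function(mrna_profiles, protein_profiles) {
  shared <- intersect(mrna_profiles$gene, protein_profiles$gene)
  dca_assert(length(shared) >= 1, "no shared genes between the profile sets")
  m <- mrna_profiles[match(shared, mrna_profiles$gene), , drop = FALSE]
  p <- protein_profiles[match(shared, protein_profiles$gene), , drop = FALSE]
  res_dev <- correlate_matrices(profile_matrix(m, "dev"),
                                profile_matrix(p, "dev"))
  res_age <- correlate_matrices(profile_matrix(m, "age"),
                                profile_matrix(p, "age"))
  tibble(gene = shared,
         rho_dev = res_dev$rho, p_dev = res_dev$p,
         rho_age = res_age$rho, p_age = res_age$p)
}

# row-wise exact Spearman between two aligned matrices
correlate_matrices <- function(A, B) {
  n <- ncol(A)
  RA <- t(apply(A, 1, rank))
  RB <- t(apply(B, 1, rank))
  rho <- rep(NA_real_, nrow(A))
  p <- rep(NA_real_, nrow(A))
  va <- apply(RA, 1, sd)
  vb <- apply(RB, 1, sd)
  ok <- va > 0 & vb > 0
  # untied genes take the fast shared-null path
  untied <- ok & apply(RA, 1, anyDuplicated) == 0 &
    apply(RB, 1, anyDuplicated) == 0
  if (any(untied)) {
    dist <- spearman_null_distribution(seq_len(n), seq_len(n))
    Tv <- rowSums(RA[untied, , drop = FALSE] * RB[untied, , drop = FALSE])
    r <- (Tv - n * mean(seq_len(n))^2) / sum((seq_len(n) - mean(seq_len(n)))^2)
    rho[untied] <- r
    p[untied] <- p_from_null(r, dist)
  }
  for (i in which(ok & !untied)) {
    res <- spearman_test(A[i, ], B[i, ])
    rho[i] <- res$rho
    p[i] <- res$p
  }
  list(rho = rho, p = p)
}

# exact two-sided p for each observed rho given a null distribution table
p_from_null <- function(rho, dist) {
  ord <- order(abs(dist$rho))
  cum <- rev(cumsum(rev(dist$prob[ord])))  # P(|rho_null| >= value)
  vals <- abs(dist$rho)[ord]
  idx <- findInterval(abs(rho) - 1e-12, vals) + 1
  out <- ifelse(idx > length(vals), 0, cum[pmin(idx, length(vals))])
  out
}

#' Classify genes as concordant or discordant with a permutation FDR
#'
#' A gene is called concordant when its developmental mRNA/protein
#' correlation is significantly positive and its aging correlation is
#' significantly positive, discordant when the developmental correlation is
#' significantly positive and the aging correlation significantly negative
#' (two-sided exact-permutation Spearman tests at level `alpha`); all other
#' genes are `other`. The false discovery rate of the labelling is estimated
#' by re-pairing each gene's mRNA profile with a randomly drawn other gene's
#' protein profile `n_perm` times (preserving every profile's
#' autocorrelation) and dividing the mean number of labelled genes in the
#' re-paired data by the observed number. Class labels are only reported
#' when that estimate is below `fdr`; otherwise every gene is reported as
#' `other` and the raw labels are kept in `class_raw`.
#'
#' Uses the current RNG state; seed the session for reproducibility.
#'
#' @inheritParams correlate_profiles
#' @param alpha Per-interval significance level.
#' @param fdr Permutation-FDR threshold for reporting classes.
#' @param n_perm Number of re-pairing permutations.
#' @return A tibble of class `concordance_calls`: `gene`, `rho_dev`,
#'   `p_dev`, `rho_age`, `p_age`, `class`, `class_raw`, with attributes
#'   `fdr_estimate`, `alpha`, `fdr`, `confident`.
#' @export
classify_concordance <- function(mrna_profiles, protein_profiles,
                                 alpha = 0.05, fdr = 0.05, n_perm = 1000L) {
  calls <- correlate_profiles(mrna_profiles, protein_profiles)
  sig_dev_pos <- !is.na(calls$p_dev) & calls$p_dev < alpha & calls$rho_dev > 0
  sig_age <- !is.na(calls$p_age) & calls$p_age < alpha
  class_raw <- rep("other", nrow(calls))
  class_raw[sig_dev_pos & sig_age & calls$rho_age > 0] <- "concordant"
  class_raw[sig_dev_pos & sig_age & calls$rho_age < 0] <- "discordant"
  n_obs <- sum(class_raw != "other")

  # re-pairing permutation null of the labelled-gene count
  G <- nrow(calls)
  m <- mrna_profiles[match(calls$gene, mrna_profiles$gene), , drop = FALSE]
  p <- protein_profiles[match(calls$gene, protein_profiles$gene), , drop = FALSE]
  RmD <- t(apply(profile_matrix(m, "dev"), 1, rank))
  RpD <- t(apply(profile_matrix(p, "dev"), 1, rank))
  RmA <- t(apply(profile_matrix(m, "age"), 1, rank))
  RpA <- t(apply(profile_matrix(p, "age"), 1, rank))
  npt <- ncol(RmD)
  crit <- spearman_critical_rho(npt, alpha)
  rho_of <- function(X, Y) {
    ok <- apply(X, 1, sd) > 0 & apply(Y, 1, sd) > 0
    r <- (rowSums(X * Y) - npt * mean(seq_len(npt))^2) /
      sum((seq_len(npt) - mean(seq_len(npt)))^2)
    r[!ok] <- NA_real_
    r
  }
  perm_counts <- integer(n_perm)
  if (n_perm > 0 && G >= 2) {
    for (b in seq_len(n_perm)) {
      idx <- sample_int(G, G)
      rd <- rho_of(RmD, RpD[idx, , drop = FALSE])
      ra <- rho_of(RmA, RpA[idx, , drop = FALSE])
      perm_counts[b] <- sum(!is.na(rd) & !is.na(ra) &
                              rd >= crit & abs(ra) >= crit)
    }
  }
  fdr_estimate <- if (n_obs == 0) NA_real_ else mean(perm_counts) / n_obs
  confident <- !is.na(fdr_estimate) && fdr_estimate < fdr
  calls$class <- if (confident) class_raw else rep("other", G)
  calls$class_raw <- class_raw
  class(calls) <- c("concordance_calls", class(calls))
  attr(calls, "fdr_estimate") <- fdr_estimate
  attr(calls, "alpha") <- alpha
  attr(calls, "fdr") <- fdr
  attr(calls, "confident") <- confident
  attr(calls, "perm_counts") <- perm_counts
  calls
}

#' Compare mRNA/protein coupling between the two lifespan intervals
#'
#' Reports the median developmental and aging correlation and the two-sided
#' Wilcoxon test (paired per gene by default) for the difference between the
#' two distributions.
#'
#' @param calls A `concordance_calls` tibble (or any tibble with `rho_dev`,
#'   `rho_age`).
#' @param paired Pair the test per gene (default) or compare distributions.
#' @return A one-row tibble: `median_rho_dev`, `median_rho_age`, `p`, `n`.
#' @export
compare_interval_coupling <- function(calls, paired = TRUE) {
  ok <- complete.cases(calls[c("rho_dev", "rho_age")])
  x <- calls$rho_dev[ok]
  y <- calls$rho_age[ok]
  if (length(x) < 2) {
    warn("fewer than 2 genes: Wilcoxon test skipped")
    return(tibble(median_rho_dev = median(x), median_rho_age = median(y),
                  p = NA_real_, n = length(x)))
  }
  p <- if (paired && all(x == y)) 1 else {
    suppressWarnings(wilcox.test(x, y, paired = paired)$p.value)
  }
  tibble(median_rho_dev = median(x), median_rho_age = median(y),
         p = p, n = length(x))
}

#' Chi-square test on signed significant-correlation counts per interval
#'
#' Builds the 2x2 table of significantly positive and significantly negative
#' mRNA/protein correlations in the developmental and aging intervals and
#' tests its homogeneity by a chi-square test without continuity correction.
#'
#' @inheritParams compare_interval_coupling
#' @param alpha Per-interval significance level.
#' @return A one-row tibble: `pos_dev`, `neg_dev`, `pos_age`, `neg_age`,
#'   `statistic`, `p`.
#' @export
signed_significance_counts <- function(calls, alpha = 0.05) {
  tab <- matrix(c(
    sum(calls$p_dev < alpha & calls$rho_dev > 0, na.rm = TRUE),
    sum(calls$p_dev < alpha & calls$rho_dev < 0, na.rm = TRUE),
    sum(calls$p_age < alpha & calls$rho_age > 0, na.rm = TRUE),
    sum(calls$p_age < alpha & calls$rho_age < 0, na.rm = TRUE)),
    nrow = 2, byrow = TRUE,
    dimnames = list(interval = c("dev", "age"), sign = c("pos", "neg")))
  if (sum(tab) == 0) dca_stop("no significant correlations: empty table")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) warn("expected cell count below 5; p is approximate")
  if (identical(tab["dev", ], tab["age", ])) {
    stat <- 0; pval <- 1
  } else {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    stat <- unname(ct$statistic); pval <- ct$p.value
  }
  tibble(pos_dev = tab[1, 1], neg_dev = tab[1, 2],
         pos_age = tab[2, 1], neg_age = tab[2, 2],
         statistic = stat, p = pval)
}

#' Per-gene expression variability within each lifespan interval
#'
#' Computes the per-gene standard deviation and coefficient of variation
#' over the samples of the developmental and of the aging interval, and
#' compares the two intervals by paired Wilcoxon tests.
#'
#' @param expr An [expression_matrix()].
#' @param maturity_days Interval boundary in days.
#' @return A tibble of class `interval_variability`: `gene`, `sd_dev`,
#'   `sd_age`, `cv_dev`, `cv_age` (`NA` when an interval has fewer than two
#'   samples), with attribute `tests` (a tibble with Wilcoxon p per metric).
#' @export
interval_variability <- function(expr, maturity_days) {
  v <- em_values(expr)
  dev <- em_ages(expr) < maturity_days
  stat <- function(cols) {
    if (sum(cols) < 2) {
      return(list(sd = rep(NA_real_, nrow(v)), cv = rep(NA_real_, nrow(v))))
    }
    m <- v[, cols, drop = FALSE]
    mu <- rowMeans(m)
    sdv <- unname(apply(m, 1, sd))
    list(sd = sdv, cv = unname(ifelse(mu > 0, sdv / unname(mu), NA_real_)))
  }
  d <- stat(dev); a <- stat(!dev)
  out <- tibble(gene = expr$gene, sd_dev = d$sd, sd_age = a$sd,
                cv_dev = d$cv, cv_age = a$cv)
  wtest <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 2) return(NA_real_)
    if (all(x[ok] == y[ok])) return(1)
    suppressWarnings(wilcox.test(x[ok], y[ok], paired = TRUE)$p.value)
  }
  attr(out, "tests") <- tibble(
    metric = c("sd", "cv"),
    median_dev = c(median(d$sd, na.rm = TRUE), median(d$cv, na.rm = TRUE)),
    median_age = c(median(a$sd, na.rm = TRUE), median(a$cv, na.rm = TRUE)),
    p = c(wtest(d$sd, a$sd), wtest(d$cv, a$cv)))
  class(out) <- c("interval_variability", class(out))
  out
}
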