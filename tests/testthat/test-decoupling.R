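mk_profiles <- function(mat_dev, mat_age, genes = NULL) {
  genes <- genes %||% sprintf("g%03d", seq_len(nrow(mat_dev)))
  m <- cbind(mat_dev, mat_age)
  colnames(m) <- c(paste0("dev_", 1:10), paste0("age_", 1:10))
  tb <- dplyr::bind_cols(tibble::tibble(gene = genes),
                         tibble::as_tibble(m, .name_repair = "minimal"))
  class(tb) <- c("interval_profiles", class(tb))
  attr(tb, "dev_grid") <- seq(4, 9.33, length.out = 10)
  attr(tb, "age_grid") <- seq(9.33, 13.8, length.out = 10)
  tb
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("classification rules follow the class definitions", {
  set.seed(2)
  base <- t(replicate(3, sort(rnorm(10))))
  # gene 1 concordant, gene 2 discordant, gene 3 uncoupled (noise profile)
  m <- mk_profiles(base, base)
  noise <- matrix(rnorm(10), 1)
  p <- mk_profiles(base, rbind(base[1, , drop = FALSE],
                               -base[2, , drop = FALSE],
                               noise)[c(1, 2, 3), , drop = FALSE])
  calls <- classify_concordance(m, p, n_perm = 50)
  expect_identical(calls$class_raw[1], "concordant")
  expect_identical(calls$class_raw[2], "discordant")
  # development coupling not significant -> other regardless of aging
  m2 <- mk_profiles(matrix(rnorm(10), 1), matrix(1:10, 1))
  p2 <- mk_profiles(matrix(rnorm(10), 1), matrix(1:10, 1))
  calls2 <- classify_concordance(m2, p2, n_perm = 10)
  if (calls2$p_dev >= 0.05) expect_identical(calls2$class_raw, "other")
})

test_that("null profile sets are suppressed by the permutation FDR gate", {
  set.seed(14)
  G <- 120
  smooth_mat <- function() {
    t(replicate(G, splinefun(seq(0, 1, length.out = 4), rnorm(4))(
      seq(0, 1, length.out = 10))))
  }
  m <- mk_profiles(smooth_mat(), smooth_mat())
  p <- mk_profiles(smooth_mat(), smooth_mat())
  calls <- classify_concordance(m, p, n_perm = 200)
  fdr <- attr(calls, "fdr_estimate")
  if (!is.na(fdr)) expect_gte(fdr, 0.05)
  expect_true(all(calls$class == "other"))
})

test_that("planted decoupling lowers the aging median (paired Wilcoxon)", {
  set.seed(20)
  cfg <- simulation_config(n_genes = 2000, seed = 20)
  run <- suppressMessages(synthetic_decoupling_run(cfg, n_perm = 30))
  expect_gt(run$coupling$median_rho_dev, run$coupling$median_rho_age)
  expect_lt(run$coupling$p, 0.001)
})

test_that("interval coupling comparison handles degenerate inputs", {
  calls <- tibble::tibble(rho_dev = c(0.5, 0.7), rho_age = c(0.5, 0.7))
  expect_equal(compare_interval_coupling(calls)$p, 1)
  one <- tibble::tibble(rho_dev = 0.5, rho_age = 0.1)
  expect_warning(res <- compare_interval_coupling(one), "fewer than 2")
  expect_true(is.na(res$p))
})

test_that("signed significance counts give the hand-computed chi-square", {
  # table ((90,10),(50,50)): statistic = sum (O-E)^2/E
  tab <- matrix(c(90, 10, 50, 50), nrow = 2, byrow = TRUE)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat_hand <- sum((tab - E)^2 / E)
  calls <- tibble::tibble(
    rho_dev = c(rep(1, 90), rep(-1, 10), rep(0, 100)),
    p_dev = c(rep(0.01, 100), rep(0.01, 100)),
    rho_age = c(rep(0, 100), rep(1, 50), rep(-1, 50)),
    p_age = c(rep(0.5, 100), rep(0.01, 100)))
  # dev: 90 pos / 10 neg significant; age: 50 / 50
  res <- signed_significance_counts(calls)
  expect_equal(res$statistic, stat_hand, tolerance = 1e-12)
  expect_equal(res$p, pchisq(stat_hand, 1, lower.tail = FALSE))
  # identical counts give p = 1
  same <- tibble::tibble(rho_dev = c(1, -1), p_dev = c(0.01, 0.01),
                         rho_age = c(1, -1), p_age = c(0.01, 0.01))
  expect_warning(res2 <- signed_significance_counts(same), "below 5")
  expect_equal(res2$p, 1)
  none <- tibble::tibble(rho_dev = 1, p_dev = 0.9, rho_age = 1, p_age = 0.9)
  expect_error(signed_significance_counts(none), "empty")
})

test_that("interval variability computes SD and CV with scale properties", {
  tb <- tibble::tibble(gene = c("g1", "g2"),
                       a = c(2, 1), b = c(2, 2), c = c(2, 3),
                       d = c(5, 2), e = c(5, 4), f = c(5, 6))
  em <- expression_matrix(tb, c(a = 100, b = 200, c = 300,
                                d = 8000, e = 9000, f = 10000))
  v <- interval_variability(em, maturity_days = 7300)
  expect_equal(v$sd_dev[1], 0)
  expect_equal(v$cv_dev[1], 0)
  expect_equal(v$sd_dev[2], 1)       # sample SD of (1,2,3)
  expect_equal(v$cv_dev[2], 0.5)
  # doubling values doubles SD, leaves CV unchanged
  tb2 <- dplyr::mutate(tb, dplyr::across(-gene, ~ .x * 2))
  em2 <- expression_matrix(tb2, em_ages(em))
  v2 <- interval_variability(em2, maturity_days = 7300)
  expect_equal(v2$sd_dev, v$sd_dev * 2)
  expect_equal(v2$cv_dev, v$cv_dev)
  expect_s3_class(glance(v), "tbl_df")
})

test_that("equalized subsampling matches stratifier histograms per round", {
  set.seed(30)
  G <- 80
  calls <- tibble::tibble(gene = sprintf("g%03d", 1:G),
                          rho_dev = runif(G, 0.3, 1),
                          rho_age = runif(G, -1, 0.5))
  strat_same <- tibble::tibble(gene = calls$gene, dev = runif(G),
                               age = NA_real_)
  strat_same$age <- strat_same$dev
  # identical stratifiers: subsample is (almost) the full set each round
  out <- equalized_subsample(calls, strat_same, n_rounds = 3)
  expect_true(all(out$n >= G - 10))
  # single round returns a single p
  out1 <- equalized_subsample(calls, strat_same, n_rounds = 1)
  expect_equal(nrow(out1), 1)
  # disjoint supports abort
  strat_bad <- tibble::tibble(gene = calls$gene, dev = runif(G, 0, 1),
                              age = runif(G, 5, 6))
  expect_error(equalized_subsample(calls, strat_bad, n_rounds = 1),
               "common support")
})

test_that("planted decoupling survives stratifier equalization", {
  set.seed(31)
  cfg <- simulation_config(n_genes = 2000, seed = 31)
  run <- suppressMessages(synthetic_decoupling_run(cfg, n_perm = 10))
  strat <- gene_stratifiers(run$profiles_mrna, "sd")
  rounds <- equalized_subsample(run$calls, strat, n_rounds = 40)
  expect_gt(mean(rounds$p < 0.05, na.rm = TRUE), 0.95)
})

test_that("gene stratifiers compute the documented statistics", {
  prof <- mk_profiles(matrix(1:10, 1), matrix(seq(2, 20, by = 2), 1))
  st <- gene_stratifiers(prof, "amplitude")
  expect_equal(st$dev, 9)
  expect_equal(st$age, 18)
  stm <- gene_stratifiers(prof, "mean")
  expect_equal(stm$dev, 5.5)
})

test_that("overlap permutation reproduces set arithmetic and the null mean", {
  set.seed(40)
  uni <- sprintf("g%03d", 1:100)
  a <- uni[1:30]
  b <- uni[21:50]
  res <- overlap_permutation(a, b, uni, uni, n_perm = 400)
  expect_equal(res$observed, length(intersect(a, b)))
  # hypergeometric expectation |A||B|/N
  expect_equal(mean(res$permuted), 30 * 30 / 100, tolerance = 0.15)
  # A = B = universe: every permutation gives the full overlap, p = 1
  res2 <- overlap_permutation(uni, uni, uni, uni, n_perm = 50)
  expect_equal(res2$observed, 100)
  expect_true(all(res2$permuted == 100))
  expect_equal(res2$p, 1)
})

test_that("strongly overlapping sets are detected against the null", {
  set.seed(41)
  uni_a <- sprintf("a%03d", 1:200)
  uni_b <- c(uni_a[1:100], sprintf("b%03d", 1:100))
  shared <- uni_a[1:40]
  a <- c(shared, uni_a[101:140])
  b <- c(shared, uni_b[141:180])
  res <- overlap_permutation(a, b, uni_a, uni_b, n_perm = 1000)
  expect_lt(res$p, 0.005)
  expect_true(res$significant)
  expect_s3_class(tidy(res), "tbl_df")
})
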