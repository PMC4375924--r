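test_that("conservation filter applies the 3-of-4-species rule", {
  tab <- tibble::tibble(
    mirna = paste0("m", 1:4), seed = paste0("s", 1:4),
    gene = paste0("g", 1:4),
    cons_mouse = c(TRUE, TRUE, TRUE, NA),
    cons_rat = c(TRUE, TRUE, TRUE, TRUE),
    cons_dog = c(TRUE, FALSE, TRUE, TRUE),
    cons_chicken = c(FALSE, FALSE, TRUE, TRUE))
  expect_warning(out <- filter_conserved_targets(tab), "missing")
  expect_identical(out$mirna, c("m1", "m3"))   # 3-of-4 and 4-of-4 kept
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  # universe of 10 genes, 4 discordant; seed targets 4 genes, 3 discordant
  disc <- paste0("d", 1:4)
  conc <- paste0("c", 1:6)
  tab <- tibble::tibble(
    mirna = "mA", seed = "SEED1",
    gene = c("d1", "d2", "d3", "c1"),
    cons_mouse = TRUE, cons_rat = TRUE, cons_dog = TRUE, cons_chicken = TRUE)
  res <- seed_enrichment(tab, disc, conc, n_perm = 50)
  expect_equal(res$p, brute_hyper_upper(3, 10, 4, 4), tolerance = 1e-12)
  expect_equal(res$n_targets_disc, 3L)
  # a seed targeting every gene cannot be enriched
  tab2 <- tibble::tibble(
    mirna = "mB", seed = "SEED2", gene = c(disc, conc),
    cons_mouse = TRUE, cons_rat = TRUE, cons_dog = TRUE, cons_chicken = TRUE)
  res2 <- seed_enrichment(tab2, disc, conc, n_perm = 10)
  expect_equal(res2$p, 1)
})

test_that("exactly one test is run per unique seed", {
  disc <- paste0("d", 1:5)
  conc <- paste0("c", 1:5)
  tab <- tibble::tibble(
    mirna = c("mA", "mA2", "mB"), seed = c("S1", "S1", "S2"),
    gene = c("d1", "d2", "d3"),
    cons_mouse = TRUE, cons_rat = TRUE, cons_dog = TRUE, cons_chicken = TRUE)
  res <- seed_enrichment(tab, disc, conc, n_perm = 10)
  expect_equal(nrow(res), 2)
  expect_setequal(res$seed, c("S1", "S2"))
  expect_identical(res$mirnas[res$seed == "S1"], "mA,mA2")
})

test_that("planted-specific seeds are flagged and the permutation null is calibrated", {
  cfg <- simulation_config(n_genes = 500, seed = 17)
  sim <- simulate_trajectories(cfg)
  reg <- simulate_regulators(cfg, sim)
  targ <- filter_conserved_targets(reg$mirna_targets)
  agedep <- reg$mirna_truth$mirna[reg$mirna_truth$age_dependent]
  targ <- targ[targ$mirna %in% agedep, ]
  pat <- "P1"
  disc <- sim$truth$gene[sim$truth$pattern == pat & sim$truth$class == "discordant"]
  conc <- sim$truth$gene[sim$truth$pattern == pat & sim$truth$class == "concordant"]
  set.seed(18)
  res <- seed_enrichment(targ, disc, conc, n_perm = 300)
  planted <- reg$mirna_truth$seed[!is.na(reg$mirna_truth$pattern) &
                                    reg$mirna_truth$pattern == pat]
  expect_true(all(planted %in% res$seed[res$specific]))
  # permutation null sees far fewer specific seeds than observed
  perm <- attr(res, "perm_specific_counts")
  expect_lt(mean(perm), sum(res$specific))
  expect_lte(stats::quantile(perm, 0.95), sum(res$specific))
})

test_that("correlation shift calls planted repression and only that", {
  cfg <- simulation_config(n_genes = 500, seed = 19)
  sim <- simulate_trajectories(cfg)
  reg <- simulate_regulators(cfg, sim)
  targ <- filter_conserved_targets(reg$mirna_targets)
  agedep <- reg$mirna_truth$mirna[reg$mirna_truth$age_dependent]
  targ <- targ[targ$mirna %in% agedep, ]
  mir_prof <- reg$latent_mirna[reg$latent_mirna$gene %in% agedep, ]
  set.seed(20)
  verdicts <- sapply(paste0("P", 1:4), function(p) {
    disc <- sim$truth$gene[sim$truth$pattern == p & sim$truth$class == "discordant"]
    pairs <- targ[targ$gene %in% disc, c("mirna", "gene")]
    cs <- correlation_shift(mir_prof,
                            sim$latent_protein[sim$latent_protein$gene %in% disc, ],
                            pairs, n_background = 300)
    cs$verdict
  })
  expect_true(verdicts[[cfg$repressed_pattern]])
  expect_false(any(verdicts[setdiff(paste0("P", 1:4), cfg$repressed_pattern)]))
})

test_that("too few pairs yield an NA verdict with a warning", {
  prof <- function(n, prefix) {
    tb <- dplyr::bind_cols(
      tibble::tibble(gene = paste0(prefix, seq_len(n))),
      tibble::as_tibble(matrix(rnorm(20 * n), n), .name_repair = "minimal"))
    names(tb) <- c("gene", paste0("dev_", 1:10), paste0("age_", 1:10))
    class(tb) <- c("interval_profiles", class(tb))
    tb
  }
  set.seed(21)
  expect_warning(
    cs <- correlation_shift(prof(3, "m"), prof(5, "g"),
                            tibble::tibble(mirna = "m1", gene = "g1")),
    "fewer than 5")
  expect_true(is.na(cs$verdict))
})

test_that("random pairs are not called repressed", {
  set.seed(22)
  prof <- function(n, prefix) {
    tb <- dplyr::bind_cols(
      tibble::tibble(gene = paste0(prefix, seq_len(n))),
      tibble::as_tibble(t(replicate(n, sort(rnorm(10))[sample(10)])) |>
                          cbind(t(replicate(n, rnorm(10)))),
                        .name_repair = "minimal"))
    names(tb) <- c("gene", paste0("dev_", 1:10), paste0("age_", 1:10))
    class(tb) <- c("interval_profiles", class(tb))
    tb
  }
  mir <- prof(20, "m")
  tgt <- prof(30, "g")
  hits <- 0
  for (i in 1:10) {
    pairs <- tibble::tibble(mirna = sample(mir$gene, 12, replace = TRUE),
                            gene = sample(tgt$gene, 12, replace = TRUE))
    cs <- correlation_shift(mir, tgt, pairs, n_background = 200)
    hits <- hits + isTRUE(cs$verdict)
  }
  expect_lte(hits, 1)   # the observed set is itself a background draw
})

test_that("age-dependent miRNA detection separates trends from nulls", {
  set.seed(23)
  m <- 12
  ages <- sort(runif(m, 30, 3.4e4))
  s <- scale_age(ages)
  n_null <- 150
  vals <- rbind(2^(6 + 2 * (s - min(s)) / diff(range(s))),   # increasing
                2^6 * matrix(2^rnorm(n_null * m, 0, 0.3), n_null))
  tb <- dplyr::bind_cols(
    tibble::tibble(gene = c("up", sprintf("n%03d", seq_len(n_null)))),
    tibble::as_tibble(vals, .name_repair = "minimal"))
  names(tb) <- c("gene", paste0("s", 1:m))
  em <- expression_matrix(tb, setNames(ages, paste0("s", 1:m)), unit = "TPM")
  hits <- age_dependent_mirnas(em)
  expect_true("up" %in% hits)
  expect_lte(mean(sprintf("n%03d", seq_len(n_null)) %in% hits), 0.075)
})
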