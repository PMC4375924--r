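cfg_small <- function(seed = 7, n_genes = 60, ...) {
  simulation_config(n_genes = n_genes, n_samples_rna = 12,
                    n_samples_protein = 10, n_samples_mirna = 10,
                    n_mirnas = 40, seed = seed, ...)
}

test_that("configuration validation rejects impossible designs", {
  expect_error(simulation_config(n_genes = 5), "at least 8")
  expect_error(simulation_config(pattern_fractions = c(0.3, 0.3, 0.3, 0.3)),
               "summing to 1")
  expect_error(simulation_config(maturity_age_days = 5e4), "smaller than")
  expect_warning(simulation_config(site_rate_discordant = 0.2,
                                   site_rate_concordant = 0.5),
                 "no planted RBP signal")
})

test_that("identical config and seed reproduce bit-identical outputs", {
  s1 <- simulate_trajectories(cfg_small())
  s2 <- simulate_trajectories(cfg_small())
  expect_identical(em_values(s1$mrna), em_values(s2$mrna))
  expect_identical(em_values(s1$protein_spc), em_values(s2$protein_spc))
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_trajectories(cfg_small(seed = 8))
  expect_false(identical(em_values(s1$mrna), em_values(s3$mrna)))
})

test_that("every pattern x coupling cell is populated and labels unique", {
  sim <- simulate_trajectories(cfg_small())
  expect_equal(nrow(sim$truth), 60)
  expect_false(anyDuplicated(sim$truth$gene) > 0)
  tab <- table(sim$truth$pattern, sim$truth$class)
  for (p in paste0("P", 1:4)) {
    expect_gte(tab[p, "concordant"], 1)
    expect_gte(tab[p, "discordant"], 1)
  }
})

test_that("noiseless latent trajectories realise the planted rank structure", {
  sim <- simulate_trajectories(cfg_small(noise_cv = 0))
  lat <- correlate_profiles(sim$latent_mrna, sim$latent_protein)
  df <- dplyr::inner_join(lat, sim$truth, by = "gene")
  conc <- df[df$class == "concordant", ]
  disc <- df[df$class == "discordant", ]
  expect_true(all(conc$rho_dev == 1 & conc$rho_age == 1))
  expect_true(all(disc$rho_dev == 1))
  expect_true(all(disc$rho_age == -1))
})

test_that("P1/P3 latent mRNA trajectories are strictly monotone", {
  sim <- simulate_trajectories(cfg_small(noise_cv = 0))
  m <- cbind(decoupleage:::profile_matrix(sim$latent_mrna, "dev"),
             decoupleage:::profile_matrix(sim$latent_mrna, "age"))
  m <- m[, c(1:10, 12:20)]   # the maturity point appears on both grids
  for (p in c("P1", "P3")) {
    genes <- sim$truth$gene[sim$truth$pattern == p]
    sgn <- if (p == "P1") -1 else 1
    for (g in genes) {
      expect_true(all(sgn * diff(m[g, ]) > 0), label = paste(p, g))
    }
  }
})

test_that("read-count model hits its specified mean", {
  sim <- simulate_trajectories(cfg_small())
  mu <- sim$mu_mrna
  # redraw the count layer many times for a handful of cells
  set.seed(99)
  for (cell in list(c(1, 1), c(10, 5), c(25, 12))) {
    m <- mu[cell[1], cell[2]]
    draws <- rnbinom(10000, mu = m, size = 1 / sim$config$nb_dispersion)
    expect_lt(abs(mean(draws) - m) / m, 0.05)
  }
  # totals are close to the configured depth
  expect_lt(abs(mean(colSums(mu)) / sim$config$seq_depth - 1), 0.3)
})

test_that("planted RBP site rates separate discordant from concordant", {
  cfg <- cfg_small(n_genes = 200)
  sim <- simulate_trajectories(cfg)
  reg <- simulate_regulators(cfg, sim)
  truthmap <- setNames(reg$rbp_truth$pattern, reg$rbp_truth$rbp)
  enriched <- names(truthmap)[!is.na(truthmap)][1]
  pat <- truthmap[[enriched]]
  disc <- sim$truth$gene[sim$truth$pattern == pat & sim$truth$class == "discordant"]
  conc <- sim$truth$gene[sim$truth$pattern == pat & sim$truth$class == "concordant"]
  cd <- decoupleage:::site_counts_for(reg$site_map, enriched, disc)
  cc <- decoupleage:::site_counts_for(reg$site_map, enriched, conc)
  expect_gt(mean(cd), mean(cc))
  # a null RBP has background rates on both sets
  nullr <- names(truthmap)[is.na(truthmap)][1]
  cn <- decoupleage:::site_counts_for(reg$site_map, nullr,
                                      c(disc, conc))
  expect_lt(mean(cn), 2 * cfg$site_rate_concordant + 1)
})

test_that("a Poisson tail bound separates the planted site rates", {
  # mean site count over 100 discordant genes at rate 5 exceeds the mean
  # over 100 concordant genes at rate 0.5 with probability > 0.999:
  # direct summation of the Poisson-difference tail via simulation-free
  # normal-free enumeration on the total counts
  n <- 100
  lam_d <- 5 * n
  lam_c <- 0.5 * n
  # P(sum_d <= sum_c) <= sum_k P(D = k) P(C >= k); truncate far in the tail
  ks <- 0:1200
  p_cross <- sum(dpois(ks, lam_d) * ppois(ks - 1, lam_c, lower.tail = FALSE))
  expect_lt(p_cross, 0.001)
})

test_that("planted repression: specific miRNA anti-correlates with targets", {
  cfg <- cfg_small(n_genes = 200, noise_cv = 0)
  sim <- simulate_trajectories(cfg)
  reg <- simulate_regulators(cfg, sim)
  spec <- reg$mirna_truth[!is.na(reg$mirna_truth$pattern) &
                            reg$mirna_truth$pattern == cfg$repressed_pattern, ]
  disc <- sim$truth$gene[sim$truth$pattern == cfg$repressed_pattern &
                           sim$truth$class == "discordant"]
  mm <- decoupleage:::profile_matrix(reg$latent_mirna, "age")
  pp <- decoupleage:::profile_matrix(sim$latent_protein, "age")
  for (mi in spec$mirna) {
    for (g in head(disc, 3)) {
      expect_equal(cor(mm[mi, ], pp[g, ], method = "spearman"), -1)
    }
  }
})

test_that("regulator simulation is deterministic given config and sim", {
  cfg <- cfg_small(n_genes = 100)
  sim <- simulate_trajectories(cfg)
  r1 <- simulate_regulators(cfg, sim)
  r2 <- simulate_regulators(cfg, sim)
  expect_identical(r1$sites, r2$sites)
  expect_identical(r1$mirna_targets, r2$mirna_targets)
})

test_that("planted conserved targets pass the 3-of-4 rule", {
  cfg <- cfg_small(n_genes = 200)
  sim <- simulate_trajectories(cfg)
  reg <- simulate_regulators(cfg, sim)
  spec <- reg$mirna_truth[!is.na(reg$mirna_truth$pattern), ]
  for (i in seq_len(nrow(spec))) {
    disc <- sim$truth$gene[sim$truth$pattern == spec$pattern[i] &
                             sim$truth$class == "discordant"]
    own <- reg$mirna_targets[reg$mirna_targets$mirna == spec$mirna[i] &
                               reg$mirna_targets$gene %in% disc, ]
    if (nrow(own) > 0) {
      flags <- as.matrix(own[c("cons_mouse", "cons_rat", "cons_dog",
                               "cons_chicken")])
      expect_true(all(rowSums(flags) >= 3))
    }
  }
})
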