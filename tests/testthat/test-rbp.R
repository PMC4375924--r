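# two genes on one chromosome with known exon structures (0-based half-open)
toy_annotation <- function() {
  tibble::tibble(
    gene = c("gA", "gA", "gB", "gB"),
    chrom = "chr1",
    start = c(100, 150, 1000, 1500),
    end = c(200, 300, 1200, 1800))
}

test_that("exon unions merge overlaps and sites need full containment", {
  ann <- toy_annotation()
  sites <- tibble::tibble(
    rbp = "R1",
    chrom = "chr1",
    start = c(120, 195, 1100, 1450, 210),
    end = c(130, 205, 1110, 1460, 220))
  suppressMessages(map <- build_exonic_sites(sites, ann))
  # gA exons [100,200) and [150,300) merge to [100,300): union length 200
  lens <- setNames(map$exon_lengths$exon_union_bp, map$exon_lengths$gene)
  expect_equal(unname(lens["gA"]), 200)
  expect_equal(unname(lens["gB"]), 500)
  # [120,130) inside the union; [195,205) inside merged gA (no junction
  # there after merging); [1100,1110) in gB; [1450,1460) intronic -> dropped;
  # [210,220) inside merged gA
  expect_equal(sum(map$sites$gene == "gA"), 3)
  expect_equal(sum(map$sites$gene == "gB"), 1)
  expect_equal(map$n_dropped, 1)
})

test_that("junction-spanning sites are dropped for unmerged exons", {
  ann <- tibble::tibble(gene = c("gC", "gC"), chrom = "chr1",
                        start = c(100, 250), end = c(200, 300))
  sites <- tibble::tibble(rbp = "R1", chrom = "chr1",
                          start = c(195, 120), end = c(205, 130))
  suppressMessages(map <- build_exonic_sites(sites, ann))
  expect_equal(nrow(map$sites), 1)        # only [120,130)
  expect_equal(map$sites$start, 120)
})

test_that("sites on unknown chromosomes are dropped with a message", {
  ann <- toy_annotation()
  sites <- tibble::tibble(rbp = "R1", chrom = c("chr1", "chrUn"),
                          start = c(120, 5), end = c(130, 15))
  expect_message(map <- build_exonic_sites(sites, ann), "unannotated")
  expect_equal(nrow(map$sites), 1)
})

test_that("BED/GTF round trip reproduces the in-memory site map", {
  cfg <- simulation_config(n_genes = 60, seed = 9)
  sim <- simulate_trajectories(cfg)
  reg <- simulate_regulators(cfg, sim)
  bed <- withr::local_tempfile(fileext = ".bed")
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_sites_bed(reg$sites, bed)
  write_annotation_gtf(reg$annotation, gtf)
  suppressMessages(map <- build_exonic_sites(bed, gtf))
  # the exonic subset is recovered exactly (decoys dropped by containment)
  got <- dplyr::arrange(map$sites, rbp, gene, start)
  want <- dplyr::arrange(reg$site_map$sites, rbp, gene, start)
  expect_equal(got$start, want$start)
  expect_equal(got$gene, want$gene)
  expect_equal(nrow(got), nrow(want))
  # exon union lengths equal the simulated gene lengths
  lens <- dplyr::inner_join(map$exon_lengths, sim$gene_lengths, by = "gene")
  expect_equal(lens$exon_union_bp, lens$length_bp)
})

test_that("binomial condition matches the direct-summation oracle", {
  # 10 of 13 discordant genes targeted vs concordant fraction 0.3
  p_oracle <- brute_binom_upper(10, 13, 0.3)
  expect_equal(pbinom(9, 13, 0.3, lower.tail = FALSE), p_oracle,
               tolerance = 1e-12)
  # build a map realising exactly that configuration
  disc <- sprintf("d%02d", 1:13)
  conc <- sprintf("c%02d", 1:10)
  sites <- tibble::tibble(rbp = "R1", gene = c(disc[1:10], conc[1:3]),
                          chrom = "chr1", start = 0, end = 10)
  map <- structure(list(
    sites = sites,
    exon_lengths = tibble::tibble(gene = c(disc, conc), exon_union_bp = 1000),
    n_dropped = 0L), class = "binding_site_map")
  res <- suppressMessages(key_regulator_test(map, disc, conc, n_rbp_tests = 1,
                                             reference = "concordant"))
  expect_equal(res$p_binom, p_oracle, tolerance = 1e-10)
  expect_equal(res$frac_targeted, 10 / 13)
  # the default pooled reference tests against the combined fraction
  res_p <- suppressMessages(key_regulator_test(map, disc, conc,
                                               n_rbp_tests = 1))
  expect_equal(res_p$p_binom, brute_binom_upper(10, 13, 13 / 23),
               tolerance = 1e-10)
})

test_that("rank-sum conditions agree with a brute-force rank computation", {
  set.seed(12)
  cd <- rnorm(9, 2)      # tie-free densities keep the test exact
  cc <- rnorm(11)
  # brute-force one-sided rank-sum p by enumeration over group assignments
  pooled <- c(cd, cc)
  r_obs <- sum(rank(pooled)[seq_along(cd)])
  combs <- combn(20, 9)
  rs <- apply(combs, 2, function(idx) sum(rank(pooled)[idx]))
  p_brute <- mean(rs >= r_obs - 1e-9)
  p_pkg <- decoupleage:::one_sided_wilcox(cd, cc)
  expect_equal(p_pkg, p_brute, tolerance = 1e-10)
})

test_that("planted enrichment is flagged and null distributions are not", {
  cfg <- simulation_config(n_genes = 300, seed = 13)
  sim <- simulate_trajectories(cfg)
  reg <- simulate_regulators(cfg, sim)
  truthmap <- setNames(reg$rbp_truth$pattern, reg$rbp_truth$rbp)
  pat <- truthmap[[which(!is.na(truthmap))[1]]]
  planted_rbp <- names(truthmap)[which(!is.na(truthmap))[1]]
  disc <- sim$truth$gene[sim$truth$pattern == pat & sim$truth$class == "discordant"]
  conc <- sim$truth$gene[sim$truth$pattern == pat & sim$truth$class == "concordant"]
  res <- suppressMessages(key_regulator_test(reg$site_map, disc, conc,
                                             pattern = pat))
  expect_true(res$key[res$rbp == planted_rbp])
  expect_gt(res$fold_change[res$rbp == planted_rbp], 2)
  # identical distributions in both sets: no key flag expected
  set.seed(14)
  same <- tibble::tibble(rbp = "R0",
                         gene = sample(c(disc, conc), 40, replace = TRUE),
                         chrom = "chr1", start = 0, end = 10)
  map0 <- structure(list(
    sites = same,
    exon_lengths = tibble::tibble(gene = c(disc, conc), exon_union_bp = 1000),
    n_dropped = 0L), class = "binding_site_map")
  res0 <- suppressMessages(key_regulator_test(map0, disc, conc,
                                              n_rbp_tests = 1))
  expect_gt(res0$p_count, 0.05)
})

test_that("regulator-target correlation recovers planted repression", {
  prof <- function(vals) {
    tb <- dplyr::bind_cols(
      tibble::tibble(gene = sprintf("t%02d", seq_len(nrow(vals)))),
      tibble::as_tibble(cbind(vals, vals), .name_repair = "minimal"))
    names(tb) <- c("gene", paste0("dev_", 1:10), paste0("age_", 1:10))
    class(tb) <- c("interval_profiles", class(tb))
    tb
  }
  base <- sort(rnorm(10))
  targets <- prof(rbind(base, base + 1, 2 * base))
  res <- regulator_target_correlation(base, targets)
  expect_equal(res$rho_protein, rep(1, 3))
  rev_res <- regulator_target_correlation(rev(base), targets)
  expect_equal(rev_res$rho_protein, rep(-1, 3))
  set.seed(15)
  noisy <- prof(t(replicate(12, -base + rnorm(10, sd = 0.2))))
  rr <- regulator_target_correlation(base, noisy)
  expect_lt(median(rr$rho_protein), 0)
  expect_gt(mean(rr$p_protein < 0.05), 0.8)
})

test_that("site-count comparison across patterns detects a planted excess", {
  set.seed(16)
  pats <- list(P1 = sprintf("a%02d", 1:15), P2 = sprintf("b%02d", 1:15),
               P3 = sprintf("c%02d", 1:15), P4 = sprintf("d%02d", 1:15))
  mk_map <- function(counts_by_pattern) {
    rows <- do.call(rbind, lapply(names(pats), function(p) {
      genes <- rep(pats[[p]], counts_by_pattern[[p]])
      if (length(genes) == 0) return(NULL)
      data.frame(rbp = "AGO2", gene = genes, chrom = "chr1",
                 start = 0, end = 10)
    }))
    structure(list(sites = tibble::as_tibble(rows),
                   exon_lengths = tibble::tibble(gene = unlist(pats),
                                                 exon_union_bp = 1000),
                   n_dropped = 0L), class = "binding_site_map")
  }
  excess <- mk_map(list(P1 = rpois(15, 1), P2 = rpois(15, 1),
                        P3 = rpois(15, 5), P4 = rpois(15, 1)))
  res <- compare_site_counts_across_patterns(excess, "AGO2", pats, "P3",
                                             n_boot = 200)
  expect_lt(res$p, 0.05)
  expect_gt(res$observed$mean_count[res$observed$pattern == "P3"],
            max(res$observed$mean_count[res$observed$pattern != "P3"]))
  flat <- mk_map(list(P1 = rpois(15, 2), P2 = rpois(15, 2),
                      P3 = rpois(15, 2), P4 = rpois(15, 2)))
  res2 <- compare_site_counts_across_patterns(flat, "AGO2", pats, "P3",
                                              n_boot = 100)
  expect_gt(res2$p, 0.05)
  # bootstrap means concentrate around the sample mean
  b3 <- res$bootstrap[res$bootstrap$pattern == "P3", ]
  expect_equal(mean(b3$mean_count),
               res$observed$mean_count[res$observed$pattern == "P3"],
               tolerance = 0.15)
})
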