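#' Simulate RBP binding sites and miRNA regulation on top of a trajectory sim
#'
#' Builds a toy genome annotation (2-4 exons per gene whose union length
#' equals the simulated exonic gene length), then plants the regulator
#' structure: each planted-enriched RBP receives
#' `Poisson(site_rate_discordant)` exonic sites per discordant gene of its
#' pattern and `Poisson(site_rate_concordant)` per other gene (null RBPs get
#' the background rate everywhere), plus intronic/junction decoy sites that
#' the exonic filter must remove. Planted-specific miRNAs target the
#' discordant genes of their pattern with elevated probability and carry
#' conservation flags passing the 3-of-4-species rule; the specific miRNAs
#' of `config$repressed_pattern` additionally get aging expression trends
#' opposite to their targets' protein trend, planting the
#' translational-repression signal in that pattern only.
#'
#' @param config The [simulation_config()] used for the trajectory run.
#' @param sim The `decouple_sim` returned by [simulate_trajectories()] (it
#'   carries the planted truth and the gene lengths).
#' @return A list of class `decouple_regulators`: `annotation` (exon table),
#'   `sites` (all simulated sites with their `region` label), `site_map` (the
#'   exonic [build_exonic_sites()]-style map), `rbp_truth`, `mirna_truth`,
#'   `mirna_targets` (with conservation flags), `mirna` (raw miRNA count
#'   [expression_matrix()]), and `latent_mirna` (noiseless log2 interval
#'   profiles).
#' @export
simulate_regulators <- function(config, sim) {
  dca_assert(inherits(config, "simulation_config"), "invalid config")
  dca_assert(inherits(sim, "decouple_sim"),
             "`sim` must come from simulate_trajectories()")
  cfg <- config
  set.seed(cfg$seed + 1L)
  truth <- sim$truth
  genes <- truth$gene
  n <- length(genes)
  if (cfg$site_rate_discordant <= cfg$site_rate_concordant) {
    warn("site_rate_discordant <= site_rate_concordant: no planted RBP signal")
  }

  annotation <- simulate_annotation(genes, sim$gene_lengths$length_bp)
  exon_lengths <- annotation |>
    group_by(.data$gene) |>
    summarise(exon_union_bp = sum(.data$end - .data$start), .groups = "drop")

  # ---- RBP sites -----------------------------------------------------------
  rbps <- sprintf("RBP%02d", seq_len(cfg$n_rbps))
  pats <- paste0("P", 1:4)
  n_enriched <- min(cfg$n_rbps, 4L * cfg$rbp_enriched_per_pattern)
  rbp_truth <- tibble(
    rbp = rbps,
    pattern = c(rep(pats, cfg$rbp_enriched_per_pattern)[seq_len(n_enriched)],
                rep(NA_character_, cfg$n_rbps - n_enriched)))
  sites <- simulate_sites(rbp_truth, truth, annotation, cfg)

  site_map <- structure(list(
    sites = sites[sites$region == "exonic",
                  c("rbp", "gene", "chrom", "start", "end")],
    exon_lengths = exon_lengths,
    n_dropped = 0L
  ), class = "binding_site_map")

  # ---- miRNAs --------------------------------------------------------------
  mirnas <- sprintf("miR-%03d", seq_len(cfg$n_mirnas))
  seeds <- random_seeds(cfg$n_mirnas)
  age_dep <- runif(cfg$n_mirnas) < cfg$mirna_age_dep_fraction
  n_spec <- cfg$mirna_specific_per_pattern
  spec_idx <- head(which(age_dep), 4L * n_spec)
  dca_assert(length(spec_idx) == 4L * n_spec,
             "too few age-dependent miRNAs to plant specific ones")
  spec_pattern <- rep(pats, each = n_spec)
  mirna_truth <- tibble(mirna = mirnas, seed = seeds,
                        age_dependent = age_dep,
                        pattern = NA_character_)
  mirna_truth$pattern[spec_idx] <- spec_pattern

  # aging-direction of the discordant PROTEIN trend per pattern is the
  # opposite of the mRNA aging sign
  sa <- c(P1 = -1, P2 = 1, P3 = 1, P4 = -1)
  dir_dev <- sample(c(-1, 1), cfg$n_mirnas, replace = TRUE)
  dir_age <- sample(c(-1, 1), cfg$n_mirnas, replace = TRUE)
  repress <- !is.na(mirna_truth$pattern) &
    mirna_truth$pattern == cfg$repressed_pattern
  # protein trend of repressed-pattern discordant genes is -sa; oppose it
  dir_age[repress] <- sa[[cfg$repressed_pattern]]
  # the other patterns' target-enriched miRNAs get balanced directions so
  # their predicted pairs are centred like the chance background
  for (p in setdiff(pats, cfg$repressed_pattern)) {
    idx <- which(!is.na(mirna_truth$pattern) & mirna_truth$pattern == p)
    if (length(idx) > 0) {
      dir_age[idx] <- rep(c(1, -1), length.out = length(idx))
    }
  }

  ages_mirna <- if (cfg$n_samples_mirna == length(em_ages(sim$protein_spc))) {
    unname(em_ages(sim$protein_spc))
  } else {
    s_of <- function(a) scale_age(a, cfg$age_offset_days)
    draw_ages(cfg$n_samples_mirna, s_of(1), s_of(cfg$maturity_age_days),
              s_of(cfg$lifespan_days), cfg$age_offset_days)
  }
  s_of <- function(a) scale_age(a, cfg$age_offset_days)
  s0 <- s_of(1); s1 <- s_of(cfg$maturity_age_days)
  s2 <- s_of(cfg$lifespan_days)
  amp_d <- runif(cfg$n_mirnas, cfg$amplitude_log2[1], cfg$amplitude_log2[2])
  amp_a <- runif(cfg$n_mirnas, cfg$amplitude_log2[1], cfg$amplitude_log2[2])
  base <- rnorm(cfg$n_mirnas, 6, 1.5)
  latent_mirna_at <- function(s) {
    hd <- ramp01((s - s0) / (s1 - s0))
    ha <- ramp01((s - s1) / (s2 - s1))
    t(vapply(seq_len(cfg$n_mirnas), function(i) {
      base[i] + age_dep[i] * (amp_d[i] * dir_dev[i] * hd +
                                amp_a[i] * dir_age[i] * ha)
    }, numeric(length(s))))
  }
  sigma_nat <- sqrt(log(1 + cfg$noise_cv^2))
  draw <- simulate_count_matrix(latent_mirna_at(s_of(ages_mirna)),
                                len = rep(1, cfg$n_mirnas),
                                depth = cfg$mirna_depth, sigma_nat,
                                size = 1 / cfg$nb_dispersion)
  samp <- sprintf("mir%02d", seq_along(ages_mirna))
  mirna_em <- counts_to_em(draw$counts, mirnas, samp, ages_mirna)
  latent_mirna <- latent_profiles(latent_mirna_at, mirnas, s_of(ages_mirna), s1)

  mirna_targets <- simulate_targets(mirna_truth, truth, cfg)

  structure(list(
    annotation = annotation,
    sites = sites,
    site_map = site_map,
    rbp_truth = rbp_truth,
    mirna_truth = mirna_truth,
    mirna_targets = mirna_targets,
    mirna = mirna_em,
    mapped_totals_mirna = setNames(rep(cfg$mirna_depth, length(ages_mirna)),
                                   samp),
    mu_mirna = draw$mu,
    latent_mirna = latent_mirna
  ), class = "decouple_regulators")
}

# lay genes along one chromosome; exon-union length matches length_bp exactly
simulate_annotation <- function(genes, length_bp) {
  n <- length(genes)
  n_ex <- pmax(2L, pmin(4L, length_bp %/% 300L))
  total <- sum(n_ex)
  out_gene <- character(total); out_start <- integer(total)
  out_end <- integer(total); out_exon <- integer(total)
  at <- 0L
  cursor <- 1000L
  for (g in seq_len(n)) {
    k <- n_ex[g]
    # split exonic length into k parts of at least 60 bp
    L <- length_bp[g]
    cuts <- sort(sample.int(L - k * 60L, k - 1L))
    parts <- diff(c(0L, cuts, L - k * 60L)) + 60L
    introns <- 200L + rpois(k - 1L, 500)
    pos <- cursor
    for (e in seq_len(k)) {
      at <- at + 1L
      out_gene[at] <- genes[g]
      out_start[at] <- pos
      out_end[at] <- pos + parts[e]
      out_exon[at] <- e
      pos <- out_end[at] + if (e < k) introns[e] else 0L
    }
    cursor <- pos + 5000L
  }
  tibble(gene = out_gene, chrom = "chr1", start = out_start, end = out_end,
         exon = out_exon)
}

# plant exonic sites at class-dependent rates plus intronic/junction decoys
simulate_sites <- function(rbp_truth, truth, annotation, cfg) {
  exons <- split(annotation[c("start", "end")], annotation$gene)
  n <- nrow(truth)
  acc_rbp <- list(); acc_gene <- list(); acc_start <- list()
  acc_region <- list()
  for (r in seq_len(nrow(rbp_truth))) {
    pat <- rbp_truth$pattern[r]
    rate <- rep(cfg$site_rate_concordant, n)
    if (!is.na(pat)) {
      rate[truth$pattern == pat & truth$class == "discordant"] <-
        cfg$site_rate_discordant
    }
    k_ex <- rpois(n, rate)
    k_decoy <- rpois(n, cfg$decoy_site_rate)
    for (g in which(k_ex + k_decoy > 0)) {
      ex <- exons[[truth$gene[g]]]
      placed <- place_sites(ex, k_ex[g], k_decoy[g], cfg$site_width)
      if (length(placed$start) == 0) next
      i <- length(acc_rbp) + 1L
      acc_rbp[[i]] <- rep(rbp_truth$rbp[r], length(placed$start))
      acc_gene[[i]] <- rep(truth$gene[g], length(placed$start))
      acc_start[[i]] <- placed$start
      acc_region[[i]] <- placed$region
    }
  }
  start <- unlist(acc_start) %||% integer(0)
  tibble(rbp = unlist(acc_rbp) %||% character(0),
         gene = unlist(acc_gene) %||% character(0),
         chrom = "chr1", start = start, end = start + cfg$site_width,
         region = unlist(acc_region) %||% character(0))
}

place_sites <- function(ex, k_ex, k_decoy, width) {
  starts <- integer(0); regions <- character(0)
  widths <- ex$end - ex$start
  usable <- widths >= width
  if (k_ex > 0 && any(usable)) {
    pick <- sample(which(usable), k_ex, replace = TRUE,
                   prob = (widths[usable] - width + 1))
    s0 <- ex$start[pick] + floor(runif(k_ex) * (widths[pick] - width + 1))
    starts <- c(starts, as.integer(s0))
    regions <- c(regions, rep("exonic", k_ex))
  }
  if (k_decoy > 0) {
    kinds <- sample(c("intronic", "junction"), k_decoy, replace = TRUE)
    n_int <- sum(kinds == "intronic")
    if (n_int > 0 && nrow(ex) >= 2) {
      e <- sample_int(nrow(ex) - 1L, n_int, replace = TRUE)
      gaplen <- ex$start[e + 1] - ex$end[e]
      s0 <- ex$end[e] + 5L + floor(runif(n_int) * pmax(1, gaplen - width - 10))
      starts <- c(starts, as.integer(s0))
      regions <- c(regions, rep("intronic", n_int))
    }
    n_jun <- sum(kinds == "junction")
    if (n_jun > 0) {
      e <- sample_int(nrow(ex), n_jun, replace = TRUE)
      s0 <- ex$end[e] - width %/% 2L   # straddles the exon 3' boundary
      starts <- c(starts, as.integer(s0))
      regions <- c(regions, rep("junction", n_jun))
    }
  }
  list(start = starts, region = regions)
}

# distinct 7-nt seeds (positions 2-8 of the mature miRNA) with ~10% of
# miRNAs reusing an earlier seed, emulating seed families
random_seeds <- function(n) {
  alphabet <- c("A", "C", "G", "U")
  pool <- unique(vapply(seq_len(3 * n), function(i) {
    paste(sample(alphabet, 7, replace = TRUE), collapse = "")
  }, character(1)))
  seeds <- pool[seq_len(n)]
  reuse <- which(runif(n) < 0.1 & seq_len(n) > 8)
  if (length(reuse) > 0) {
    seeds[reuse] <- seeds[vapply(reuse, function(i) sample_int(i - 1L, 1),
                                 integer(1))]
  }
  seeds
}

# predicted target table with 4-species conservation flags
simulate_targets <- function(mirna_truth, truth, cfg) {
  rows <- list()
  for (i in seq_len(nrow(mirna_truth))) {
    hit <- runif(nrow(truth)) < cfg$target_prob_background
    if (!is.na(mirna_truth$pattern[i])) {
      own <- truth$pattern == mirna_truth$pattern[i] &
        truth$class == "discordant"
      hit[own] <- hit[own] | (runif(sum(own)) < cfg$target_prob_specific)
      planted <- own & hit
    } else {
      planted <- rep(FALSE, nrow(truth))
    }
    if (!any(hit)) next
    n_hit <- sum(hit)
    # planted pairs always pass the 3-of-4 rule; background pairs half do
    n_true <- ifelse(planted[hit], sample(3:4, n_hit, replace = TRUE,
                                          prob = c(0.4, 0.6)),
                     sample(0:4, n_hit, replace = TRUE,
                            prob = c(0.05, 0.15, 0.3, 0.3, 0.2)))
    flags <- t(vapply(n_true, function(k) {
      f <- rep(FALSE, 4)
      if (k > 0) f[sample_int(4, k)] <- TRUE
      f
    }, logical(4)))
    rows[[length(rows) + 1L]] <- tibble(
      mirna = mirna_truth$mirna[i], seed = mirna_truth$seed[i],
      gene = truth$gene[hit],
      cons_mouse = flags[, 1], cons_rat = flags[, 2],
      cons_dog = flags[, 3], cons_chicken = flags[, 4])
  }
  bind_rows(rows)
}
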