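#' Simulate mRNA and protein lifespan time series with planted coupling
#'
#' Generates read counts and spectral counts for `config$n_genes` genes whose
#' latent log2 trajectories follow the four lifespan patterns (see
#' [simulation_config()]). Concordant genes' protein trajectories track their
#' mRNA in both intervals; discordant genes track in development and mirror
#' the mRNA increments after maturity, so their latent aging-interval rank
#' correlation is exactly -1; "null" genes have protein trajectories
#' independent of their mRNA. Read counts are negative binomial with mean
#' proportional to abundance x exonic length x sequencing depth; spectral
#' counts are Poisson with mean proportional to protein abundance x protein
#' length, and are split over simulated peptides (most genes receive two or
#' more unique peptides; a few receive one, or ambiguous peptides, to
#' exercise the protein-identification filters).
#'
#' @param config A [simulation_config()].
#' @return A list of class `decouple_sim` with elements `config`, `truth`
#'   (gene, pattern, class), `mrna` and `protein_spc` (raw
#'   [expression_matrix()] objects), `peptides`, `gene_lengths`,
#'   `protein_lengths`, `mu_mrna` / `mu_protein` (expected count matrices),
#'   and `latent_mrna` / `latent_protein` (noiseless log2 interval profiles
#'   on each dataset's own grids).
#' @export
simulate_trajectories <- function(config) {
  dca_assert(inherits(config, "simulation_config"),
             "`config` must come from simulation_config()")
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_genes
  genes <- sprintf("G%04d", seq_len(n))

  s_of <- function(a) scale_age(a, cfg$age_offset_days)
  s0 <- s_of(1)
  s1 <- s_of(cfg$maturity_age_days)
  s2 <- s_of(cfg$lifespan_days)

  ages_rna <- draw_ages(cfg$n_samples_rna, s0, s1, s2, cfg$age_offset_days)
  # protein donors mirror the mRNA age distribution: most are shared with
  # the mRNA series and the shared set always includes the youngest and
  # oldest donors, so both datasets cover the same lifespan window
  n_shared <- max(0L, min(cfg$n_samples_rna, cfg$n_samples_protein) - 2L)
  shared <- ages_rna[unique(round(seq(1, length(ages_rna),
                                      length.out = n_shared)))]
  extra <- runif(cfg$n_samples_protein - length(shared),
                 min(scale_age(ages_rna, cfg$age_offset_days)),
                 max(scale_age(ages_rna, cfg$age_offset_days)))
  extra <- extra^4 - cfg$age_offset_days
  ages_prot <- sort(c(shared, extra))

  # planted labels; background genes are age-independent ballast
  background <- runif(n) < cfg$background_fraction
  pattern <- sample(paste0("P", 1:4), n, replace = TRUE,
                    prob = cfg$pattern_fractions)
  cls <- sample(c("discordant", "null", "concordant"), n, replace = TRUE,
                prob = c(cfg$discordant_fraction, cfg$null_fraction,
                         1 - cfg$discordant_fraction - cfg$null_fraction))
  pattern[background] <- "flat"
  cls[background] <- "null"
  # guarantee every pattern x {concordant, discordant} cell is populated
  cells <- expand.grid(p = paste0("P", 1:4),
                       k = c("concordant", "discordant"),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cells))) {
    if (!any(pattern == cells$p[i] & cls == cells$k[i])) {
      slot <- which(pattern == "flat" | cls != "discordant")[1]
      if (is.na(slot)) slot <- i
      pattern[slot] <- cells$p[i]
      cls[slot] <- cells$k[i]
    }
  }
  truth <- tibble(gene = genes, pattern = pattern, class = cls)

  # per-gene latent parameters
  sigma_nat <- sqrt(log(1 + cfg$noise_cv^2))
  wig_sd <- cfg$wiggle_scale * sigma_nat / log(2)   # log2 units
  amp1 <- runif(n, cfg$amplitude_log2[1], cfg$amplitude_log2[2])
  amp2 <- runif(n, cfg$amplitude_log2[1], cfg$amplitude_log2[2])
  # highly expressed genes are disproportionately age-stable, so the flat
  # background carries the bulk of the expression mass; this keeps the
  # per-sample RPKM/NSAF denominators as stable as in real libraries
  b_rna <- rnorm(n, 5, 1.5) + 2 * (pattern == "flat")
  b_prot <- rnorm(n, 5, 1.5) + 2 * (pattern == "flat")
  knots <- seq(s0, s2, length.out = cfg$wiggle_knots)
  wig_m <- matrix(rnorm(n * cfg$wiggle_knots, 0, wig_sd), n)
  wig_null <- matrix(rnorm(n * cfg$wiggle_knots, 0, wig_sd), n)
  sg <- c(P1 = -1, P2 = -1, P3 = 1, P4 = 1, flat = 0)[pattern]  # dev sign
  sa <- c(P1 = -1, P2 = 1, P3 = 1, P4 = -1, flat = 0)[pattern]   # aging sign
  amp1[pattern == "flat"] <- 0
  amp2[pattern == "flat"] <- 0
  wig_m[pattern == "flat", ] <- 0
  wig_null[pattern == "flat", ] <- 0

  # latent log2 trajectories, exact piecewise-cubic functions of scaled age
  latent_mrna_at <- function(s) {
    hd <- ramp01((s - s0) / (s1 - s0))
    ha <- ramp01((s - s1) / (s2 - s1))
    t(vapply(seq_len(n), function(g) {
      w <- splinefun(knots, wig_m[g, ], method = "natural")(s)
      b_rna[g] + amp1[g] * sg[g] * hd + amp2[g] * sa[g] * ha + w
    }, numeric(length(s))))
  }
  latent_prot_at <- function(s) {
    hd <- ramp01((s - s0) / (s1 - s0))
    ha <- ramp01((s - s1) / (s2 - s1))
    t(vapply(seq_len(n), function(g) {
      if (cls[g] == "null") {
        w <- splinefun(knots, wig_null[g, ], method = "natural")(s)
        return(b_prot[g] + w)
      }
      w <- splinefun(knots, wig_m[g, ], method = "natural")(s)
      w1 <- splinefun(knots, wig_m[g, ], method = "natural")(s1)
      dev_part <- amp1[g] * sg[g] * hd
      age_part <- amp2[g] * sa[g] * ha
      if (cls[g] == "concordant") {
        b_prot[g] + dev_part + age_part + w
      } else {
        # mirror every aging-interval increment (trend and shared wiggle)
        aging <- s > s1
        out <- b_prot[g] + dev_part + age_part + w
        if (any(aging)) {
          out[aging] <- b_prot[g] + amp1[g] * sg[g] +
            (w1 - (age_part[aging] + (w[aging] - w1)))
        }
        out
      }
    }, numeric(length(s))))
  }

  # gene and protein lengths
  len_bp <- round(runif(n, 500, 5000))
  len_aa <- round(runif(n, 100, 1000))

  # counts
  mrna_draw <- simulate_count_matrix(latent_mrna_at(s_of(ages_rna)), len_bp,
                                     cfg$seq_depth, sigma_nat,
                                     size = 1 / cfg$nb_dispersion)
  prot_draw <- simulate_count_matrix(latent_prot_at(s_of(ages_prot)), len_aa,
                                     cfg$spectral_depth, sigma_nat,
                                     size = Inf)   # Poisson
  sample_names_r <- sprintf("rna%02d", seq_along(ages_rna))
  sample_names_p <- sprintf("prot%02d", seq_along(ages_prot))
  mrna <- counts_to_em(mrna_draw$counts, genes, sample_names_r, ages_rna)
  protein_spc <- counts_to_em(prot_draw$counts, genes, sample_names_p,
                              ages_prot)
  peptides <- split_into_peptides(prot_draw$counts, genes, sample_names_p)

  # noiseless latent interval profiles on each dataset's own grids
  latent_mrna <- latent_profiles(latent_mrna_at, genes, s_of(ages_rna), s1)
  latent_protein <- latent_profiles(latent_prot_at, genes, s_of(ages_prot), s1)

  structure(list(
    config = cfg,
    truth = truth,
    mrna = mrna,
    mapped_totals_rna = setNames(rep(cfg$seq_depth, length(ages_rna)),
                                 sample_names_r),
    protein_spc = protein_spc,
    peptides = peptides,
    gene_lengths = tibble(gene = genes, length_bp = len_bp),
    protein_lengths = tibble(gene = genes, length_aa = len_aa),
    mu_mrna = mrna_draw$mu,
    mu_protein = prot_draw$mu,
    latent_mrna = latent_mrna,
    latent_protein = latent_protein
  ), class = "decouple_sim")
}

# clamped saturating ramp: 0 below 0, 1 above 1, linear between. Linear
# segments on the fourth-root age scale give the planted patterns uniform
# rank spacing within each interval, so no grid point is noise-dominated.
ramp01 <- function(u) {
  pmin(pmax(u, 0), 1)
}

# jittered stratified ages, uniform on the fourth-root scale: donor panels
# in lifespan studies are chosen to tile the whole age range, so each of k
# equal strata on the scaled-age axis contributes one donor
draw_ages <- function(k, s0, s1, s2, offset) {
  if (k <= 0) return(numeric(0))
  step <- (s2 - s0) / k
  s <- s0 + (seq_len(k) - 0.5 + runif(k, -0.45, 0.45)) * step
  sort(s^4 - offset)
}

# counts with mean proportional to abundance * length * depth; the absolute
# scale treats the simulated panel as part of a much larger library, so the
# per-sample totals are exogenous (dominated by genes outside the panel)
# rather than renormalised within the panel. size = Inf draws Poisson.
simulate_count_matrix <- function(log2_latent, len, depth, sigma_nat, size) {
  n <- nrow(log2_latent)
  m <- ncol(log2_latent)
  noise <- matrix(rlnorm(n * m, meanlog = -sigma_nat^2 / 2,
                         sdlog = sigma_nat), n, m)
  abundance <- 2^log2_latent * noise
  w <- abundance * len
  mu <- w / mean(colSums(2^log2_latent * len)) * depth
  counts <- if (is.infinite(size)) {
    matrix(rpois(n * m, mu), n, m)
  } else {
    matrix(rnbinom(n * m, mu = mu, size = size), n, m)
  }
  list(counts = counts, mu = mu)
}

counts_to_em <- function(counts, genes, samples, ages) {
  colnames(counts) <- samples
  tb <- bind_cols(tibble(gene = genes),
                  as_tibble(counts, .name_repair = "minimal"))
  expression_matrix(tb, setNames(ages, samples), unit = "raw")
}

# distribute each gene's spectral counts over simulated peptides
split_into_peptides <- function(counts, genes, samples) {
  n <- length(genes)
  m <- length(samples)
  n_pep <- pmax(1L, 2L + rpois(n, 1.5))
  n_pep[runif(n) < 0.03] <- 1L          # under-supported proteins
  total <- sum(n_pep)
  cnt <- matrix(0, total, m)
  gene_of <- rep(genes, n_pep)
  offs <- cumsum(c(0L, n_pep))
  for (g in seq_len(n)) {
    share <- runif(n_pep[g]) + 1e-9
    idx <- (offs[g] + 1L):offs[g + 1L]
    for (j in seq_len(m)) {
      cnt[idx, j] <- stats::rmultinom(1, counts[g, j], prob = share)
    }
  }
  # a few ambiguous peptides shared by two genes (discarded downstream)
  n_amb <- max(1L, round(0.02 * n))
  amb_genes <- vapply(seq_len(n_amb), function(a) {
    paste(genes[sample_int(n, 2)], collapse = ";")
  }, character(1))
  cnt <- rbind(cnt, matrix(rpois(n_amb * m, 1), n_amb, m))
  gene_of <- c(gene_of, amb_genes)
  colnames(cnt) <- samples
  out <- bind_cols(
    tibble(peptide = vapply(seq_len(nrow(cnt)), random_peptide, character(1)),
           genes = gene_of,
           unique = !grepl(";", gene_of, fixed = TRUE)),
    as_tibble(cnt, .name_repair = "minimal"))
  out
}

random_peptide <- function(i) {
  paste0(paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 8,
                      replace = TRUE), collapse = ""), i)
}

# noiseless latent log2 profiles on this dataset's uniform interval grids
latent_profiles <- function(latent_at, genes, s_samples, s_mat) {
  dev_grid <- seq(min(s_samples), s_mat, length.out = 10)
  age_grid <- seq(s_mat, max(s_samples), length.out = 10)
  prof <- latent_at(c(dev_grid, age_grid))
  colnames(prof) <- c(paste0("dev_", 1:10), paste0("age_", 1:10))
  out <- bind_cols(tibble(gene = genes),
                   as_tibble(prof, .name_repair = "minimal"))
  class(out) <- c("interval_profiles", class(out))
  attr(out, "dev_grid") <- dev_grid
  attr(out, "age_grid") <- age_grid
  out
}

#' @export
print.decouple_sim <- function(x, ...) {
  cat(sprintf(
    "<decouple_sim> %d genes (%s), %d rna / %d protein samples, seed %d\n",
    nrow(x$truth),
    paste(names(table(x$truth$class)), table(x$truth$class),
          sep = "=", collapse = ", "),
    length(em_samples(x$mrna)), length(em_samples(x$protein_spc)),
    x$config$seed))
  invisible(x)
}
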