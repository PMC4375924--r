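#' Configuration for the synthetic lifespan simulator
#'
#' Defines the study design being emulated: paired mRNA / protein / miRNA
#' time series over a primate lifespan with four age-trajectory patterns,
#' planted concordant and discordant mRNA/protein coupling, and planted
#' RBP-site and miRNA-target enrichment in the discordant genes. Defaults
#' mirror the brain time-series design: 14 mRNA, 12 protein and 12 miRNA
#' samples spanning 1 day to 98 years, with sexual maturity at 20 years
#' separating the developmental and aging intervals.
#'
#' Trajectories are built on the fourth-root age scale `s = (age + 280)^0.25`
#' from saturating linear ramps, one per interval, so that the four patterns
#' are realised exactly with uniform rank spacing: P1 decreases in both
#' intervals, P2 decreases then increases, P3 increases in both, P4
#' increases then decreases. Genes also carry a smooth gene-specific
#' trajectory component (a natural cubic spline through `wiggle_knots`
#' random knots, standard deviation `wiggle_scale` times the log-scale
#' measurement noise) shared between mRNA and protein according to the
#' planted class. Donor ages are jittered stratified draws, uniform on the
#' scaled-age axis, and the protein donors are an even thinning of the mRNA
#' donors plus two extras, emulating the mirrored age distributions of the
#' real sampling designs.
#'
#' @param n_samples_rna,n_samples_protein,n_samples_mirna Sample counts per
#'   dataset. The protein samples reuse most of the mRNA donors (all but
#'   two), and the miRNA samples are the protein donors.
#' @param lifespan_days,maturity_age_days Lifespan and the
#'   developmental/aging boundary, in days.
#' @param n_genes Number of simulated genes (at least 8, to populate 4
#'   patterns x 2 coupling classes).
#' @param pattern_fractions Four proportions (sum 1) of genes assigned to
#'   patterns P1-P4.
#' @param discordant_fraction,null_fraction Proportions of the age-dependent
#'   genes planted as discordant and as uncoupled (protein independent of
#'   mRNA); the rest are concordant.
#' @param background_fraction Fraction of genes with no age trend at all
#'   (pattern `"flat"`, class `"null"`). Real brain transcriptomes keep
#'   roughly 40% of expressed genes age-independent; without this stable
#'   expression mass the per-sample RPKM/NSAF denominators would inherit a
#'   common age trend from the patterned genes.
#' @param noise_cv Coefficient of variation of the multiplicative log-normal
#'   measurement noise.
#' @param site_rate_discordant,site_rate_concordant Poisson means of exonic
#'   binding sites per gene for a planted-enriched RBP on its pattern's
#'   discordant genes, and on every other gene.
#' @param seq_depth,spectral_depth,mirna_depth Expected total mapped reads /
#'   spectra per sample for the three count models.
#' @param nb_dispersion Negative-binomial dispersion of the read-count model
#'   (`size = 1/nb_dispersion`).
#' @param amplitude_log2 Range (min, max) of the per-interval trajectory
#'   amplitude in log2 units.
#' @param wiggle_scale,wiggle_knots Gene-specific smooth-component magnitude
#'   (relative to the log-scale noise sd) and number of spline knots.
#' @param age_offset_days Offset of the fourth-root age scale.
#' @param n_rbps,rbp_enriched_per_pattern RBP universe size and number of
#'   planted-enriched RBPs per pattern.
#' @param decoy_site_rate Poisson mean of intronic/junction decoy sites per
#'   gene per RBP (removed by the exonic filter).
#' @param site_width Binding-site width in bp.
#' @param n_mirnas,mirna_age_dep_fraction,mirna_specific_per_pattern miRNA
#'   universe size, fraction with age-dependent expression, and number of
#'   planted target-enriched miRNAs per pattern.
#' @param target_prob_specific,target_prob_background Probability that a
#'   planted-specific miRNA targets a discordant gene of its pattern, and
#'   baseline targeting probability for any miRNA/gene pair.
#' @param repressed_pattern Pattern whose planted-specific miRNAs are given
#'   aging expression opposite to their targets' protein trend (the
#'   translational-repression signal); one of `"P1".."P4"`.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   config.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_samples_rna = 14L,
                              n_samples_protein = 12L,
                              n_samples_mirna = 12L,
                              lifespan_days = 35770,
                              maturity_age_days = 7300,
                              n_genes = 1000L,
                              pattern_fractions = c(0.25, 0.25, 0.25, 0.25),
                              discordant_fraction = 0.25,
                              null_fraction = 0.2,
                              background_fraction = 0.4,
                              noise_cv = 0.2,
                              site_rate_discordant = 5,
                              site_rate_concordant = 0.5,
                              seq_depth = 2e6,
                              spectral_depth = 2e5,
                              mirna_depth = 2e6,
                              nb_dispersion = 0.01,
                              amplitude_log2 = c(1.5, 2.5),
                              wiggle_scale = 0.5,
                              wiggle_knots = 5L,
                              age_offset_days = 280,
                              n_rbps = 17L,
                              rbp_enriched_per_pattern = 1L,
                              decoy_site_rate = 0.5,
                              site_width = 10L,
                              n_mirnas = 150L,
                              mirna_age_dep_fraction = 0.5,
                              mirna_specific_per_pattern = 2L,
                              target_prob_specific = 0.8,
                              target_prob_background = 0.04,
                              repressed_pattern = "P3",
                              seed = 1L) {
  cfg <- as.list(environment())
  dca_assert(is_count(n_samples_rna) && n_samples_rna >= 6,
             "n_samples_rna must be a count >= 6")
  dca_assert(is_count(n_samples_protein) && n_samples_protein >= 6,
             "n_samples_protein must be a count >= 6")
  dca_assert(is_count(n_samples_mirna) && n_samples_mirna >= 6,
             "n_samples_mirna must be a count >= 6")
  dca_assert(is_count(n_genes), "n_genes must be a count")
  if (n_genes < 8) {
    dca_stop("n_genes must be at least 8 (4 patterns x 2 coupling classes)")
  }
  dca_assert(lifespan_days > 0 && maturity_age_days > 0,
             "lifespan and maturity must be positive")
  dca_assert(maturity_age_days < lifespan_days,
             "maturity_age_days must be smaller than lifespan_days")
  dca_assert(length(pattern_fractions) == 4 && all(pattern_fractions >= 0) &&
               abs(sum(pattern_fractions) - 1) < 1e-9,
             "pattern_fractions must be 4 proportions summing to 1")
  dca_assert(is_prob(discordant_fraction) && is_prob(null_fraction) &&
               discordant_fraction + null_fraction <= 1,
             "class fractions must be proportions with sum <= 1")
  dca_assert(is_prob(background_fraction) && background_fraction < 1,
             "background_fraction must be a proportion below 1")
  dca_assert(noise_cv >= 0, "noise_cv must be non-negative")
  dca_assert(site_rate_discordant >= 0 && site_rate_concordant >= 0,
             "site rates must be non-negative")
  dca_assert(repressed_pattern %in% paste0("P", 1:4),
             "repressed_pattern must be one of P1..P4")
  dca_assert(is.numeric(seed) && length(seed) == 1 && abs(seed) < 2^31,
             "seed must be a single integer")
  if (site_rate_discordant <= site_rate_concordant) {
    warn("site_rate_discordant <= site_rate_concordant: no planted RBP signal")
  }
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<simulation_config> %d genes, %d/%d/%d rna/protein/mirna samples,\n",
    "  lifespan %.0f d (maturity %.0f d), discordant %.0f%%, noise_cv %.2f, seed %d\n"),
    x$n_genes, x$n_samples_rna, x$n_samples_protein, x$n_samples_mirna,
    x$lifespan_days, x$maturity_age_days, 100 * x$discordant_fraction,
    x$noise_cv, x$seed))
  invisible(x)
}
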