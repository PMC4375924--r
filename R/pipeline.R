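#' Pipeline configuration
#'
#' Assembles the configuration shared by all pipeline stages: the synthetic
#' study design (passed through to [simulation_config()]), the analysis
#' thresholds, and the output directory. A YAML file with the same keys can
#' be loaded and partially overridden.
#'
#' @param path Optional YAML file with configuration keys.
#' @param ... Overrides (e.g. `seed = 7`, `n_genes = 500`, `alpha = 0.01`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, ...) {
  defaults <- list(
    out_dir = "decouple-run",
    seed = 1L,
    maturity_days = 7300,
    age_offset_days = 280,
    alpha = 0.05,
    fdr = 0.05,
    n_perm = 1000L,
    n_restart = 1000L,
    k = 4L,
    degrees = 0:3,
    stratifier = "sd",
    simulation = list())
  cfg <- defaults
  if (!is.null(path)) {
    dca_assert(file.exists(path), "config file not found: ", path)
    cfg <- modifyList(cfg, yaml::read_yaml(path))
  }
  dots <- list(...)
  sim_keys <- names(formals(simulation_config))
  cfg$simulation <- modifyList(cfg$simulation, dots[names(dots) %in% sim_keys])
  cfg <- modifyList(cfg, dots[!(names(dots) %in% sim_keys)])
  dca_assert(is_prob(cfg$alpha) && is_prob(cfg$fdr),
             "alpha and fdr must be in (0, 1)")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

sim_config_of <- function(cfg) {
  args <- cfg$simulation
  args$seed <- args$seed %||% cfg$seed
  args$maturity_age_days <- args$maturity_age_days %||% cfg$maturity_days
  args$age_offset_days <- args$age_offset_days %||% cfg$age_offset_days
  do.call(simulation_config, args)
}

pipeline_files <- list(
  simulate = c("mrna_counts.tsv", "samples_rna.tsv", "gene_lengths.tsv",
               "peptides.tsv", "protein_lengths.tsv", "samples_protein.tsv",
               "mirna_counts.tsv", "samples_mirna.tsv", "truth.tsv",
               "sites.bed", "annotation.gtf", "mirna_targets.tsv",
               "mirna_truth.tsv", "rbp_truth.tsv", "mapped_totals.tsv"),
  quantify = c("mrna_rpkm.tsv", "protein_nsaf.tsv", "mirna_tpm.tsv"),
  agefit = c("age_fits_mrna.tsv", "profiles_mrna.tsv",
             "profiles_protein.tsv", "profiles_mirna.tsv",
             "age_fits_mirna.tsv"),
  decouple = c("concordance.tsv", "decouple_summary.tsv"),
  cluster = c("patterns.tsv"),
  rbp = c("rbp_results.tsv"),
  mirna = c("mirna_enrichment.tsv", "correlation_shift.tsv"),
  report = c("report.json"))

#' Run one pipeline stage
#'
#' Stages (`simulate`, `quantify`, `agefit`, `decouple`, `cluster`, `rbp`,
#' `mirna`, `report`) read their inputs from `out_dir`, write their outputs
#' atomically (temp file + rename), and record a manifest
#' (`<stage>.manifest.json`) with the config hash, seed and input/output
#' checksums, so every number in the final report is traceable. A stage
#' whose prerequisites are missing stops with a message naming the stage to
#' run first.
#'
#' @param stage Stage name.
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest list.
#' @export
run_stage <- function(stage, config) {
  dca_assert(inherits(config, "pipeline_config"), "invalid pipeline config")
  stage <- match.arg(stage, names(pipeline_files))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage_idx <- match(stage, names(pipeline_files))
  set.seed(config$seed + 1000L * stage_idx)
  inputs <- stage_inputs(stage)
  missing <- inputs[!file.exists(file.path(config$out_dir, inputs))]
  if (length(missing) > 0) {
    prereq <- names(pipeline_files)[vapply(
      names(pipeline_files), function(s) any(missing %in% pipeline_files[[s]]),
      logical(1))]
    dca_stop(sprintf(
      "stage '%s' is missing input(s) %s: run stage '%s' first",
      stage, paste(missing, collapse = ", "), prereq[1]))
  }
  do.call(paste0("stage_", stage), list(config))
  manifest <- list(
    stage = stage,
    seed = config$seed,
    config_hash = config_hash(config),
    inputs = file_checksums(config$out_dir, inputs),
    outputs = file_checksums(config$out_dir, pipeline_files[[stage]]))
  manifest_path <- file.path(config$out_dir,
                             paste0(stage, ".manifest.json"))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  inform(sprintf("stage '%s' complete (%d output file(s))", stage,
                 length(pipeline_files[[stage]])))
  invisible(manifest)
}

stage_inputs <- function(stage) {
  switch(stage,
    simulate = character(0),
    quantify = pipeline_files$simulate,
    agefit = c("mrna_rpkm.tsv", "protein_nsaf.tsv", "mirna_tpm.tsv",
               "samples_rna.tsv", "samples_protein.tsv", "samples_mirna.tsv"),
    decouple = c("profiles_mrna.tsv", "profiles_protein.tsv"),
    cluster = c("concordance.tsv", "profiles_mrna.tsv"),
    rbp = c("sites.bed", "annotation.gtf", "patterns.tsv"),
    mirna = c("mirna_tpm.tsv", "samples_mirna.tsv", "mirna_targets.tsv",
              "patterns.tsv", "profiles_protein.tsv", "profiles_mirna.tsv"),
    report = c("truth.tsv", "concordance.tsv", "patterns.tsv",
               "rbp_results.tsv", "mirna_enrichment.tsv"))
}

#' Run the whole pipeline
#' @param config A [pipeline_config()].
#' @param stages Stages to run, in order.
#' @return Invisibly, the output directory.
#' @export
run_pipeline <- function(config, stages = names(pipeline_files)) {
  for (s in stages) run_stage(s, config)
  invisible(config$out_dir)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

file_checksums <- function(dir, files) {
  paths <- file.path(dir, files)
  ok <- file.exists(paths)
  as.list(setNames(ifelse(ok, tools::md5sum(paths), NA_character_), files))
}

# write a TSV (or arbitrary writer output) atomically
write_atomic <- function(writer, path) {
  tmp <- file.path(dirname(path), paste0(".tmp-", basename(path)))
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

out_path <- function(config, file) file.path(config$out_dir, file)

# ---- stage implementations -------------------------------------------------

stage_simulate <- function(config) {
  scfg <- sim_config_of(config)
  sim <- simulate_trajectories(scfg)
  reg <- simulate_regulators(scfg, sim)
  d <- config$out_dir
  w <- function(obj, file) {
    write_atomic(function(p) readr::write_tsv(obj, p), file.path(d, file))
  }
  write_atomic(function(p) write_expression_tsv(sim$mrna, p),
               file.path(d, "mrna_counts.tsv"))
  write_atomic(function(p) write_metadata_tsv(sim$mrna, p),
               file.path(d, "samples_rna.tsv"))
  w(sim$gene_lengths, "gene_lengths.tsv")
  w(sim$peptides, "peptides.tsv")
  w(sim$protein_lengths, "protein_lengths.tsv")
  write_atomic(function(p) write_metadata_tsv(sim$protein_spc, p),
               file.path(d, "samples_protein.tsv"))
  write_atomic(function(p) write_expression_tsv(reg$mirna, p),
               file.path(d, "mirna_counts.tsv"))
  write_atomic(function(p) write_metadata_tsv(reg$mirna, p),
               file.path(d, "samples_mirna.tsv"))
  write_atomic(function(p) write_truth_tsv(sim$truth, p),
               file.path(d, "truth.tsv"))
  write_atomic(function(p) write_sites_bed(reg$sites, p),
               file.path(d, "sites.bed"))
  write_atomic(function(p) write_annotation_gtf(reg$annotation, p),
               file.path(d, "annotation.gtf"))
  w(reg$mirna_targets, "mirna_targets.tsv")
  w(reg$mirna_truth, "mirna_truth.tsv")
  w(reg$rbp_truth, "rbp_truth.tsv")
  totals <- bind_rows(
    tibble(dataset = "rna", sample = names(sim$mapped_totals_rna),
           total = unname(sim$mapped_totals_rna)),
    tibble(dataset = "mirna", sample = names(reg$mapped_totals_mirna),
           total = unname(reg$mapped_totals_mirna)))
  w(totals, "mapped_totals.tsv")
}

stage_quantify <- function(config) {
  d <- config$out_dir
  meta_rna <- read_tsv_quiet(file.path(d, "samples_rna.tsv"))
  meta_prot <- read_tsv_quiet(file.path(d, "samples_protein.tsv"))
  meta_mir <- read_tsv_quiet(file.path(d, "samples_mirna.tsv"))
  counts <- read_tsv_quiet(file.path(d, "mrna_counts.tsv"))
  totals <- read_tsv_quiet(file.path(d, "mapped_totals.tsv"))
  tot_of <- function(ds) {
    sub <- totals[totals$dataset == ds, ]
    setNames(sub$total, sub$sample)
  }
  rpkm <- compute_rpkm(counts, read_tsv_quiet(file.path(d, "gene_lengths.tsv")),
                       meta_rna, mapped_totals = tot_of("rna")) |>
    filter_expressed_rna()
  write_atomic(function(p) write_expression_tsv(rpkm, p),
               file.path(d, "mrna_rpkm.tsv"))
  spc <- aggregate_peptides(read_tsv_quiet(file.path(d, "peptides.tsv")))
  nsaf <- compute_nsaf(spc, read_tsv_quiet(file.path(d, "protein_lengths.tsv")),
                       meta_prot) |>
    filter_detected_protein()
  write_atomic(function(p) write_expression_tsv(nsaf, p),
               file.path(d, "protein_nsaf.tsv"))
  tpm <- compute_tpm(read_tsv_quiet(file.path(d, "mirna_counts.tsv")), meta_mir,
                     mapped_totals = tot_of("mirna"))
  write_atomic(function(p) write_expression_tsv(tpm, p),
               file.path(d, "mirna_tpm.tsv"))
}

write_profiles_tsv <- function(profiles, path) {
  tb <- as_tibble(as.data.frame(profiles))
  con <- file(path, "w")
  writeLines(c(
    sprintf("# dev_grid=%s", paste(attr(profiles, "dev_grid"), collapse = ",")),
    sprintf("# age_grid=%s", paste(attr(profiles, "age_grid"), collapse = ","))),
    con)
  close(con)
  readr::write_tsv(tb, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

read_profiles_tsv <- function(path) {
  hdr <- readLines(path, n = 2L)
  tb <- read_tsv_quiet(path)
  class(tb) <- c("interval_profiles", class(tb))
  attr(tb, "dev_grid") <-
    as.numeric(strsplit(sub("^# dev_grid=", "", hdr[1]), ",")[[1]])
  attr(tb, "age_grid") <-
    as.numeric(strsplit(sub("^# age_grid=", "", hdr[2]), ",")[[1]])
  tb
}

stage_agefit <- function(config) {
  d <- config$out_dir
  rpkm <- read_expression_tsv(file.path(d, "mrna_rpkm.tsv"),
                              file.path(d, "samples_rna.tsv"))
  nsaf <- read_expression_tsv(file.path(d, "protein_nsaf.tsv"),
                              file.path(d, "samples_protein.tsv"))
  tpm <- read_expression_tsv(file.path(d, "mirna_tpm.tsv"),
                             file.path(d, "samples_mirna.tsv"))
  fits <- fit_age_models(rpkm, degrees = config$degrees,
                         offset_days = config$age_offset_days)
  write_atomic(function(p) readr::write_tsv(as_tibble(as.data.frame(fits)), p),
               file.path(d, "age_fits_mrna.tsv"))
  agedep <- fits$gene[fits$q < config$alpha]
  if (length(agedep) == 0) {
    warn("no age-dependent genes; interpolating all genes")
    agedep <- fits$gene
  }
  prof_m <- interpolate_profiles(rpkm[rpkm$gene %in% agedep, ],
                                 config$maturity_days, config$age_offset_days)
  prof_p <- interpolate_profiles(nsaf, config$maturity_days,
                                 config$age_offset_days)
  fits_mir <- fit_age_models(tpm, degrees = config$degrees,
                             offset_days = config$age_offset_days)
  write_atomic(function(p) readr::write_tsv(as_tibble(as.data.frame(fits_mir)), p),
               file.path(d, "age_fits_mirna.tsv"))
  prof_mir <- interpolate_profiles(tpm, config$maturity_days,
                                   config$age_offset_days)
  write_atomic(function(p) write_profiles_tsv(prof_m, p),
               file.path(d, "profiles_mrna.tsv"))
  write_atomic(function(p) write_profiles_tsv(prof_p, p),
               file.path(d, "profiles_protein.tsv"))
  write_atomic(function(p) write_profiles_tsv(prof_mir, p),
               file.path(d, "profiles_mirna.tsv"))
}

stage_decouple <- function(config) {
  d <- config$out_dir
  prof_m <- read_profiles_tsv(file.path(d, "profiles_mrna.tsv"))
  prof_p <- read_profiles_tsv(file.path(d, "profiles_protein.tsv"))
  calls <- classify_concordance(prof_m, prof_p, alpha = config$alpha,
                                fdr = config$fdr, n_perm = config$n_perm)
  write_atomic(function(p) readr::write_tsv(as_tibble(as.data.frame(calls)), p),
               file.path(d, "concordance.tsv"))
  coup <- compare_interval_coupling(calls)
  summary <- bind_cols(coup,
                       tibble(fdr_estimate = attr(calls, "fdr_estimate"),
                              confident = attr(calls, "confident"),
                              n_concordant = sum(calls$class == "concordant"),
                              n_discordant = sum(calls$class == "discordant")))
  write_atomic(function(p) readr::write_tsv(summary, p),
               file.path(d, "decouple_summary.tsv"))
}

stage_cluster <- function(config) {
  d <- config$out_dir
  calls <- read_tsv_quiet(file.path(d, "concordance.tsv"))
  prof_m <- read_profiles_tsv(file.path(d, "profiles_mrna.tsv"))
  labelled <- calls[calls$class %in% c("concordant", "discordant"), ]
  if (nrow(labelled) < config$k) {
    warn("too few confidently labelled genes; clustering raw labels")
    labelled <- calls[calls$class_raw %in% c("concordant", "discordant"), ]
  }
  dca_assert(nrow(labelled) >= config$k, "not enough labelled genes to cluster")
  prof <- prof_m[prof_m$gene %in% labelled$gene, ]
  pats <- consensus_kmeans(prof, k = config$k, n_restart = config$n_restart)
  out <- inner_join(as_tibble(pats),
                    labelled[c("gene", "class")], by = "gene")
  write_atomic(function(p) readr::write_tsv(out, p),
               file.path(d, "patterns.tsv"))
}

stage_rbp <- function(config) {
  d <- config$out_dir
  map <- build_exonic_sites(file.path(d, "sites.bed"),
                            file.path(d, "annotation.gtf"))
  pats <- read_tsv_quiet(file.path(d, "patterns.tsv"))
  res <- lapply(sort(unique(pats$pattern)), function(p) {
    disc <- pats$gene[pats$pattern == p & pats$class == "discordant"]
    conc <- pats$gene[pats$pattern == p & pats$class == "concordant"]
    if (length(disc) == 0 || length(conc) == 0) return(NULL)
    key_regulator_test(map, disc, conc, pattern = p)
  })
  write_atomic(function(p) readr::write_tsv(bind_rows(res), p),
               file.path(d, "rbp_results.tsv"))
}

stage_mirna <- function(config) {
  d <- config$out_dir
  tpm <- read_expression_tsv(file.path(d, "mirna_tpm.tsv"),
                             file.path(d, "samples_mirna.tsv"))
  agedep <- age_dependent_mirnas(tpm, alpha = config$alpha,
                                 degrees = config$degrees,
                                 offset_days = config$age_offset_days)
  targets <- filter_conserved_targets(
    read_tsv_quiet(file.path(d, "mirna_targets.tsv")))
  targets <- targets[targets$mirna %in% agedep, ]
  pats <- read_tsv_quiet(file.path(d, "patterns.tsv"))
  prof_p <- read_profiles_tsv(file.path(d, "profiles_protein.tsv"))
  prof_mir <- read_profiles_tsv(file.path(d, "profiles_mirna.tsv"))
  prof_mir <- prof_mir[prof_mir$gene %in% agedep, ]
  enr <- list(); shifts <- list()
  for (p in sort(unique(pats$pattern))) {
    disc <- pats$gene[pats$pattern == p & pats$class == "discordant"]
    conc <- pats$gene[pats$pattern == p & pats$class == "concordant"]
    if (length(disc) == 0 || length(conc) == 0) next
    e <- seed_enrichment(targets, disc, conc, n_perm = config$n_perm)
    if (nrow(e) > 0) {
      e$pattern <- p
      enr[[p]] <- as_tibble(as.data.frame(e))
    }
    pairs <- targets[targets$gene %in% disc, c("mirna", "gene")]
    cs <- correlation_shift(prof_mir, prof_p[prof_p$gene %in% disc, ], pairs,
                            n_background = config$n_perm)
    shifts[[p]] <- tibble(pattern = p, n_pairs = nrow(pairs),
                          excess_negative = cs$excess_negative,
                          band_lo = cs$band[1], band_hi = cs$band[2],
                          verdict = cs$verdict, p_excess = cs$p)
  }
  write_atomic(function(p) readr::write_tsv(bind_rows(enr), p),
               file.path(d, "mirna_enrichment.tsv"))
  write_atomic(function(p) readr::write_tsv(bind_rows(shifts), p),
               file.path(d, "correlation_shift.tsv"))
}

stage_report <- function(config) {
  d <- config$out_dir
  truth <- read_tsv_quiet(file.path(d, "truth.tsv"))
  calls <- read_tsv_quiet(file.path(d, "concordance.tsv"))
  pats <- read_tsv_quiet(file.path(d, "patterns.tsv"))
  rbp <- read_tsv_quiet(file.path(d, "rbp_results.tsv"))
  mir <- read_tsv_quiet(file.path(d, "mirna_enrichment.tsv"))
  rec <- recovery_summary(calls, truth)
  report <- list(
    n_genes = nrow(truth),
    n_called = nrow(calls),
    n_concordant = sum(calls$class == "concordant"),
    n_discordant = sum(calls$class == "discordant"),
    pct_discordant_of_called = percent_value(
      sum(calls$class == "discordant"), max(1, nrow(calls))),
    recovery = as.list(rec),
    pattern_sizes = as.list(table(pats$pattern)),
    n_key_regulators = if (nrow(rbp) > 0) sum(rbp$key) else 0L,
    n_specific_seeds = if (nrow(mir) > 0) sum(mir$specific) else 0L)
  write_atomic(function(p) jsonlite::write_json(report, p, auto_unbox = TRUE,
                                                pretty = TRUE, digits = NA),
               file.path(d, "report.json"))
}

#' End-to-end synthetic run, in memory
#'
#' Convenience wrapper chaining simulation, quantification, age-trajectory
#' fitting, interpolation and concordance classification without touching
#' the file system; used by the worked examples and the acceptance checks.
#'
#' @param config A [simulation_config()].
#' @param alpha,fdr,n_perm Classification parameters (see
#'   [classify_concordance()]).
#' @param q_age q-value threshold for the age-dependence filter.
#' @return A list with `sim`, `rpkm`, `nsaf`, `fits`, `profiles_mrna`,
#'   `profiles_protein`, `calls`, `coupling`, `recovery`.
#' @export
synthetic_decoupling_run <- function(config, alpha = 0.05, fdr = 0.05,
                                     n_perm = 1000L, q_age = 0.05) {
  sim <- simulate_trajectories(config)
  set.seed(config$seed + 500L)
  rpkm <- compute_rpkm(as_tibble(as.data.frame(sim$mrna)), sim$gene_lengths,
                       tibble(sample = em_samples(sim$mrna),
                              age_days = unname(em_ages(sim$mrna))),
                       mapped_totals = sim$mapped_totals_rna) |>
    filter_expressed_rna()
  spc <- aggregate_peptides(sim$peptides)
  nsaf <- compute_nsaf(spc, sim$protein_lengths,
                       tibble(sample = em_samples(sim$protein_spc),
                              age_days = unname(em_ages(sim$protein_spc)))) |>
    filter_detected_protein()
  fits <- fit_age_models(rpkm, offset_days = config$age_offset_days)
  agedep <- fits$gene[fits$q < q_age]
  prof_m <- interpolate_profiles(rpkm[rpkm$gene %in% agedep, ],
                                 config$maturity_age_days,
                                 config$age_offset_days)
  prof_p <- interpolate_profiles(nsaf, config$maturity_age_days,
                                 config$age_offset_days)
  calls <- classify_concordance(prof_m, prof_p, alpha = alpha, fdr = fdr,
                                n_perm = n_perm)
  list(sim = sim, rpkm = rpkm, nsaf = nsaf, fits = fits,
       profiles_mrna = prof_m, profiles_protein = prof_p, calls = calls,
       coupling = compare_interval_coupling(calls),
       recovery = recovery_summary(calls, sim$truth))
}
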