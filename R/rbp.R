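#' Map CLIP binding sites onto gene exon unions
#'
#' Computes the exon union (merged overlapping exons) of every annotated
#' gene and assigns each binding site to a gene if and only if the site lies
#' fully within one interval of that gene's exon union; intronic and
#' junction-spanning sites are dropped. Coordinates are 0-based half-open
#' (BED convention) throughout; GTF input (1-based closed) is converted on
#' read.
#'
#' @param sites Binding sites: a BED6 file path (the `name` field holds the
#'   RBP), or a data frame with columns `rbp`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param annotation Exon annotation: a GTF file path, or a data frame with
#'   columns `gene`, `chrom`, `start`, `end` (0-based half-open exons).
#' @return A list of class `binding_site_map`: `sites` (assigned sites with
#'   their gene), `exon_lengths` (`gene`, `exon_union_bp`), `n_dropped`.
#' @export
build_exonic_sites <- function(sites, annotation) {
  site_df <- read_sites(sites)
  exon_df <- read_exons(annotation)
  exon_gr <- GenomicRanges::GRanges(
    exon_df$chrom,
    IRanges::IRanges(exon_df$start + 1L, exon_df$end),
    gene = exon_df$gene)
  by_gene <- GenomicRanges::split(exon_gr, exon_gr$gene)
  union_gr <- unlist(GenomicRanges::reduce(by_gene))
  union_gene <- names(union_gr)
  exon_lengths <- tibble(gene = union_gene,
                         width = GenomicRanges::width(union_gr)) |>
    group_by(.data$gene) |>
    summarise(exon_union_bp = sum(.data$width), .groups = "drop")

  known <- site_df$chrom %in% unique(exon_df$chrom)
  if (any(!known)) {
    inform(sprintf("dropping %d site(s) on unannotated chromosomes",
                   sum(!known)))
  }
  site_df <- site_df[known, , drop = FALSE]
  site_gr <- GenomicRanges::GRanges(
    site_df$chrom, IRanges::IRanges(site_df$start + 1L, site_df$end))
  hits <- GenomicRanges::findOverlaps(site_gr, union_gr, type = "within")
  assigned <- tibble(
    rbp = site_df$rbp[S4Vectors::queryHits(hits)],
    gene = union_gene[S4Vectors::subjectHits(hits)],
    chrom = site_df$chrom[S4Vectors::queryHits(hits)],
    start = site_df$start[S4Vectors::queryHits(hits)],
    end = site_df$end[S4Vectors::queryHits(hits)])
  n_dropped <- nrow(site_df) - length(unique(S4Vectors::queryHits(hits)))
  inform(sprintf("%d of %d sites assigned to exon unions; %d dropped",
                 length(unique(S4Vectors::queryHits(hits))), nrow(site_df),
                 n_dropped))
  structure(list(sites = assigned, exon_lengths = exon_lengths,
                 n_dropped = n_dropped),
            class = "binding_site_map")
}

read_sites <- function(sites) {
  if (is.character(sites) && length(sites) == 1) {
    gr <- rtracklayer::import(sites, format = "BED")
    return(tibble(rbp = gr$name,
                  chrom = as.character(GenomicRanges::seqnames(gr)),
                  start = GenomicRanges::start(gr) - 1L,
                  end = GenomicRanges::end(gr)))
  }
  dca_assert(all(c("rbp", "chrom", "start", "end") %in% names(sites)),
             "sites need columns rbp, chrom, start, end")
  dca_assert(all(sites$start < sites$end), "malformed intervals (start >= end)")
  as_tibble(sites[c("rbp", "chrom", "start", "end")])
}

read_exons <- function(annotation) {
  if (is.character(annotation) && length(annotation) == 1) {
    gr <- rtracklayer::import(annotation, format = "GTF")
    gr <- gr[gr$type == "exon"]
    return(tibble(gene = gr$gene_id,
                  chrom = as.character(GenomicRanges::seqnames(gr)),
                  start = GenomicRanges::start(gr) - 1L,
                  end = GenomicRanges::end(gr)))
  }
  dca_assert(all(c("gene", "chrom", "start", "end") %in% names(annotation)),
             "annotation needs columns gene, chrom, start, end")
  as_tibble(annotation[c("gene", "chrom", "start", "end")])
}

#' @export
print.binding_site_map <- function(x, ...) {
  cat(sprintf("<binding_site_map> %d sites, %d RBPs, %d genes with exon unions\n",
              nrow(x$sites), length(unique(x$sites$rbp)),
              nrow(x$exon_lengths)))
  invisible(x)
}

# per-gene site counts (zeros included) for one RBP over a gene set
site_counts_for <- function(map, rbp, genes) {
  sub <- map$sites[map$sites$rbp == rbp & map$sites$gene %in% genes, ,
                   drop = FALSE]
  counts <- table(factor(sub$gene, levels = genes))
  as.numeric(counts)
}

#' Key-regulator tests for RBP binding-site enrichment
#'
#' For every RBP in the map, tests the three key-regulator conditions
#' comparing the discordant against the concordant genes of one pattern:
#' (1) a one-sided binomial test of the number of discordant genes carrying
#' at least one site against the concordant targeted fraction; (2) a
#' one-sided Wilcoxon rank-sum test on per-gene site counts (discordant
#' greater); (3) the same on per-gene site densities (count / exon-union
#' length). All p-values are Bonferroni-adjusted over `n_rbp_tests`. An RBP
#' is flagged a key regulator when condition 1 holds (adjusted p < 0.05)
#' together with at least one of conditions 2 and 3. Genes without an exon
#' union are excluded from all three conditions, keeping them on one gene
#' universe.
#'
#' @param map A [build_exonic_sites()] result.
#' @param discordant,concordant Disjoint, non-empty character vectors of
#'   gene identifiers.
#' @param n_rbp_tests Bonferroni denominator (default: number of RBPs in
#'   the map).
#' @param pattern Optional pattern label carried into the output.
#' @param alpha Significance level for the key flag.
#' @param reference Targeted fraction the binomial condition tests against:
#'   the pooled fraction over both gene sets (default; calibrated under the
#'   null) or the concordant fraction alone (the literal rule, mildly
#'   anticonservative).
#' @return A tibble of class `regulator_results`: `rbp`, `pattern`,
#'   `fold_change`, `frac_targeted`, `p_binom`, `p_count`, `p_density`,
#'   `key`.
#' @export
key_regulator_test <- function(map, discordant, concordant,
                               n_rbp_tests = NULL, pattern = NA_character_,
                               alpha = 0.05,
                               reference = c("pooled", "concordant")) {
  reference <- match.arg(reference)
  dca_assert(length(discordant) > 0 && length(concordant) > 0,
             "both gene sets must be non-empty")
  dca_assert(length(intersect(discordant, concordant)) == 0,
             "gene sets must be disjoint")
  with_len <- map$exon_lengths$gene
  drop <- setdiff(c(discordant, concordant), with_len)
  if (length(drop) > 0) {
    inform(sprintf("excluding %d gene(s) without exon unions", length(drop)))
    discordant <- intersect(discordant, with_len)
    concordant <- intersect(concordant, with_len)
  }
  rbps <- sort(unique(map$sites$rbp))
  n_rbp_tests <- n_rbp_tests %||% length(rbps)
  len <- setNames(map$exon_lengths$exon_union_bp, map$exon_lengths$gene)
  out <- lapply(rbps, function(r) {
    cd <- site_counts_for(map, r, discordant)
    cc <- site_counts_for(map, r, concordant)
    k <- sum(cd > 0)
    # the pooled targeted fraction is the default binomial reference:
    # conditioning on the concordant fraction alone ignores its sampling
    # error and roughly doubles the upper-tail false rate of the condition
    p0 <- if (reference == "pooled") mean(c(cd, cc) > 0) else mean(cc > 0)
    if (p0 == 0 && k > 0) {
      warn(sprintf("%s targets no concordant gene; using pseudo-fraction", r))
      p0 <- 1 / (length(concordant) + 1)
    }
    p_binom <- if (k == 0 && p0 == 0) 1 else {
      pbinom(k - 1, length(cd), p0, lower.tail = FALSE)
    }
    p_count <- one_sided_wilcox(cd, cc)
    p_density <- one_sided_wilcox(cd / len[discordant], cc / len[concordant])
    tibble(rbp = r, pattern = pattern,
           fold_change = mean(cd) / mean(cc),
           frac_targeted = mean(cd > 0),
           p_binom = min(1, p_binom * n_rbp_tests),
           p_count = min(1, p_count * n_rbp_tests),
           p_density = min(1, p_density * n_rbp_tests))
  }) |> bind_rows()
  out$key <- out$p_binom < alpha & (out$p_count < alpha | out$p_density < alpha)
  class(out) <- c("regulator_results", class(out))
  out
}

one_sided_wilcox <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) return(NA_real_)
  if (all(c(x, y) == c(x, y)[1])) return(1)
  suppressWarnings(wilcox.test(x, y, alternative = "greater")$p.value)
}

#' Correlation between a regulator's profile and its targets' profiles
#'
#' Spearman correlation (exact permutation p) between the regulator's
#' interpolated interval profile and each target gene's protein — and
#' optionally mRNA — profile on the same grid.
#'
#' @param regulator_profile Numeric vector (the regulator's interval
#'   profile).
#' @param target_protein_profiles An `interval_profiles` tibble for the
#'   targets' protein expression.
#' @param target_mrna_profiles Optional matching mRNA profiles.
#' @param targets Gene identifiers to test (default: all in the protein
#'   profiles).
#' @param interval Which interval grid to use.
#' @return A tibble: `gene`, `rho_protein`, `p_protein` (and `rho_mrna`,
#'   `p_mrna` when mRNA profiles are supplied), with attribute `summary`
#'   (median rho and fraction significant at 0.05).
#' @export
regulator_target_correlation <- function(regulator_profile,
                                         target_protein_profiles,
                                         target_mrna_profiles = NULL,
                                         targets = NULL,
                                         interval = c("age", "dev")) {
  interval <- match.arg(interval)
  targets <- targets %||% target_protein_profiles$gene
  prot <- profile_matrix(target_protein_profiles, interval)
  targets <- intersect(targets, rownames(prot))
  dca_assert(length(targets) > 0, "no targets with protein profiles")
  res <- lapply(targets, function(g) {
    rp <- spearman_test(regulator_profile, prot[g, ])
    row <- tibble(gene = g, rho_protein = rp$rho, p_protein = rp$p)
    if (!is.null(target_mrna_profiles) &&
          g %in% target_mrna_profiles$gene) {
      mm <- profile_matrix(target_mrna_profiles, interval)
      rm <- spearman_test(regulator_profile, mm[g, ])
      row$rho_mrna <- rm$rho
      row$p_mrna <- rm$p
    }
    row
  }) |> bind_rows()
  attr(res, "summary") <- tibble(
    median_rho_protein = median(res$rho_protein, na.rm = TRUE),
    frac_significant = mean(res$p_protein < 0.05, na.rm = TRUE))
  res
}

#' Compare one RBP's site counts across the four patterns
#'
#' Bootstraps the mean per-gene site count within each pattern's gene set
#' and tests the focal pattern's excess by a one-sided Wilcoxon rank-sum
#' test of its per-gene counts against the pooled other patterns.
#'
#' Uses the current RNG state; seed the session for reproducibility.
#'
#' @param map A [build_exonic_sites()] result.
#' @param rbp The RBP to test.
#' @param pattern_sets Named list of gene-identifier vectors (one per
#'   pattern).
#' @param focal Name of the focal pattern.
#' @param n_boot Bootstrap replicates per pattern.
#' @return A list of class `site_count_comparison`: `bootstrap` (tibble
#'   `pattern`, `replicate`, `mean_count`), `observed` (tibble `pattern`,
#'   `mean_count`, `n_genes`), `p` (one-sided Wilcoxon).
#' @export
compare_site_counts_across_patterns <- function(map, rbp, pattern_sets,
                                                focal, n_boot = 1000L) {
  dca_assert(focal %in% names(pattern_sets), "unknown focal pattern")
  small <- vapply(pattern_sets, length, integer(1)) < 2
  if (any(small)) {
    warn(sprintf("excluding pattern(s) with < 2 genes: %s",
                 paste(names(pattern_sets)[small], collapse = ", ")))
    pattern_sets <- pattern_sets[!small]
    dca_assert(focal %in% names(pattern_sets), "focal pattern too small")
  }
  counts <- lapply(pattern_sets, function(g) site_counts_for(map, rbp, g))
  boot <- imap(counts, function(cnt, pat) {
    tibble(pattern = pat, replicate = seq_len(n_boot),
           mean_count = vapply(seq_len(n_boot), function(b) {
             mean(cnt[sample_int(length(cnt), length(cnt), replace = TRUE)])
           }, numeric(1)))
  }) |> bind_rows()
  observed <- imap(counts, function(cnt, pat) {
    tibble(pattern = pat, mean_count = mean(cnt), n_genes = length(cnt))
  }) |> bind_rows()
  others <- unlist(counts[setdiff(names(counts), focal)])
  p <- one_sided_wilcox(counts[[focal]], others)
  structure(list(bootstrap = boot, observed = observed, p = p, focal = focal,
                 rbp = rbp),
            class = "site_count_comparison")
}
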