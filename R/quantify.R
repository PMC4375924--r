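#' RNA-seq quantification: RPKM
#'
#' Reads per kilobase per million mapped reads:
#' `RPKM = count / (length/1e3) / (total/1e6)`. Genes without a supplied
#' length are dropped with a warning.
#'
#' @param counts Data frame with a `gene` column and integer read counts per
#'   sample.
#' @param gene_lengths Data frame with columns `gene` and `length_bp`
#'   (exon-union length in bp), or a named numeric vector.
#' @param metadata Sample metadata (`sample`, `age_days`) or named age
#'   vector.
#' @param mapped_totals Named numeric vector of total mapped reads per
#'   sample; defaults to the column sums of `counts`.
#' @return An [expression_matrix()] with `unit = "RPKM"`.
#' @export
compute_rpkm <- function(counts, gene_lengths, metadata, mapped_totals = NULL) {
  raw <- expression_matrix(counts, metadata, unit = "raw")
  len <- as_length_vector(gene_lengths, "length_bp")
  dca_assert(all(len > 0), "gene lengths must be positive")
  missing <- setdiff(raw$gene, names(len))
  if (length(missing) > 0) {
    warn(sprintf("dropping %d gene(s) without a length (e.g. %s)",
                 length(missing), missing[1]))
    raw <- raw[!(raw$gene %in% missing), , drop = FALSE]
  }
  v <- em_values(raw)
  totals <- resolve_totals(mapped_totals, v)
  rpkm <- v / (len[rownames(v)] / 1e3)
  rpkm <- sweep(rpkm, 2, totals / 1e6, "/")
  em_replace(raw, rpkm, genes = rownames(v), unit = "RPKM")
}

as_length_vector <- function(x, col) {
  if (is.data.frame(x)) {
    dca_assert(all(c("gene", col) %in% names(x)),
               "lengths need columns `gene` and `", col, "`")
    setNames(x[[col]], x$gene)
  } else {
    dca_assert(!is.null(names(x)), "length vector must be named by gene")
    x
  }
}

resolve_totals <- function(mapped_totals, v) {
  if (is.null(mapped_totals)) return(colSums(v))
  dca_assert(all(colnames(v) %in% names(mapped_totals)),
             "mapped_totals must name every sample")
  totals <- mapped_totals[colnames(v)]
  dca_assert(all(totals > 0), "mapped totals must be positive")
  totals
}

#' Reliable-expression filter for mRNA
#'
#' Retains genes with `RPKM >= min_rpkm` in strictly more than `min_fraction`
#' of the samples (the reliably-expressed rule; at 15 samples a gene present
#' in 11 is kept, one present in exactly 10 is not).
#'
#' @param expr An `expr_mat` with `unit = "RPKM"`.
#' @param min_rpkm Expression threshold.
#' @param min_fraction Required fraction of samples (strict inequality).
#' @return The filtered `expr_mat`.
#' @export
filter_expressed_rna <- function(expr, min_rpkm = 1, min_fraction = 2 / 3) {
  dca_assert(inherits(expr, "expr_mat") && em_unit(expr) == "RPKM",
             "`expr` must be an RPKM expr_mat")
  v <- em_values(expr)
  keep <- rowMeans(v >= min_rpkm) > min_fraction
  if (!any(keep)) warn("no genes pass the expression filter")
  out <- expr[keep, , drop = FALSE]
  attr(out, "unit") <- "RPKM"
  attr(out, "ages") <- em_ages(expr)
  class(out) <- class(expr)
  out
}

#' Aggregate peptide spectral counts to genes
#'
#' Peptides mapping to more than one gene are discarded, genes supported by
#' fewer than `min_unique_peptides` distinct observed unique peptides are
#' discarded, and the remaining counts are summed per gene and sample.
#'
#' @param peptides Data frame with columns `peptide`, `genes`
#'   (semicolon-separated gene assignment; a single gene marks the peptide
#'   unique) and one integer spectral-count column per sample.
#' @param min_unique_peptides Minimum number of distinct unique peptides with
#'   nonzero counts required to keep a gene (protein identification rule;
#'   default 2).
#' @return A tibble with `gene` plus per-sample summed spectral counts.
#' @export
aggregate_peptides <- function(peptides, min_unique_peptides = 2L) {
  dca_assert(all(c("peptide", "genes") %in% names(peptides)),
             "`peptides` needs columns `peptide` and `genes`")
  samples <- setdiff(names(peptides), c("peptide", "genes", "unique"))
  v <- as.matrix(peptides[samples])
  dca_assert(all(v >= 0) && all(abs(v - round(v)) < 1e-9),
             "spectral counts must be non-negative integers")
  uniq <- !grepl(";", peptides$genes, fixed = TRUE)
  kept <- peptides[uniq, , drop = FALSE]
  observed <- rowSums(as.matrix(kept[samples])) > 0
  support <- table(kept$genes[observed])
  good <- names(support)[support >= min_unique_peptides]
  kept <- kept[kept$genes %in% good, , drop = FALSE]
  out <- as_tibble(kept[c("genes", samples)]) |>
    rename(gene = "genes") |>
    group_by(.data$gene) |>
    summarise(across(all_of(samples), sum), .groups = "drop")
  out
}

#' Label-free protein quantification: NSAF
#'
#' Spectral counts are normalised to protein length (`SAF = SpC / length`)
#' and each SAF is divided by the per-sample SAF sum, so unscaled NSAF
#' columns sum to 1. Because a mean-NSAF threshold is only meaningful on a
#' fixed scale, the values are then multiplied by `rescale` (default: the
#' number of detected genes, which makes every sample's mean NSAF equal 1);
#' the factor used is recorded in the `rescale_factor` attribute.
#'
#' @param spc Data frame with `gene` plus per-sample spectral counts (e.g.
#'   from [aggregate_peptides()]).
#' @param protein_lengths Data frame with `gene`, `length_aa` (residues), or
#'   named vector.
#' @param metadata Sample metadata (`sample`, `age_days`).
#' @param rescale `"n_genes"`, `"none"`, or a positive number.
#' @return An [expression_matrix()] with `unit = "NSAF"`. Samples whose
#'   column is entirely zero are flagged and excluded with a warning.
#' @export
compute_nsaf <- function(spc, protein_lengths, metadata, rescale = "n_genes") {
  raw <- expression_matrix(spc, metadata, unit = "raw")
  len <- as_length_vector(protein_lengths, "length_aa")
  dca_assert(all(len > 0), "protein lengths must be positive")
  missing <- setdiff(raw$gene, names(len))
  if (length(missing) > 0) {
    warn(sprintf("dropping %d protein(s) without a length", length(missing)))
    raw <- raw[!(raw$gene %in% missing), , drop = FALSE]
  }
  v <- em_values(raw)
  saf <- v / len[rownames(v)]
  colsum <- colSums(saf)
  dead <- colsum == 0
  if (any(dead)) {
    warn(sprintf("excluding %d all-zero sample(s): %s",
                 sum(dead), paste(colnames(v)[dead], collapse = ", ")))
    saf <- saf[, !dead, drop = FALSE]
    colsum <- colsum[!dead]
  }
  nsaf <- sweep(saf, 2, colsum, "/")
  factor <- if (identical(rescale, "n_genes")) nrow(nsaf)
            else if (identical(rescale, "none")) 1
            else {dca_assert(is.numeric(rescale) && rescale > 0,
                             "invalid rescale"); rescale}
  out <- em_replace(raw, nsaf * factor, genes = rownames(nsaf), unit = "NSAF",
                    samples = colnames(nsaf))
  attr(out, "rescale_factor") <- factor
  out
}

#' Reliable-detection filter for proteins
#'
#' Retains genes with mean rescaled NSAF of at least `min_mean` and a
#' positive NSAF in at least `min_samples` samples (default: half of them,
#' rounded up — the at-least-6-of-12 rule).
#'
#' @param expr An `expr_mat` with `unit = "NSAF"`.
#' @param min_mean Mean rescaled NSAF threshold.
#' @param min_samples Required number of samples with positive values.
#' @return The filtered `expr_mat`.
#' @export
filter_detected_protein <- function(expr, min_mean = 1, min_samples = NULL) {
  dca_assert(inherits(expr, "expr_mat") && em_unit(expr) == "NSAF",
             "`expr` must be an NSAF expr_mat")
  v <- em_values(expr)
  min_samples <- min_samples %||% ceiling(ncol(v) / 2)
  keep <- rowMeans(v) >= min_mean & rowSums(v > 0) >= min_samples
  out <- expr[keep, , drop = FALSE]
  attr(out, "unit") <- "NSAF"
  attr(out, "ages") <- em_ages(expr)
  attr(out, "rescale_factor") <- attr(expr, "rescale_factor")
  class(out) <- class(expr)
  out
}

#' Small-RNA quantification: TPM
#'
#' Transcripts per million mapped reads: `TPM = count / (total/1e6)`.
#'
#' @param mirna_counts Data frame with `gene` (miRNA name) plus per-sample
#'   counts.
#' @inheritParams compute_rpkm
#' @return An [expression_matrix()] with `unit = "TPM"`.
#' @export
compute_tpm <- function(mirna_counts, metadata, mapped_totals = NULL) {
  raw <- expression_matrix(mirna_counts, metadata, unit = "raw")
  v <- em_values(raw)
  totals <- resolve_totals(mapped_totals, v)
  em_replace(raw, sweep(v, 2, totals / 1e6, "/"), genes = rownames(v),
             unit = "TPM")
}
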