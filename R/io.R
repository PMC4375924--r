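#' Write simulated binding sites as BED6
#'
#' One line per site, 0-based half-open, with the RBP name in the `name`
#' field (the layout [build_exonic_sites()] reads back).
#'
#' @param sites Tibble with `rbp`, `chrom`, `start`, `end`.
#' @param path Output path.
#' @export
write_sites_bed <- function(sites, path) {
  bed <- tibble(chrom = sites$chrom, start = sites$start, end = sites$end,
                name = sites$rbp, score = 0L, strand = "+")
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Write an exon table as GTF
#'
#' Exons are written as `exon` features with `gene_id` attributes,
#' converting the internal 0-based half-open coordinates to GTF's 1-based
#' closed convention.
#'
#' @param annotation Tibble with `gene`, `chrom`, `start`, `end`.
#' @param path Output path.
#' @export
write_annotation_gtf <- function(annotation, path) {
  lines <- sprintf(
    "%s\tsim\texon\t%d\t%d\t.\t+\t.\tgene_id \"%s\"; transcript_id \"%s.t1\";",
    annotation$chrom, annotation$start + 1L, annotation$end,
    annotation$gene, annotation$gene)
  writeLines(lines, path)
  invisible(path)
}

#' Write the planted ground truth as TSV (`gene pattern class`)
#' @param truth Tibble with `gene`, `pattern`, `class`.
#' @param path Output path.
#' @export
write_truth_tsv <- function(truth, path) {
  readr::write_tsv(truth[c("gene", "pattern", "class")], path)
  invisible(path)
}
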