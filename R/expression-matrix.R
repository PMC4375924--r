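#' Expression matrices with sample ages and a unit tag
#'
#' An expression matrix is a tibble whose first column `gene` holds gene
#' identifiers and whose remaining columns hold per-sample abundances, with
#' two attributes: `unit` (one of `"raw"`, `"RPKM"`, `"NSAF"`, `"TPM"`) and
#' `ages` (a named numeric vector of donor ages in days, one per sample
#' column). All quantification and trajectory functions consume and return
#' this shape, so calls chain with the pipe.
#'
#' @param values A data frame with a `gene` column followed by one numeric
#'   column per sample.
#' @param ages Named numeric vector of ages in days (names must match the
#'   sample columns), or a metadata data frame with columns `sample` and
#'   `age_days`.
#' @param unit Unit tag for the values.
#' @return A tibble of class `expr_mat`.
#' @examples
#' em <- expression_matrix(
#'   tibble::tibble(gene = c("g1", "g2"), s1 = c(1, 2), s2 = c(3, 4)),
#'   ages = c(s1 = 100, s2 = 2000), unit = "raw")
#' em_ages(em)
#' @export
expression_matrix <- function(values, ages,
                              unit = c("raw", "RPKM", "NSAF", "TPM")) {
  unit <- match.arg(unit)
  dca_assert(is.data.frame(values) && "gene" %in% names(values),
             "`values` must be a data frame with a `gene` column")
  values <- as_tibble(values)
  samples <- setdiff(names(values), "gene")
  dca_assert(length(samples) >= 1L, "no sample columns found")
  if (is.data.frame(ages)) {
    dca_assert(all(c("sample", "age_days") %in% names(ages)),
               "metadata must have columns `sample` and `age_days`")
    ages <- setNames(ages$age_days, ages$sample)
  }
  dca_assert(all(samples %in% names(ages)),
             "every sample column needs an age: missing ",
             paste(setdiff(samples, names(ages)), collapse = ", "))
  ages <- ages[samples]
  dca_assert(all(is.finite(ages)) && all(ages > 0), "ages must be positive")
  dca_assert(!anyDuplicated(values$gene), "duplicate gene identifiers")
  dca_assert(!anyDuplicated(samples), "duplicate sample identifiers")
  vals <- as.matrix(values[samples])
  dca_assert(is.numeric(vals) && all(is.finite(vals)) && all(vals >= 0),
             "expression values must be finite and non-negative")
  structure(values, unit = unit, ages = ages,
            class = c("expr_mat", class(values)))
}

#' @rdname expression_matrix
#' @param x An `expr_mat`.
#' @export
em_unit <- function(x) attr(x, "unit")

#' @rdname expression_matrix
#' @export
em_ages <- function(x) attr(x, "ages")

#' @rdname expression_matrix
#' @export
em_samples <- function(x) names(em_ages(x))

#' @rdname expression_matrix
#' @export
em_values <- function(x) {
  m <- as.matrix(as.data.frame(x)[em_samples(x)])
  rownames(m) <- x$gene
  m
}

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf("<expr_mat> unit=%s, %d genes x %d samples, ages %.3g-%.3g days\n",
              em_unit(x), nrow(x), length(em_samples(x)),
              min(em_ages(x)), max(em_ages(x))))
  NextMethod()
}

# rebuild an expr_mat from a plain value matrix, keeping metadata
em_replace <- function(template, values, genes = NULL, unit = em_unit(template),
                       samples = em_samples(template)) {
  genes <- genes %||% rownames(values)
  colnames(values) <- samples
  tb <- bind_cols(tibble(gene = genes),
                  as_tibble(values, .name_repair = "minimal"))
  expression_matrix(tb, em_ages(template)[samples], unit = unit)
}

#' Read and write expression matrices as TSV
#'
#' Matrices are written with a `# unit=` comment header; ages travel in a
#' separate sample-metadata TSV with columns `sample` and `age_days` (the
#' format consumed by the pipeline throughout).
#'
#' @param x An `expr_mat`.
#' @param path Output (or input) TSV path.
#' @param metadata For reading: metadata path or data frame with `sample`,
#'   `age_days`.
#' @return `write_expression_tsv()` returns `path` invisibly;
#'   `read_expression_tsv()` returns an `expr_mat`.
#' @export
write_expression_tsv <- function(x, path) {
  dca_assert(inherits(x, "expr_mat"), "`x` must be an expr_mat")
  con <- file(path, "w")
  writeLines(sprintf("# unit=%s", em_unit(x)), con)
  close(con)
  readr::write_tsv(as_tibble(as.data.frame(x)), path, append = TRUE,
                   col_names = TRUE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path, metadata) {
  first <- readLines(path, n = 1L)
  unit <- if (grepl("^# unit=", first)) sub("^# unit=", "", first) else "raw"
  tb <- read_tsv_quiet(path)
  if (is.character(metadata)) metadata <- read_tsv_quiet(metadata)
  expression_matrix(tb, metadata, unit = unit)
}

#' Write sample metadata (`sample`, `age_days`) for an expression matrix
#' @inheritParams write_expression_tsv
#' @export
write_metadata_tsv <- function(x, path) {
  readr::write_tsv(tibble(sample = em_samples(x), age_days = unname(em_ages(x))),
                   path)
  invisible(path)
}
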