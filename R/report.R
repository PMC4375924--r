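#' Format a count fraction as a printed percentage
#'
#' Small reporting helper used throughout the result tables: `k` of `n`
#' rendered at the stated precision, e.g. `percent_label(1963, 6955, 1)` is
#' `"28.2%"` and `percent_label(10, 13, 0)` is `"77%"`.
#'
#' @param k,n Numerator and denominator counts.
#' @param digits Decimal places to print.
#' @return A character scalar like `"28.2%"`.
#' @export
percent_label <- function(k, n, digits = 1) {
  dca_assert(n > 0, "denominator must be positive")
  sprintf("%.*f%%", digits, round(100 * k / n, digits))
}

#' Numeric percentage at printed precision
#' @inheritParams percent_label
#' @return `round(100 * k / n, digits)`.
#' @export
percent_value <- function(k, n, digits = 1) {
  dca_assert(n > 0, "denominator must be positive")
  round(100 * k / n, digits)
}

#' Recovery of planted coupling classes
#'
#' Compares concordance calls against the planted ground truth of a
#' synthetic run: sensitivity and specificity of the discordant label, and
#' the corresponding rates for the concordant label, computed over the genes
#' present in the call set.
#'
#' @param calls A `concordance_calls` tibble.
#' @param truth The `truth` tibble of a `decouple_sim` (`gene`, `pattern`,
#'   `class`).
#' @param use `"reported"` scores the FDR-gated `class` column;
#'   `"raw"` scores the classification rule itself (`class_raw`, the
#'   per-gene labels at level alpha before the global permutation-FDR gate).
#' @return A one-row tibble with `n_called`, `sensitivity_discordant`,
#'   `specificity_discordant`, `sensitivity_concordant`,
#'   `frac_null_labelled`.
#' @export
recovery_summary <- function(calls, truth, use = c("reported", "raw")) {
  use <- match.arg(use)
  col <- if (use == "raw" && "class_raw" %in% names(calls)) "class_raw"
         else "class"
  picked <- as_tibble(calls[c("gene", col)])
  names(picked) <- c("gene", "class")
  df <- inner_join(picked,
                   rename(truth, truth_class = "class"), by = "gene")
  disc <- df$truth_class == "discordant"
  conc <- df$truth_class == "concordant"
  nul <- df$truth_class == "null"
  tibble(
    n_called = nrow(df),
    sensitivity_discordant = mean(df$class[disc] == "discordant"),
    specificity_discordant = 1 - mean(df$class[conc] == "discordant"),
    sensitivity_concordant = mean(df$class[conc] == "concordant"),
    frac_null_labelled = if (any(nul)) mean(df$class[nul] != "other") else NA_real_)
}
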