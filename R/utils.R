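#' @importFrom rlang abort warn inform .data %||%
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom dplyr mutate filter select arrange left_join inner_join group_by
#'   summarise ungroup bind_rows bind_cols rename pull n across all_of distinct
#' @importFrom purrr map map_dbl map_chr map_lgl map2 pmap imap
#' @importFrom stats approx cor lm median pbinom pchisq pf phyper p.adjust
#'   predict quantile rbinom rlnorm rnbinom rnorm rpois runif sd setNames
#'   smooth.spline var wilcox.test chisq.test kmeans spline splinefun complete.cases
#' @importFrom utils head modifyList
NULL

# internal: stop with a clean, user-facing message
dca_stop <- function(...) abort(paste0(...), call = NULL)

dca_assert <- function(cond, ...) {
  if (!isTRUE(cond)) dca_stop(...)
  invisible(TRUE)
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 0 && abs(x - round(x)) < 1e-9

is_prob <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 0 && x <= 1

# sample() without the length-1 surprise
sample_int <- function(n, size, replace = FALSE) {
  sample.int(n, size = size, replace = replace)
}

read_tsv_quiet <- function(path, comment = "#", ...) {
  readr::read_tsv(path, comment = comment, show_col_types = FALSE,
                  progress = FALSE, ...)
}
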