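#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @method tidy concordance_calls
#' @export
tidy.concordance_calls <- function(x, ...) {
  as_tibble(as.data.frame(x))
}

#' @method glance concordance_calls
#' @export
glance.concordance_calls <- function(x, ...) {
  tibble(n_genes = nrow(x),
         n_concordant = sum(x$class == "concordant"),
         n_discordant = sum(x$class == "discordant"),
         fdr_estimate = attr(x, "fdr_estimate"),
         alpha = attr(x, "alpha"),
         confident = attr(x, "confident"))
}

#' @method tidy age_fits
#' @export
tidy.age_fits <- function(x, ...) {
  as_tibble(as.data.frame(x))
}

#' @method glance age_fits
#' @export
glance.age_fits <- function(x, ...) {
  tibble(n_genes = nrow(x),
         n_age_dependent = sum(x$q < 0.05),
         median_adj_r2 = median(x$adj_r2))
}

#' @method tidy overlap_test
#' @export
tidy.overlap_test <- function(x, ...) {
  tibble(observed = x$observed, perm_mean = mean(x$permuted),
         q95 = x$q95, p = x$p, significant = x$significant)
}

#' @method tidy interval_variability
#' @export
tidy.interval_variability <- function(x, ...) {
  as_tibble(as.data.frame(x))
}

#' @method glance interval_variability
#' @export
glance.interval_variability <- function(x, ...) {
  attr(x, "tests")
}

#' @method tidy correlation_shift
#' @export
tidy.correlation_shift <- function(x, ...) {
  x$curves
}

#' @method glance correlation_shift
#' @export
glance.correlation_shift <- function(x, ...) {
  tibble(n_pairs = x$n_pairs %||% 0L,
         excess_negative = x$excess_negative,
         band_lo = x$band[1], band_hi = x$band[2],
         verdict = x$verdict, p = x$p)
}

#' @method glance pattern_assignment
#' @export
glance.pattern_assignment <- function(x, ...) {
  tibble(n_genes = nrow(x),
         k = nrow(attr(x, "centroids")),
         modal_share = attr(x, "modal_share"),
         wcss = attr(x, "wcss"))
}

#' @method tidy mirna_enrichment
#' @export
tidy.mirna_enrichment <- function(x, ...) {
  as_tibble(as.data.frame(x))
}

#' @method glance mirna_enrichment
#' @export
glance.mirna_enrichment <- function(x, ...) {
  tibble(n_seeds = nrow(x),
         n_specific = sum(x$specific),
         perm_mean_specific = mean(attr(x, "perm_specific_counts")))
}
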