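#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_ribbon
#'   geom_histogram geom_vline geom_hline facet_wrap labs theme_minimal
#' @export
ggplot2::autoplot

#' Scatter of developmental vs aging mRNA/protein correlations
#'
#' The classic two-interval concordance view: each point is a gene, the
#' dashed lines mark the exact-permutation significance cutoff, and colours
#' show the reported class.
#'
#' @param object A `concordance_calls` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot concordance_calls
#' @export
autoplot.concordance_calls <- function(object, ...) {
  crit <- spearman_critical_rho(10, attr(object, "alpha") %||% 0.05)
  ggplot(as_tibble(as.data.frame(object)),
         aes(x = .data$rho_dev, y = .data$rho_age, colour = .data$class)) +
    geom_point(alpha = 0.6, size = 1) +
    geom_vline(xintercept = c(-crit, crit), linetype = "dashed",
               colour = "grey50") +
    geom_hline(yintercept = c(-crit, crit), linetype = "dashed",
               colour = "grey50") +
    labs(x = "Spearman rho (development)", y = "Spearman rho (aging)",
         colour = NULL) +
    theme_minimal()
}

#' Cluster centroid trajectories of the four lifespan patterns
#'
#' @param object A `pattern_assignment` from [consensus_kmeans()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pattern_assignment
#' @export
autoplot.pattern_assignment <- function(object, ...) {
  cen <- attr(object, "centroids")
  n2 <- ncol(cen) / 2
  df <- tibble(
    pattern = rep(rownames(cen), each = ncol(cen)),
    point = rep(seq_len(ncol(cen)), nrow(cen)),
    interval = rep(rep(c("development", "aging"), each = n2), nrow(cen)),
    value = as.vector(t(cen)))
  ggplot(df, aes(x = .data$point, y = .data$value,
                 colour = .data$interval)) +
    geom_line() +
    geom_vline(xintercept = n2 + 0.5, linetype = "dashed",
               colour = "grey50") +
    facet_wrap(~pattern) +
    labs(x = "interpolated point", y = "standardised expression",
         colour = NULL) +
    theme_minimal()
}

#' Observed overlap against its permutation distribution
#'
#' @param object An `overlap_test` from [overlap_permutation()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot overlap_test
#' @export
autoplot.overlap_test <- function(object, ...) {
  ggplot(tibble(overlap = object$permuted), aes(x = .data$overlap)) +
    geom_histogram(bins = 30, fill = "grey70") +
    geom_vline(xintercept = object$observed, colour = "red") +
    geom_vline(xintercept = object$q95, linetype = "dashed") +
    labs(x = "permuted overlap", y = "count") +
    theme_minimal()
}

#' Centred cumulative correlation curves of the correlation-shift estimate
#'
#' The observed miRNA-target correlation distribution against the 95%
#' background band, both centred on the background median.
#'
#' @param object A `correlation_shift`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot correlation_shift
#' @export
autoplot.correlation_shift <- function(object, ...) {
  dca_assert(!is.null(object$curves), "no curves (verdict NA)")
  wide <- tidyr::pivot_wider(object$curves, names_from = "curve",
                             values_from = "value")
  ggplot(wide, aes(x = .data$rho)) +
    geom_ribbon(aes(ymin = .data$band_lo, ymax = .data$band_hi),
                fill = "grey80") +
    geom_line(aes(y = .data$observed), colour = "red") +
    geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    labs(x = "Spearman rho (miRNA vs target protein)",
         y = "centred cumulative frequency") +
    theme_minimal()
}

#' Plot interpolated interval profiles for selected genes
#'
#' @param profiles An [interpolate_profiles()] result.
#' @param genes Genes to display (default: first 8).
#' @return A ggplot.
#' @export
plot_profiles <- function(profiles, genes = head(profiles$gene, 8)) {
  sel <- profiles[profiles$gene %in% genes, , drop = FALSE]
  dev <- profile_matrix(sel, "dev")
  age <- profile_matrix(sel, "age")
  s <- c(attr(profiles, "dev_grid"), attr(profiles, "age_grid"))
  df <- tibble(gene = rep(sel$gene, each = length(s)),
               s = rep(s, nrow(sel)),
               interval = rep(rep(c("development", "aging"),
                                  each = length(s) / 2), nrow(sel)),
               value = as.vector(t(cbind(dev, age))))
  ggplot(df, aes(x = .data$s, y = .data$value, colour = .data$interval)) +
    geom_line() +
    facet_wrap(~gene, scales = "free_y") +
    labs(x = "scaled age (fourth root of days)", y = "log2 expression",
         colour = NULL) +
    theme_minimal()
}
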