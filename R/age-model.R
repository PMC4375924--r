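#' Fourth-root age scale
#'
#' Donor ages are analysed on the scale `s = (age_days + offset_days)^0.25`,
#' which spreads the dense early-life sampling and compresses late life so
#' that developmental and aging changes can be captured by one polynomial
#' family. The default offset of 280 days (roughly gestation) keeps the
#' derivative finite at birth.
#'
#' @param age_days Ages in days (positive).
#' @param offset_days Offset added before the fourth root.
#' @return Scaled ages.
#' @examples
#' scale_age(16, offset_days = 0) # 2
#' @export
scale_age <- function(age_days, offset_days = 280) {
  dca_assert(all(is.finite(age_days)), "ages must be finite")
  dca_assert(all(age_days + offset_days > 0),
             "age_days + offset_days must be positive")
  (age_days + offset_days)^0.25
}

#' Fit polynomial age models to one expression vector
#'
#' Least-squares polynomial fits in scaled age are computed for every degree
#' in `degrees`; the degree maximising the adjusted r-squared is selected and
#' its overall F-test against the intercept-only model gives the p-value. A
#' constant expression vector selects degree 0 with `p = 1`.
#'
#' @param values Per-sample expression values.
#' @param ages_scaled Per-sample scaled ages (same length).
#' @param degrees Integer vector of polynomial degrees to search.
#' @return A one-row tibble: `degree`, `adj_r2`, `fstat`, `p`.
#' @export
fit_age_model <- function(values, ages_scaled, degrees = 0:3) {
  dca_assert(length(values) == length(ages_scaled), "length mismatch")
  dca_assert(length(values) >= max(degrees) + 2,
             "need at least max(degrees) + 2 samples")
  fits <- fit_age_matrix(matrix(values, nrow = 1), ages_scaled, degrees)
  fits
}

# vectorised core: one QR per degree, all genes at once
fit_age_matrix <- function(Y, s, degrees = 0:3) {
  n <- ncol(Y)
  g <- nrow(Y)
  dca_assert(n >= max(degrees) + 2, "need at least max(degrees) + 2 samples")
  ybar <- rowMeans(Y)
  rss0 <- rowSums((Y - ybar)^2)
  best_deg <- rep(0L, g)
  best_adj <- rep(0, g)       # degree-0 adjusted r2 is 0 by definition
  best_f <- rep(NA_real_, g)
  best_p <- rep(1, g)
  for (d in sort(setdiff(degrees, 0L))) {
    X <- cbind(1, stats::poly(s, degree = d, raw = TRUE))
    qrx <- qr(X)
    resid <- t(qr.resid(qrx, t(Y)))
    rss <- rowSums(resid^2)
    adj <- ifelse(rss0 > 0, 1 - (rss / (n - d - 1)) / (rss0 / (n - 1)), 0)
    better <- adj > best_adj + 1e-12
    if (any(better)) {
      fstat <- ((rss0 - rss) / d) / (rss / (n - d - 1))
      pval <- pf(fstat, d, n - d - 1, lower.tail = FALSE)
      # guard the numerically-perfect fit
      pval[rss <= rss0 * 1e-14] <- 0
      best_deg[better] <- d
      best_adj[better] <- adj[better]
      best_f[better] <- fstat[better]
      best_p[better] <- pval[better]
    }
  }
  constant <- rss0 <= 0
  best_deg[constant] <- 0L
  best_adj[constant] <- 0
  best_f[constant] <- NA_real_
  best_p[constant] <- 1
  tibble(degree = best_deg, adj_r2 = best_adj, fstat = best_f, p = best_p)
}

#' Detect age-dependent genes across an expression matrix
#'
#' Applies [fit_age_model()] to every gene of an expression matrix (by
#' default on `log2(x + 1)` values) and corrects the F-test p-values across
#' all genes by Benjamini-Hochberg.
#'
#' @param expr An [expression_matrix()].
#' @param degrees Polynomial degrees to search.
#' @param offset_days Age offset for [scale_age()].
#' @param log2_transform Fit on `log2(x + 1)` (default) or raw values.
#' @return A tibble of class `age_fits`: `gene`, `degree`, `adj_r2`, `fstat`,
#'   `p`, `q`.
#' @export
fit_age_models <- function(expr, degrees = 0:3, offset_days = 280,
                           log2_transform = TRUE) {
  dca_assert(inherits(expr, "expr_mat"), "`expr` must be an expr_mat")
  Y <- em_values(expr)
  if (log2_transform) Y <- log2(Y + 1)
  s <- scale_age(em_ages(expr), offset_days)
  fits <- fit_age_matrix(Y, s, degrees)
  out <- bind_cols(tibble(gene = expr$gene), fits)
  out$q <- p.adjust(out$p, method = "BH")
  class(out) <- c("age_fits", class(out))
  attr(out, "degrees") <- degrees
  attr(out, "offset_days") <- offset_days
  out
}

#' Interpolate expression onto uniform developmental and aging grids
#'
#' A cubic smoothing spline (smoothing chosen by generalised
#' cross-validation) is fitted per gene to expression against scaled age and
#' evaluated at 10 points uniform on the scaled-age axis within each lifespan
#' interval: development, `[min s, s_maturity]`, and aging,
#' `[s_maturity, max s]`.
#'
#' @param expr An [expression_matrix()].
#' @param maturity_days Age of sexual maturity in days (the interval
#'   boundary); must lie inside the sampled age range.
#' @param offset_days Age offset for [scale_age()].
#' @param log2_transform Interpolate `log2(x + 1)` values (default).
#' @param n_points Grid points per interval.
#' @return A tibble of class `interval_profiles`: `gene`, `dev_1..dev_10`,
#'   `age_1..age_10`, with the scaled-age grids in attributes `dev_grid` and
#'   `age_grid`.
#' @export
interpolate_profiles <- function(expr, maturity_days, offset_days = 280,
                                 log2_transform = TRUE, n_points = 10L) {
  dca_assert(inherits(expr, "expr_mat"), "`expr` must be an expr_mat")
  ages <- em_ages(expr)
  s <- scale_age(ages, offset_days)
  dca_assert(length(unique(s)) >= 4L,
             "need at least 4 distinct sample ages for a cubic spline")
  s_mat <- scale_age(maturity_days, offset_days)
  dca_assert(s_mat > min(s) && s_mat < max(s),
             "maturity age must lie inside the sampled age range")
  dev_grid <- seq(min(s), s_mat, length.out = n_points)
  age_grid <- seq(s_mat, max(s), length.out = n_points)
  Y <- em_values(expr)
  if (log2_transform) Y <- log2(Y + 1)
  prof <- matrix(NA_real_, nrow(Y), 2 * n_points)
  ok <- rep(TRUE, nrow(Y))
  for (i in seq_len(nrow(Y))) {
    y <- Y[i, ]
    if (sd(y) == 0) {            # constant gene: spline is the constant
      prof[i, ] <- y[1]
      next
    }
    fit <- tryCatch(guarded_spline(s, y), error = function(e) NULL)
    if (is.null(fit)) {
      ok[i] <- FALSE
      next
    }
    prof[i, ] <- predict(fit, c(dev_grid, age_grid))$y
  }
  if (any(!ok)) {
    warn(sprintf("excluding %d gene(s) with degenerate spline fits", sum(!ok)))
  }
  colnames(prof) <- c(paste0("dev_", seq_len(n_points)),
                      paste0("age_", seq_len(n_points)))
  out <- bind_cols(tibble(gene = expr$gene[ok]),
                   as_tibble(prof[ok, , drop = FALSE],
                             .name_repair = "minimal"))
  class(out) <- c("interval_profiles", class(out))
  attr(out, "dev_grid") <- dev_grid
  attr(out, "age_grid") <- age_grid
  attr(out, "offset_days") <- offset_days
  out
}

# Cubic smoothing spline with GCV-chosen smoothness, guarded at small n:
# generalised cross-validation is erratic with 12-15 points and sometimes
# collapses to a near-line (losing the aging-interval deviation) or to full
# interpolation of the noise. When the GCV fit is not effectively noiseless,
# its equivalent degrees of freedom are clamped to [4, 0.75 n]. A noiseless
# trajectory keeps the unconstrained GCV fit, which reproduces polynomials
# up to the cubic exactly.
guarded_spline <- function(s, y, df_min = 4, df_frac_max = 0.75) {
  n <- length(unique(s))
  fit <- smooth.spline(s, y)
  resid_sd <- sqrt(mean((predict(fit, s)$y - y)^2))
  if (resid_sd <= 1e-8 * (sd(y) + 1e-12)) return(fit)
  df_max <- max(df_min, floor(df_frac_max * n))
  if (fit$df < df_min) fit <- smooth.spline(s, y, df = df_min)
  else if (fit$df > df_max) fit <- smooth.spline(s, y, df = df_max)
  fit
}

# extract the 10-point interval sub-matrices from an interval_profiles tibble
profile_matrix <- function(profiles, interval = c("dev", "age")) {
  interval <- match.arg(interval)
  cols <- grep(paste0("^", interval, "_"), names(profiles), value = TRUE)
  m <- as.matrix(as.data.frame(profiles)[cols])
  rownames(m) <- profiles$gene
  m
}
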