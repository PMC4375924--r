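#' Consensus k-means clustering of lifespan expression patterns
#'
#' Standardises each gene's concatenated 20-point mRNA profile to mean 0 and
#' standard deviation 1, runs k-means with random initialisation `n_restart`
#' times, and returns the partition (up to cluster relabelling) that occurs
#' most often — the modal "constellation". Clusters of the modal partition
#' are then mapped to the four lifespan patterns by the signs of their
#' centroid's mean first differences within each interval (P1 decreasing in
#' both intervals, P2 decreasing then increasing, P3 increasing in both,
#' P4 increasing then decreasing), choosing the label assignment that
#' maximises the total agreement. For `k != 4` clusters keep generic
#' `C1..Ck` labels ordered by developmental slope.
#'
#' @param profiles An [interpolate_profiles()] result (mRNA profiles).
#' @param k Number of clusters.
#' @param n_restart Number of random restarts.
#' @param seed Optional integer seed.
#' @return A tibble of class `pattern_assignment`: `gene`, `pattern`, with
#'   attributes `centroids` (pattern x 20 matrix), `modal_share` (fraction
#'   of restarts yielding the modal partition), `wcss`, and
#'   `restart_wcss` (per-restart within-cluster sums of squares).
#' @export
consensus_kmeans <- function(profiles, k = 4L, n_restart = 1000L,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- cbind(profile_matrix(profiles, "dev"), profile_matrix(profiles, "age"))
  sds <- apply(m, 1, sd)
  if (any(sds == 0)) {
    warn(sprintf("dropping %d constant gene(s) before clustering",
                 sum(sds == 0)))
    m <- m[sds > 0, , drop = FALSE]
  }
  dca_assert(nrow(m) >= k, "fewer genes than clusters")
  z <- (m - rowMeans(m)) / apply(m, 1, sd)
  uz <- unique(z)
  dca_assert(nrow(uz) >= k, "fewer distinct profiles than clusters")
  sig <- character(n_restart)
  parts <- vector("list", n_restart)
  wcss <- numeric(n_restart)
  for (r in seq_len(n_restart)) {
    centers <- uz[sample_int(nrow(uz), k), , drop = FALSE]
    km <- suppressWarnings(kmeans(z, centers = centers, iter.max = 50))
    canon <- canonical_partition(km$cluster)
    sig[r] <- paste(canon, collapse = "")
    parts[[r]] <- canon
    wcss[r] <- km$tot.withinss
  }
  freq <- table(sig)
  top <- freq[freq == max(freq)]
  if (length(top) > 1) {
    warn("no strict modal partition; breaking the tie lexicographically")
  }
  winner <- min(names(top))
  cluster <- parts[[match(winner, sig)]]
  centroids <- t(vapply(seq_len(k), function(c) colMeans(z[cluster == c, ,
                                                           drop = FALSE]),
                        numeric(ncol(z))))
  labels <- label_patterns(centroids, k)
  wcss_modal <- sum((z - centroids[cluster, , drop = FALSE])^2)
  out <- tibble(gene = rownames(m), pattern = labels[cluster])
  rownames(centroids) <- labels
  class(out) <- c("pattern_assignment", class(out))
  attr(out, "centroids") <- centroids[order(rownames(centroids)), ,
                                      drop = FALSE]
  attr(out, "modal_share") <- max(freq) / n_restart
  attr(out, "wcss") <- wcss_modal
  attr(out, "restart_wcss") <- wcss
  out
}

# relabel clusters in order of first appearance so label-swapped partitions
# compare equal
canonical_partition <- function(cluster) {
  match(cluster, unique(cluster))
}

# map centroids to P1..P4 by interval slope signs (k == 4), maximising the
# summed slope agreement over all label permutations
label_patterns <- function(centroids, k) {
  n2 <- ncol(centroids) / 2
  d_dev <- apply(centroids[, seq_len(n2), drop = FALSE], 1,
                 function(v) mean(diff(v)))
  d_age <- apply(centroids[, n2 + seq_len(n2), drop = FALSE], 1,
                 function(v) mean(diff(v)))
  if (k != 4) {
    return(paste0("C", rank(d_dev, ties.method = "first")))
  }
  # score of assigning cluster c the pattern with signs (sd, sa)
  signs <- list(P1 = c(-1, -1), P2 = c(-1, 1), P3 = c(1, 1), P4 = c(1, -1))
  score <- vapply(signs, function(s) s[1] * d_dev + s[2] * d_age,
                  numeric(k))   # k x 4
  perms <- perms_of(4)
  best <- perms[[which.max(vapply(perms, function(pp) {
    sum(score[cbind(seq_len(4), pp)])
  }, numeric(1)))]]
  names(signs)[best]
}

perms_of <- function(n) {
  if (n == 1) return(list(1L))
  sub <- perms_of(n - 1L)
  out <- list()
  for (p in sub) {
    for (i in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = i - 1L)
    }
  }
  out
}
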