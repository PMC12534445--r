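#' Exact one-dimensional k-means
#'
#' Globally optimal k-means partition of scalar data. An optimal k-means
#' partition of points on the line is contiguous in sorted order, so the
#' optimum is found deterministically by dynamic programming over the k - 1
#' cut positions (prefix-sum within-cluster costs, no random initialization
#' and no seed sensitivity).
#'
#' @param values numeric vector.
#' @param k number of clusters, `1 <= k <=` number of distinct values.
#' @return List with `assignments` (integer cluster labels 1..k in order of
#'   increasing cluster mean, aligned with `values`), `wcss` (total
#'   within-cluster sum of squared deviations), `centers` (cluster means,
#'   increasing) and `sizes`.
#' @export
kmeans_1d <- function(values, k) {
  n <- length(values)
  ndist <- length(unique(values))
  if (k < 1 || k != round(k))
    explor_error("k must be a positive integer", "explor_domain_error")
  if (k > ndist)
    explor_error(sprintf("k = %d exceeds the %d distinct value(s)", k, ndist),
                 "explor_domain_error")
  ord <- order(values)
  x <- values[ord]
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  # cost of putting sorted points i..j in one cluster
  seg_cost <- function(i, j) {
    s <- cs[j + 1] - cs[i]
    cs2[j + 1] - cs2[i] - s^2 / (j - i + 1)
  }
  # D[m, j]: best cost of splitting x[1..j] into m clusters
  D <- matrix(Inf, k, n)
  B <- matrix(0L, k, n)   # backpointer: start index of the last cluster
  for (j in 1:n) { D[1, j] <- seg_cost(1, j); B[1, j] <- 1L }
  if (k > 1) {
    for (m in 2:k) {
      for (j in m:n) {
        for (i in m:j) {
          cand <- D[m - 1, i - 1] + seg_cost(i, j)
          if (cand < D[m, j]) { D[m, j] <- cand; B[m, j] <- i }
        }
      }
    }
  }
  lab_sorted <- integer(n)
  j <- n
  for (m in k:1) {
    i <- B[m, j]
    lab_sorted[i:j] <- m
    j <- i - 1
  }
  assignments <- integer(n)
  assignments[ord] <- lab_sorted
  centers <- as.numeric(tapply(x, lab_sorted, mean))
  sizes <- as.integer(table(lab_sorted))
  list(assignments = assignments, wcss = D[k, n], centers = centers,
       sizes = sizes)
}

#' Elbow-method selection of the number of clusters
#'
#' Computes the within-cluster sum of squares (WCSS) for k = 1..`k_max` with
#' [kmeans_1d()] and selects the k maximizing the discrete second difference
#' \eqn{WCSS(k-1) - 2\,WCSS(k) + WCSS(k+1)} over k = 2..`k_max` - 1 - the
#' sharpest bend of the WCSS curve - with ties broken toward smaller k.
#' A constant input returns k = 1 with a note.
#'
#' @param values numeric vector, length >= `k_max`.
#' @param k_max largest k scanned (>= 3; capped at the number of distinct
#'   values).
#' @return List with `k_selected`, `wcss_by_k` (named numeric vector) and
#'   optionally `note`.
#' @export
select_k_elbow <- function(values, k_max = 6) {
  if (k_max < 3)
    explor_error("k_max must be at least 3", "explor_domain_error")
  if (length(values) < k_max)
    explor_error("need at least k_max values", "explor_domain_error")
  ndist <- length(unique(values))
  if (ndist == 1) {
    return(list(k_selected = 1L,
                wcss_by_k = stats::setNames(0, "1"),
                note = "constant input: zero variance, k = 1"))
  }
  k_max <- min(k_max, ndist)
  wcss <- vapply(1:k_max, function(k) kmeans_1d(values, k)$wcss, numeric(1))
  names(wcss) <- as.character(1:k_max)
  if (k_max < 3) {
    return(list(k_selected = k_max,
                wcss_by_k = wcss,
                note = "fewer than 3 distinct values; k capped"))
  }
  ks <- 2:(k_max - 1)
  d2 <- wcss[ks - 1] - 2 * wcss[ks] + wcss[ks + 1]
  k_sel <- ks[which.max(d2)]   # which.max takes the first (smallest k) on ties
  list(k_selected = as.integer(k_sel), wcss_by_k = wcss)
}

#' Partition individuals into high and low explorers
#'
#' Runs elbow selection of k on the Exploration Indexes, clusters them with
#' exact one-dimensional k-means at the selected k and, when k = 2, labels
#' the cluster with the larger mean index `"high"` and the other `"low"`,
#' summarizes each cluster (mean, sample SD, range, size, member sex counts
#' when available) and compares the two clusters with a Mann-Whitney U test.
#' The reported `u_statistic` is the U for the high cluster; because an
#' optimal 2-means partition of scalar data is a threshold rule, every high
#' index exceeds every low index and this U always equals
#' `n_high * n_low` (its minimum-orientation counterpart `u_min` is 0).
#'
#' @param profiles either a data.frame with columns `individual_id` and
#'   `exploration_index` (as returned by [exploration_profiles()]) or a
#'   plain numeric vector of indexes (names used as IDs when present).
#'   At least 4 values required.
#' @param k_max passed to [select_k_elbow()].
#' @return An object of class `explor_clusters`: list with `k_selected`,
#'   `wcss_by_k`, `assignments` (named character vector, `"high"`/`"low"`
#'   when k = 2, `"c1"`, `"c2"`, ... otherwise), `cluster_summary`
#'   (data.frame with mean, sd, min, max, size per cluster), and - when
#'   k = 2 - `u_statistic`, `u_min`, `p_value`, `u_test`.
#' @export
partition_explorers <- function(profiles, k_max = 6) {
  if (is.data.frame(profiles)) {
    idx <- profiles$exploration_index
    ids <- profiles$individual_id
  } else {
    idx <- as.numeric(profiles)
    ids <- names(profiles)
  }
  if (is.null(ids)) ids <- sprintf("i%02d", seq_along(idx))
  if (length(idx) < 4)
    explor_error("partition_explorers requires at least 4 individuals",
                 "explor_domain_error")
  sel <- select_k_elbow(idx, k_max = min(k_max, length(idx)))
  k <- sel$k_selected
  km <- kmeans_1d(idx, k)
  labels <- if (k == 2) c("low", "high") else sprintf("c%d", 1:k)
  assignments <- stats::setNames(labels[km$assignments], ids)
  summ <- data.frame(
    cluster = labels,
    size = km$sizes,
    mean = km$centers,
    sd = as.numeric(tapply(idx, km$assignments, stats::sd)),
    min = as.numeric(tapply(idx, km$assignments, min)),
    max = as.numeric(tapply(idx, km$assignments, max)),
    stringsAsFactors = FALSE)
  out <- list(k_selected = k, wcss_by_k = sel$wcss_by_k,
              assignments = assignments, cluster_summary = summ,
              note = sel$note)
  if (k == 2) {
    ut <- mann_whitney_u(idx[km$assignments == 2], idx[km$assignments == 1])
    out$u_statistic <- ut$u_a   # U for the high cluster (max orientation)
    out$u_min <- ut$n1 * ut$n2 - ut$u_a
    out$p_value <- ut$p_value
    out$u_test <- ut
  }
  class(out) <- "explor_clusters"
  out
}

#' @export
print.explor_clusters <- function(x, ...) {
  cat(sprintf("<explor_clusters> k = %d\n", x$k_selected))
  print(x$cluster_summary, row.names = FALSE)
  if (!is.null(x$u_statistic))
    cat(sprintf("  Mann-Whitney U (high orientation) = %g, p = %.3g\n",
                x$u_statistic, x$p_value))
  invisible(x)
}
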