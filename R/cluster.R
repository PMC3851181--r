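## Expression-profile clustering: shape-based and identity-based grouping on
## discretized trajectories, and Lloyd's k-means on raw aggregated profiles.

new_partition <- function(groups, method, parameters = list()) {
  structure(list(groups = groups, method = method, parameters = parameters),
            class = "Partition")
}

#' @export
print.Partition <- function(x, ...) {
  cat(sprintf("Partition (%s): %d groups over %d probes\n", x$method,
              length(x$groups),
              sum(vapply(x$groups, length, 0L))))
  invisible(x)
}

delta_matrix <- function(traj) {
  if (ncol(traj) < 2L)
    stop("shape operations need at least 2 time points")
  traj[, -1L, drop = FALSE] - traj[, -ncol(traj), drop = FALSE]
}

delta_key <- function(deltas) apply(deltas, 1L, paste, collapse = ",")

#' Group trajectories by shape
#'
#' Two trajectories share a shape when their successive bin differences
#' agree: the group key is the delta vector `(b_2-b_1, ..., b_N-b_{N-1})`.
#' The grouping is therefore invariant to vertical shifts -- trajectories at
#' different absolute expression levels but with the same movements cluster
#' together.
#'
#' @param dset `DiscretizedTrajectorySet` with >= 2 time points.
#' @return `Partition` keyed by comma-separated delta vectors.
#' @export
cluster_by_shape <- function(dset) {
  stopifnot(inherits(dset, "DiscretizedTrajectorySet"))
  deltas <- delta_matrix(dset$trajectories)
  keys <- delta_key(deltas)
  groups <- split(rownames(dset$trajectories), keys)
  new_partition(groups[order(names(groups))], "shape",
                list(width = dset$width))
}

#' Group trajectories by exact identity
#'
#' Two trajectories are identical when they occupy the same bin at every
#' time point; the group key is the full bin sequence. The identity
#' partition always refines the shape partition.
#'
#' @param dset `DiscretizedTrajectorySet`.
#' @return `Partition` keyed by comma-separated bin sequences.
#' @export
cluster_by_identity <- function(dset) {
  stopifnot(inherits(dset, "DiscretizedTrajectorySet"))
  keys <- apply(dset$trajectories, 1L, paste, collapse = ",")
  groups <- split(rownames(dset$trajectories), keys)
  new_partition(groups[order(names(groups))], "identity",
                list(width = dset$width))
}

## k-means++ seeding: first centre uniform, later centres with probability
## proportional to squared distance to the nearest chosen centre.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  if (k > 1L) {
    d2 <- rowSums((x - matrix(centers[1L, ], n, ncol(x), byrow = TRUE))^2)
    for (j in 2:k) {
      if (all(d2 <= 0)) idx <- sample.int(n, 1L)
      else idx <- sample.int(n, 1L, prob = d2)
      centers[j, ] <- x[idx, ]
      d2j <- rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2)
      d2 <- pmin(d2, d2j)
    }
  }
  centers
}

dist2_to_centers <- function(x, centers) {
  ## n x k matrix of squared Euclidean distances
  xx <- rowSums(x^2)
  cc <- rowSums(centers^2)
  outer(xx, cc, "+") - 2 * x %*% t(centers)
}

lloyd_once <- function(x, k, max_iter, tol) {
  centers <- kmeanspp_init(x, k)
  assign <- rep(0L, nrow(x))
  wcss_trace <- numeric()
  for (it in seq_len(max_iter)) {
    d2 <- dist2_to_centers(x, centers)
    assign <- max.col(-d2, ties.method = "first")
    wcss_trace <- c(wcss_trace, sum(d2[cbind(seq_len(nrow(x)), assign)]))
    new_centers <- centers
    for (j in seq_len(k)) {
      sel <- assign == j
      if (!any(sel)) {
        ## empty cluster: re-seed to the point farthest from its centre
        far <- which.max(d2[cbind(seq_len(nrow(x)), assign)])
        new_centers[j, ] <- x[far, ]
      } else {
        new_centers[j, ] <- colMeans(x[sel, , drop = FALSE])
      }
    }
    shift <- sqrt(max(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    if (shift < tol) break
  }
  d2 <- dist2_to_centers(x, centers)
  assign <- max.col(-d2, ties.method = "first")
  wcss <- sum(d2[cbind(seq_len(nrow(x)), assign)])
  list(assign = assign, centers = centers, wcss = wcss,
       wcss_trace = wcss_trace, iterations = it)
}

#' k-means clustering of raw expression profiles
#'
#' Lloyd's algorithm with squared-Euclidean distance on the un-discretized
#' aggregated profiles, k-means++ initialization, and the best of `n_init`
#' seeded restarts by within-cluster sum of squares (WCSS). An empty cluster
#' is repaired by re-seeding it to the point farthest from its current
#' centre. With a fixed `seed` the partition is bit-for-bit reproducible.
#'
#' @param agg `AggregatedDataset` without missing cells among clustered
#'   probes (exclude incomplete probes first; see [discretize()]'s
#'   exclusion list).
#' @param k number of clusters, at most the probe count.
#' @param seed integer RNG seed, recorded in provenance.
#' @param n_init number of k-means++ restarts (default 10).
#' @param max_iter Lloyd iteration cap per restart (default 300).
#' @param tol convergence threshold on maximum centroid movement
#'   (Euclidean, default 1e-6).
#' @return `Partition` with groups `"1"..."k"`; attribute `centers` holds
#'   the centroid matrix, attribute `wcss` the final WCSS.
#' @export
kmeans_profiles <- function(agg, k, seed = 1L, n_init = 10L,
                            max_iter = 300L, tol = 1e-6) {
  stopifnot(inherits(agg, "AggregatedDataset"))
  x <- agg$values
  if (anyNA(x))
    stop("missing cells among clustered probes; exclude incomplete probes ",
         "(see the discretization exclusion list) before k-means")
  k <- as.integer(k)
  if (k < 1L) stop("`k` must be positive")
  if (k > nrow(x)) stop("`k` (", k, ") exceeds the probe count (", nrow(x), ")")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                           globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(n_init)) {
    fit <- lloyd_once(x, k, max_iter, tol)
    if (any(diff(fit$wcss_trace) > 1e-8 * (1 + fit$wcss_trace[1L])))
      warning("WCSS increased during a Lloyd run (numerical anomaly)")
    if (is.null(best) || fit$wcss < best$wcss) best <- fit
  }
  groups <- split(rownames(x), best$assign)
  cluster_ids <- as.integer(names(groups))
  ## relabel clusters deterministically: by first member probe id
  ord <- order(vapply(groups, function(g) sort(g)[1L], ""))
  centers <- best$centers[cluster_ids[ord], , drop = FALSE]
  groups <- stats::setNames(groups[ord], as.character(seq_along(groups)))
  dimnames(centers) <- list(names(groups), colnames(x))
  p <- new_partition(groups, "kmeans",
                     list(k = k, seed = as.integer(seed), n_init = n_init,
                          max_iter = max_iter, tol = tol))
  attr(p, "centers") <- centers
  attr(p, "wcss") <- best$wcss
  p
}

#' Partition membership as a named vector
#' @param p `Partition`.
#' @return named character vector probe -> group key.
#' @export
partition_assignments <- function(p) {
  stopifnot(inherits(p, "Partition"))
  keys <- rep(names(p$groups), vapply(p$groups, length, 0L))
  stats::setNames(keys, unlist(p$groups, use.names = FALSE))
}
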