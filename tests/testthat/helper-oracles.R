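# Independent oracles. These deliberately avoid the code paths they check:
# the hypergeometric oracle enumerates subsets, the k-means oracle searches
# all partitions, ARI is computed from the contingency table directly.

# P[overlap = k] by enumerating all C(N, n) draws from a universe whose
# first D elements are "in the pathway". Exact in integer arithmetic.
hyper_enum <- function(N, D, n) {
  if (n == 0L) return(c(`0` = 1))
  draws <- utils::combn(N, n)
  k_of_draw <- colSums(draws <= D)
  counts <- tabulate(k_of_draw + 1L, nbins = min(n, D) + 1L)
  stats::setNames(counts / choose(N, n), 0:min(n, D))
}

# Adjusted Rand index from two label vectors (same order).
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# Exhaustive minimum-WCSS 2-partition of the rows of x (n <= 20).
best_two_partition <- function(x) {
  n <- nrow(x)
  wcss_of <- function(sel) {
    part_ss <- function(rows) {
      if (!length(rows)) return(0)
      m <- x[rows, , drop = FALSE]
      sum(sweep(m, 2L, colMeans(m))^2)
    }
    part_ss(which(sel)) + part_ss(which(!sel))
  }
  best <- NULL
  # first point fixed in cluster 1 to halve the search; both sides non-empty
  for (mask in 0:(2^(n - 1) - 2)) {
    sel <- c(TRUE, bitwAnd(mask, 2^(0:(n - 2))) > 0)
    w <- wcss_of(sel)
    if (is.null(best) || w < best$wcss) best <- list(wcss = w, sel = sel)
  }
  best
}

f1_score <- function(selected, reference) {
  pr <- precision_recall(selected, reference)
  if (any(is.na(pr)) || sum(pr) == 0) return(0)
  2 * pr[["precision"]] * pr[["recall"]] / (pr[["precision"]] + pr[["recall"]])
}
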