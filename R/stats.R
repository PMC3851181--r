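## Numerical and statistical operators: hypergeometric association p-values,
## precision/recall, trajectory volatility and linear trend, volatility
## ranking, and pathway-intersection counts.

check_hyper_args <- function(N, D, n, k) {
  if (any(c(N, D, n, k) < 0) || any(c(N, D, n, k) != floor(c(N, D, n, k))))
    stop("N, D, n, k must be non-negative integers")
  if (D > N) stop("D > N")
  if (n > N) stop("n > N")
  if (k > min(n, D)) stop("k > min(n, D)")
  if (n - k > N - D) stop("n - k > N - D (more non-pathway picks than exist)")
}

#' Point hypergeometric probability of an overlap
#'
#' The probability that a uniformly drawn size-`n` probe set from a universe
#' of `N` probes, `D` of which lie in a pathway, overlaps the pathway in
#' exactly `k` probes: `C(D,k) C(N-D,n-k) / C(N,n)`. Computed in log space
#' so large universes do not overflow.
#'
#' @param N universe size.
#' @param D probes in the pathway.
#' @param n probes in the association (cluster, filter result, ...).
#' @param k observed overlap.
#' @return probability in `[0, 1]`.
#' @export
hypergeom_point <- function(N, D, n, k) {
  check_hyper_args(N, D, n, k)
  exp(lchoose(D, k) + lchoose(N - D, n - k) - lchoose(N, n))
}

#' Upper-tail hypergeometric p-value
#'
#' `P[X >= k]`: the sum of the point probabilities from the observed
#' overlap up to `min(n, D)`. This is the usual over-representation p-value;
#' the point term alone is available through [hypergeom_point()].
#'
#' @inheritParams hypergeom_point
#' @return p-value in `[0, 1]`; exactly 1 when `k = 0`.
#' @export
hypergeom_tail <- function(N, D, n, k) {
  check_hyper_args(N, D, n, k)
  js <- k:min(n, D)
  valid <- (n - js) <= (N - D)
  sum(vapply(js[valid], function(j) hypergeom_point(N, D, n, j), 0))
}

#' Pathway/label association scan of a selected probe set
#'
#' For every pathway and label with at least one member in the universe
#' (`D > 0`), scores the overlap with the selected set by the hypergeometric
#' point probability or upper-tail p-value; optional Benjamini-Hochberg
#' adjustment across the scored sets. Sets with `D = 0` are skipped and
#' listed in the `skipped` attribute.
#'
#' @param selected probe set of interest, a subset of `universe`.
#' @param annotation `AnnotationSet` holding the pathways and labels.
#' @param universe probe universe `N` is counted over.
#' @param mode `"tail"` (default, upper-tail p-value) or `"point"`
#'   (the bare point term).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return `EnrichmentTable` (a data frame), one row per scored set, sorted
#'   ascending by p: columns `set_name`, `kind`, `N`, `D`, `n`, `k`,
#'   `p_point`, `p_tail`, `p`, and `q` when adjusted.
#' @export
enrich <- function(selected, annotation, universe,
                   mode = c("tail", "point"), adjust = c("none", "BH")) {
  mode <- match.arg(mode)
  adjust <- match.arg(adjust)
  stopifnot(inherits(annotation, "AnnotationSet"))
  selected <- unique(selected)
  if (!all(selected %in% universe))
    stop("`selected` is not a subset of `universe`: ",
         paste(utils::head(setdiff(selected, universe), 5L), collapse = ", "))
  N <- length(unique(universe))
  n <- length(selected)
  sets <- c(stats::setNames(annotation$pathways,
                            names(annotation$pathways)),
            stats::setNames(annotation$labels, names(annotation$labels)))
  kind <- c(rep("pathway", length(annotation$pathways)),
            rep("label", length(annotation$labels)))
  Ds <- vapply(sets, function(s) length(intersect(s, universe)), 0L)
  skipped <- names(sets)[Ds == 0L]
  keep <- Ds > 0L
  sets <- sets[keep]; kind <- kind[keep]; Ds <- Ds[keep]
  rows <- lapply(seq_along(sets), function(i) {
    D <- Ds[[i]]
    k <- length(intersect(selected, intersect(sets[[i]], universe)))
    data.frame(set_name = names(sets)[i], kind = kind[i],
               N = N, D = D, n = n, k = k,
               p_point = hypergeom_point(N, D, n, k),
               p_tail = hypergeom_tail(N, D, n, k),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(set_name = character(), kind = character(),
                      N = integer(), D = integer(), n = integer(),
                      k = integer(), p_point = numeric(),
                      p_tail = numeric(), stringsAsFactors = FALSE)
  tab$p <- if (mode == "tail") tab$p_tail else tab$p_point
  if (adjust == "BH" && nrow(tab)) tab$q <- stats::p.adjust(tab$p, "BH")
  tab <- tab[order(tab$p, tab$set_name), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, class = c("EnrichmentTable", "data.frame"),
            mode = mode, adjust = adjust, skipped = skipped)
}

#' Precision and recall of a selected set against a reference
#'
#' `precision = |S  intersect  R| / |S|`, `recall = |S intersect R| / |R|`;
#' an empty selected or reference set makes the corresponding value `NA`
#' ("not applicable") rather than an error.
#'
#' @param selected probe set `S`.
#' @param reference probe set `R`.
#' @return named numeric vector `c(precision =, recall =)`.
#' @export
precision_recall <- function(selected, reference) {
  S <- unique(selected); R <- unique(reference)
  common <- length(intersect(S, R))
  c(precision = if (length(S)) common / length(S) else NA_real_,
    recall = if (length(R)) common / length(R) else NA_real_)
}

#' Trajectory volatility
#'
#' The sum of absolute successive differences of a trajectory,
#' `V(T) = sum_{i=2..N} |e_i - e_{i-1}|`: zero iff the trajectory is
#' constant, high for strongly moving (or erroneous) probes.
#'
#' @param T numeric sequence of at least 2 values (bins or log2 units).
#' @return non-negative scalar.
#' @export
volatility <- function(T) {
  if (length(T) < 2L) stop("volatility needs at least 2 time points")
  sum(abs(diff(T)))
}

#' Trajectory linear trend
#'
#' The sum of successive differences, `L(T) = sum_{i=2..N} (e_i - e_{i-1})`,
#' which telescopes to `e_N - e_1`: net movement over the whole course.
#' Always `|L(T)| <= V(T)`, with equality iff the trajectory is monotone.
#'
#' @param T numeric sequence of at least 2 values.
#' @return scalar (may be negative).
#' @export
linear_trend <- function(T) {
  if (length(T) < 2L) stop("linear trend needs at least 2 time points")
  sum(diff(T))
}

#' Score and rank all probes by volatility
#'
#' Works on either a `DiscretizedTrajectorySet` (bin units) or an
#' `AggregatedDataset` (log2 units); the unit is recorded in the result.
#' Ties are broken by probe id ascending, so the ranking is deterministic.
#'
#' @param dset trajectory set or aggregated dataset with >= 2 time points.
#' @param descending sort most-volatile first (default `TRUE`).
#' @return data frame with columns `probe`, `volatility`, `linear_trend`,
#'   in rank order; attribute `units` is `"bins"` or `"log2"`.
#' @export
rank_by_volatility <- function(dset, descending = TRUE) {
  if (inherits(dset, "DiscretizedTrajectorySet")) {
    m <- dset$trajectories; units <- "bins"
  } else if (inherits(dset, "AggregatedDataset")) {
    m <- dset$values; units <- "log2"
  } else stop("need a DiscretizedTrajectorySet or AggregatedDataset")
  if (ncol(m) < 2L) stop("ranking needs at least 2 time points")
  V <- apply(m, 1L, volatility)
  L <- apply(m, 1L, linear_trend)
  out <- data.frame(probe = rownames(m), volatility = unname(V),
                    linear_trend = unname(L), stringsAsFactors = FALSE)
  o <- if (descending) order(-out$volatility, out$probe)
       else order(out$volatility, out$probe)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "units") <- units
  out
}

#' Context / pathway / overlap counts for every pathway
#'
#' The sidebar-style intersection view: for each pathway, the size of the
#' current probe context, the pathway size, and their overlap. Consistent by
#' construction with `enrich()`'s `n`, `D`, `k` on the same inputs.
#'
#' @param context current probe set.
#' @param annotation `AnnotationSet`.
#' @return data frame with columns `pathway`, `n_context`, `n_pathway`,
#'   `n_common`.
#' @export
pathway_intersection <- function(context, annotation) {
  stopifnot(inherits(annotation, "AnnotationSet"))
  context <- unique(context)
  data.frame(
    pathway = names(annotation$pathways),
    n_context = length(context),
    n_pathway = vapply(annotation$pathways, length, 0L),
    n_common = vapply(annotation$pathways,
                      function(s) length(intersect(context, s)), 0L),
    row.names = NULL, stringsAsFactors = FALSE)
}
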