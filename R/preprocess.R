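## Temporal aggregation and equi-width trajectory discretization.

new_aggregated <- function(values, timepoint_order, method, provenance) {
  structure(list(values = values, timepoint_order = timepoint_order,
                 method = method, provenance = provenance),
            class = "AggregatedDataset")
}

#' @export
print.AggregatedDataset <- function(x, ...) {
  cat(sprintf("AggregatedDataset (%s): %d probes x %d time points\n",
              x$method, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Collapse replicate samples to one value per time point
#'
#' Each cell (probe, time point) becomes the mean or median over the
#' non-missing replicate values of that probe at that time point. A cell is
#' missing only if every replicate was missing; such cells are counted in the
#' `aggregation_report` attribute.
#'
#' @param ds `ExpressionDataset`.
#' @param method `"mean"` or `"median"`.
#' @return `AggregatedDataset` with one ordered column per time point.
#' @export
aggregate_replicates <- function(ds, method = c("median", "mean")) {
  method <- match.arg(method)
  stopifnot(inherits(ds, "ExpressionDataset"))
  fun <- if (method == "mean") function(v) mean(v, na.rm = TRUE)
         else function(v) stats::median(v, na.rm = TRUE)
  tp <- ds$timepoint_order
  cols <- lapply(tp, function(t) {
    sel <- ds$sample_ids[ds$sample_to_timepoint == t]
    sub <- ds$values[, sel, drop = FALSE]
    apply(sub, 1L, fun)
  })
  values <- do.call(cbind, cols)
  values[is.nan(values)] <- NA_real_
  dimnames(values) <- list(ds$probe_ids, tp)
  agg <- new_aggregated(values, tp, method,
                        provenance = list(op = "aggregate_replicates",
                                          method = method))
  attr(agg, "aggregation_report") <-
    list(n_all_missing_cells = sum(is.na(values)))
  agg
}

#' Re-aggregate consecutive time points into fixed-length segments
#'
#' Time points are grouped left to right into segments of `segment_length`;
#' each segment becomes one new time point whose value is the mean or median
#' over its member columns. A shorter final segment is kept and aggregated
#' over its members (flagged in the report). New labels record the member
#' range, e.g. `"t1..t3"`.
#'
#' @param agg `AggregatedDataset`.
#' @param segment_length positive integer, at most the time-point count.
#' @param method `"mean"` or `"median"`.
#' @return `AggregatedDataset` over the segment time points.
#' @export
segment_aggregate <- function(agg, segment_length,
                              method = c("median", "mean")) {
  method <- match.arg(method)
  stopifnot(inherits(agg, "AggregatedDataset"))
  nt <- ncol(agg$values)
  segment_length <- as.integer(segment_length)
  if (is.na(segment_length) || segment_length < 1L)
    stop("`segment_length` must be a positive integer")
  if (segment_length > nt)
    stop("`segment_length` (", segment_length,
         ") exceeds the number of time points (", nt, ")")
  grp <- rep(seq_len(ceiling(nt / segment_length)),
             each = segment_length, length.out = nt)
  fun <- if (method == "mean") function(v) mean(v, na.rm = TRUE)
         else function(v) stats::median(v, na.rm = TRUE)
  labels <- unname(vapply(split(agg$timepoint_order, grp), function(ts) {
    if (length(ts) == 1L) ts else paste0(ts[1L], "..", ts[length(ts)])
  }, ""))
  cols <- lapply(split(seq_len(nt), grp), function(idx) {
    sub <- agg$values[, idx, drop = FALSE]
    out <- apply(sub, 1L, fun)
    out[is.nan(out)] <- NA_real_
    out
  })
  values <- do.call(cbind, cols)
  dimnames(values) <- list(rownames(agg$values), labels)
  out <- new_aggregated(values, labels, method,
                        provenance = c(agg$provenance,
                                       list(segment_length = segment_length)))
  attr(out, "segment_report") <- list(
    n_segments = length(labels),
    partial_final_segment = (nt %% segment_length) != 0L)
  out
}

## Boundary guard: values within 1e-9*w below a bin boundary are snapped up
## before flooring, so representation error cannot drop an exact boundary
## value into the lower bin.
BOUNDARY_GUARD <- 1e-9

#' Equi-width discretization of aggregated trajectories
#'
#' Assigns every value `e` the integer bin `b = floor(e / w)`, i.e. the
#' half-open interval `[b*w, (b+1)*w)` -- exact boundary values join the
#' upper bin. Probes with any missing aggregated value are excluded (listed
#' in `$excluded`), because the trajectory operators need full-length bin
#' sequences.
#'
#' @param agg `AggregatedDataset`.
#' @param w bin width, positive, in the units of the matrix (log2).
#' @return `DiscretizedTrajectorySet`: integer matrix `trajectories`
#'   (probes x time points), `width`, `timepoint_order`, `excluded`.
#' @export
discretize <- function(agg, w) {
  stopifnot(inherits(agg, "AggregatedDataset"))
  if (!is.numeric(w) || length(w) != 1L || !is.finite(w) || w <= 0)
    stop("`w` must be a positive number")
  complete <- !apply(is.na(agg$values), 1L, any)
  excluded <- rownames(agg$values)[!complete]
  vals <- agg$values[complete, , drop = FALSE]
  bins <- floor(vals / w + BOUNDARY_GUARD)
  storage.mode(bins) <- "integer"
  structure(list(trajectories = bins, width = w,
                 timepoint_order = agg$timepoint_order,
                 excluded = excluded,
                 provenance = c(agg$provenance, list(width = w))),
            class = "DiscretizedTrajectorySet")
}

#' @export
print.DiscretizedTrajectorySet <- function(x, ...) {
  cat(sprintf(
    "DiscretizedTrajectorySet: %d probes x %d time points, width %g (%d excluded)\n",
    nrow(x$trajectories), ncol(x$trajectories), x$width, length(x$excluded)))
  invisible(x)
}

#' Pair discretized trajectories with their raw profiles
#'
#' Returns, for every probe kept at discretization, both the raw aggregated
#' profile and its bin sequence -- the data behind a hybrid
#' (discretized + raw) trajectory view. Probes excluded at discretization are
#' absent from the pairing.
#'
#' @param dset `DiscretizedTrajectorySet` derived from `agg`.
#' @param agg the source `AggregatedDataset`.
#' @return list with `probe_ids`, `raw` (matrix), `bins` (matrix), `width`.
#' @export
undiscretize_view <- function(dset, agg) {
  stopifnot(inherits(dset, "DiscretizedTrajectorySet"),
            inherits(agg, "AggregatedDataset"))
  if (!identical(dset$timepoint_order, agg$timepoint_order))
    stop("provenance mismatch: time points of trajectory set and dataset differ")
  probes <- rownames(dset$trajectories)
  if (!all(probes %in% rownames(agg$values)))
    stop("provenance mismatch: trajectory set has probes absent from dataset")
  raw <- agg$values[probes, , drop = FALSE]
  resid <- raw - dset$trajectories * dset$width
  if (any(resid < -BOUNDARY_GUARD * dset$width |
          resid >= dset$width * (1 + BOUNDARY_GUARD), na.rm = TRUE))
    stop("provenance mismatch: values do not lie in their assigned bins")
  list(probe_ids = probes, raw = raw, bins = dset$trajectories,
       width = dset$width)
}
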