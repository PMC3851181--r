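## Cross-dataset comparison: primary/secondary pairing and the
## differentiation operator.

#' Pair a primary (experiment) and secondary (control) aggregated dataset
#'
#' The pair is built over the probe intersection; time points are matched by
#' ORDER (first with first, and so on), not by label, because control and
#' treatment arms often label the same design positions differently -- a
#' warning is raised when labels differ. Dropped probes are reported per
#' side in the `drop_report` attribute.
#'
#' @param primary `AggregatedDataset` (the experiment arm).
#' @param secondary `AggregatedDataset` (the control arm).
#' @return `ComparisonPair` with both datasets restricted to the shared
#'   probes, `shared_probes`, `shared_timepoints` (primary's labels).
#' @export
make_pair <- function(primary, secondary) {
  stopifnot(inherits(primary, "AggregatedDataset"),
            inherits(secondary, "AggregatedDataset"))
  if (ncol(primary$values) != ncol(secondary$values))
    stop("time-point counts differ: ", ncol(primary$values), " vs ",
         ncol(secondary$values))
  shared <- intersect(rownames(primary$values), rownames(secondary$values))
  if (!length(shared)) stop("datasets share no probes")
  if (!identical(primary$timepoint_order, secondary$timepoint_order))
    warning("time-point labels differ between arms; matching by order")
  dropped_primary <- setdiff(rownames(primary$values), shared)
  dropped_secondary <- setdiff(rownames(secondary$values), shared)
  pr <- primary
  pr$values <- primary$values[shared, , drop = FALSE]
  se <- secondary
  se$values <- secondary$values[shared, , drop = FALSE]
  pair <- structure(list(primary = pr, secondary = se,
                         shared_probes = shared,
                         shared_timepoints = primary$timepoint_order),
                    class = "ComparisonPair")
  attr(pair, "drop_report") <- list(primary_only = dropped_primary,
                                    secondary_only = dropped_secondary)
  pair
}

#' Differential dataset: primary minus secondary, per probe and time point
#'
#' Each cell is `primary(p, t) - secondary(p, t)`; the result is a regular
#' `AggregatedDataset` (provenance marks it differential) and feeds
#' discretization, clustering and filtering unchanged -- negative bins then
#' mean "below control".
#'
#' @param pair `ComparisonPair`.
#' @return `AggregatedDataset` of differences on the shared probes.
#' @export
differential_dataset <- function(pair) {
  stopifnot(inherits(pair, "ComparisonPair"))
  values <- pair$primary$values - pair$secondary$values
  dimnames(values) <- list(pair$shared_probes, pair$shared_timepoints)
  new_aggregated(values, pair$shared_timepoints,
                 method = pair$primary$method,
                 provenance = list(op = "differential",
                                   primary = pair$primary$provenance,
                                   secondary = pair$secondary$provenance))
}

#' Primary, secondary and difference profiles for one probe
#'
#' The comparative-view export: the probe's profile in each arm plus their
#' per-time-point difference (which always equals the corresponding row of
#' [differential_dataset()]).
#'
#' @param pair `ComparisonPair`.
#' @param probe probe id; must be shared by both arms.
#' @return list with `probe`, `timepoints`, `primary`, `secondary`,
#'   `difference` (numeric vectors).
#' @export
subtractive_profile <- function(pair, probe) {
  stopifnot(inherits(pair, "ComparisonPair"))
  if (!(probe %in% pair$shared_probes))
    stop("probe '", probe, "' is not shared by both datasets")
  p <- pair$primary$values[probe, ]
  s <- pair$secondary$values[probe, ]
  list(probe = probe, timepoints = pair$shared_timepoints,
       primary = unname(p), secondary = unname(s),
       difference = unname(p - s))
}
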