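# Fixture builders used across the suite. Everything goes through the
# public API: an AggregatedDataset is produced by aggregating a one-
# replicate-per-time-point ExpressionDataset (the identity aggregation).

make_eds <- function(values, replicates_per_tp = 1L,
                     tp = paste0("t", seq_len(ncol(values) / replicates_per_tp))) {
  n_samp <- ncol(values)
  samples <- paste0("s", seq_len(n_samp))
  colnames(values) <- samples
  if (is.null(rownames(values)))
    rownames(values) <- paste0("P", seq_len(nrow(values)))
  map <- stats::setNames(rep(tp, each = replicates_per_tp), samples)
  expression_dataset(values, map, tp)
}

make_agg <- function(values, method = "median") {
  aggregate_replicates(make_eds(values), method)
}

# Integer bin matrix -> DiscretizedTrajectorySet with exactly those bins
# (values are placed mid-bin so no boundary ambiguity).
make_dset <- function(bins, w = 1) {
  if (is.null(rownames(bins))) rownames(bins) <- paste0("P", seq_len(nrow(bins)))
  discretize(make_agg(bins * w + 0.25 * w), w)
}

rand_bins <- function(n_probes, n_tp, max_bin = 5L) {
  matrix(sample(seq(-max_bin, max_bin), n_probes * n_tp, replace = TRUE),
         nrow = n_probes,
         dimnames = list(sprintf("P%03d", seq_len(n_probes)),
                         paste0("t", seq_len(n_tp))))
}

write_tsv_lines <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

# Minimal 3-probe x 4-sample matrix + map over 2 time points.
tiny_matrix_files <- function() {
  mat <- write_tsv_lines(c(
    "probe_id\tS1\tS2\tS3\tS4",
    "P1\t1.0\t1.2\t2.0\t2.2",
    "P2\t0.5\t0.7\t0.4\t0.6",
    "P3\t3.0\tNA\t3.5\t3.6"))
  map <- write_tsv_lines(c(
    "sample_id\ttimepoint\torder",
    "S1\tearly\t1", "S2\tearly\t1", "S3\tlate\t2", "S4\tlate\t2"))
  list(matrix = mat, map = map)
}
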