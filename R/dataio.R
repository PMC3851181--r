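RESULT_SCHEMA_VERSION <- "1.0"

## ---------------------------------------------------------------------------
## Domain types
## ---------------------------------------------------------------------------

#' Construct a validated expression dataset
#'
#' An `ExpressionDataset` holds a probe x sample matrix of base-2
#' log-transformed expression values together with the replicate design:
#' which sample belongs to which time point, and in what order the time
#' points occur. Missing cells (`NA`) are allowed.
#'
#' @param values numeric matrix, rows = probes, cols = samples; `rownames`
#'   and `colnames` must be set and unique.
#' @param sample_to_timepoint named character vector mapping every sample id
#'   to a time-point label.
#' @param timepoint_order character vector of time-point labels in temporal
#'   order; every mapped label must appear here and every label must have at
#'   least one sample.
#' @return object of class `ExpressionDataset` with fields `probe_ids`,
#'   `sample_ids`, `values`, `sample_to_timepoint`, `timepoint_order`.
#' @export
expression_dataset <- function(values, sample_to_timepoint, timepoint_order) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  probe_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(probe_ids) || is.null(sample_ids))
    stop("`values` must carry probe rownames and sample colnames")
  if (anyDuplicated(probe_ids))
    stop("duplicate probe IDs: ",
         paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample IDs: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  sample_to_timepoint <- sample_to_timepoint[sample_ids]
  missing_map <- sample_ids[is.na(sample_to_timepoint) |
                              is.na(names(sample_to_timepoint))]
  if (length(missing_map))
    stop("samples absent from the sample map: ",
         paste(missing_map, collapse = ", "))
  if (anyDuplicated(timepoint_order))
    stop("duplicated labels in `timepoint_order`")
  bad_tp <- setdiff(unique(sample_to_timepoint), timepoint_order)
  if (length(bad_tp))
    stop("time-point labels not in `timepoint_order`: ",
         paste(bad_tp, collapse = ", "))
  empty_tp <- setdiff(timepoint_order, sample_to_timepoint)
  if (length(empty_tp))
    stop("time points with no samples: ", paste(empty_tp, collapse = ", "))
  structure(
    list(probe_ids = probe_ids,
         sample_ids = sample_ids,
         values = values,
         sample_to_timepoint = sample_to_timepoint,
         timepoint_order = timepoint_order),
    class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d probes x %d samples, %d time points\n",
              length(x$probe_ids), length(x$sample_ids),
              length(x$timepoint_order)))
  invisible(x)
}

#' Construct an annotation set
#'
#' Bundles probe-to-gene mapping, pathway membership and free-form probe
#' labels. Members outside the declared probe universe are not silently
#' dropped: they are recorded per set in the `report` field.
#'
#' @param probe_to_gene named character vector (probe -> gene symbol),
#'   possibly partial.
#' @param pathways named list of character vectors of probe ids.
#' @param labels named list of character vectors of probe ids.
#' @param universe optional probe universe; when given, members outside it
#'   are moved to the load report (`unmatched`) and sets are restricted.
#' @return object of class `AnnotationSet`.
#' @export
annotation_set <- function(probe_to_gene = character(),
                           pathways = list(),
                           labels = list(),
                           universe = NULL) {
  restrict <- function(sets) {
    unmatched <- lapply(sets, function(s) {
      s <- unique(s)
      if (is.null(universe)) character() else setdiff(s, universe)
    })
    kept <- lapply(sets, function(s) {
      s <- unique(s)
      if (is.null(universe)) s else intersect(s, universe)
    })
    list(kept = kept, unmatched = unmatched)
  }
  pw <- restrict(pathways)
  lb <- restrict(labels)
  structure(
    list(probe_to_gene = probe_to_gene,
         pathways = pw$kept,
         labels = lb$kept,
         report = list(pathway_unmatched = vapply(pw$unmatched, length, 0L),
                       label_unmatched = vapply(lb$unmatched, length, 0L))),
    class = "AnnotationSet")
}

## ---------------------------------------------------------------------------
## Readers
## ---------------------------------------------------------------------------

MISSING_TOKENS <- c("NA", "NaN", "")

#' Read a probe x sample expression matrix plus its sample map
#'
#' The matrix file is tab-separated: first row sample ids, first column probe
#' ids, `#`-prefixed comment lines ignored. Cells are numeric or one of the
#' missing tokens `NA`, `NaN`, or empty. The sample map is a TSV with columns
#' `sample_id`, `timepoint` and an optional integer `order` column fixing the
#' temporal order of the time-point labels; without it lexical order is used
#' with a warning.
#'
#' @param path expression matrix TSV.
#' @param sample_map_path sample map TSV.
#' @param log2_transform apply `log2()` at load (for raw-scale inputs);
#'   errors on values <= 0.
#' @return `ExpressionDataset`; attribute `load_report` carries probe /
#'   sample / time-point / missing-cell counts.
#' @export
read_expression_matrix <- function(path, sample_map_path,
                                   log2_transform = FALSE) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) < 2L) stop("expression matrix has no data rows: ", path)
  ## keep trailing empty cells: strsplit drops a trailing field
  fields <- strsplit(paste0(lines, "\x1e"), "\t", fixed = TRUE)
  fields <- lapply(fields, function(f) {
    f[length(f)] <- sub("\x1e$", "", f[length(f)])
    f
  })
  header <- fields[[1L]]
  sample_ids <- header[-1L]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample IDs in header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  body <- fields[-1L]
  probe_ids <- vapply(body, `[`, "", 1L)
  if (anyDuplicated(probe_ids))
    stop("duplicate probe IDs: ",
         paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "))
  ncol_expected <- length(sample_ids) + 1L
  nf <- lengths(body)
  if (any(nf != ncol_expected))
    stop("row ", probe_ids[which(nf != ncol_expected)[1L]],
         " has ", nf[which(nf != ncol_expected)[1L]] - 1L,
         " cells, expected ", length(sample_ids))
  cells <- matrix(unlist(body), nrow = length(body), byrow = TRUE)[, -1L,
                                                                   drop = FALSE]
  is_missing <- cells %in% MISSING_TOKENS
  num <- suppressWarnings(as.numeric(cells))
  bad <- which(is.na(num) & !is_missing)
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(cells)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(cells)) + 1L
    stop(sprintf("non-numeric cell '%s' at (%s, %s)",
                 cells[bad[1L]], probe_ids[i], sample_ids[j]))
  }
  num[is_missing] <- NA_real_
  values <- matrix(num, nrow = length(probe_ids),
                   dimnames = list(probe_ids, sample_ids))
  if (log2_transform) {
    if (any(values <= 0, na.rm = TRUE))
      stop("--log2 requested but matrix contains values <= 0")
    values <- log2(values)
  }

  sm <- utils::read.delim(sample_map_path, comment.char = "#",
                          colClasses = "character")
  if (!all(c("sample_id", "timepoint") %in% names(sm)))
    stop("sample map must have columns sample_id and timepoint")
  if (anyDuplicated(sm$sample_id))
    stop("duplicate sample IDs in sample map")
  map <- stats::setNames(sm$timepoint, sm$sample_id)
  absent <- setdiff(sample_ids, sm$sample_id)
  if (length(absent))
    stop("samples in matrix but not in map: ", paste(absent, collapse = ", "))
  if ("order" %in% names(sm)) {
    ord <- as.integer(sm$order)
    if (anyNA(ord)) stop("non-integer values in sample-map `order` column")
    tp <- unique(sm$timepoint[order(ord)])
  } else {
    warning("sample map has no `order` column; using lexical time-point order")
    tp <- sort(unique(sm$timepoint))
  }
  ds <- expression_dataset(values, map, tp)
  attr(ds, "load_report") <- list(
    n_probes = length(probe_ids),
    n_samples = length(sample_ids),
    n_timepoints = length(tp),
    n_missing_cells = sum(is.na(values)))
  ds
}

#' Read gene sets in GMT format into pathway annotations
#'
#' Standard GMT: one set per line -- name, description, then members,
#' tab-separated. Members may be gene symbols (mapped to probes through
#' `probe_to_gene`, many-to-many: a gene claims all its probes) or probe ids.
#' Sets that map to nothing are kept at size zero with a warning, so that
#' downstream statistics can handle D = 0 explicitly.
#'
#' @param path GMT file.
#' @param universe probe universe used to restrict memberships.
#' @param probe_to_gene named character vector probe -> gene.
#' @return `AnnotationSet` with populated `pathways`.
#' @export
read_gene_sets_gmt <- function(path, universe, probe_to_gene = character()) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  gene_to_probes <- if (length(probe_to_gene))
    split(names(probe_to_gene), unname(probe_to_gene)) else list()
  pathways <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 2L) stop("malformed GMT line: ", substr(ln, 1, 40))
    name <- f[1L]
    members <- unique(f[-(1:2)])
    probes <- unique(c(
      members[members %in% universe],
      unlist(gene_to_probes[members[members %in% names(gene_to_probes)]],
             use.names = FALSE)))
    probes <- intersect(probes, universe)
    if (!length(probes))
      warning("gene set '", name, "' matched no probes in the universe")
    pathways[[name]] <- probes
  }
  annotation_set(probe_to_gene = probe_to_gene, pathways = pathways,
                 universe = universe)
}

#' Read a two-column probe annotation TSV
#'
#' @param path TSV with columns (probe, value); `#` comments ignored.
#' @return named character vector probe -> value.
#' @export
read_probe_annotation <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           colClasses = "character")
  if (ncol(tab) < 2L) stop("annotation file needs two columns: ", path)
  stats::setNames(tab[[2L]], tab[[1L]])
}

## ---------------------------------------------------------------------------
## Result serialization (JSON, schema-versioned, lossless round trip)
## ---------------------------------------------------------------------------

result_type_of <- function(obj) {
  if (inherits(obj, "Partition")) "partition"
  else if (inherits(obj, "TrajectoryGraph")) "trajectory_graph"
  else if (inherits(obj, "EnrichmentTable")) "enrichment_table"
  else if (inherits(obj, "AggregatedDataset")) "aggregated_dataset"
  else if (inherits(obj, "DiscretizedTrajectorySet")) "trajectory_set"
  else if (is.character(obj)) "probe_set"
  else stop("unknown result type: ", paste(class(obj), collapse = "/"))
}

#' Write an analysis result to a schema-versioned JSON document
#'
#' Supported result types: probe sets (character vectors), `Partition`,
#' `TrajectoryGraph`, `EnrichmentTable`, `AggregatedDataset` and
#' `DiscretizedTrajectorySet`. `read_result()` restores the object exactly.
#'
#' @param obj result object.
#' @param path output file.
#' @export
write_result <- function(obj, path) {
  type <- result_type_of(obj)
  payload <- switch(
    type,
    probe_set = list(probes = as.character(obj)),
    partition = list(groups = lapply(obj$groups, as.character),
                     group_keys = names(obj$groups),
                     method = obj$method, parameters = obj$parameters),
    trajectory_graph = list(
      node_ids = names(obj$members),
      node_t = unname(obj$node_t), node_bin = unname(obj$node_bin),
      parent = unname(obj$parent), members = unname(obj$members),
      timepoint_order = obj$timepoint_order),
    enrichment_table = list(table = as.list(as.data.frame(obj)),
                            mode = attr(obj, "mode"),
                            adjust = attr(obj, "adjust")),
    aggregated_dataset = list(
      probe_ids = rownames(obj$values),
      timepoint_order = obj$timepoint_order,
      values = apply(obj$values, 1L, function(r) unname(r),
                     simplify = FALSE),
      method = obj$method, provenance = obj$provenance),
    trajectory_set = list(
      probe_ids = rownames(obj$trajectories),
      timepoint_order = obj$timepoint_order,
      width = obj$width,
      trajectories = apply(obj$trajectories, 1L, function(r) unname(r),
                           simplify = FALSE),
      excluded = obj$excluded,
      provenance = obj$provenance))
  doc <- list(schema_version = RESULT_SCHEMA_VERSION, type = type,
              payload = payload)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = FALSE)
  invisible(path)
}

#' Read a result written by `write_result`
#' @param path JSON file produced by [write_result()].
#' @return the restored result object.
#' @export
read_result <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$schema_version))
    stop("not a trajex result file (no schema_version): ", path)
  p <- doc$payload
  chr <- function(x) vapply(x, as.character, "", USE.NAMES = FALSE)
  num_mat <- function(rows, rn, cn) {
    m <- do.call(rbind, lapply(rows, function(r)
      vapply(r, function(v) if (is.null(v)) NA_real_ else as.numeric(v), 0)))
    if (is.null(m)) m <- matrix(numeric(), 0L, length(cn))
    dimnames(m) <- list(rn, cn)
    m
  }
  switch(
    doc$type,
    probe_set = if (length(p$probes)) chr(p$probes) else character(),
    partition = new_partition(
      stats::setNames(lapply(p$groups, chr), chr(p$group_keys)),
      method = p$method, parameters = p$parameters),
    trajectory_graph = {
      ids <- chr(p$node_ids)
      structure(list(
        node_t = stats::setNames(vapply(p$node_t, as.integer, 0L), ids),
        node_bin = stats::setNames(vapply(p$node_bin, as.integer, 0L), ids),
        parent = stats::setNames(chr(p$parent), ids),
        members = stats::setNames(lapply(p$members, chr), ids),
        timepoint_order = chr(p$timepoint_order)),
        class = "TrajectoryGraph")
    },
    enrichment_table = {
      tab <- as.data.frame(lapply(p$table, function(col)
        unlist(lapply(col, function(v) if (is.null(v)) NA else v))),
        stringsAsFactors = FALSE)
      structure(tab, class = c("EnrichmentTable", "data.frame"),
                mode = p$mode, adjust = p$adjust)
    },
    aggregated_dataset = {
      tp <- chr(p$timepoint_order)
      new_aggregated(num_mat(p$values, chr(p$probe_ids), tp), tp,
                     method = p$method, provenance = p$provenance)
    },
    trajectory_set = {
      tp <- chr(p$timepoint_order)
      m <- num_mat(p$trajectories, chr(p$probe_ids), tp)
      storage.mode(m) <- "integer"
      structure(list(trajectories = m, width = as.numeric(p$width),
                     timepoint_order = tp,
                     excluded = if (length(p$excluded)) chr(p$excluded)
                                else character(),
                     provenance = p$provenance),
                class = "DiscretizedTrajectorySet")
    },
    stop("unknown result type in file: ", doc$type))
}

#' Write an expression dataset and its sample map as TSV
#' @param ds `ExpressionDataset`.
#' @param path matrix TSV path.
#' @param sample_map_path sample map TSV path.
#' @export
write_expression_matrix <- function(ds, path, sample_map_path) {
  m <- ds$values
  header <- paste(c("probe_id", colnames(m)), collapse = "\t")
  rows <- vapply(seq_len(nrow(m)), function(i)
    paste(c(rownames(m)[i], format(m[i, ], digits = 12, trim = TRUE,
                                   scientific = FALSE)),
          collapse = "\t"), "")
  writeLines(c(header, rows), path)
  ord <- match(ds$sample_to_timepoint, ds$timepoint_order)
  map_rows <- paste(ds$sample_ids, unname(ds$sample_to_timepoint), ord,
                    sep = "\t")
  writeLines(c("sample_id\ttimepoint\torder", map_rows), sample_map_path)
  invisible(path)
}

#' Write an aggregated dataset as a matrix TSV (one column per time point)
#' @param agg `AggregatedDataset`.
#' @param path output TSV.
#' @export
write_aggregated_tsv <- function(agg, path) {
  m <- agg$values
  header <- paste(c("probe_id", colnames(m)), collapse = "\t")
  rows <- vapply(seq_len(nrow(m)), function(i)
    paste(c(rownames(m)[i], format(m[i, ], digits = 12, trim = TRUE,
                                   scientific = FALSE)),
          collapse = "\t"), "")
  writeLines(c(header, rows), path)
  invisible(path)
}
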