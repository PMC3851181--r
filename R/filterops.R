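## Shape-based trajectory filtering, inverse-pattern search, and selection
## set algebra (highlight / isolate / exclude).

#' Build a trajectory shape criterion
#'
#' A criterion has one predicate per transition (time point relative to the
#' previous one): a direction -- `up` (bin delta > 0), `down` (delta < 0),
#' `same` (delta exactly 0) or `any` -- plus optional magnitude bounds
#' `min_delta`/`max_delta` on `|delta|`, in whole bins. The string syntax is
#' comma-separated transition specs: `"any,any,down:1"` means "anything,
#' anything, then down by at least 1 bin"; `"up:1:3"` bounds the magnitude
#' between 1 and 3 bins.
#'
#' @param spec either a character scalar in the syntax above, or a data
#'   frame with columns `direction`, `min_delta`, `max_delta`.
#' @return object of class `ShapeCriterion` (a data frame, one row per
#'   transition).
#' @export
shape_criterion <- function(spec) {
  if (is.character(spec) && length(spec) == 1L) {
    parts <- strsplit(spec, ",", fixed = TRUE)[[1L]]
    rows <- lapply(parts, function(p) {
      f <- strsplit(trimws(p), ":", fixed = TRUE)[[1L]]
      dir <- f[1L]
      mn <- if (length(f) >= 2L) as.integer(f[2L]) else NA_integer_
      mx <- if (length(f) >= 3L) as.integer(f[3L]) else NA_integer_
      data.frame(direction = dir, min_delta = mn, max_delta = mx)
    })
    spec <- do.call(rbind, rows)
  }
  stopifnot(is.data.frame(spec),
            all(c("direction", "min_delta", "max_delta") %in% names(spec)))
  if (!all(spec$direction %in% c("up", "down", "same", "any")))
    stop("direction must be one of up, down, same, any")
  both <- !is.na(spec$min_delta) & !is.na(spec$max_delta)
  if (any(spec$min_delta[both] > spec$max_delta[both]))
    stop("min_delta exceeds max_delta")
  if (any(spec$direction == "same" &
          ((!is.na(spec$min_delta) & spec$min_delta > 0L) |
           (!is.na(spec$max_delta) & spec$max_delta != 0L))))
    stop("direction 'same' forces delta 0; magnitude bounds must allow 0")
  structure(spec, class = c("ShapeCriterion", "data.frame"))
}

criterion_matches <- function(crit, deltas) {
  ## deltas: probes x transitions integer matrix; returns logical per probe
  ok <- rep(TRUE, nrow(deltas))
  for (i in seq_len(nrow(crit))) {
    d <- deltas[, i]
    ok <- ok & switch(crit$direction[i],
                      up = d > 0L, down = d < 0L, same = d == 0L,
                      any = rep(TRUE, length(d)))
    if (!is.na(crit$min_delta[i])) ok <- ok & abs(d) >= crit$min_delta[i]
    if (!is.na(crit$max_delta[i])) ok <- ok & abs(d) <= crit$max_delta[i]
  }
  ok
}

#' Filter trajectories by a shape criterion
#'
#' Returns the probes in `scope` whose bin-delta vector satisfies every
#' per-transition predicate of the criterion.
#'
#' @param dset `DiscretizedTrajectorySet`.
#' @param crit `ShapeCriterion` (or its string syntax); its length must
#'   equal the number of transitions.
#' @param scope probe ids to search within, or `NULL` for all probes in
#'   `dset`.
#' @return character vector of matching probe ids (a subset of scope).
#' @export
filter_by_shape <- function(dset, crit, scope = NULL) {
  stopifnot(inherits(dset, "DiscretizedTrajectorySet"))
  if (is.character(crit) && length(crit) == 1L && !inherits(crit, "ShapeCriterion"))
    crit <- shape_criterion(crit)
  deltas <- delta_matrix(dset$trajectories)
  if (nrow(crit) != ncol(deltas))
    stop("criterion has ", nrow(crit), " transitions but trajectories have ",
         ncol(deltas))
  probes <- rownames(dset$trajectories)
  if (!is.null(scope)) {
    keep <- probes %in% scope
    deltas <- deltas[keep, , drop = FALSE]
    probes <- probes[keep]
  }
  probes[criterion_matches(crit, deltas)]
}

#' Find trajectories with the inverse shape of a reference
#'
#' Matches probes whose delta vector is the element-wise negation of the
#' reference's -- candidate inverse co-regulation partners. A constant
#' reference (all-zero deltas) is its own negation and matches all constant
#' trajectories.
#'
#' @param dset `DiscretizedTrajectorySet`.
#' @param reference a probe id present in `dset`, or an integer delta
#'   vector of length `timepoints - 1`.
#' @param scope probe ids to search within, or `NULL` for all.
#' @return character vector of matching probe ids.
#' @export
find_inverse <- function(dset, reference, scope = NULL) {
  stopifnot(inherits(dset, "DiscretizedTrajectorySet"))
  deltas <- delta_matrix(dset$trajectories)
  if (is.character(reference) && length(reference) == 1L) {
    if (!(reference %in% rownames(dset$trajectories)))
      stop("unknown reference probe: '", reference, "'")
    ref <- deltas[reference, ]
  } else {
    ref <- as.integer(reference)
    if (length(ref) != ncol(deltas))
      stop("reference delta vector must have length ", ncol(deltas))
  }
  target <- paste(-ref, collapse = ",")
  probes <- rownames(dset$trajectories)
  hit <- delta_key(deltas) == target
  out <- probes[hit]
  if (!is.null(scope)) out <- intersect(out, scope)
  out
}

#' Combine named probe sets into a selection
#'
#' Computes `(universe  intersect  union(include))  minus  union(exclude)`.
#' An empty include list means the whole universe. Named sets are looked up
#' in the annotation's labels and pathways, plus any extra sets supplied.
#'
#' @param universe probe universe (character vector).
#' @param include character vector of set names to include (OR-combined).
#' @param exclude character vector of set names to subtract.
#' @param annotation optional `AnnotationSet` providing named sets.
#' @param extra_sets optional named list of additional probe sets (e.g.
#'   prior results).
#' @return character vector of selected probes.
#' @export
apply_selection <- function(universe, include = character(),
                            exclude = character(), annotation = NULL,
                            extra_sets = list()) {
  pool <- extra_sets
  if (!is.null(annotation)) {
    stopifnot(inherits(annotation, "AnnotationSet"))
    pool <- c(pool, annotation$labels, annotation$pathways)
  }
  lookup <- function(nm) {
    if (!nm %in% names(pool)) stop("unknown set name: '", nm, "'")
    pool[[nm]]
  }
  sel <- if (length(include) == 0L) universe
         else intersect(universe,
                        unique(unlist(lapply(include, lookup),
                                      use.names = FALSE)))
  if (length(exclude))
    sel <- setdiff(sel, unique(unlist(lapply(exclude, lookup),
                                      use.names = FALSE)))
  sel
}

#' Convert an expression-unit change threshold to whole bins
#' @param x threshold in expression (log2) units.
#' @param w bin width.
#' @return `ceiling(x / w)` as integer.
#' @export
threshold_to_bins <- function(x, w) {
  if (w <= 0) stop("`w` must be positive")
  as.integer(ceiling(x / w))
}
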