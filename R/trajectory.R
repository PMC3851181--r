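## Prefix-tree trajectory graph over discretized bin sequences.
##
## Node identity is the full bin-sequence PREFIX up to a time point, not the
## (time point, bin) pair: with prefix keying every non-root node has exactly
## one parent, and two histories that converge on the same bin stay separate
## nodes. The (t, bin) view is available as the derived query node_probes().

node_id <- function(t, bins) paste0(t, ":", paste(bins, collapse = ","))

#' Build the trajectory graph of a discretized trajectory set
#'
#' The graph is a prefix tree: a node at level `t` is a distinct bin-sequence
#' prefix `(b_1, ..., b_t)`, and its members are the probes whose trajectory
#' starts with that prefix. At every level the member sets partition the
#' probe universe, and each node's member set is the union of its children's.
#' Nodes are ordered by time point, then bin descending (high expression
#' first), then lexically by prefix -- a deterministic export order.
#'
#' @param dset non-empty `DiscretizedTrajectorySet`.
#' @return `TrajectoryGraph` with fields `node_t`, `node_bin`, `parent`
#'   (empty string for roots), `members`, `timepoint_order`.
#' @export
build_trajectory_graph <- function(dset) {
  stopifnot(inherits(dset, "DiscretizedTrajectorySet"))
  traj <- dset$trajectories
  if (nrow(traj) == 0L) stop("trajectory set is empty")
  nt <- ncol(traj)
  probes <- rownames(traj)
  ids <- character(); t_of <- integer(); bin_of <- integer()
  parent_of <- character(); members <- list()
  prev_id_of_probe <- rep("", nrow(traj))
  for (t in seq_len(nt)) {
    key <- vapply(seq_len(nrow(traj)), function(i)
      node_id(t, traj[i, seq_len(t)]), "")
    grp <- split(seq_len(nrow(traj)), key)
    ord_bin <- vapply(grp, function(idx) traj[idx[1L], t], 0L)
    o <- order(-ord_bin, names(grp))
    grp <- grp[o]
    for (nid in names(grp)) {
      idx <- grp[[nid]]
      ids <- c(ids, nid)
      t_of <- c(t_of, t)
      bin_of <- c(bin_of, traj[idx[1L], t])
      parent_of <- c(parent_of, prev_id_of_probe[idx[1L]])
      members[[nid]] <- probes[idx]
      prev_id_of_probe[idx] <- nid
    }
  }
  structure(list(node_t = stats::setNames(t_of, ids),
                 node_bin = stats::setNames(bin_of, ids),
                 parent = stats::setNames(parent_of, ids),
                 members = members,
                 timepoint_order = dset$timepoint_order),
            class = "TrajectoryGraph")
}

#' @export
print.TrajectoryGraph <- function(x, ...) {
  n_probes <- sum(vapply(x$members[x$node_t == 1L], length, 0L))
  cat(sprintf("TrajectoryGraph: %d nodes over %d time points, %d probes\n",
              length(x$members), length(x$timepoint_order), n_probes))
  invisible(x)
}

#' Probes occupying a given bin at a given time point
#'
#' The (time point, bin) view over the prefix tree: the union of the member
#' sets of all level-`t` nodes whose prefix ends in bin `b`. An unoccupied
#' (t, b) returns the empty set, not an error.
#'
#' @param g `TrajectoryGraph`.
#' @param t time-point index (1-based) or time-point label.
#' @param b integer bin.
#' @return character vector of probe ids (sorted).
#' @export
node_probes <- function(g, t, b) {
  stopifnot(inherits(g, "TrajectoryGraph"))
  if (is.character(t)) {
    t <- match(t, g$timepoint_order)
    if (is.na(t)) stop("unknown time-point label")
  }
  if (t < 1L || t > length(g$timepoint_order))
    stop("time index out of range: ", t)
  sel <- g$node_t == t & g$node_bin == b
  sort(unique(c(character(), unlist(g$members[sel], use.names = FALSE))))
}

#' Look up one probe's full bin sequence
#'
#' @param dset `DiscretizedTrajectorySet`.
#' @param probe probe id; excluded or unknown probes raise an error naming
#'   the probe.
#' @return integer vector of bins, one per time point.
#' @export
probe_trajectory <- function(dset, probe) {
  stopifnot(inherits(dset, "DiscretizedTrajectorySet"))
  if (!(probe %in% rownames(dset$trajectories))) {
    if (probe %in% dset$excluded)
      stop("probe '", probe, "' was excluded at discretization (missing data)")
    stop("unknown probe: '", probe, "'")
  }
  dset$trajectories[probe, ]
}

#' Export a trajectory graph as an edge-list data frame
#' @param g `TrajectoryGraph`.
#' @return data frame with columns parent, child, t, bin, n_members.
#' @export
graph_edge_list <- function(g) {
  stopifnot(inherits(g, "TrajectoryGraph"))
  ids <- names(g$members)
  data.frame(parent = unname(g$parent),
             child = ids,
             t = unname(g$node_t),
             bin = unname(g$node_bin),
             n_members = vapply(g$members, length, 0L),
             stringsAsFactors = FALSE)
}
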