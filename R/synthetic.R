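## Synthetic short time-course expression data with planted ground truth:
## co-expression groups sharing a trajectory shape, probes affected by a
## treatment (paired control/treatment arms), and planted pathway
## enrichment. Every operator in the package can be exercised against the
## recorded truth without any external download.

#' Specify a synthetic time-course dataset
#'
#' A probe's replicate value at time t is
#' `baseline + cumulative pattern(t) [+ condition offset in the treatment
#' arm] + Gaussian noise(sd)` on the log2 scale. Baselines are drawn
#' uniformly per probe from the group's offset range; probes not claimed by
#' any group are flat background.
#'
#' @param n_probes total probes.
#' @param timepoint_count number of time points.
#' @param replicates integer vector of replicate counts per time point
#'   (recycled if shorter).
#' @param groups list of planted co-expression groups, each a list with
#'   `name`, `size`, `pattern` (numeric per-step log2 deltas, length
#'   `timepoint_count - 1`) and `offset_range` (length-2 numeric for the
#'   uniform baseline draw).
#' @param noise_sd replicate noise standard deviation, log2 units, >= 0.
#' @param planted_pathways list of planted gene sets, each a list with
#'   `name`, `group` (source group name), `in_fraction` (fraction of the
#'   group included) and `background_fraction` (fraction of non-group
#'   probes mixed in).
#' @param paired_condition `NULL` for a single-arm dataset, else a named
#'   list mapping group names to a numeric offset profile (length
#'   `timepoint_count`) added in the treatment arm; groups with any nonzero
#'   offset form the planted affected set.
#' @param seed integer seed; the whole fixture is a deterministic function
#'   of the spec.
#' @return object of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(n_probes = 200L,
                           timepoint_count = 9L,
                           replicates = c(5L, 4L, 5L, 3L, 4L, 5L, 5L, 5L, 5L),
                           groups = default_groups(timepoint_count),
                           noise_sd = 0,
                           planted_pathways = default_pathways(),
                           paired_condition = default_paired_condition(
                             timepoint_count),
                           seed = 1L) {
  timepoint_count <- as.integer(timepoint_count)
  if (timepoint_count < 2L) stop("need at least 2 time points")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  replicates <- rep_len(as.integer(replicates), timepoint_count)
  if (any(replicates < 1L)) stop("every time point needs >= 1 replicate")
  sizes <- vapply(groups, function(g) as.integer(g$size), 0L)
  if (sum(sizes) > n_probes)
    stop("group sizes sum (", sum(sizes), ") exceeds n_probes (", n_probes, ")")
  for (g in groups)
    if (length(g$pattern) != timepoint_count - 1L)
      stop("group '", g$name, "' pattern must have length ",
           timepoint_count - 1L)
  for (pw in planted_pathways) {
    if (pw$in_fraction < 0 || pw$in_fraction > 1 ||
        pw$background_fraction < 0 || pw$background_fraction > 1)
      stop("pathway fractions must lie in [0, 1]")
  }
  if (!is.null(paired_condition)) {
    for (nm in names(paired_condition))
      if (length(paired_condition[[nm]]) != timepoint_count)
        stop("condition offset profile for '", nm, "' must have length ",
             timepoint_count)
  }
  structure(list(n_probes = as.integer(n_probes),
                 timepoint_count = timepoint_count,
                 replicates = replicates, groups = groups,
                 noise_sd = noise_sd, planted_pathways = planted_pathways,
                 paired_condition = paired_condition,
                 seed = as.integer(seed)),
            class = "SyntheticSpec")
}

## Default planted world, sized like a small two-arm heat-stress style
## recovery course: 9 time points with 3-5 replicates each. Pattern steps
## are multiples of 0.5 so a bin width of 0.5 tracks them exactly, and the
## treatment offsets sit mid-bin (x.25) so the differential signal is not
## parked on a bin boundary.
default_groups <- function(nt = 9L) {
  pad <- function(x) c(x, rep(0, nt - 1L - length(x)))
  list(
    list(name = "affected", size = 30L,
         pattern = pad(c(0.5, 0.5, 0)), offset_range = c(6, 10)),
    list(name = "rising", size = 30L,
         pattern = pad(c(0, 0.5, 0.5, 0.5)), offset_range = c(4, 8)),
    list(name = "falling", size = 30L,
         pattern = pad(c(-0.5, -0.5, 0, -0.5)), offset_range = c(8, 12)))
}

default_pathways <- function() {
  list(list(name = "PW_AFFECTED", group = "affected",
            in_fraction = 1.0, background_fraction = 0),
       list(name = "PW_RISING_PART", group = "rising",
            in_fraction = 0.5, background_fraction = 0.05))
}

## Treatment arm: the affected group drops by 1.25 log2 units at the first
## recovery time point and the negative differential deepens before
## levelling off -- the "negatively affected shortly after treatment"
## motif. All offsets are mid-bin at width 0.5.
default_paired_condition <- function(nt = 9L) {
  ramp <- c(-1.25, -2.25, -3.25)
  list(affected = c(ramp, rep(-3.25, nt - length(ramp))))
}

#' Generate a synthetic fixture from a spec
#'
#' @param spec `SyntheticSpec`.
#' @return list with `control` (`ExpressionDataset`), `treatment`
#'   (`ExpressionDataset` or `NULL`), `annotation` (`AnnotationSet` with the
#'   planted pathways and a `DEG` label over the affected probes), and
#'   `truth` (group membership, affected set, pathway membership, the
#'   noise-free mean profiles).
#' @export
generate <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                           globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(spec$seed)
  nt <- spec$timepoint_count
  np <- spec$n_probes
  probes <- sprintf("P%04d", seq_len(np))
  tp <- sprintf("t%d", seq_len(nt))

  ## assign probes to groups (first blocks), remainder = background
  sizes <- vapply(spec$groups, function(g) as.integer(g$size), 0L)
  gnames <- vapply(spec$groups, function(g) g$name, "")
  group_of <- rep("background", np)
  at <- 1L
  membership <- list()
  for (i in seq_along(spec$groups)) {
    idx <- seq.int(at, length.out = sizes[i])
    group_of[idx] <- gnames[i]
    membership[[gnames[i]]] <- probes[idx]
    at <- at + sizes[i]
  }
  membership$background <- probes[group_of == "background"]

  ## noise-free mean profile per probe (control arm)
  means <- matrix(0, np, nt, dimnames = list(probes, tp))
  for (i in seq_len(np)) {
    g <- group_of[i]
    if (g == "background") {
      base <- stats::runif(1L, 4, 12)
      means[i, ] <- base
    } else {
      gdef <- spec$groups[[match(g, gnames)]]
      base <- stats::runif(1L, gdef$offset_range[1L], gdef$offset_range[2L])
      means[i, ] <- base + c(0, cumsum(gdef$pattern))
    }
  }

  ## condition offsets (treatment arm)
  cond <- matrix(0, np, nt, dimnames = list(probes, tp))
  affected <- character()
  if (!is.null(spec$paired_condition)) {
    for (nm in names(spec$paired_condition)) {
      mem <- membership[[nm]]
      if (is.null(mem)) stop("paired_condition names unknown group '", nm, "'")
      cond[mem, ] <- matrix(spec$paired_condition[[nm]], length(mem), nt,
                            byrow = TRUE)
      if (any(spec$paired_condition[[nm]] != 0))
        affected <- c(affected, mem)
    }
  }

  make_arm <- function(arm_means, prefix) {
    cols <- list(); ids <- character(); map <- character()
    for (t in seq_len(nt)) {
      for (r in seq_len(spec$replicates[t])) {
        sid <- sprintf("%s_%s_r%d", prefix, tp[t], r)
        noise <- if (spec$noise_sd > 0) stats::rnorm(np, 0, spec$noise_sd)
                 else numeric(np)
        cols[[sid]] <- arm_means[, t] + noise
        ids <- c(ids, sid)
        map[sid] <- tp[t]
      }
    }
    values <- do.call(cbind, cols)
    dimnames(values) <- list(probes, ids)
    expression_dataset(values, map, tp)
  }

  control <- make_arm(means, "C")
  treatment <- if (is.null(spec$paired_condition)) NULL
               else make_arm(means + cond, "S")

  ## planted pathways: in_fraction of the source group + a sprinkle of
  ## background probes
  pathways <- list()
  for (pw in spec$planted_pathways) {
    mem <- membership[[pw$group]]
    if (is.null(mem)) stop("planted pathway names unknown group '",
                           pw$group, "'")
    n_in <- round(pw$in_fraction * length(mem))
    core <- if (n_in > 0) sort(sample(mem, n_in)) else character()
    others <- setdiff(probes, mem)
    n_bg <- round(pw$background_fraction * length(others))
    bg <- if (n_bg > 0) sort(sample(others, n_bg)) else character()
    pathways[[pw$name]] <- sort(unique(c(core, bg)))
  }
  labels <- list()
  if (length(affected)) labels$DEG <- affected
  annotation <- annotation_set(
    probe_to_gene = stats::setNames(sub("^P", "G", probes), probes),
    pathways = pathways, labels = labels, universe = probes)

  list(control = control, treatment = treatment, annotation = annotation,
       truth = list(groups = membership, affected = affected,
                    pathways = pathways, means = means,
                    condition_offsets = cond, spec = spec))
}
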