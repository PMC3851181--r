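---
title: "Trajectory methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectory methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajex)
```

## The data model

`trajex` targets short expression time courses: a probe × sample matrix of
base-2 log intensities, a handful of time points, and a few replicate
samples per time point. The package assumes the matrix is already
normalized and log2-transformed (a `--log2` load flag covers raw-scale
inputs, refusing values ≤ 0); background correction, normalization and
batch correction are out of scope.

The analysis pipeline is a chain of small operators:

1. **Replicate aggregation** collapses the samples at each time point to
   one value by mean or median (median is the default: robust to a single
   aberrant array in the typical 3–5-replicate design). A cell is missing
   only if *all* replicates were missing. **Segment aggregation**
   optionally re-cuts the course into fixed-length windows; a shorter
   final window is kept and flagged rather than dropped.
2. **Equi-width discretization** maps each value `e` to the integer bin
   `b = ⌊e/w⌋`.
3. Everything downstream — the trajectory graph, shape/identity
   clustering, shape filtering — operates on the integer bin sequences;
   k-means and the volatility/trend statistics also accept the raw
   profiles.

## Discretization: conventions that make results reproducible

The width `w` is the single most consequential parameter: it is the
resolution at which two expression levels count as "the same". It is in
log2 units; `w = 0.5` (the default used throughout the examples) means a
bin spans a √2-fold expression change, so a 2-fold change moves a
trajectory by two bins.

Three conventions are fixed so that every downstream result is exactly
reproducible:

- **Half-open bins** `[bw, (b+1)w)` with `b = ⌊e/w⌋`: a value exactly on a
  boundary joins the *upper* bin. Any consistent convention would do; one
  had to be chosen and stated.
- **Boundary guard**: values within `10⁻⁹·w` below a boundary are snapped
  up before flooring, so floating-point representation error cannot drop
  an exact boundary value into the lower bin. The guard is far below any
  biologically meaningful difference.
- **Full-length trajectories only**: a probe with a missing aggregated
  value at any time point is excluded from discretization and listed in
  the exclusion report. Shape comparison over partial trajectories would
  silently compare different transitions; exclusion is loud and
  reversible (impute or re-aggregate upstream if needed).

A useful identity follows from the flooring rule: adding `m·w` (integer
`m`) to every value shifts every bin index by exactly `m`. This
equivariance is what makes shape clustering genuinely level-invariant, and
it is asserted as a property test.

## The trajectory graph: why prefix identity

A "node" could mean two things: the set of probes in bin `b` at time `t`,
or the set of probes sharing the whole bin-sequence *prefix* up to `t`.
The two disagree as soon as two different histories converge on one bin.
Only the prefix reading makes the graph a tree in which every non-root
node has exactly one parent, the member sets at each level partition the
probe universe, and a parent's member set is the union of its children's —
three invariants the package asserts on every build. The `(t, bin)`
reading remains available as the derived query `node_probes()`, which
unions the matching prefixes; it is the natural way to "click a node" in
scripted form. Export order (level, then bin descending, then prefix) is
fixed purely for deterministic golden files.

## Clustering

**Shape clustering** keys probes by the delta vector of successive bin
differences. It deliberately runs in bin space, not on raw values: the
claim "similar shape regardless of level" holds *exactly* for integer bin
deltas (by the shift equivariance above) and only approximately for noisy
raw values. **Identity clustering** keys by the full bin sequence; each
identity key determines its delta key, so identity refines shape on every
input — a property test, not an aspiration.

**k-means** runs on the raw aggregated profiles with Euclidean distance.
The mechanics are pinned down so that a seed fully determines the result:
k-means++ initialization, Lloyd iterations to a `10⁻⁶` centroid-movement
tolerance (cap 300), best of 10 restarts by within-cluster sum of squares,
and an empty cluster repaired by re-seeding it at the point farthest from
its centroid. WCSS is checked to be non-increasing across iterations at
run time. Profiles are aggregated, not replicate-level: replicate counts
differ between time points and arms, and the trajectory is the object of
interest. On small instances the result is checked against an exhaustive
minimum-WCSS partition search.

## Filtering and selection

A shape criterion has one predicate per transition: a direction (`up`,
`down`, `same`, `any`) plus optional bounds on the delta magnitude in
whole bins. `same` means *exactly* zero bins — tolerance belongs in the
choice of `w`, not in the predicate. A convenience converter
`threshold_to_bins(x, w) = ⌈x/w⌉` turns an effect size in log2 units into
a bin threshold. Inverse search matches the exact element-wise negation of
a reference delta vector (approximate negation, if wanted, is again the
width's job). Selection algebra is plain set algebra,
`(universe ∩ ∪include) ∖ ∪exclude`, monotone in both arguments.

## Cross-dataset comparison

Pairing matches time points **by order**, not label (control and treatment
arms typically label the same design positions differently; a warning is
raised when labels differ), and intersects probes, reporting drops.
Differencing happens **after** replicate aggregation, because the
differential is defined per time point while replicate counts differ
between arms (the default fixture has 5 vs 4 at some points). The
differential dataset is an ordinary aggregated dataset: it discretizes,
clusters and filters unchanged, with negative bins meaning "below
control".

## Association statistics

For a selected set of `n` probes out of a universe of `N`, and a pathway
covering `D` of them with overlap `k`, the point probability is the
hypergeometric mass `C(D,k)·C(N−D,n−k)/C(N,n)`, computed in log space so
`N` of 10⁴ or more cannot overflow. The point mass alone is not a p-value
in the usual sense, so the default reported value is the upper tail
`P[X ≥ k]`; `mode = "point"` reproduces the bare term for fidelity with
the formula as printed. Benjamini–Hochberg adjustment across the scored
sets is available but **off by default** — the original procedure applied
none, and silently changing reported numbers is worse than offering the
option. Sets with `D = 0` after universe restriction are kept by the GMT
loader (with a warning) and skipped by the scan with a note, so an empty
mapping is visible rather than invisible.

Volatility `V(T) = Σ|eᵢ−eᵢ₋₁|` and linear trend `L(T) = Σ(eᵢ−eᵢ₋₁) =
e_N − e₁` are computed on whichever representation is passed — bins or
log2 values — with the unit recorded in the result; both are meaningful in
either space and the choice is the caller's. `|L| ≤ V` always, with
equality exactly for monotone trajectories.

## The synthetic world

The generator emulates the structure of a paired recovery experiment at
toy scale: 9 time points with replicate counts (5, 4, 5, 3, 4, 5, 5, 5, 5),
200 probes, three planted co-expression groups of 30 (plus flat
background), i.i.d. Gaussian noise on the log2 scale (the standard minimal
model for log-intensity noise), and a treatment arm in which one group is
negatively affected immediately after treatment with a deepening
differential: offsets −1.25, −2.25, −3.25 log2 units, then static.

Two generator choices are deliberate and fixed:

- Planted **pattern steps are multiples of 0.5**, so at `w = 0.5` the bin
  deltas track the patterns exactly and noiseless shape recovery is exact
  for *any* baseline (by shift equivariance).
- Planted **treatment offsets sit mid-bin** (x.25 values at `w = 0.5`).
  The unaffected differential is exactly 0 — which *is* a bin boundary —
  so the affected signal is kept off boundaries; otherwise replicate noise
  of either sign would flip bins at random and no filter could be stable.
  This is a statement about the planted world, not a tuning knob: the
  effect size (≥ 1.0 log2 units) and the recovery filter
  (`down:2` = `threshold_to_bins(1.0, 0.5)` bins at the first transition)
  were fixed at design time.

What a green test establishes: the operator chain recovers a planted
signal of stated size under stated noise. What it does not establish:
robustness to array-level artifacts (dye bias, spatial effects),
non-Gaussian heavy-tailed noise, or missingness structure — none of which
the generator models.

## Numerical and degenerate-input policy

Errors are loud and early: duplicate IDs, unmapped samples and
non-numeric cells name the offender; `k > n_probes`, missing cells in
k-means input, criterion/transition length mismatches, and unknown
probes/sets are errors, not warnings. Degenerate cases with a defined
answer return it: an unoccupied `(t, bin)` is an empty set, an empty probe
set serializes fine, `k = 0` gives tail p exactly 1, precision of an empty
selection is reported `NA` ("not applicable") rather than 0 or an error.

## Known limitations

- Trajectory operators need complete trajectories; heavy missingness
  shrinks the analyzable universe (visible in the exclusion report).
- Equi-width binning is sensitive to `w` near signal of comparable size;
  there is no adaptive or quantile binning.
- The association scan assumes the universe is the set of probes actually
  under study; passing a larger universe inflates significance.
- The CLI's `export` emits data products (edge lists, JSON); it does not
  render figures.
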