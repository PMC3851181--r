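test_that("criterion string syntax parses directions and magnitude bounds", {
  crit <- shape_criterion("any,up:1,down:1:3,same")
  expect_equal(crit$direction, c("any", "up", "down", "same"))
  expect_equal(crit$min_delta, c(NA, 1L, 1L, NA))
  expect_equal(crit$max_delta, c(NA, NA, 3L, NA))
  expect_error(shape_criterion("sideways"), "direction")
  expect_error(shape_criterion("up:3:1"), "min_delta")
  expect_error(shape_criterion("same:1"), "forces delta 0")
})

test_that("filter_by_shape applies per-transition predicates", {
  bins <- rbind(A = c(0L, 1L, 1L, 0L),   # up, same, down
                B = c(0L, 2L, 2L, 0L),   # up2, same, down2
                C = c(0L, 1L, 2L, 3L),   # monotone up
                D = c(2L, 2L, 2L, 2L))   # flat
  dset <- make_dset(bins)
  expect_setequal(filter_by_shape(dset, "any,any,down:1"), c("A", "B"))
  expect_setequal(filter_by_shape(dset, "any,any,down:2"), "B")
  expect_setequal(filter_by_shape(dset, "up,same,down"), c("A", "B"))
  expect_setequal(filter_by_shape(dset, "same,same,same"), "D")
  # all-any criterion is the identity on any scope
  expect_setequal(filter_by_shape(dset, "any,any,any"), rownames(bins))
  expect_setequal(filter_by_shape(dset, "any,any,any", scope = c("A", "C")),
                  c("A", "C"))
  # up-then-down on a monotone probe set is empty
  expect_length(filter_by_shape(dset, "up,down,any", scope = "C"), 0L)
  expect_error(filter_by_shape(dset, "up,down"), "transitions")
})

test_that("filter results are subsets of scope (random property)", {
  set.seed(31)
  for (rep in 1:10) {
    dset <- make_dset(rand_bins(40, 5))
    scope <- sample(rownames(dset$trajectories), 15)
    crit <- paste(sample(c("up", "down", "same", "any"), 4, TRUE),
                  collapse = ",")
    hits <- filter_by_shape(dset, crit, scope = scope)
    expect_true(all(hits %in% scope))
    expect_setequal(filter_by_shape(dset, "any,any,any,any", scope = scope),
                    scope)
  }
})

test_that("find_inverse matches element-wise negated delta vectors", {
  bins <- rbind(A = c(0L, 1L, 1L, 0L),    # deltas (1, 0, -1)
                B = c(5L, 4L, 4L, 5L),    # deltas (-1, 0, 1)  = inverse of A
                C = c(2L, 1L, 1L, 2L),    # same inverse shape
                D = c(0L, 0L, 0L, 0L))    # constant
  dset <- make_dset(bins)
  expect_setequal(find_inverse(dset, "A"), c("B", "C"))
  expect_setequal(find_inverse(dset, c(1L, 0L, -1L)), c("B", "C"))
  # constant reference is its own negation
  expect_setequal(find_inverse(dset, "D"), "D")
  expect_error(find_inverse(dset, "nope"), "nope")
  # inverse of inverse lands back in the reference's own shape group
  back <- find_inverse(dset, "B")
  expect_true("A" %in% back && "A" %in% c(back))
})

test_that("selection algebra: include/exclude over named sets", {
  universe <- sprintf("P%02d", 1:10)
  ann <- annotation_set(pathways = list(PW1 = universe[1:4]),
                        labels = list(DEG = universe[3:7]),
                        universe = universe)
  expect_setequal(apply_selection(universe, include = "PW1",
                                  annotation = ann), universe[1:4])
  expect_setequal(apply_selection(universe, exclude = "DEG",
                                  annotation = ann),
                  setdiff(universe, universe[3:7]))
  expect_length(apply_selection(universe, include = "PW1", exclude = "PW1",
                                annotation = ann), 0L)
  expect_setequal(apply_selection(universe, annotation = ann), universe)
  expect_error(apply_selection(universe, include = "missing",
                               annotation = ann), "missing")
})

test_that("selection is monotone in include and exclude", {
  set.seed(32)
  universe <- sprintf("P%02d", 1:20)
  sets <- list(a = sample(universe, 6), b = sample(universe, 9),
               c = sample(universe, 4))
  s1 <- apply_selection(universe, include = "a", extra_sets = sets)
  s2 <- apply_selection(universe, include = c("a", "b"), extra_sets = sets)
  expect_true(all(s1 %in% s2))
  e1 <- apply_selection(universe, exclude = "c", extra_sets = sets)
  e2 <- apply_selection(universe, exclude = c("c", "b"), extra_sets = sets)
  expect_true(all(e2 %in% e1))
})

test_that("expression-unit thresholds convert to whole bins", {
  expect_equal(threshold_to_bins(1.0, 0.5), 2L)
  expect_equal(threshold_to_bins(0.4, 0.5), 1L)
  expect_error(threshold_to_bins(1, 0), "positive")
})
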