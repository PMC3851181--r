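test_that("hypergeometric point/tail match frozen enumeration values", {
  # values computed with hyper_enum (exact subset enumeration)
  expect_equal(hypergeom_point(10, 5, 4, 2), 100 / 210, tolerance = 1e-12)
  expect_equal(hypergeom_point(4, 2, 2, 2), 1 / 6, tolerance = 1e-12)
  expect_equal(hypergeom_point(10, 0, 0, 0), 1)
  expect_equal(hypergeom_tail(10, 5, 4, 4), 5 / 210, tolerance = 1e-12)
  expect_equal(hypergeom_tail(10, 5, 4, 0), 1)   # full support
  expect_error(hypergeom_point(10, 11, 2, 1), "D > N")
  expect_error(hypergeom_point(10, 5, 4, 5), "k > min")
})

test_that("point and tail equal the enumeration oracle on random cases", {
  set.seed(51)
  for (rep in 1:15) {
    N <- sample(4:11, 1)
    D <- sample(0:N, 1)
    n <- sample(1:N, 1)
    oracle <- hyper_enum(N, D, n)
    for (k in 0:min(n, D)) {
      if (n - k > N - D) next
      expect_equal(hypergeom_point(N, D, n, k), oracle[[as.character(k)]],
                   tolerance = 1e-12)
      expect_equal(hypergeom_tail(N, D, n, k),
                   sum(oracle[as.character(k:min(n, D))]),
                   tolerance = 1e-12)
    }
  }
})

test_that("point masses sum to one even for large N (log-space)", {
  set.seed(52)
  for (rep in 1:20) {
    N <- sample(100:10000, 1)
    D <- sample(1:N, 1)
    n <- sample(1:min(N, 300), 1)
    ks <- max(0, n - (N - D)):min(n, D)
    total <- sum(vapply(ks, function(k) hypergeom_point(N, D, n, k), 0))
    expect_equal(total, 1, tolerance = 1e-12)
  }
})

test_that("volatility and linear trend follow their definitions", {
  expect_equal(volatility(c(2, 2, 2, 2)), 0)
  expect_equal(volatility(c(0, 1, 0, 1)), 3)
  expect_equal(volatility(c(1.0, 2.5, 2.0)), 2.0)
  expect_equal(linear_trend(c(0, 1, 0, 1)), 1)
  expect_equal(linear_trend(c(2, 2, 2)), 0)
  expect_equal(linear_trend(c(3, 1, -2)), -5)
  expect_error(volatility(1), "at least 2")
  expect_error(linear_trend(numeric()), "at least 2")
})

test_that("telescoping identity and |L| <= V with equality iff monotone", {
  set.seed(53)
  for (rep in 1:200) {
    T <- rnorm(sample(2:12, 1), sd = 3)
    expect_equal(linear_trend(T), T[length(T)] - T[1], tolerance = 1e-12)
    expect_lte(abs(linear_trend(T)), volatility(T) + 1e-12)
    d <- diff(T)
    monotone <- all(d >= 0) || all(d <= 0)
    expect_equal(abs(linear_trend(T)) == volatility(T), monotone)
  }
})

test_that("volatility ranking is a deterministic permutation, flats last", {
  bins <- rbind(OSC = c(0L, 3L, 0L, 3L), FLAT1 = c(1L, 1L, 1L, 1L),
                MILD = c(0L, 1L, 1L, 0L), FLAT2 = c(5L, 5L, 5L, 5L))
  r <- rank_by_volatility(make_dset(bins))
  expect_equal(r$probe, c("OSC", "MILD", "FLAT1", "FLAT2"))
  expect_setequal(r$probe, rownames(bins))
  expect_equal(r$volatility, c(9, 2, 0, 0))
  expect_equal(attr(r, "units"), "bins")
  # scores equal direct evaluation of the definition
  for (i in seq_len(nrow(r)))
    expect_equal(r$volatility[i], sum(abs(diff(bins[r$probe[i], ]))))
  r_asc <- rank_by_volatility(make_dset(bins), descending = FALSE)
  expect_equal(r_asc$probe, rev(c("OSC", "MILD", "FLAT2", "FLAT1")))
})

test_that("precision/recall handles the standard and degenerate cases", {
  S <- sprintf("P%d", 1:4); R <- sprintf("P%d", 3:10)
  expect_equal(precision_recall(S, R),
               c(precision = 0.5, recall = 0.25))
  expect_equal(precision_recall(R, R), c(precision = 1, recall = 1))
  expect_equal(precision_recall("A", "B"), c(precision = 0, recall = 0))
  expect_true(is.na(precision_recall(character(), R)[["precision"]]))
  expect_true(is.na(precision_recall(S, character())[["recall"]]))
  # symmetry: precision(S, R) = recall(R, S)
  set.seed(54)
  u <- sprintf("P%02d", 1:30)
  for (rep in 1:10) {
    a <- sample(u, sample(1:20, 1)); b <- sample(u, sample(1:20, 1))
    expect_equal(precision_recall(a, b)[["precision"]],
                 precision_recall(b, a)[["recall"]])
  }
})

test_that("enrich scores pathways against the hypergeometric oracle", {
  universe <- sprintf("P%03d", 1:60)
  selected <- universe[1:8]
  ann <- annotation_set(
    pathways = list(HIT = universe[1:10],        # holds all selected
                    PART = universe[5:20],
                    MISS = universe[40:50],
                    EMPTY = character()),
    universe = universe)
  expect_warning(tab <- enrich(selected, ann, universe), NA)
  expect_equal(tab$set_name[1], "HIT")
  expect_true("EMPTY" %in% attr(tab, "skipped"))
  hit <- tab[tab$set_name == "HIT", ]
  expect_equal(hit$p_tail,
               hypergeom_tail(60, 10, 8, 8), tolerance = 1e-12)
  expect_true(all(tab$p_tail >= tab$p_point - 1e-12))
  expect_true(!is.unsorted(tab$p))
  # point mode and BH adjustment
  tabp <- enrich(selected, ann, universe, mode = "point", adjust = "BH")
  expect_equal(tabp$p, tabp$p_point)
  expect_equal(tabp$q, stats::p.adjust(tabp$p, "BH"))
  expect_error(enrich(c(selected, "PX"), ann, universe), "subset")
})

test_that("selected = universe forces k = D and tail p = 1 everywhere", {
  universe <- sprintf("P%02d", 1:12)
  ann <- annotation_set(pathways = list(A = universe[1:5], B = universe[6:9]),
                        universe = universe)
  tab <- enrich(universe, ann, universe)
  expect_equal(tab$k, tab$D)
  expect_true(all(abs(tab$p_tail - 1) < 1e-12))
})

test_that("pathway_intersection triples agree with enrich's n, D, k", {
  set.seed(55)
  universe <- sprintf("P%02d", 1:40)
  ann <- annotation_set(pathways = list(X = sample(universe, 12),
                                        Y = sample(universe, 5)),
                        universe = universe)
  context <- sample(universe, 9)
  tri <- pathway_intersection(context, ann)
  tab <- enrich(context, ann, universe)
  for (pw in tri$pathway) {
    row_t <- tri[tri$pathway == pw, ]
    row_e <- tab[tab$set_name == pw, ]
    expect_equal(row_t$n_context, row_e$n)
    expect_equal(row_t$n_pathway, row_e$D)
    expect_equal(row_t$n_common, row_e$k)
  }
  expect_equal(pathway_intersection(character(), ann)$n_common, c(0L, 0L))
  sub <- ann$pathways$X[1:3]
  expect_equal(pathway_intersection(sub, ann)$n_common[1], 3L)
})
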