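test_that("expression matrix loads with correct bookkeeping", {
  f <- tiny_matrix_files()
  ds <- read_expression_matrix(f$matrix, f$map)
  expect_s3_class(ds, "ExpressionDataset")
  expect_equal(length(ds$probe_ids), 3L)
  expect_equal(length(ds$sample_ids), 4L)
  expect_equal(ds$timepoint_order, c("early", "late"))
  rep <- attr(ds, "load_report")
  expect_equal(rep$n_probes, 3L)
  expect_equal(rep$n_samples, 4L)
  expect_equal(rep$n_timepoints, 2L)
  expect_equal(rep$n_missing_cells, 1L)
  expect_equal(unname(ds$values["P1", "S3"]), 2.0)
})

test_that("malformed matrices fail loudly, naming the offender", {
  map <- write_tsv_lines(c("sample_id\ttimepoint\torder",
                           "S1\ta\t1", "S2\ta\t1", "S3\tb\t2"))
  dup <- write_tsv_lines(c("probe_id\tS1\tS2\tS3",
                           "P1\t1\t2\t3", "P1\t4\t5\t6"))
  expect_error(read_expression_matrix(dup, map), "P1")
  bad <- write_tsv_lines(c("probe_id\tS1\tS2\tS3",
                           "P1\t1\t2\t3", "P2\t1\t2\tabc"))
  expect_error(read_expression_matrix(bad, map), "abc.*P2.*S3")
  orphan <- write_tsv_lines(c("probe_id\tS1\tS2\tS3\tS9",
                              "P1\t1\t2\t3\t4"))
  expect_error(read_expression_matrix(orphan, map), "S9")
})

test_that("missing tokens and comments are handled; --log2 guards", {
  map <- write_tsv_lines(c("sample_id\ttimepoint\torder",
                           "S1\ta\t1", "S2\tb\t2"))
  mat <- write_tsv_lines(c("# a comment", "probe_id\tS1\tS2",
                           "P1\tNaN\t", "P2\t4\t8"))
  ds <- read_expression_matrix(mat, map)
  expect_true(all(is.na(ds$values["P1", ])))
  neg <- write_tsv_lines(c("probe_id\tS1\tS2", "P1\t0\t8"))
  expect_error(read_expression_matrix(neg, map, log2_transform = TRUE),
               "<= 0", fixed = FALSE)
  pos <- write_tsv_lines(c("probe_id\tS1\tS2", "P1\t4\t8"))
  ds2 <- read_expression_matrix(pos, map, log2_transform = TRUE)
  expect_equal(unname(ds2$values["P1", ]), c(2, 3))
})

test_that("time-point order comes from the order column, else lexical + warning", {
  mat <- write_tsv_lines(c("probe_id\tS1\tS2", "P1\t1\t2"))
  map_ord <- write_tsv_lines(c("sample_id\ttimepoint\torder",
                               "S1\tzeta\t1", "S2\talpha\t2"))
  expect_equal(read_expression_matrix(mat, map_ord)$timepoint_order,
               c("zeta", "alpha"))
  map_lex <- write_tsv_lines(c("sample_id\ttimepoint",
                               "S1\tzeta", "S2\talpha"))
  expect_warning(ds <- read_expression_matrix(mat, map_lex), "lexical")
  expect_equal(ds$timepoint_order, c("alpha", "zeta"))
})

test_that("GMT parsing maps genes to probes, keeps empty sets, dedupes", {
  universe <- c("P1", "P2", "P3", "P4", "P5")
  p2g <- c(P1 = "G1", P2 = "G1", P3 = "G2", P4 = "G2")
  gmt <- write_tsv_lines(c(
    "PW1\tdesc\tG1\tG2",
    "PW_EMPTY\tdesc\tGX\tGY",
    "PW_DUP\tdesc\tG1\tG1\tP1",
    "PW_PROBE\tdesc\tP5\tP_missing"))
  expect_warning(ann <- read_gene_sets_gmt(gmt, universe, p2g),
                 "PW_EMPTY")
  expect_setequal(ann$pathways$PW1, c("P1", "P2", "P3", "P4"))
  expect_length(ann$pathways$PW_EMPTY, 0L)
  expect_setequal(ann$pathways$PW_DUP, c("P1", "P2"))
  expect_setequal(ann$pathways$PW_PROBE, "P5")
})

test_that("annotation sets report unmatched members instead of dropping silently", {
  ann <- annotation_set(pathways = list(PW = c("P1", "PX")),
                        labels = list(L = c("P2", "PY", "PZ")),
                        universe = c("P1", "P2"))
  expect_equal(ann$pathways$PW, "P1")
  expect_equal(unname(ann$report$pathway_unmatched["PW"]), 1L)
  expect_equal(unname(ann$report$label_unmatched["L"]), 2L)
})

test_that("every result type round-trips through JSON losslessly", {
  set.seed(42)
  bins <- rand_bins(20, 5)
  dset <- make_dset(bins, w = 0.5)
  agg <- make_agg(matrix(rnorm(40), 8, 5))
  # session-report attributes are transient, not part of the serialized result
  attr(agg, "aggregation_report") <- NULL
  objs <- list(
    probe_set = sort(rownames(bins))[1:7],
    empty_probe_set = character(),
    partition = cluster_by_shape(dset),
    graph = build_trajectory_graph(dset),
    agg = agg,
    dset = dset,
    enrichment = {
      ann <- annotation_set(pathways = list(PW = rownames(bins)[1:6]),
                            universe = rownames(bins))
      tab <- enrich(rownames(bins)[1:5], ann, rownames(bins))
      attr(tab, "skipped") <- NULL
      tab
    })
  for (nm in names(objs)) {
    path <- tempfile(fileext = ".json")
    write_result(objs[[nm]], path)
    back <- read_result(path)
    expect_equal(back, objs[[nm]], ignore_attr = FALSE,
                 label = paste("round trip of", nm))
  }
  expect_error(write_result(sum, tempfile()), "unknown result type")
})
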