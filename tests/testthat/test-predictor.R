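# origin decision rules and the evaluation harness

test_that("a replication-gene-adjacent region with one ORB is predicted (rule A)", {
  truth <- make_toy_genome(toy_genome_spec(length = 30000L, seed = 501L))
  preds <- predict_oric(truth$genome)
  expect_s3_class(preds, "oric_predictions")
  a <- preds[preds$rule == "gene_adjacent_orb", , drop = FALSE]
  expect_equal(nrow(a), 1L)
  expect_equal(a$start, truth$true_origin_interval$start)
  expect_equal(a$end, truth$true_origin_interval$end)
  expect_gte(a$motif_count, 1L)
  expect_true(grepl("orc1_cdc6", a$adjacent_role))
  expect_true(a$at_content >= 0 && a$at_content <= 1)
  # evidence bundle is attached
  expect_s3_class(preds$orb_hits[[1]], "data.frame")
  expect_gte(nrow(preds$orb_hits[[1]]), 1L)
  expect_true(is.finite(a$dist_gc))
})

test_that("three motif hits trigger rule B, two do not", {
  spec3 <- toy_genome_spec(length = 20000L, seed = 502L,
                           planted_motifs = list(list(motif = "Common",
                                                      region = "origin",
                                                      copies = 3L)),
                           planted_role_products = list())
  t3 <- make_toy_genome(spec3)
  p3 <- predict_oric(t3$genome)
  b <- p3[p3$rule == "multi_motif", , drop = FALSE]
  expect_equal(nrow(b), 1L)
  expect_equal(b$start, t3$true_origin_interval$start)
  expect_gte(b$motif_count, 3L)

  spec2 <- toy_genome_spec(length = 20000L, seed = 502L,
                           planted_motifs = list(list(motif = "Common",
                                                      region = "origin",
                                                      copies = 2L)),
                           planted_role_products = list())
  t2 <- make_toy_genome(spec2)
  p2 <- predict_oric(t2$genome)
  expect_equal(nrow(p2), 0L)
})

test_that("a region satisfying both rules reports rule A once", {
  spec <- toy_genome_spec(length = 20000L, seed = 503L,
                          planted_motifs = list(list(motif = "Common",
                                                     region = "origin",
                                                     copies = 3L)))
  truth <- make_toy_genome(spec)
  preds <- predict_oric(truth$genome)
  at_origin <- preds[preds$start == truth$true_origin_interval$start, ,
                     drop = FALSE]
  expect_equal(nrow(at_origin), 1L)
  expect_equal(at_origin$rule, "gene_adjacent_orb")
})

test_that("unplanted genomes stay (almost) prediction-free", {
  false_calls <- 0L
  for (i in 1:20) {
    truth <- make_toy_genome(toy_genome_spec(
      length = 20000L, seed = 600L + i, planted_motifs = list(),
      planted_role_products = list()))
    false_calls <- false_calls + nrow(predict_oric(truth$genome))
  }
  expect_lte(false_calls, 1L)
})

test_that("predictions always lie in intergenic space and respect monotonicity", {
  truth <- make_toy_genome(toy_genome_spec(length = 30000L, seed = 504L))
  g <- truth$genome
  preds <- predict_oric(g)
  regs <- extract_intergenic(g, 0L)
  key <- paste(regs$start, regs$end)
  expect_true(all(paste(preds$start, preds$end) %in% key))

  # relaxing the cutoff or min length never removes a rule-A prediction
  relaxed <- predict_oric(g, p_cutoff = 1e-3, min_intergenic = 10L)
  a0 <- preds[preds$rule == "gene_adjacent_orb", ]
  expect_true(all(paste(a0$start, a0$end) %in%
                  paste(relaxed$start, relaxed$end)))

  # genome without annotation is a usage error
  empty <- annotated_genome("X", random_seq(1000), archori:::empty_gene_df())
  expect_error(predict_oric(empty), class = "archori_usage_error")
})

test_that("evaluation arithmetic and the degenerate cases", {
  r <- evaluation_result(18L, 27L, 29L)
  expect_equal(round(100 * r$sensitivity, 1), 66.7)
  expect_equal(round(100 * r$precision, 1), 62.1)

  ref <- data.frame(start = c(100L, 500L), end = c(200L, 600L))
  exact <- evaluate_predictions(ref, ref, genome_size = 1000L)
  expect_equal(exact$sensitivity, 1)
  expect_equal(exact$precision, 1)

  none <- evaluate_predictions(ref[0, ], ref, genome_size = 1000L)
  expect_equal(none$sensitivity, 0)
  expect_false(none$precision_defined)
  expect_true(is.na(none$precision))

  expect_error(evaluate_predictions(ref, ref[0, ], genome_size = 1000L),
               class = "archori_usage_error")
})

test_that("overlap matching is one-to-one and greedy by overlap length", {
  # one prediction overlapping two references counts once
  preds <- data.frame(start = 100L, end = 300L)
  ref <- data.frame(start = c(90L, 250L), end = c(150L, 400L))
  r <- evaluate_predictions(preds, ref, genome_size = 1000L)
  expect_equal(r$true_positives, 1L)
  expect_equal(r$sensitivity, 0.5)

  # two predictions, two references, crossed overlaps resolve one-to-one
  preds2 <- data.frame(start = c(100L, 140L), end = c(150L, 260L))
  ref2 <- data.frame(start = c(90L, 200L), end = c(160L, 280L))
  r2 <- evaluate_predictions(preds2, ref2, genome_size = 1000L)
  expect_equal(r2$true_positives, 2L)

  # wrap-around intervals overlap across the coordinate origin
  predw <- data.frame(start = 950L, end = 1050L)
  refw <- data.frame(start = 0L, end = 40L)
  rw <- evaluate_predictions(predw, refw, genome_size = 1000L)
  expect_equal(rw$true_positives, 1L)

  # midpoint rule
  rm1 <- evaluate_predictions(data.frame(start = 100L, end = 300L),
                              data.frame(start = 190L, end = 210L),
                              match_rule = "midpoint", genome_size = 1000L)
  expect_equal(rm1$true_positives, 1L)
  rm2 <- evaluate_predictions(data.frame(start = 100L, end = 300L),
                              data.frame(start = 290L, end = 350L),
                              match_rule = "midpoint", genome_size = 1000L)
  expect_equal(rm2$true_positives, 0L)
})

test_that("reference readers convert BED and 1-based TSV", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("toy\t99\t200\toriC1", bed)
  expect_equal(read_reference(bed), data.frame(start = 99L, end = 200L))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("start\tend", "100\t200"), tsv)
  expect_equal(read_reference(tsv), data.frame(start = 99L, end = 200L))
  expect_error(read_reference(file.path(tempdir(), "absent.bed")),
               class = "archori_input_error")
})

test_that("prediction writers emit TSV, BED and GFF3", {
  truth <- make_toy_genome(toy_genome_spec(length = 30000L, seed = 505L))
  preds <- predict_oric(truth$genome)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  bed <- withr::local_tempfile(fileext = ".bed")
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_predictions(preds, tsv, "tsv")
  write_predictions(preds, bed, "bed")
  write_predictions(preds, gff, "gff3")
  df <- read.delim(tsv)
  expect_equal(df$start_1based, preds$start + 1L)
  expect_equal(df$rule, preds$rule)
  bed_df <- read.delim(bed, header = FALSE)
  expect_equal(bed_df$V2, preds$start)
  gff_lines <- readLines(gff)
  expect_equal(gff_lines[1], "##gff-version 3")
  expect_equal(sum(grepl("replication_origin", gff_lines)), nrow(preds))
  expect_gte(sum(grepl("sequence_feature", gff_lines)), 1L)
})
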