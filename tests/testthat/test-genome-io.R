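# genome readers, coordinate conventions, and intergenic extraction

test_that("GenBank coordinates convert to 0-based half-open", {
  path <- withr::local_tempfile(fileext = ".gbk")
  write_mini_genbank(path)
  g <- read_genbank(path)
  expect_s3_class(g, "annotated_genome")
  expect_true(g$circular)
  expect_equal(g$accession, "MINI01")
  # genes come back sorted by start
  expect_equal(g$genes$start, c(9L, 189L))
  expect_equal(g$genes$end, c(30L, 255L))
  expect_equal(g$genes$strand, c("-", "+"))
  expect_equal(g$genes$product[2], "Cdc6-related protein")
})

test_that("GenBank round trip preserves the planted gene list", {
  truth <- make_toy_genome(toy_genome_spec(length = 20000L, seed = 7L))
  path <- withr::local_tempfile(fileext = ".gbk")
  write_genbank(truth$genome, path)
  back <- read_genbank(path)
  expect_equal(back$sequence, truth$genome$sequence)
  expect_equal(back$genes[, c("id", "start", "end", "strand", "product")],
               truth$genome$genes[, c("id", "start", "end", "strand", "product")])
  expect_true(back$circular)
})

test_that("GenBank errors and warnings fire on malformed input", {
  expect_error(read_genbank(file.path(tempdir(), "nope.gbk")),
               class = "archori_input_error")
  path <- withr::local_tempfile(fileext = ".gbk")
  writeLines(c("LOCUS       X 10 bp DNA circular", "FEATURES",
               "     CDS             complement(join(5..2))",
               "ORIGIN", "        1 acgtacgtac", "//"), path)
  expect_warning(g <- read_genbank(path), "unparseable")
  expect_equal(nrow(g$genes), 0L)
  path2 <- withr::local_tempfile(fileext = ".gbk")
  writeLines(c("LOCUS       X 0 bp DNA circular", "ORIGIN", "//"), path2)
  expect_error(read_genbank(path2), class = "archori_input_error")
})

test_that("PTT rows parse per the NCBI layout and bad rows are skipped", {
  fa <- withr::local_tempfile(fileext = ".fna")
  pt <- withr::local_tempfile(fileext = ".ptt")
  writeLines(c(">ACC1 test", strrep("ACGT", 100)), fa)
  writeLines(c("ACC1 - 1..400", "2 proteins",
               "Location\tStrand\tLength\tPID\tGene\tSynonym\tCode\tCOG\tProduct",
               "190..255\t+\t21\t-\t-\ttag1\t-\t-\tCdc6-related protein",
               "garbage..row\t+\t5\t-\t-\ttagX\t-\t-\tjunk"), pt)
  expect_warning(g <- read_fasta_ptt(fa, pt), "malformed Location")
  expect_equal(nrow(g$genes), 1L)
  expect_equal(g$genes$start, 189L)
  expect_equal(g$genes$end, 255L)
  expect_equal(g$genes$strand, "+")
  expect_equal(g$genes$product, "Cdc6-related protein")
  expect_equal(g$genes$id, "tag1")
  expect_length(g$taxonomy, 0L)
})

test_that("empty PTT body is an input error", {
  fa <- withr::local_tempfile(fileext = ".fna")
  pt <- withr::local_tempfile(fileext = ".ptt")
  writeLines(c(">ACC1", "ACGTACGTACGT"), fa)
  writeLines(c("ACC1 - 1..12", "0 proteins",
               "Location\tStrand\tLength\tPID\tGene\tSynonym\tCode\tCOG\tProduct"),
             pt)
  expect_error(read_fasta_ptt(fa, pt), class = "archori_input_error")
})

test_that("FASTA+PTT round trip preserves the planted gene list", {
  truth <- make_toy_genome(toy_genome_spec(length = 20000L, seed = 11L))
  prefix <- withr::local_tempfile()
  paths <- write_toy_files(truth, prefix)
  back <- read_fasta_ptt(paths[["fna"]], paths[["ptt"]])
  expect_equal(back$sequence, truth$genome$sequence)
  expect_equal(back$genes[, c("id", "start", "end", "strand", "product")],
               truth$genome$genes[, c("id", "start", "end", "strand", "product")])
})

test_that("intergenic extraction matches the brute-force complement", {
  # single gene on a circular genome: one wrap-around region
  g <- annotated_genome("X", random_seq(1000),
                        data.frame(id = "g1", start = 100L, end = 200L,
                                   strand = "+", product = "p",
                                   stringsAsFactors = FALSE))
  regs <- extract_intergenic(g, 0L)
  expect_equal(nrow(regs), 1L)
  expect_equal(regs$start, 200L)
  expect_equal(regs$end, 1100L)
  expect_equal(regs$length, 900L)
  expect_equal(nchar(regs$sequence), 900L)
  expect_equal(regs$left_gene, "g1")
  expect_equal(regs$right_gene, "g1")

  # brute force: region positions are exactly the uncovered positions
  pos <- unlist(lapply(seq_len(nrow(regs)), function(i)
    (regs$start[i]:(regs$end[i] - 1L)) %% 1000L))
  expect_setequal(pos, brute_force_intergenic_positions(g))
})

test_that("gene spans plus intergenic regions tile random circular genomes", {
  set.seed(301)
  for (rep in 1:10) {
    n <- 500L
    k <- sample(2:6, 1)
    starts <- sort(sample(0:(n - 30L), k))
    lens <- sample(10:60, k, replace = TRUE)
    genes <- data.frame(id = paste0("g", 1:k), start = starts,
                        end = pmin(starts + lens, n + starts),  # may overlap
                        strand = "+", product = "p", stringsAsFactors = FALSE)
    g <- annotated_genome("X", random_seq(n), genes)
    regs <- extract_intergenic(g, 0L)
    inter <- if (nrow(regs)) unlist(lapply(seq_len(nrow(regs)), function(i)
      (regs$start[i]:(regs$end[i] - 1L)) %% n)) else integer(0)
    expect_false(any(duplicated(inter)))
    expect_setequal(inter, brute_force_intergenic_positions(g))
  }
})

test_that("full coverage, thresholds and wrap genes are handled", {
  # genes covering the whole sequence -> no intergenic regions
  g <- annotated_genome("X", random_seq(100),
                        data.frame(id = c("a", "b"), start = c(0L, 50L),
                                   end = c(60L, 100L), strand = "+",
                                   product = "p", stringsAsFactors = FALSE))
  expect_equal(nrow(extract_intergenic(g, 0L)), 0L)

  # 30 bp gap excluded at min_len = 50
  g2 <- annotated_genome("X", random_seq(400),
                         data.frame(id = c("a", "b"), start = c(0L, 130L),
                                    end = c(100L, 400L), strand = "+",
                                    product = "p", stringsAsFactors = FALSE))
  expect_equal(nrow(extract_intergenic(g2, 50L)), 0L)
  regs <- extract_intergenic(g2, 30L)
  expect_equal(regs$start, 100L)
  expect_equal(regs$end, 130L)

  # gene wrapping the coordinate origin
  g3 <- annotated_genome("X", random_seq(300),
                         data.frame(id = c("w", "m"), start = c(250L, 100L),
                                    end = c(320L, 150L), strand = "+",
                                    product = "p", stringsAsFactors = FALSE))
  regs3 <- extract_intergenic(g3, 0L)
  expect_setequal(unlist(lapply(seq_len(nrow(regs3)), function(i)
    (regs3$start[i]:(regs3$end[i] - 1L)) %% 300L)),
    brute_force_intergenic_positions(g3))
})

test_that("coordinate round trip reproduces PTT Location strings", {
  truth <- make_toy_genome(toy_genome_spec(length = 20000L, seed = 3L))
  prefix <- withr::local_tempfile()
  paths <- write_toy_files(truth, prefix)
  lines <- readLines(paths[["ptt"]])[-(1:3)]
  locs <- vapply(strsplit(lines, "\t"), `[`, "", 1L)
  back <- read_fasta_ptt(paths[["fna"]], paths[["ptt"]])
  n <- genome_length(back)
  relocs <- vapply(seq_len(nrow(back$genes)), function(i) {
    a <- back$genes$start[i] + 1L
    b <- if (back$genes$end[i] <= n) back$genes$end[i] else back$genes$end[i] - n
    sprintf("%d..%d", a, b)
  }, character(1))
  expect_equal(sort(relocs), sort(locs))
})
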