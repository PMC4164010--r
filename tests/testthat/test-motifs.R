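# ORB motif set, consensus matching, PSSM scoring and exact p-values

test_that("the built-in ORB motif set is complete and normalized", {
  m <- builtin_motifs()
  expect_length(m, 11L)
  expect_equal(m$Common$width, 20L)
  expect_equal(m$Methanococcaceae$consensus,
               "TT[TA][GT]ATTCA[TC][GA]AT[AT]T[AT]T[AT]")
  taxa <- vapply(m, `[[`, "", "taxonomy")
  expect_setequal(unique(taxa),
                  c("Halobacteriaceae", "Methanobacteriaceae",
                    "Methanomicrobia", "Methanococcaceae", "Sulfolobaceae",
                    "Thermococcaceae", "Common"))
  expect_equal(sum(taxa == "Sulfolobaceae"), 3L)
  expect_equal(sum(taxa == "Thermococcaceae"), 3L)
  for (mm in m) {
    expect_equal(unname(rowSums(mm$pspm)), rep(1, mm$width), tolerance = 1e-9)
    expect_true(all(mm$pspm >= 0 & mm$pspm <= 1))
    expect_equal(mm$width, length(archori:::parse_consensus(mm$consensus)))
  }
})

test_that("degenerate consensus matching finds hits on both strands", {
  common <- builtin_motifs()$Common
  inst <- "TCCACTTGAAATGAAGGGGT"
  hits <- match_regex(common, inst)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$region_offset, 0L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$matched_sequence, inst)

  rc_hits <- match_regex(common, rev_comp(inst))
  expect_equal(nrow(rc_hits), 1L)
  expect_equal(rc_hits$strand, "-")
  expect_equal(rc_hits$region_offset, 0L)
  expect_equal(rc_hits$matched_sequence, inst)

  expect_equal(nrow(match_regex(common, "AAAA")), 0L)
})

test_that("window scores follow the log-likelihood-ratio formula", {
  m <- motif_model("AA", "AA", epsilon = 0)
  expect_equal(score_window(m, "AA"), 4)          # 2 * log2(1/0.25)
  expect_equal(score_window(m, "AC"), -Inf)       # zero-probability base
  m2 <- motif_model("AA2", "AA", epsilon = 0.005)
  expect_equal(score_window(m2, "AC"),
               log2(0.985 / 0.25) + log2(0.005 / 0.25))
  expect_equal(score_window(m2, "AN"), -Inf)      # ambiguity rule
  expect_error(score_window(m2, "AAA"), class = "archori_usage_error")
})

test_that("p-value DP matches closed forms and exhaustive enumeration", {
  # width-2 all-A motif, uniform background: only AA attains the maximum
  m <- motif_model("AA", "AA", epsilon = 0.005)
  pv <- pvalue_table(m)
  smax <- score_window(m, "AA")
  expect_equal(motif_pvalue(pv, smax), 1 / 16, tolerance = 1e-9)
  expect_equal(motif_pvalue(pv, -Inf), 1)
  expect_equal(motif_pvalue(pv, pv$lo * pv$bin), 1)
  # monotone non-increasing tail
  expect_true(all(diff(pv$tail) <= 1e-12))

  # DP vs exhaustive enumeration on truncations (widths 3..5)
  set.seed(140)
  for (w in 3:5) {
    mm <- truncate_motif(builtin_motifs()$Common, w)
    pvt <- pvalue_table(mm)
    oracle <- enumerate_pvalue(mm)
    for (q in c(0.01, 0.25, 0.5, 0.9)) {
      s <- stats::quantile(replicate(20, score_window(mm, random_seq(w))), q)
      expect_equal(motif_pvalue(pvt, s), oracle(s), tolerance = 1e-6)
    }
    expect_equal(motif_pvalue(pvt, -10), oracle(-10), tolerance = 1e-6)
  }
})

test_that("scanning reports planted instances and obeys the cutoff", {
  common <- builtin_motifs()$Common
  inst <- "TCCACTTGAAATGAAGGGGT"
  set.seed(150)
  region <- paste0(random_seq(60), inst, random_seq(60))
  hits <- scan_motif(common, region, p_cutoff = 1e-4, offset = 1000L)
  expect_gte(nrow(hits), 1L)
  expect_true(any(hits$region_offset == 60L))
  expect_true(all(hits$p_value <= 1e-4))
  expect_equal(hits$genome_position, hits$region_offset + 1000L)
  # matched_sequence equals the (revcomp'd) genome subsequence
  for (i in seq_len(nrow(hits))) {
    sub <- substr(region, hits$region_offset[i] + 1L,
                  hits$region_offset[i] + common$width)
    expect_equal(hits$matched_sequence[i],
                 if (hits$strand[i] == "-") rev_comp(sub) else sub)
  }
  # all-N region and too-short region give nothing
  expect_equal(nrow(scan_motif(common, strrep("N", 100))), 0L)
  expect_equal(nrow(scan_motif(common, "ACGT")), 0L)
  expect_error(scan_motif(common, region, p_cutoff = 2),
               class = "archori_usage_error")
})

test_that("doubling the cutoff never loses hits; strand scan is symmetric", {
  set.seed(151)
  m <- builtin_motifs()$Methanococcaceae
  for (rep in 1:10) {
    s <- random_seq(300)
    h1 <- scan_motif(m, s, p_cutoff = 0.005)
    h2 <- scan_motif(m, s, p_cutoff = 0.01)
    expect_gte(nrow(h2), nrow(h1))

    # strand symmetry: hits on revcomp(s) mirror hits on s
    ha <- scan_motif(m, s, p_cutoff = 0.01)
    hb <- scan_motif(m, rev_comp(s), p_cutoff = 0.01)
    n <- nchar(s); w <- m$width
    mirrored <- sort(n - hb$region_offset - w)
    expect_equal(sort(ha$region_offset), mirrored)
    expect_equal(sort(ha$score), sort(hb$score))
  }
})

test_that("every regex match is also a PSSM hit at the 1e-4 cutoff", {
  set.seed(152)
  for (m in builtin_motifs()) {
    # embed a random realization of the consensus in random flanks
    tokens <- archori:::parse_consensus(m$consensus)
    inst <- paste(vapply(tokens, function(t) sample(t, 1L), ""), collapse = "")
    s <- paste0(random_seq(30), inst, random_seq(30))
    rx <- match_regex(m, s)
    expect_gte(nrow(rx), 1L)
    ps <- scan_motif(m, s, p_cutoff = 1e-4)
    for (off in rx$region_offset) {
      expect_true(off %in% ps$region_offset,
                  label = sprintf("%s regex hit at %d is a PSSM hit", m$name, off))
    }
  }
})

test_that("MEME export is well formed and hits export to TSV and BED", {
  m <- builtin_motifs()
  path <- withr::local_tempfile(fileext = ".meme")
  write_meme_motifs(m, path)
  lines <- readLines(path)
  expect_equal(sum(grepl("^MOTIF ", lines)), 11L)
  expect_true(any(grepl("letter-probability matrix: alength= 4 w= 20", lines)))

  hits <- scan_motif(m$Common, paste0("AC", "TCCACTTGAAATGAAGGGGT", "CA"),
                     offset = 100L)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_hits(hits, tsv, "tsv")
  write_hits(hits, bed, "bed", chrom = "toy")
  expect_equal(read.delim(tsv)$start, 102L)
  bed_df <- read.delim(bed, header = FALSE)
  expect_equal(bed_df$V2, 102L)
  expect_equal(bed_df$V3, 122L)
})
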