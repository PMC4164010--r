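# motif_scan: the built-in ORB (origin recognition box) motif set, degenerate
# consensus matching, PSSM log-likelihood-ratio scoring and exact p-values by
# dynamic programming on a discretized score lattice.

BASES <- c("A", "C", "G", "T")

# The ORB consensus patterns, grouped by the taxonomic cluster of the origin
# collection each was derived from; "Common" is derived from all clusters.
# Bracket notation: [XY] = X or Y at that position.
ORB_CONSENSUS <- data.frame(
  name = c("Halobacteriaceae", "Methanobacteriaceae", "Methanomicrobia",
           "Methanococcaceae", "Sulfolobaceae_1", "Sulfolobaceae_2",
           "Sulfolobaceae_3", "Thermococcaceae_1", "Thermococcaceae_2",
           "Thermococcaceae_3", "Common"),
  taxonomy = c("Halobacteriaceae", "Methanobacteriaceae", "Methanomicrobia",
               "Methanococcaceae", "Sulfolobaceae", "Sulfolobaceae",
               "Sulfolobaceae", "Thermococcaceae", "Thermococcaceae",
               "Thermococcaceae", "Common"),
  consensus = c(
    "TT[TC]CACC[GCT]GAAAC[GA][AC][GA]G[GT]G[GT]",
    "TT[TA]CACTTGAAAT[GTA]T[CT][CG]TC",
    "TCCA[GC]T[GT]GAAA[CT][AG]A[AT]GGGGT",
    "TT[TA][GT]ATTCA[TC][GA]AT[AT]T[AT]T[AT]",
    "[GC]GGCCGG[AG]A[GT][CT][GT]T[CG]A[CA]CC[TC]GG",
    "TCCA[AG][AT][TG]GAA[CA][CT][GA]AAGGGGT",
    "GAGTGC[GT]CGGTT[CGT]GCA[ATC]CC[AG]",
    "[TC]TCCAGTGGAAA[TC][GA]AA[AG]CTC",
    "[CAG]TTTCCA[CT][TA]GGA[AT][CGA][CT]",
    "AATG[ACT]ACA[AT]A[AGT]ATG[TA][TG]CATT",
    "TCCA[CG]T[TG]GAAA[TC][GA]AAGGGGT"),
  stringsAsFactors = FALSE)

# tokenize a bracket consensus into a list of allowed-base character vectors
parse_consensus <- function(consensus) {
  chars <- strsplit(consensus, "", fixed = TRUE)[[1]]
  out <- list()
  i <- 1L
  while (i <= length(chars)) {
    if (chars[i] == "[") {
      j <- i + 1L
      while (chars[j] != "]") j <- j + 1L
      out[[length(out) + 1L]] <- chars[(i + 1L):(j - 1L)]
      i <- j + 1L
    } else {
      out[[length(out) + 1L]] <- chars[i]
      i <- i + 1L
    }
  }
  stopifnot(all(unlist(out) %in% BASES))
  out
}

IUPAC_BY_SET <- c(A = "A", C = "C", G = "G", T = "T",
                  AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
                  ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N")

consensus_to_iupac <- function(tokens) {
  paste(vapply(tokens, function(s) {
    IUPAC_BY_SET[[paste(sort(unique(s)), collapse = "")]]
  }, character(1)), collapse = "")
}

#' Construct a motif model from a degenerate consensus
#'
#' Builds the position-specific probability matrix (PSPM) from a bracket
#' consensus: at each position the bases not listed in the pattern receive a
#' small pseudo-probability (`epsilon` each) and the listed alternatives share
#' the remainder uniformly. This reproduces the consensus ordering of the
#' motif while keeping every base scorable.
#'
#' @param name motif name.
#' @param consensus degenerate pattern in bracket notation, e.g.
#'   `"TCCA[CG]T..."`.
#' @param taxonomy taxonomic cluster label (default `"Common"`).
#' @param background length-4 base probability vector (A, C, G, T); default
#'   uniform.
#' @param epsilon pseudo-probability given to each unlisted base (default
#'   0.005).
#' @return object of class `motif_model`: list with `name`, `taxonomy`,
#'   `consensus`, `width`, `pspm` (width x 4 matrix, columns A, C, G, T) and
#'   `background`.
#' @export
motif_model <- function(name, consensus, taxonomy = "Common",
                        background = rep(0.25, 4), epsilon = 0.005) {
  stopifnot(length(background) == 4L, abs(sum(background) - 1) < 1e-9,
            all(background > 0))
  tokens <- parse_consensus(consensus)
  w <- length(tokens)
  pspm <- matrix(0, nrow = w, ncol = 4L, dimnames = list(NULL, BASES))
  for (i in seq_len(w)) {
    listed <- unique(tokens[[i]])
    unlisted <- setdiff(BASES, listed)
    pspm[i, unlisted] <- epsilon
    pspm[i, listed] <- (1 - epsilon * length(unlisted)) / length(listed)
  }
  structure(list(name = name, taxonomy = taxonomy, consensus = consensus,
                 width = w, pspm = pspm,
                 background = stats::setNames(background, BASES)),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("motif_model %s (%s): width %d, consensus %s\n",
              x$name, x$taxonomy, x$width, x$consensus))
  invisible(x)
}

#' The built-in ORB motif set
#'
#' Eleven origin recognition box motifs organized by taxonomic cluster
#' (Halobacteriaceae, Methanobacteriaceae, Methanomicrobia, Methanococcaceae,
#' Sulfolobaceae x3, Thermococcaceae x3) plus the cluster-independent Common
#' motif, as degenerate consensus patterns with PSPMs derived via
#' [motif_model()].
#'
#' @param background length-4 base probability vector (A, C, G, T) used for
#'   all models; default uniform.
#' @param epsilon pseudo-probability for unlisted bases (default 0.005).
#' @return list of `motif_model` objects, named by motif name.
#' @export
builtin_motifs <- function(background = rep(0.25, 4), epsilon = 0.005) {
  out <- lapply(seq_len(nrow(ORB_CONSENSUS)), function(i) {
    motif_model(ORB_CONSENSUS$name[i], ORB_CONSENSUS$consensus[i],
                taxonomy = ORB_CONSENSUS$taxonomy[i],
                background = background, epsilon = epsilon)
  })
  stats::setNames(out, ORB_CONSENSUS$name)
}

#' Select motifs for a genome by taxonomy
#'
#' Matches the genome's lineage strings against the cluster names of the
#' motif set (case-insensitive); the Common motif is always included. With no
#' lineage match only the Common motif is used.
#'
#' @param genome an [annotated_genome].
#' @param motifs motif list (default [builtin_motifs()]).
#' @return a named list of `motif_model`s.
#' @export
select_motifs <- function(genome, motifs = builtin_motifs()) {
  taxa <- vapply(motifs, function(m) m$taxonomy, character(1))
  lineage <- tolower(genome$taxonomy)
  hit <- vapply(taxa, function(tx) {
    tx != "Common" && any(grepl(tolower(tx), lineage, fixed = TRUE))
  }, logical(1))
  motifs[hit | taxa == "Common"]
}

# ---- degenerate consensus matching ----------------------------------------

#' Match a motif's degenerate consensus against a sequence
#'
#' Finds every occurrence of the bracket pattern on both strands (the minus
#' strand is scanned as the reverse complement and mapped back to
#' forward-strand coordinates). Score and p-value are not computed here; use
#' [scan_motif()] for PSSM scoring.
#'
#' @param motif a `motif_model`.
#' @param sequence nucleotide string.
#' @return data.frame of hits with columns `motif_name`, `region_offset`
#'   (0-based start of the match footprint on the forward strand), `strand`,
#'   `matched_sequence` (in motif orientation), `score`, `p_value`
#'   (both `NA`).
#' @export
match_regex <- function(motif, sequence) {
  w <- motif$width
  n <- nchar(sequence)
  empty <- data.frame(motif_name = character(), region_offset = integer(),
                      strand = character(), matched_sequence = character(),
                      score = numeric(), p_value = numeric(),
                      stringsAsFactors = FALSE)
  if (n < w) return(empty)
  pat <- consensus_to_iupac(parse_consensus(motif$consensus))
  subj <- Biostrings::DNAString(sequence)
  hit_rows <- function(m, strand) {
    if (length(m) == 0L) return(NULL)
    starts0 <- BiocGenerics::start(m) - 1L
    if (strand == "-") starts0 <- n - starts0 - w  # map back to forward strand
    seqs <- vapply(starts0, function(s0) {
      sub <- substr(sequence, s0 + 1L, s0 + w)
      if (strand == "-") rev_comp(sub) else sub
    }, character(1))
    data.frame(motif_name = motif$name, region_offset = starts0,
               strand = strand, matched_sequence = seqs,
               score = NA_real_, p_value = NA_real_, stringsAsFactors = FALSE)
  }
  fwd <- Biostrings::matchPattern(pat, subj, fixed = FALSE)
  rev <- Biostrings::matchPattern(pat, Biostrings::reverseComplement(subj),
                                  fixed = FALSE)
  out <- rbind(hit_rows(fwd, "+"), hit_rows(rev, "-"))
  if (is.null(out)) return(empty)
  out <- out[order(out$region_offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- PSSM scoring ----------------------------------------------------------

# width x 4 log-likelihood-ratio matrix in bits
score_matrix <- function(motif) {
  log2(sweep(motif$pspm, 2, motif$background, "/"))
}

#' Score one window against a motif
#'
#' Log-likelihood ratio in bits: the sum over positions of
#' `log2(pspm[i, base] / background[base])`. A window containing any
#' non-ACGT base is unscorable and returns `-Inf`.
#'
#' @param motif a `motif_model`.
#' @param window nucleotide string of exactly the motif width.
#' @return numeric score in bits (`-Inf` sentinel for unscorable windows).
#' @export
score_window <- function(motif, window) {
  if (nchar(window) != motif$width)
    err_usage(sprintf("window length %d != motif width %d",
                      nchar(window), motif$width))
  v <- strsplit(toupper(window), "", fixed = TRUE)[[1]]
  idx <- match(v, BASES)
  if (anyNA(idx)) return(-Inf)
  S <- score_matrix(motif)
  sum(S[cbind(seq_along(idx), idx)])
}

#' Exact p-value table for a motif score under the background
#'
#' Computes the exact null distribution of the log-likelihood-ratio score of
#' a random background string of the motif's width by dynamic programming
#' over positions on a discretized score lattice (default bin 1/1000 bit).
#' P-values are non-increasing in score and the p-value at the minimum
#' attainable score is 1.
#'
#' @param motif a `motif_model`.
#' @param bin lattice bin width in bits (default 0.001).
#' @return object of class `motif_pvalue_table`: list with the integer score
#'   matrix `int_scores` (width x 4), `bin`, `lo` (smallest attainable
#'   integer score) and `tail`, where `tail[k]` is `P(int score >= lo + k - 1)`.
#' @export
pvalue_table <- function(motif, bin = 0.001) {
  S <- score_matrix(motif)
  I <- round(S / bin)
  w <- motif$width
  bg <- motif$background
  mins <- apply(I, 1, min); maxs <- apply(I, 1, max)
  cur <- 1; curlo <- 0
  for (j in seq_len(w)) {
    newlo <- curlo + mins[j]
    newhi <- curlo + length(cur) - 1 + maxs[j]
    new <- numeric(newhi - newlo + 1)
    for (b in 1:4) {
      sh <- curlo + I[j, b] - newlo
      idx <- (sh + 1):(sh + length(cur))
      new[idx] <- new[idx] + cur * bg[b]
    }
    cur <- new; curlo <- newlo
  }
  tail <- rev(cumsum(rev(cur)))
  tail <- pmin(tail, 1)   # guard against summation round-off
  structure(list(int_scores = I, bin = bin, lo = curlo, tail = tail,
                 prob = cur, width = w),
            class = "motif_pvalue_table")
}

#' Look up the p-value of a score
#'
#' The null distribution lives on a lattice of per-position-rounded scores,
#' so a real-valued window score can drift from its lattice point by up to
#' `width` bins of accumulated rounding. Scores within that tolerance of an
#' attainable lattice score are snapped to it before the tail lookup, making
#' `motif_pvalue(table, score_window(motif, w))` agree with the exact
#' distribution; scores farther from any attainable value are treated as
#' plain thresholds.
#'
#' @param table a `motif_pvalue_table` from [pvalue_table()].
#' @param score_bits numeric vector of scores in bits; `-Inf` maps to
#'   p-value 1 (every attainable score exceeds it).
#' @return numeric vector of p-values `P(score >= s)` under the background.
#' @export
motif_pvalue <- function(table, score_bits) {
  p <- numeric(length(score_bits))
  p[!is.finite(score_bits) & score_bits < 0] <- 1
  fin <- which(is.finite(score_bits))
  if (!length(fin)) return(p)
  k <- round(score_bits[fin] / table$bin) - table$lo + 1
  attainable <- which(table$prob > 0)
  # snap to the nearest attainable lattice index within the rounding slack
  iv <- findInterval(k, attainable)
  lo_idx <- attainable[pmax(iv, 1L)]
  hi_idx <- attainable[pmin(iv + 1L, length(attainable))]
  nearest <- ifelse(abs(k - lo_idx) <= abs(hi_idx - k), lo_idx, hi_idx)
  snap <- abs(nearest - k) <= table$width
  k[snap] <- nearest[snap]
  p[fin] <- ifelse(k <= 1, 1,
                   ifelse(k > length(table$tail), 0, table$tail[pmax(k, 1L)]))
  p
}

# integer-lattice window scores for every window of a coded sequence;
# codes: 1..4 for ACGT, NA otherwise. Returns list(int, bits, valid).
window_scores <- function(I, S, codes) {
  w <- nrow(I)
  m <- length(codes) - w + 1L
  if (m < 1L) return(list(int = integer(0), bits = numeric(0), valid = logical(0)))
  int <- numeric(m); bits <- numeric(m); bad <- logical(m)
  for (j in seq_len(w)) {
    cj <- codes[j:(j + m - 1L)]
    nas <- is.na(cj)
    bad <- bad | nas
    cj[nas] <- 1L
    int <- int + I[cbind(rep.int(j, m), cj)]
    bits <- bits + S[cbind(rep.int(j, m), cj)]
  }
  list(int = int, bits = bits, valid = !bad)
}

#' Scan a sequence for motif occurrences above a p-value cutoff
#'
#' Scores every window on both strands with the motif PSSM and reports the
#' windows whose exact p-value is at or below the cutoff, sorted by position.
#' Overlapping hits are all retained. Windows containing any non-ACGT base
#' are skipped.
#'
#' @param motif a `motif_model`.
#' @param sequence nucleotide string (an intergenic region, typically).
#' @param p_cutoff p-value cutoff in (0, 1); default `1e-4`.
#' @param offset genomic position of the first base of `sequence` (0-based);
#'   hit coordinates are reported both region-relative and genomic.
#' @param genome_size circumference for wrapping genomic positions (`NULL`
#'   to leave them unwrapped).
#' @param pv optional precomputed [pvalue_table()] for the motif.
#' @return data.frame of hits: `motif_name`, `region_offset`,
#'   `genome_position`, `strand`, `score` (bits), `p_value`,
#'   `matched_sequence` (motif orientation).
#' @export
scan_motif <- function(motif, sequence, p_cutoff = 1e-4, offset = 0L,
                       genome_size = NULL, pv = NULL) {
  if (!(p_cutoff > 0 && p_cutoff < 1)) err_usage("p_cutoff must be in (0, 1)")
  w <- motif$width
  empty <- empty_hits_df()
  n <- nchar(sequence)
  if (n < w) return(empty)
  if (is.null(pv)) pv <- pvalue_table(motif)
  S <- score_matrix(motif)
  I <- pv$int_scores
  codes <- match(strsplit(toupper(sequence), "", fixed = TRUE)[[1]], BASES)

  strand_hits <- function(codes_s, strand) {
    ws <- window_scores(I, S, codes_s)
    if (!length(ws$int)) return(NULL)
    k <- ws$int - pv$lo + 1
    p <- ifelse(k <= 1, 1, ifelse(k > length(pv$tail), 0, pv$tail[pmax(k, 1)]))
    keep <- ws$valid & p <= p_cutoff
    if (!any(keep)) return(NULL)
    s0 <- which(keep) - 1L                       # 0-based on the scanned strand
    fwd0 <- if (strand == "+") s0 else n - s0 - w
    seqs <- vapply(fwd0, function(a) {
      sub <- substr(sequence, a + 1L, a + w)
      if (strand == "-") rev_comp(sub) else sub
    }, character(1))
    data.frame(motif_name = motif$name, region_offset = fwd0,
               genome_position = fwd0 + offset, strand = strand,
               score = ws$bits[keep], p_value = p[keep],
               matched_sequence = seqs, stringsAsFactors = FALSE)
  }
  rc_codes <- rev(5L - codes)   # A<->T, C<->G on the integer coding
  out <- rbind(strand_hits(codes, "+"), strand_hits(rc_codes, "-"))
  if (is.null(out)) return(empty)
  if (!is.null(genome_size)) out$genome_position <- out$genome_position %% genome_size
  out <- out[order(out$region_offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a sequence with a set of motifs
#'
#' @inheritParams scan_motif
#' @param motifs list of `motif_model`s.
#' @param pv_cache optional named list of precomputed p-value tables.
#' @return pooled hit data.frame (see [scan_motif()]), sorted by position.
#' @export
scan_motif_set <- function(motifs, sequence, p_cutoff = 1e-4, offset = 0L,
                           genome_size = NULL, pv_cache = NULL) {
  hits <- lapply(motifs, function(m) {
    scan_motif(m, sequence, p_cutoff = p_cutoff, offset = offset,
               genome_size = genome_size, pv = pv_cache[[m$name]])
  })
  out <- do.call(rbind, hits)
  out <- out[order(out$region_offset, out$motif_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# p-value tables depend only on the PSPM/background/bin, so repeated
# predictions can share them
.pv_cache <- new.env(parent = emptyenv())
cached_pvalue_table <- function(motif, bin = 0.001) {
  key <- paste(motif$consensus, paste(signif(motif$background, 10), collapse = ","),
               paste(signif(range(motif$pspm), 10), collapse = ","), bin)
  tab <- .pv_cache[[key]]
  if (is.null(tab)) {
    tab <- pvalue_table(motif, bin = bin)
    .pv_cache[[key]] <- tab
  }
  tab
}

empty_hits_df <- function() {
  data.frame(motif_name = character(), region_offset = integer(),
             genome_position = integer(), strand = character(),
             score = numeric(), p_value = numeric(),
             matched_sequence = character(), stringsAsFactors = FALSE)
}

# ---- export formats --------------------------------------------------------

#' Write motifs in MEME minimal motif format
#'
#' Letter-probability matrices consumable by MEME-suite tools (FIMO etc.).
#'
#' @param motifs list of `motif_model`s.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_meme_motifs <- function(motifs, path) {
  con <- file(path, "w"); on.exit(close(con))
  bg <- motifs[[1]]$background
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "", "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f",
                       bg["A"], bg["C"], bg["G"], bg["T"]), ""), con)
  for (m in motifs) {
    writeLines(sprintf("MOTIF %s", m$name), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       m$width), con)
    for (i in seq_len(m$width))
      writeLines(sprintf(" %.6f %.6f %.6f %.6f", m$pspm[i, 1], m$pspm[i, 2],
                         m$pspm[i, 3], m$pspm[i, 4]), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Write motif hits as TSV or BED6
#'
#' TSV columns: motif, start, end, strand, score_bits, p_value, sequence.
#' BED6 uses 0-based half-open coordinates with score = bits x 100 capped at
#' 1000.
#'
#' @param hits hit data.frame from [scan_motif()]/[scan_motif_set()].
#' @param path output path.
#' @param format `"tsv"` or `"bed"`.
#' @param width motif width used for the end coordinate when the hits come
#'   from a single motif; inferred from `matched_sequence` otherwise.
#' @param chrom chromosome/accession name for BED output.
#' @return invisibly, `path`.
#' @export
write_hits <- function(hits, path, format = c("tsv", "bed"), width = NULL,
                       chrom = "chr") {
  format <- match.arg(format)
  w <- if (!is.null(width)) rep(width, nrow(hits)) else nchar(hits$matched_sequence)
  start <- hits$genome_position
  if (is.null(start)) start <- hits$region_offset
  if (format == "tsv") {
    df <- data.frame(motif = hits$motif_name, start = start, end = start + w,
                     strand = hits$strand, score_bits = hits$score,
                     p_value = hits$p_value, sequence = hits$matched_sequence)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    df <- data.frame(chrom = chrom, start = start, end = start + w,
                     name = hits$motif_name,
                     score = pmin(1000, round(pmax(hits$score, 0) * 100)),
                     strand = hits$strand)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}
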