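# Independent oracles and fixture builders used across the test files. Each
# oracle is a deliberately naive implementation (direct counting, exhaustive
# enumeration, quadratic search) kept separate from the package's own
# algorithms.

random_seq <- function(n, prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# per-prefix base-counting oracle for the Z-curve components
zcurve_counting_oracle <- function(sequence) {
  v <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  n <- length(v)
  cnt <- function(b) c(0, cumsum(v == b))
  A <- cnt("A"); C <- cnt("C"); G <- cnt("G"); T <- cnt("T")
  list(x = (A + G) - (C + T), y = (A + C) - (G + T), z = (A + T) - (G + C),
       at = A - T, gc = G - C)
}

# exhaustive enumeration of the motif-score null distribution: scores and
# probabilities of all 4^width windows under the background
enumerate_pvalue <- function(motif) {
  w <- motif$width
  S <- log2(sweep(motif$pspm, 2, motif$background, "/"))
  grid <- as.matrix(expand.grid(rep(list(1:4), w)))
  scores <- numeric(nrow(grid))
  probs <- numeric(nrow(grid))
  for (j in seq_len(w)) {
    scores <- scores + S[j, grid[, j]]
    probs <- probs + log(motif$background[grid[, j]])
  }
  probs <- exp(probs)
  function(s) sum(probs[scores >= s - 1e-9])
}

# truncate a motif model to its first `w` positions
truncate_motif <- function(motif, w) {
  tokens <- archori:::parse_consensus(motif$consensus)[seq_len(w)]
  cons <- paste(vapply(tokens, function(t)
    if (length(t) == 1L) t else paste0("[", paste(t, collapse = ""), "]"),
    character(1)), collapse = "")
  motif_model(paste0(motif$name, "_w", w), cons, taxonomy = motif$taxonomy,
              background = unname(motif$background))
}

# quadratic brute-force maximal exact repeat finder
brute_force_repeats <- function(sequence, min_len,
                                kinds = c("direct", "palindromic")) {
  s <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  n <- length(s)
  rc1 <- function(b) chartr("ACGT", "TGCA", b)
  hits <- list()
  if ("direct" %in% kinds) {
    for (a in 1:n) for (b in 1:n) {
      if (b <= a) next
      len <- 0L
      while (a + len <= n && b + len <= n && s[a + len] == s[b + len])
        len <- len + 1L
      if (len < min_len) next
      left_max <- a == 1L || b == 1L || s[a - 1L] != s[b - 1L]
      if (left_max) hits[[length(hits) + 1L]] <-
          data.frame(kind = "direct", pos1 = a - 1L, pos2 = b - 1L,
                     length = len)
    }
  }
  if ("palindromic" %in% kinds) {
    # the relation s[b..b+len) == revcomp(s[a..a+len)) pairs s[a+i] with
    # s[b+len-1-i], so it is tested at each length directly (it is not
    # prefix-closed, unlike direct repeats); windows are compared wholesale
    # per length
    su <- paste(s, collapse = "")
    rcs <- paste(rev(rc1(s)), collapse = "")
    for (len in min_len:n) {
      m <- n - len + 1L
      if (m < 1L) break
      W <- substring(su, 1:m, len:n)
      # revcomp of the window starting at a (1-based): rcs[n+2-a-len .. n+1-a]
      R <- substring(rcs, n + 2L - (1:m) - len, n + 1L - (1:m))
      buckets <- split(seq_len(m), W)
      for (a in 1:m) {
        partners <- buckets[[R[a]]]
        for (b in partners) {
          if (b < a) next
          front_ext <- a > 1L && b + len <= n && s[b + len] == rc1(s[a - 1L])
          back_ext <- b > 1L && a + len <= n && s[b - 1L] == rc1(s[a + len])
          if (!front_ext && !back_ext) hits[[length(hits) + 1L]] <-
              data.frame(kind = "palindromic", pos1 = a - 1L, pos2 = b - 1L,
                         length = len)
        }
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(kind = character(), pos1 = integer(),
                      pos2 = integer(), length = integer()))
  }
  df <- unique(do.call(rbind, hits))
  df <- df[order(df$pos1, df$pos2, df$kind), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# brute-force complement of gene-covered positions on a circular genome
brute_force_intergenic_positions <- function(genome) {
  n <- genome_length(genome)
  covered <- logical(n)
  g <- genome$genes
  for (i in seq_len(nrow(g))) {
    pos <- (g$start[i]:(g$end[i] - 1L)) %% n
    covered[pos + 1L] <- TRUE
  }
  which(!covered) - 1L
}

# a tiny hand-written GenBank fixture with two genes
write_mini_genbank <- function(path, seq = NULL) {
  if (is.null(seq)) seq <- strrep("ACGT", 100)  # 400 bp
  g <- annotated_genome("MINI01", seq,
                        data.frame(id = c("g1", "g2"),
                                   start = c(189L, 9L), end = c(255L, 30L),
                                   strand = c("+", "-"),
                                   product = c("Cdc6-related protein",
                                               "hypothetical protein"),
                                   stringsAsFactors = FALSE))
  write_genbank(g, path)
  path
}
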