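# repeats: maximal exact direct repeats and reverse-complement (palindromic)
# repeats within a candidate region, by seed-and-extend over k-mer buckets.
# Regions are short (typically < 5 kb), so the simple algorithm with a cheap
# correctness oracle beats suffix-structure machinery.

#' Find maximal exact repeats in a sequence
#'
#' Reports every maximal pair occurrence of an exact direct repeat
#' (`seq[pos1..] == seq[pos2..]`) and/or reverse-complement palindromic
#' repeat (`seq[pos2..] == revcomp(seq[pos1..])`) of at least `min_len` bp.
#' Maximal means extending the pair one base left or right breaks the
#' equality. Self-overlapping pairs are allowed (tandem repeats); a sequence
#' equal to its own reverse complement reports a palindromic hit with
#' `pos1 == pos2`. Low-complexity hits (repeated string using at most two
#' distinct bases) are flagged, not removed: G-stretches flanking ORBs are
#' biologically meaningful.
#'
#' @param sequence nucleotide string.
#' @param min_len minimum repeat length in bp (>= 4; default 8).
#' @param kinds subset of `c("direct", "palindromic")`.
#' @return data.frame with columns `kind`, `pos1`, `pos2` (0-based starts,
#'   `pos1 <= pos2`), `length`, `sequence` (the repeated string, at `pos1`),
#'   `low_complexity`; sorted by `(pos1, pos2)`.
#' @export
find_repeats <- function(sequence, min_len = 8L,
                         kinds = c("direct", "palindromic")) {
  if (min_len < 4L) err_usage("min_len must be >= 4")
  kinds <- match.arg(kinds, several.ok = TRUE)
  s <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  n <- length(s)
  out <- list()
  if (n >= min_len) {
    k <- as.integer(min_len)
    kmers <- substring(sequence, 1:(n - k + 1L), k:n)
    kmers <- toupper(kmers)
    buckets <- split(seq_along(kmers), kmers)

    seen <- new.env(parent = emptyenv())
    add_hit <- function(kind, a, b, len) {
      key <- paste(kind, a, b, len)
      if (!is.null(seen[[key]])) return()
      seen[[key]] <- TRUE
      rep_seq <- paste(s[a:(a + len - 1L)], collapse = "")
      out[[length(out) + 1L]] <<- data.frame(
        kind = kind, pos1 = a - 1L, pos2 = b - 1L, length = len,
        sequence = rep_seq,
        low_complexity = length(unique(s[a:(a + len - 1L)])) <= 2L,
        stringsAsFactors = FALSE)
    }

    if ("direct" %in% kinds) {
      for (pos in buckets) {
        if (length(pos) < 2L) next
        for (ii in 1:(length(pos) - 1L)) for (jj in (ii + 1L):length(pos)) {
          a <- pos[ii]; b <- pos[jj]; len <- k
          # extend left
          while (a > 1L && b > 1L && s[a - 1L] == s[b - 1L]) {
            a <- a - 1L; b <- b - 1L; len <- len + 1L
          }
          # extend right
          while (a + len <= n && b + len <= n && s[a + len] == s[b + len]) {
            len <- len + 1L
          }
          if (a != b) add_hit("direct", a, b, len)
        }
      }
    }

    if ("palindromic" %in% kinds) {
      rc_kmers <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(kmers)))
      for (i in seq_along(kmers)) {
        partners <- buckets[[rc_kmers[i]]]
        if (is.null(partners)) next
        for (b0 in partners) {
          if (b0 < i) next   # symmetric relation: count each pair once
          a <- i; b <- b0; len <- k
          # grow the pattern front: s[a-1] must pair with s[b+len]
          while (a > 1L && b + len <= n && s[b + len] == comp_vec(s[a - 1L])) {
            a <- a - 1L; len <- len + 1L
          }
          # grow the pattern back: s[a+len] must pair with s[b-1]
          while (b > 1L && a + len <= n && s[b - 1L] == comp_vec(s[a + len])) {
            b <- b - 1L; len <- len + 1L
          }
          p1 <- min(a, b); p2 <- max(a, b)
          add_hit("palindromic", p1, p2, len)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(kind = character(), pos1 = integer(), pos2 = integer(),
                      length = integer(), sequence = character(),
                      low_complexity = logical(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  df <- df[!duplicated(df[, c("kind", "pos1", "pos2", "length")]), , drop = FALSE]
  df <- df[order(df$pos1, df$pos2, df$kind), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write repeat hits as TSV
#' @param repeats data.frame from [find_repeats()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_repeats_tsv <- function(repeats, path) {
  utils::write.table(repeats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
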