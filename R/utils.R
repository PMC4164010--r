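# Internal helpers shared across modules. All genomic coordinates inside the
# package are 0-based half-open on the forward strand; converters to the
# 1-based inclusive conventions of GenBank/PTT/TSV live at the I/O boundary.

# condition constructors so the CLI can map error kinds to exit codes
err_input <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("archori_input_error", "error", "condition")))
}

err_usage <- function(msg) {
  stop(errorCondition(msg, class = c("archori_usage_error", "error", "condition")))
}

#' Reverse complement of a nucleotide string
#'
#' Handles the full IUPAC alphabet; case is upper-cased first.
#'
#' @param x single character string of nucleotides.
#' @return the reverse complement as a character string.
#' @export
rev_comp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- toupper(x)
  comp <- chartr("ACGTMRWSYKVHDBN", "TGCAKYWSRMBDHVN", x)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

# complement of a character vector of single bases
comp_vec <- function(v) chartr("ACGTMRWSYKVHDBN", "TGCAKYWSRMBDHVN", v)

# Extract [start, end) from a circular sequence; end may exceed nchar(seq),
# in which case the subsequence wraps past the coordinate origin.
circ_subseq <- function(seq, start0, end0) {
  n <- nchar(seq)
  stopifnot(start0 >= 0, start0 < n, end0 >= start0, end0 - start0 <= n)
  if (end0 <= n) {
    substr(seq, start0 + 1L, end0)
  } else {
    paste0(substr(seq, start0 + 1L, n), substr(seq, 1L, end0 - n))
  }
}

# signed circular distance from a to b on a circle of size n, in (-n/2, n/2]
circ_signed_dist <- function(from, to, n) {
  d <- (to - from) %% n
  ifelse(d > n / 2, d - n, d)
}

# fraction of A+T among A,C,G,T characters of a sequence (ambiguity codes
# excluded from the denominator); NA for a sequence with no unambiguous base
at_content <- function(seq) {
  v <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  acgt <- v %in% c("A", "C", "G", "T")
  if (!any(acgt)) return(NA_real_)
  sum(v %in% c("A", "T")) / sum(acgt)
}
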