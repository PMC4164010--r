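# gene_roles: classify gene products into replication-related roles. The
# adjacency rule of the predictor keys on these roles: archaeal origins sit
# next to the genes for Orc1/Cdc6 initiators, Whip and DNA primase.

ROLE_PRIORITY <- c("orc1_cdc6", "whip", "primase", "other_replication")

#' Default replication-role keyword table
#'
#' Case-insensitive substrings matched against gene product annotations.
#' Covers the gene families typically flanking archaeal origins (Orc1/Cdc6
#' initiators, the Whip winged-helix initiator, DNA primase) plus
#' conservative extensions for other replication machinery. The table is a
#' deliberate sensitivity knob: extend it via a plain-text config (one
#' `role<TAB>keyword` per line, see [read_role_table()]).
#'
#' @return data.frame with columns `role`, `keyword`.
#' @export
default_role_keywords <- function() {
  if (is.null(.role_cache$df)) {
    .role_cache$df <- read_role_table(system.file(
      "extdata", "replication_roles.tsv", package = "archori", mustWork = TRUE))
  }
  .role_cache$df
}

.role_cache <- new.env(parent = emptyenv())

#' Read a role keyword table
#'
#' Plain-text config: one `role<TAB>keyword` pair per line; `#` comments and
#' blank lines ignored. Roles must be among `orc1_cdc6`, `whip`, `primase`,
#' `other_replication`; no keyword may appear under two roles.
#'
#' @param path path to the table.
#' @return data.frame with columns `role`, `keyword`.
#' @export
read_role_table <- function(path) {
  if (!file.exists(path)) err_input(sprintf("cannot read role table: %s", path))
  lines <- readLines(path, warn = FALSE)
  # keywords may legitimately end in a space ("orc " avoids matching inside
  # longer words), so lines are not trimmed; comments/blank detected trimmed
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L)) err_input("role table rows must be role<TAB>keyword")
  df <- data.frame(role = vapply(parts, `[`, "", 1L),
                   keyword = tolower(vapply(parts, `[`, "", 2L)),
                   stringsAsFactors = FALSE)
  bad <- setdiff(df$role, ROLE_PRIORITY)
  if (length(bad)) err_input(sprintf("unknown role(s) in table: %s",
                                     paste(bad, collapse = ", ")))
  if (anyDuplicated(df$keyword))
    err_input("a keyword appears under two roles in the role table")
  if (!all(ROLE_PRIORITY %in% df$role) && nrow(df) == 0L)
    err_input("empty role table")
  df
}

#' Classify a gene product string
#'
#' Case-insensitive substring match of the product annotation against the
#' role keyword table, resolved in priority order
#' `orc1_cdc6 > whip > primase > other_replication`; `"none"` when no
#' keyword matches.
#'
#' @param product product annotation text (vectorized; empty strings allowed).
#' @param role_table keyword table (default [default_role_keywords()]).
#' @return character vector of roles.
#' @export
classify_gene <- function(product, role_table = default_role_keywords()) {
  p <- tolower(product)
  out <- rep("none", length(p))
  for (role in rev(intersect(ROLE_PRIORITY, unique(role_table$role)))) {
    kws <- role_table$keyword[role_table$role == role]
    hit <- Reduce(`|`, lapply(kws, function(k) grepl(k, p, fixed = TRUE)))
    out[hit] <- role
  }
  out
}

#' Fill the role column of a genome's gene table
#'
#' Pure and idempotent: every `genes$role` entry is recomputed from the
#' product string.
#'
#' @param genome an [annotated_genome].
#' @param role_table keyword table (default [default_role_keywords()]).
#' @param verbose log the replication-related gene count (default FALSE).
#' @return the genome with `genes$role` filled.
#' @export
annotate_roles <- function(genome, role_table = default_role_keywords(),
                           verbose = FALSE) {
  if (nrow(genome$genes)) {
    genome$genes$role <- classify_gene(genome$genes$product, role_table)
  }
  if (verbose) {
    k <- sum(genome$genes$role != "none")
    message(sprintf("%d replication-related gene(s) of %d annotated", k,
                    nrow(genome$genes)))
  }
  genome
}
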