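# genome_io: read annotated genomes (GenBank flat file, or FASTA + NCBI PTT
# protein table), normalize coordinates, and extract intergenic regions on a
# circular chromosome.

#' Construct an annotated genome object
#'
#' The central container of the package: a (usually circular) nucleotide
#' sequence plus a table of annotated genes. Gene coordinates are 0-based
#' half-open on the forward strand; a gene spanning the coordinate origin of a
#' circular chromosome has `end > genome length` (its length is still
#' `end - start`).
#'
#' @param accession accession or locus name.
#' @param sequence nucleotide string (IUPAC codes allowed); upper-cased.
#' @param genes data.frame with columns `id`, `start`, `end`, `strand`
#'   (`"+"`/`"-"`), `product`; a `role` column is added (filled with
#'   `"none"`) if absent. Rows are sorted by `start`.
#' @param circular logical; is the chromosome circular?
#' @param taxonomy character vector of lineage strings (may be empty).
#' @return object of class `annotated_genome`: a list with elements
#'   `accession`, `sequence`, `circular`, `genes`, `taxonomy`.
#' @export
annotated_genome <- function(accession, sequence, genes, circular = TRUE,
                             taxonomy = character()) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n == 0L) err_input("genome sequence is empty")
  if (is.null(genes$role)) genes$role <- "none"
  genes <- genes[, c("id", "start", "end", "strand", "product", "role")]
  if (nrow(genes) > 0) {
    stopifnot(all(genes$start >= 0), all(genes$start < n),
              all(genes$end > genes$start),
              all(genes$strand %in% c("+", "-")))
    genes <- genes[order(genes$start, genes$end), , drop = FALSE]
    rownames(genes) <- NULL
  }
  structure(list(accession = accession, sequence = sequence,
                 circular = isTRUE(circular), genes = genes,
                 taxonomy = taxonomy),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  gc <- {
    v <- strsplit(x$sequence, "", fixed = TRUE)[[1]]
    sum(v %in% c("G", "C")) / max(1L, sum(v %in% c("A", "C", "G", "T")))
  }
  cat(sprintf("annotated_genome %s: %d bp (%s), %d genes, GC %.1f%%\n",
              x$accession, nchar(x$sequence),
              if (x$circular) "circular" else "linear",
              nrow(x$genes), 100 * gc))
  invisible(x)
}

#' Genome length in bp
#' @param genome an `annotated_genome`.
#' @return integer length.
#' @export
genome_length <- function(genome) nchar(genome$sequence)

empty_gene_df <- function() {
  data.frame(id = character(), start = integer(), end = integer(),
             strand = character(), product = character(),
             role = character(), stringsAsFactors = FALSE)
}

# ---- GenBank flat file -----------------------------------------------------

# Parse a GenBank location string into (start0, end0, strand) in 0-based
# half-open coordinates; returns NULL for locations it cannot represent.
# join(a..n, 1..b) across the origin of a circular molecule becomes a wrap
# gene with end0 = b + n.
parse_gb_location <- function(loc, seq_len) {
  loc <- gsub("[<>[:space:]]", "", loc)
  strand <- "+"
  if (grepl("^complement\\(.*\\)$", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  m <- regmatches(loc, regexec("^(\\d+)\\.\\.(\\d+)$", loc))[[1]]
  if (length(m) == 3L) {
    a <- as.integer(m[2]); b <- as.integer(m[3])
    if (a < 1 || b < a) return(NULL)
    return(list(start = a - 1L, end = b, strand = strand))
  }
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(inner, ",", fixed = TRUE)[[1]]
    pm <- lapply(parts, function(p)
      regmatches(p, regexec("^(\\d+)\\.\\.(\\d+)$", p))[[1]])
    if (any(lengths(pm) != 3L)) return(NULL)
    ab <- do.call(rbind, lapply(pm, function(v) as.integer(v[2:3])))
    if (nrow(ab) == 2L && ab[1, 2] == seq_len && ab[2, 1] == 1L) {
      # wrap across the coordinate origin
      return(list(start = ab[1, 1] - 1L, end = ab[2, 2] + seq_len,
                  strand = strand))
    }
    # contiguous ascending join: collapse to its span
    if (all(diff(as.vector(t(ab))) >= 0)) {
      return(list(start = ab[1, 1] - 1L, end = ab[nrow(ab), 2],
                  strand = strand))
    }
    return(NULL)
  }
  NULL
}

#' Read a single-record GenBank flat file
#'
#' Parses the LOCUS topology, ACCESSION, ORGANISM lineage, gene features and
#' ORIGIN sequence of one GenBank record. CDS features (and, by default,
#' tRNA/rRNA/ncRNA/tmRNA features) become gene records; 1-based inclusive
#' GenBank locations are converted to 0-based half-open coordinates, with
#' `join()` across the origin of a circular molecule handled as a wrapping
#' gene. Features whose locations cannot be parsed are skipped with a warning.
#'
#' @param path path to the GenBank file.
#' @param include_rna also treat annotated RNA genes as genes (default TRUE).
#' @return an [annotated_genome].
#' @export
read_genbank <- function(path, include_rna = TRUE) {
  if (!file.exists(path)) err_input(sprintf("cannot read GenBank file: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) err_input("empty GenBank file")

  locus <- grep("^LOCUS", lines, value = TRUE)
  circular <- if (length(locus)) !grepl("linear", locus[1], ignore.case = TRUE) else TRUE
  accession <- NA_character_
  acc_line <- grep("^ACCESSION", lines, value = TRUE)
  if (length(acc_line)) {
    accession <- strsplit(trimws(sub("^ACCESSION", "", acc_line[1])), "\\s+")[[1]][1]
  }
  if (is.na(accession) || !nzchar(accession)) {
    accession <- if (length(locus)) strsplit(trimws(sub("^LOCUS", "", locus[1])), "\\s+")[[1]][1] else "unknown"
  }

  # ORGANISM lineage: indented continuation lines up to the next keyword
  taxonomy <- character()
  oi <- grep("^  ORGANISM", lines)
  if (length(oi)) {
    j <- oi[1] + 1L
    tax_lines <- character()
    while (j <= length(lines) && grepl("^\\s{4,}", lines[j])) {
      tax_lines <- c(tax_lines, trimws(lines[j]))
      j <- j + 1L
    }
    taxonomy <- trimws(strsplit(sub("\\.$", "", paste(tax_lines, collapse = " ")), ";")[[1]])
    taxonomy <- taxonomy[nzchar(taxonomy)]
  }

  # ORIGIN sequence
  ori <- grep("^ORIGIN", lines)
  if (length(ori) == 0L) err_input("GenBank record has no ORIGIN sequence")
  end_rec <- grep("^//", lines)
  end_rec <- if (length(end_rec)) end_rec[end_rec > ori[1]][1] else length(lines) + 1L
  seq_lines <- lines[seq.int(ori[1] + 1L,
                             length.out = max(0L, end_rec - ori[1] - 1L))]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) == 0L) err_input("GenBank record has no sequence")

  # FEATURES table
  fi <- grep("^FEATURES", lines)
  genes <- empty_gene_df()
  if (length(fi)) {
    feat_lines <- lines[(fi[1] + 1L):(ori[1] - 1L)]
    keep_types <- c("CDS", if (include_rna) c("tRNA", "rRNA", "ncRNA", "tmRNA"))
    # feature starts: key at column 6
    starts <- grep("^ {5}\\S", feat_lines)
    n_feat <- length(starts)
    recs <- list()
    for (k in seq_len(n_feat)) {
      block <- feat_lines[starts[k]:(if (k < n_feat) starts[k + 1] - 1L else length(feat_lines))]
      key <- sub("^\\s*(\\S+).*$", "\\1", block[1])
      if (!key %in% keep_types) next
      # location may continue over lines until the first qualifier
      loc <- trimws(sub("^\\s*\\S+\\s*", "", block[1]))
      i <- 2L
      while (i <= length(block) && !grepl("^\\s*/", block[i])) {
        loc <- paste0(loc, trimws(block[i])); i <- i + 1L
      }
      parsed <- parse_gb_location(loc, nchar(sequence))
      if (is.null(parsed)) {
        warning(sprintf("skipping %s feature with unparseable location: %s", key, loc))
        next
      }
      quals <- parse_gb_qualifiers(block[seq.int(i, length.out = max(0L, length(block) - i + 1L))])
      id <- quals[["locus_tag"]] %||% quals[["gene"]] %||% sprintf("feature_%d", k)
      recs[[length(recs) + 1L]] <- data.frame(
        id = id, start = parsed$start, end = parsed$end, strand = parsed$strand,
        product = quals[["product"]] %||% "", role = "none",
        stringsAsFactors = FALSE)
    }
    if (length(recs)) genes <- do.call(rbind, recs)
  }
  annotated_genome(accession, sequence, genes, circular = circular,
                   taxonomy = taxonomy)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# qualifier lines -> named list; quoted values may span lines
parse_gb_qualifiers <- function(lines) {
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (startsWith(ln, "/")) {
      eq <- regexpr("=", ln, fixed = TRUE)
      if (eq > 0) {
        name <- substr(ln, 2L, eq - 1L)
        val <- substr(ln, eq + 1L, nchar(ln))
        if (startsWith(val, "\"") && !(nchar(val) > 1L && endsWith(val, "\""))) {
          while (i + 1L <= length(lines) && !startsWith(trimws(lines[i + 1L]), "/")) {
            i <- i + 1L
            val <- paste(val, trimws(lines[i]))
          }
        }
        out[[name]] <- gsub("\"", "", val)
      } else {
        out[[substring(ln, 2L)]] <- TRUE
      }
    }
    i <- i + 1L
  }
  out
}

# ---- FASTA + PTT -----------------------------------------------------------

#' Read a genome from FASTA plus an NCBI protein table (PTT)
#'
#' The PTT layout is the legacy NCBI tab-separated protein table: two header
#' lines, a column-header line, then one row per protein with columns
#' Location ("a..b", 1-based inclusive), Strand, Length, PID, Gene, Synonym,
#' Code, COG, Product. A Location with `b < a` is interpreted as a gene
#' wrapping the origin of the circular chromosome. Malformed rows are skipped
#' with a warning.
#'
#' @param fasta path to a single-record nucleotide FASTA.
#' @param ptt path to the PTT file.
#' @param circular logical; topology is not recorded in FASTA/PTT (default
#'   TRUE, the archaeal chromosome norm).
#' @return an [annotated_genome] with empty taxonomy.
#' @export
read_fasta_ptt <- function(fasta, ptt, circular = TRUE) {
  if (!file.exists(fasta)) err_input(sprintf("cannot read FASTA file: %s", fasta))
  if (!file.exists(ptt)) err_input(sprintf("cannot read PTT file: %s", ptt))
  ss <- Biostrings::readDNAStringSet(fasta)
  if (length(ss) != 1L) err_input("FASTA must contain exactly one record")
  sequence <- as.character(ss[[1]])
  n <- nchar(sequence)
  accession <- strsplit(names(ss)[1], "\\s+")[[1]][1]

  lines <- readLines(ptt, warn = FALSE)
  if (length(lines) < 4L) err_input("PTT file has no data rows")
  body <- lines[-(1:3)]
  body <- body[nzchar(trimws(body))]
  recs <- list()
  for (k in seq_along(body)) {
    f <- strsplit(body[k], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L) { warning(sprintf("skipping short PTT row %d", k)); next }
    m <- regmatches(f[1], regexec("^(\\d+)\\.\\.(\\d+)$", trimws(f[1])))[[1]]
    if (length(m) != 3L) { warning(sprintf("skipping PTT row %d with malformed Location '%s'", k, f[1])); next }
    a <- as.integer(m[2]); b <- as.integer(m[3])
    start0 <- a - 1L
    end0 <- if (b >= a) b else b + n   # wrap gene
    if (start0 < 0 || start0 >= n) { warning(sprintf("skipping PTT row %d out of range", k)); next }
    syn <- trimws(f[6]); gene <- trimws(f[5])
    id <- if (nzchar(syn) && syn != "-") syn else if (nzchar(gene) && gene != "-") gene else sprintf("protein_%d", k)
    recs[[length(recs) + 1L]] <- data.frame(
      id = id, start = start0, end = end0, strand = trimws(f[2]),
      product = trimws(f[9]), role = "none", stringsAsFactors = FALSE)
  }
  if (!length(recs)) err_input("no parsable rows in PTT file")
  annotated_genome(accession, sequence, do.call(rbind, recs),
                   circular = circular, taxonomy = character())
}

# ---- writers (used by the synthetic generator and the CLI) -----------------

#' Write a genome as a minimal GenBank flat file
#' @param genome an [annotated_genome].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_genbank <- function(genome, path) {
  n <- genome_length(genome)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("LOCUS       %-16s %d bp    DNA     %s     UNA 01-JAN-2026",
                     genome$accession, n,
                     if (genome$circular) "circular" else "linear"), con)
  writeLines(sprintf("DEFINITION  %s.", genome$accession), con)
  writeLines(sprintf("ACCESSION   %s", genome$accession), con)
  if (length(genome$taxonomy)) {
    writeLines("SOURCE      synthetic construct", con)
    writeLines("  ORGANISM  synthetic construct", con)
    writeLines(strwrap(paste0(paste(genome$taxonomy, collapse = "; "), "."),
                       width = 67, initial = "            ",
                       prefix = "            "), con)
  }
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", n), con)
  g <- genome$genes
  for (i in seq_len(nrow(g))) {
    a <- g$start[i] + 1L; b <- g$end[i]
    loc <- if (b <= n) sprintf("%d..%d", a, b)
           else sprintf("join(%d..%d,1..%d)", a, n, b - n)
    if (g$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     CDS             %s", loc), con)
    writeLines(sprintf("                     /locus_tag=\"%s\"", g$id[i]), con)
    writeLines(sprintf("                     /product=\"%s\"", g$product[i]), con)
  }
  writeLines("ORIGIN", con)
  s <- tolower(genome$sequence)
  pos <- seq(1L, n, by = 60L)
  for (p in pos) {
    chunk <- substr(s, p, min(p + 59L, n))
    tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
                      pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", p, paste(tens, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Write a genome sequence as FASTA
#' @param genome an [annotated_genome].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$sequence)
  names(ss) <- genome$accession
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Write gene annotations as an NCBI PTT protein table
#' @param genome an [annotated_genome].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_ptt <- function(genome, path) {
  n <- genome_length(genome)
  g <- genome$genes
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("%s - 1..%d", genome$accession, n), con)
  writeLines(sprintf("%d proteins", nrow(g)), con)
  writeLines("Location\tStrand\tLength\tPID\tGene\tSynonym\tCode\tCOG\tProduct", con)
  for (i in seq_len(nrow(g))) {
    a <- g$start[i] + 1L
    b <- if (g$end[i] <= n) g$end[i] else g$end[i] - n   # wrap gene: b < a
    len_aa <- (g$end[i] - g$start[i]) %/% 3L - 1L
    writeLines(sprintf("%d..%d\t%s\t%d\t-\t-\t%s\t-\t-\t%s",
                       a, b, g$strand[i], max(len_aa, 1L), g$id[i],
                       g$product[i]), con)
  }
  invisible(path)
}

# ---- intergenic extraction -------------------------------------------------

#' Extract intergenic regions of a circular chromosome
#'
#' Overlapping or nested gene spans are merged into covered blocks first; the
#' maximal gaps between consecutive blocks (including the wrap-around gap on a
#' circular chromosome) are returned, each with its flanking genes. With
#' `min_len = 0` the gaps and the merged gene blocks tile the chromosome
#' exactly once.
#'
#' @param genome an [annotated_genome] with at least one gene.
#' @param min_len minimum region length in bp to report (default 50; an ORB
#'   motif is about 17-21 bp).
#' @return data.frame with columns `start`, `end` (0-based half-open, `end`
#'   may exceed the genome length for the wrap-around gap), `length`,
#'   `sequence`, `left_gene`, `right_gene` (ids of the flanking genes), and
#'   `left_index`, `right_index` (row indices into `genome$genes`).
#' @export
extract_intergenic <- function(genome, min_len = 50L) {
  g <- genome$genes
  if (nrow(g) == 0L) err_usage("genome has no annotated genes")
  n <- genome_length(genome)

  # unroll wrap genes into linear pieces, remembering the owning gene row
  pieces <- list()
  for (i in seq_len(nrow(g))) {
    s <- g$start[i]; e <- g$end[i]
    if (e <= n) {
      pieces[[length(pieces) + 1L]] <- c(s, e, i)
    } else {
      pieces[[length(pieces) + 1L]] <- c(s, n, i)
      pieces[[length(pieces) + 1L]] <- c(0L, e - n, i)
    }
  }
  p <- do.call(rbind, pieces)
  p <- p[order(p[, 1], p[, 2]), , drop = FALSE]

  # merge into covered blocks on [0, n)
  blocks <- list()
  cur <- p[1, 1:2]
  if (nrow(p) > 1) for (i in 2:nrow(p)) {
    if (p[i, 1] <= cur[2]) {
      cur[2] <- max(cur[2], p[i, 2])
    } else {
      blocks[[length(blocks) + 1L]] <- cur
      cur <- p[i, 1:2]
    }
  }
  blocks[[length(blocks) + 1L]] <- cur
  b <- do.call(rbind, blocks)
  nb <- nrow(b)

  if (genome$circular && nb == 1 && b[1, 1] == 0L && b[1, 2] == n) {
    return(empty_intergenic_df())   # fully covered
  }
  # circular closure: a block starting at 0 and a block ending at n are one
  # covered block crossing the coordinate origin
  if (genome$circular && nb > 1 && b[1, 1] == 0L && b[nb, 2] == n) {
    b[nb, 2] <- b[1, 2] + n
    b <- b[-1, , drop = FALSE]
    nb <- nb - 1L
  }

  # gaps between consecutive blocks (circularly for circular chromosomes)
  regions <- list()
  for (i in seq_len(nb)) {
    if (i < nb) {
      gap_start <- b[i, 2]; gap_end <- b[i + 1, 1]
    } else if (genome$circular) {
      gap_start <- b[nb, 2] %% n
      gap_end <- b[1, 1] %% n
      if (gap_end <= gap_start) gap_end <- gap_end + n
      if (gap_end - gap_start >= n || b[nb, 2] - b[1, 1] >= n) next
      # the wrap gap degenerates when block nb already abuts block 1
      if ((b[nb, 2] - b[1, 1]) %% n == 0L) next
    } else {
      if (b[nb, 2] < n)
        regions[[length(regions) + 1L]] <- c(b[nb, 2], n)
      break
    }
    if (gap_end > gap_start)
      regions[[length(regions) + 1L]] <- c(gap_start, gap_end)
  }
  if (!length(regions)) return(empty_intergenic_df())

  r <- do.call(rbind, regions)
  # flanking genes: the gene whose end (mod n) equals the gap start, and the
  # gene whose start (mod n) equals the gap end
  out <- lapply(seq_len(nrow(r)), function(i) {
    gs <- r[i, 1]; ge <- r[i, 2]
    li <- which(g$end %% n == gs %% n)
    ri <- which(g$start %% n == ge %% n)
    li <- if (length(li)) li[which.max(g$end[li])] else NA_integer_
    ri <- if (length(ri)) ri[which.min(g$start[ri])] else NA_integer_
    data.frame(start = gs, end = ge, length = ge - gs,
               sequence = circ_subseq(genome$sequence, gs %% n, gs %% n + (ge - gs)),
               left_gene = if (!is.na(li)) g$id[li] else NA_character_,
               right_gene = if (!is.na(ri)) g$id[ri] else NA_character_,
               left_index = li, right_index = ri,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[out$length >= min_len, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_intergenic_df <- function() {
  data.frame(start = integer(), end = integer(), length = integer(),
             sequence = character(), left_gene = character(),
             right_gene = character(), left_index = integer(),
             right_index = integer(), stringsAsFactors = FALSE)
}
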