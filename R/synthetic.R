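# synthetic_fixtures: seeded toy archaeal genomes with known ground truth.
# The generator emulates the origin features the predictor keys on: a
# two-replichore base-composition skew switching sign at a planted origin
# (and at the antipodal terminus), protein-coding genes tiled with intergenic
# gaps, an Orc1/Cdc6-like product on an origin-flanking gene, and ORB
# consensus instances planted in chosen intergenic regions. It does not
# attempt codon usage, operon structure or phylogenetic realism.

#' Specification of a toy genome
#'
#' Defaults describe the standard validation condition: a 100 kb circular
#' chromosome, composition skew 0.08 switching at the origin, genes of
#' 900 bp separated by 150 bp gaps, a 500 bp intergenic origin region whose
#' left flanking gene is an orc1/cdc6 initiator, and one Common-motif ORB
#' consensus planted in the origin region.
#'
#' @param length chromosome length in bp.
#' @param origin_position planted origin (bp); default `length %/% 3`.
#' @param skew_strength per-base excess of G over C (and A over T) on the
#'   arm ascending into the origin, in `[0, 0.25]`.
#' @param gene_length,gap_length gene/intergenic tiling sizes in bp.
#' @param origin_gap length of the intergenic origin region in bp.
#' @param planted_motifs list of `list(motif =, region =, copies =)` entries;
#'   `region` is `"origin"` or a 1-based index among the non-origin gaps in
#'   tiling order; `motif` names an entry of [builtin_motifs()].
#' @param planted_role_products list of `list(gene =, product =)` entries;
#'   `gene` is `"origin_left"`, `"origin_right"` or a gene row index.
#' @param seed integer RNG seed; all randomness flows from it.
#' @param accession accession string for the emitted genome.
#' @return a list of class `toy_genome_spec`.
#' @export
toy_genome_spec <- function(length = 100000L, origin_position = NULL,
                            skew_strength = 0.08, gene_length = 900L,
                            gap_length = 150L, origin_gap = 500L,
                            planted_motifs = list(
                              list(motif = "Common", region = "origin",
                                   copies = 1L)),
                            planted_role_products = list(
                              list(gene = "origin_left",
                                   product = "orc1/cdc6 replication initiation protein")),
                            seed = 1L, accession = "TOY0001") {
  length <- as.integer(length)
  if (is.null(origin_position)) origin_position <- length %/% 3L
  stopifnot(length > 0L, origin_position >= 0L, origin_position < length,
            skew_strength >= 0, skew_strength <= 0.25,
            gene_length > 0L, gap_length > 0L, origin_gap > 0L)
  structure(list(length = length,
                 origin_position = as.integer(origin_position),
                 skew_strength = skew_strength,
                 gene_length = as.integer(gene_length),
                 gap_length = as.integer(gap_length),
                 origin_gap = as.integer(origin_gap),
                 planted_motifs = planted_motifs,
                 planted_role_products = planted_role_products,
                 seed = as.integer(seed), accession = accession),
            class = "toy_genome_spec")
}

#' Generate a toy genome with ground truth
#'
#' Draws the sequence under the two-replichore composition model — on the
#' arm running (in increasing coordinate) from the terminus to the origin,
#' `P(G) = P(A) = 0.25 + skew_strength` and `P(C) = P(T) = 0.25 -
#' skew_strength`, mirrored on the other arm, so the cumulative GC and AT
#' disparities peak at the origin and trough at the terminus — then tiles
#' genes around the chromosome leaving the origin region intergenic, plants
#' the requested ORB consensus copies and role products, and returns the
#' annotated genome plus ground truth. Fully reproducible from the seed (the
#' caller's RNG state is restored on exit).
#'
#' @param spec a [toy_genome_spec()].
#' @return list of class `toy_ground_truth`: `genome` (an
#'   [annotated_genome]), `true_origin_interval` (data.frame `start`, `end`),
#'   `planted_hit_positions` (integer vector of 0-based genomic starts of
#'   planted motif copies), `terminus_position`, and `spec`.
#' @export
make_toy_genome <- function(spec) {
  stopifnot(inherits(spec, "toy_genome_spec"))
  n <- spec$length; o <- spec$origin_position; s <- spec$skew_strength
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old_seed, envir = .GlobalEnv), add = TRUE)
  }
  set.seed(spec$seed)

  ter <- (o + n %/% 2L) %% n
  # arm1 = circular [ter, o): G/A-rich so both disparities ascend into the
  # origin; arm2 = [o, ter): C/T-rich
  arm1_len <- (o - ter) %% n
  arm2_len <- n - arm1_len
  p1 <- c(0.25 + s, 0.25 - s, 0.25 + s, 0.25 - s)  # A, C, G, T
  p2 <- c(0.25 - s, 0.25 + s, 0.25 - s, 0.25 + s)
  b1 <- sample(BASES, arm1_len, replace = TRUE, prob = p1)
  b2 <- sample(BASES, arm2_len, replace = TRUE, prob = p2)
  seqv <- character(n)
  idx1 <- (seq_len(arm1_len) - 1L + ter) %% n + 1L
  idx2 <- (seq_len(arm2_len) - 1L + o) %% n + 1L
  seqv[idx1] <- b1
  seqv[idx2] <- b2

  # gene tiling: the origin gap is [o - og/2, o - og/2 + og); genes of
  # gene_length bp separated by gap_length bp run from its end around the
  # chromosome; the last gap before the origin gap absorbs the remainder
  og <- spec$origin_gap
  gap0_start <- (o - og %/% 2L) %% n
  gap0_end <- gap0_start + og             # may exceed n (wrap)
  avail <- n - og
  # k genes with k-1 interior gaps fill the rest of the circle, so a gene
  # abuts the origin gap on both sides; the remainder widens the last
  # interior gap (or the single gene when k == 1)
  k <- (avail + spec$gap_length) %/% (spec$gene_length + spec$gap_length)
  if (k < 1L) err_usage("toy genome too short for one gene")
  rem <- avail - (k * spec$gene_length + (k - 1L) * spec$gap_length)
  gene_lens <- rep(spec$gene_length, k)
  gap_lens <- rep(spec$gap_length, length.out = max(0L, k - 1L))
  if (k == 1L) gene_lens[1] <- avail else gap_lens[k - 1L] <- gap_lens[k - 1L] + rem

  cursor <- gap0_end %% n
  genes <- vector("list", k); gaps <- vector("list", max(0L, k - 1L))
  for (i in seq_len(k)) {
    genes[[i]] <- c(cursor, cursor + gene_lens[i])
    cursor <- (cursor + gene_lens[i]) %% n
    if (i < k) {
      gaps[[i]] <- c(cursor, cursor + gap_lens[i])
      cursor <- (cursor + gap_lens[i]) %% n
    }
  }
  stopifnot(cursor == gap0_start)
  gdf <- data.frame(
    id = sprintf("TOY_%04d", seq_along(genes)),
    start = vapply(genes, `[`, 0, 1L),
    end = vapply(genes, `[`, 0, 2L),     # wrap genes keep end = start + len
    strand = rep(c("+", "-"), length.out = length(genes)),
    product = "hypothetical protein", role = "none",
    stringsAsFactors = FALSE)

  # resolve planted role products
  for (pr in spec$planted_role_products) {
    gidx <- if (identical(pr$gene, "origin_left")) {
      which(gdf$end %% n == gap0_start)[1]
    } else if (identical(pr$gene, "origin_right")) {
      which(gdf$start == gap0_end %% n)[1]
    } else as.integer(pr$gene)
    if (is.na(gidx) || gidx < 1L || gidx > nrow(gdf))
      err_usage("planted role product: gene not resolvable")
    gdf$product[gidx] <- pr$product
  }

  # plant motif consensus copies in the requested gaps
  motifs <- builtin_motifs()
  gap_bounds <- function(region) {
    if (identical(region, "origin")) c(gap0_start, gap0_end)
    else {
      ri <- as.integer(region)
      if (is.na(ri) || ri < 1L || ri > length(gaps))
        err_usage("planted motif: no such intergenic region")
      gaps[[ri]]
    }
  }
  planted_positions <- integer()
  for (pm in spec$planted_motifs) {
    m <- motifs[[pm$motif]]
    if (is.null(m)) err_usage(sprintf("unknown motif '%s'", pm$motif))
    copies <- as.integer(pm$copies %||% 1L)
    inst <- consensus_top_string(m)
    spacer <- 3L
    total <- copies * m$width + (copies - 1L) * spacer
    gb <- gap_bounds(pm$region)
    gap_len <- gb[2] - gb[1]
    if (total > gap_len)
      err_usage("planted motifs do not fit inside the target intergenic region")
    at <- gb[1] + (gap_len - total) %/% 2L
    for (cc in seq_len(copies)) {
      pos0 <- (at + (cc - 1L) * (m$width + spacer)) %% n
      ii <- ((pos0 + seq_len(m$width) - 1L) %% n) + 1L
      seqv[ii] <- strsplit(inst, "", fixed = TRUE)[[1]]
      planted_positions <- c(planted_positions, pos0)
    }
  }

  genome <- annotated_genome(spec$accession, paste(seqv, collapse = ""), gdf,
                             circular = TRUE, taxonomy = character())
  structure(list(genome = genome,
                 true_origin_interval = data.frame(start = gap0_start,
                                                   end = gap0_end),
                 planted_hit_positions = planted_positions,
                 terminus_position = ter,
                 spec = spec),
            class = "toy_ground_truth")
}

# the maximum-probability string of a motif (first listed base per position
# has equal share; take it for determinism)
consensus_top_string <- function(motif) {
  tokens <- parse_consensus(motif$consensus)
  paste(vapply(tokens, `[`, character(1), 1L), collapse = "")
}

#' @export
print.toy_ground_truth <- function(x, ...) {
  cat(sprintf("toy_ground_truth: %d bp, origin at %d (region %d-%d), %d genes, %d planted motif copies\n",
              genome_length(x$genome), x$spec$origin_position,
              x$true_origin_interval$start, x$true_origin_interval$end,
              nrow(x$genome$genes), length(x$planted_hit_positions)))
  invisible(x)
}

#' Write toy genome files to disk
#'
#' Emits `<prefix>.gbk`, `<prefix>.fna`, `<prefix>.ptt` and
#' `<prefix>.truth.tsv` (1-based inclusive origin interval plus planted
#' motif positions).
#'
#' @param truth a `toy_ground_truth` from [make_toy_genome()].
#' @param prefix output path prefix.
#' @return invisibly, the vector of paths written.
#' @export
write_toy_files <- function(truth, prefix) {
  paths <- c(gbk = paste0(prefix, ".gbk"), fna = paste0(prefix, ".fna"),
             ptt = paste0(prefix, ".ptt"),
             truth = paste0(prefix, ".truth.tsv"))
  write_genbank(truth$genome, paths["gbk"])
  write_fasta(truth$genome, paths["fna"])
  write_ptt(truth$genome, paths["ptt"])
  df <- data.frame(key = c("origin_start_1based", "origin_end_1based",
                           "terminus_position_1based",
                           rep("planted_motif_start_1based",
                               length(truth$planted_hit_positions))),
                   value = c(truth$true_origin_interval$start + 1L,
                             truth$true_origin_interval$end,
                             truth$terminus_position + 1L,
                             truth$planted_hit_positions + 1L))
  utils::write.table(df, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
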