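# predictor: apply the origin decision rules to intergenic regions and
# evaluate predictions against a reference interval set.
#
# Rule A (gene_adjacent_orb): an intergenic region flanked by at least one
#   replication-related gene and containing >= 1 ORB hit at p <= cutoff.
# Rule B (multi_motif): an intergenic region containing >= 3 ORB hits,
#   regardless of flanking genes (catches origins next to unrecognized
#   replication genes).
# Z-curve extremum proximity, AT content and repeats are reported as
# evidence, never used as filters.

#' Predict replication origin regions
#'
#' Runs the full decision procedure: intergenic extraction, taxonomy-matched
#' ORB motif scanning with exact p-values, the two decision rules, and the
#' evidence bundle (AT content, repeats, signed distance from the region
#' midpoint to the nearest global extremum of each disparity curve). A region
#' satisfying both rules is reported once under `gene_adjacent_orb`.
#'
#' @param genome an [annotated_genome] with at least one gene. Roles are
#'   (re)annotated from `role_table` unless already present and
#'   `reannotate = FALSE`.
#' @param motifs list of `motif_model`s, or `NULL` to select by taxonomy
#'   via [select_motifs()] (no lineage match: Common motif only).
#' @param p_cutoff FIMO-style p-value cutoff for ORB hits (default `1e-4`).
#' @param min_intergenic minimum intergenic region length in bp (default 50).
#' @param rule_b_min motif hits required for the multi-motif rule (default 3,
#'   i.e. "more than two conserved motifs").
#' @param adjacency how many genes on each side count as "adjacent"
#'   (default 1: the two immediately flanking genes).
#' @param role_table replication-role keyword table.
#' @param repeat_min_len minimal repeat length annotated per region
#'   (default 8); `NA` disables repeat annotation.
#' @param reannotate recompute gene roles (default TRUE).
#' @return object of class `oric_predictions`: a data.frame with one row per
#'   predicted region — columns `start`, `end` (0-based half-open; `end` may
#'   wrap past the genome length), `length`, `rule`, `motif_count`,
#'   `adjacent_gene`, `adjacent_role`, `at_content`, `dist_at`, `dist_gc`,
#'   `dist_ry`, `dist_mk` (signed bp from region midpoint to the nearest
#'   global extremum of each disparity curve) — with list columns `orb_hits`
#'   and `repeats` carrying the per-region evidence tables.
#' @export
predict_oric <- function(genome, motifs = NULL, p_cutoff = 1e-4,
                         min_intergenic = 50L, rule_b_min = 3L,
                         adjacency = 1L, role_table = default_role_keywords(),
                         repeat_min_len = 8L, reannotate = TRUE) {
  if (!(p_cutoff > 0 && p_cutoff < 1)) err_usage("p_cutoff must be in (0, 1)")
  if (min_intergenic < 0 || rule_b_min < 1 || adjacency < 1)
    err_usage("thresholds must be positive")
  if (nrow(genome$genes) == 0L)
    err_usage("genome has no annotated genes; annotation is required")
  if (reannotate) genome <- annotate_roles(genome, role_table)

  n <- genome_length(genome)
  regions <- extract_intergenic(genome, min_len = min_intergenic)
  if (is.null(motifs)) motifs <- select_motifs(genome)
  pv_cache <- lapply(motifs, cached_pvalue_table)
  names(pv_cache) <- vapply(motifs, function(m) m$name, character(1))

  profile <- compute_zcurve(genome$sequence)
  ext <- lapply(c(at = "at", gc = "gc", ry = "ry", mk = "mk"), function(k)
    find_extrema(profile, k, local = FALSE))

  preds <- list()
  for (i in seq_len(nrow(regions))) {
    reg <- regions[i, ]
    hits <- scan_motif_set(motifs, reg$sequence, p_cutoff = p_cutoff,
                           offset = reg$start, genome_size = n,
                           pv_cache = pv_cache)
    mc <- nrow(hits)
    adj <- adjacent_genes(genome, reg, adjacency)
    rep_flank <- adj$role[adj$role != "none"]
    rule <- if (mc >= 1L && length(rep_flank)) "gene_adjacent_orb"
            else if (mc >= rule_b_min) "multi_motif"
            else NA_character_
    if (is.na(rule)) next
    mid <- (reg$start + reg$length / 2) %% n
    dists <- vapply(ext, function(e) {
      if (e$flat) return(NA_real_)
      d <- circ_signed_dist(mid, c(e$max_position, e$min_position), n)
      d[which.min(abs(d))]
    }, numeric(1))
    reps <- if (is.na(repeat_min_len)) NULL
            else find_repeats(reg$sequence, min_len = repeat_min_len)
    preds[[length(preds) + 1L]] <- list(
      row = data.frame(
        start = reg$start, end = reg$end, length = reg$length, rule = rule,
        motif_count = mc,
        adjacent_gene = paste(adj$id, collapse = ","),
        adjacent_role = paste(adj$role, collapse = ","),
        at_content = at_content(reg$sequence),
        dist_at = dists[["at"]], dist_gc = dists[["gc"]],
        dist_ry = dists[["ry"]], dist_mk = dists[["mk"]],
        stringsAsFactors = FALSE),
      orb_hits = hits, repeats = reps)
  }

  if (!length(preds)) {
    df <- data.frame(start = integer(), end = integer(), length = integer(),
                     rule = character(), motif_count = integer(),
                     adjacent_gene = character(), adjacent_role = character(),
                     at_content = numeric(), dist_at = numeric(),
                     dist_gc = numeric(), dist_ry = numeric(),
                     dist_mk = numeric(), stringsAsFactors = FALSE)
    df$orb_hits <- list(); df$repeats <- list()
  } else {
    df <- do.call(rbind, lapply(preds, `[[`, "row"))
    df <- df[order(df$start), , drop = FALSE]
    ord <- order(vapply(preds, function(p) p$row$start, numeric(1)))
    df$orb_hits <- I(lapply(preds[ord], `[[`, "orb_hits"))
    df$repeats <- I(lapply(preds[ord], `[[`, "repeats"))
    rownames(df) <- NULL
  }
  structure(df, class = c("oric_predictions", "data.frame"),
            accession = genome$accession, genome_length = n)
}

# the k nearest genes on each side of an intergenic region (circular order)
adjacent_genes <- function(genome, region, k = 1L) {
  g <- genome$genes
  ng <- nrow(g)
  li <- region$left_index; ri <- region$right_index
  if (is.na(li) || is.na(ri)) {
    # fall back to nearest by circular distance
    n <- genome_length(genome)
    d <- abs(circ_signed_dist(g$start, region$start %% n, n))
    li <- ri <- which.min(d)
  }
  idx <- unique(c(vapply(seq_len(k), function(j) ((li - 1L - (j - 1L)) %% ng) + 1L, integer(1)),
                  vapply(seq_len(k), function(j) ((ri - 1L + (j - 1L)) %% ng) + 1L, integer(1))))
  g[idx, c("id", "role", "product"), drop = FALSE]
}

#' @export
print.oric_predictions <- function(x, ...) {
  cat(sprintf("oric_predictions: %d predicted origin region(s) on %s (%d bp)\n",
              nrow(x), attr(x, "accession") %||% "?",
              attr(x, "genome_length") %||% NA))
  if (nrow(x)) {
    print.data.frame(x[, c("start", "end", "length", "rule", "motif_count",
                           "adjacent_role")])
  }
  invisible(x)
}

# ---- evaluation ------------------------------------------------------------

#' Build an evaluation result from counts
#'
#' Sensitivity = TP / reference count; precision = TP / predicted count.
#' Precision is `NA` (flagged) when nothing was predicted.
#'
#' @param true_positives number of reference origins recovered.
#' @param reference_count number of reference origins.
#' @param predicted_count number of predictions.
#' @return object of class `evaluation_result`: list with the three counts,
#'   `sensitivity`, `precision` and `precision_defined`.
#' @export
evaluation_result <- function(true_positives, reference_count,
                              predicted_count) {
  if (reference_count < 1) err_usage("sensitivity undefined: empty reference")
  stopifnot(true_positives >= 0, true_positives <= reference_count,
            true_positives <= max(predicted_count, true_positives))
  structure(list(
    true_positives = true_positives,
    reference_count = reference_count,
    predicted_count = predicted_count,
    sensitivity = true_positives / reference_count,
    precision = if (predicted_count > 0) true_positives / predicted_count else NA_real_,
    precision_defined = predicted_count > 0),
    class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("evaluation: TP %d / reference %d / predicted %d\n",
              x$true_positives, x$reference_count, x$predicted_count))
  cat(sprintf("sensitivity %.1f%%, precision %s\n", 100 * x$sensitivity,
              if (x$precision_defined) sprintf("%.1f%%", 100 * x$precision)
              else "undefined (no predictions)"))
  invisible(x)
}

#' Evaluate predictions against a reference origin set
#'
#' A reference interval counts as recovered when a prediction overlaps it by
#' at least one bp (default rule) or when the prediction midpoint falls
#' inside it (`match_rule = "midpoint"`). Matching is one-to-one: pairs are
#' assigned greedily by decreasing overlap length, so each prediction
#' recovers at most one reference and vice versa. Wrapping intervals
#' (`end > genome_length`) are split at the coordinate origin before overlap
#' computation.
#'
#' @param predictions an `oric_predictions` object or any data.frame with
#'   `start`/`end` columns (0-based half-open).
#' @param reference data.frame with `start`/`end` columns (0-based
#'   half-open), e.g. from [read_reference()].
#' @param match_rule `"overlap"` or `"midpoint"`.
#' @param genome_size circumference for splitting wrapped intervals; taken
#'   from the predictions object when available.
#' @return an [evaluation_result()].
#' @export
evaluate_predictions <- function(predictions, reference,
                                 match_rule = c("overlap", "midpoint"),
                                 genome_size = NULL) {
  match_rule <- match.arg(match_rule)
  if (is.null(genome_size)) genome_size <- attr(predictions, "genome_length")
  if (nrow(reference) == 0L) err_usage("sensitivity undefined: empty reference")
  npred <- nrow(predictions)
  if (npred == 0L) return(evaluation_result(0L, nrow(reference), 0L))

  split_circ <- function(df) {
    # returns IRanges plus the owning row index, splitting wrapped intervals
    rows <- integer(); starts <- integer(); ends <- integer()
    for (i in seq_len(nrow(df))) {
      s <- df$start[i]; e <- df$end[i]
      if (!is.null(genome_size) && e > genome_size) {
        rows <- c(rows, i, i); starts <- c(starts, s, 0L)
        ends <- c(ends, genome_size, e - genome_size)
      } else {
        rows <- c(rows, i); starts <- c(starts, s); ends <- c(ends, e)
      }
    }
    list(ir = IRanges::IRanges(start = starts + 1L, end = ends), row = rows)
  }
  p <- split_circ(predictions)
  r <- split_circ(reference)

  if (match_rule == "midpoint") {
    mids <- floor((predictions$start + predictions$end) / 2)
    if (!is.null(genome_size)) mids <- mids %% genome_size
    p <- list(ir = IRanges::IRanges(start = mids + 1L, width = 1L),
              row = seq_len(npred))
  }
  ov <- IRanges::findOverlaps(p$ir, r$ir)
  if (length(ov) == 0L) return(evaluation_result(0L, nrow(reference), npred))
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  w <- IRanges::width(IRanges::pintersect(p$ir[qh], r$ir[sh]))
  pairs <- data.frame(pred = p$row[qh], ref = r$row[sh], w = w)
  # same pred/ref pair may appear twice through circular splitting
  pairs <- stats::aggregate(w ~ pred + ref, data = pairs, FUN = sum)
  pairs <- pairs[order(-pairs$w, pairs$pred, pairs$ref), , drop = FALSE]
  used_p <- logical(npred); used_r <- logical(nrow(reference))
  tp <- 0L
  for (i in seq_len(nrow(pairs))) {
    pi <- pairs$pred[i]; ri <- pairs$ref[i]
    if (used_p[pi] || used_r[ri]) next
    used_p[pi] <- TRUE; used_r[ri] <- TRUE
    tp <- tp + 1L
  }
  evaluation_result(tp, nrow(reference), npred)
}

#' Read a reference origin interval set
#'
#' BED (0-based half-open, first three columns used) or a 2-column TSV of
#' 1-based inclusive `start`, `end` intervals; both are converted to the
#' package's 0-based half-open convention.
#'
#' @param path input path.
#' @param format `"bed"` or `"tsv"`; default guessed from the extension
#'   (`.bed` vs anything else).
#' @return data.frame with columns `start`, `end`.
#' @export
read_reference <- function(path, format = NULL) {
  if (!file.exists(path)) err_input(sprintf("cannot read reference: %s", path))
  if (is.null(format)) {
    format <- if (tolower(tools::file_ext(path)) == "bed") "bed" else "tsv"
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (format == "bed") {
    out <- data.frame(start = as.integer(df[[2]]), end = as.integer(df[[3]]))
  } else {
    first <- suppressWarnings(as.integer(df[[1]][1]))
    if (is.na(first)) df <- df[-1, , drop = FALSE]   # tolerate a header line
    out <- data.frame(start = as.integer(df[[1]]) - 1L,
                      end = as.integer(df[[2]]))
  }
  if (nrow(out) == 0L || anyNA(out)) err_input("no parsable reference intervals")
  out
}

# ---- prediction output formats --------------------------------------------

#' Write predictions as TSV, BED or GFF3
#'
#' TSV columns: accession, start_1based, end_1based, length, rule,
#' motif_count, adjacent_gene, adjacent_role, at_content,
#' nearest_extremum_bp (the smallest-magnitude disparity-extremum distance).
#' BED is 0-based half-open. GFF3 emits one `replication_origin` feature per
#' prediction with child `sequence_feature` rows for its ORB hits.
#'
#' @param predictions an `oric_predictions` object.
#' @param path output path.
#' @param format one of `"tsv"`, `"bed"`, `"gff3"`.
#' @return invisibly, `path`.
#' @export
write_predictions <- function(predictions, path,
                              format = c("tsv", "bed", "gff3")) {
  format <- match.arg(format)
  acc <- attr(predictions, "accession") %||% "genome"
  n <- attr(predictions, "genome_length")
  x <- as.data.frame(predictions)
  if (format == "tsv") {
    nearest <- apply(x[, c("dist_at", "dist_gc", "dist_ry", "dist_mk"), drop = FALSE],
                     1, function(v) if (all(is.na(v))) NA_real_ else v[which.min(abs(v))])
    df <- data.frame(accession = rep(acc, nrow(x)),
                     start_1based = x$start + 1L, end_1based = x$end,
                     length = x$length, rule = x$rule,
                     motif_count = x$motif_count,
                     adjacent_gene = x$adjacent_gene,
                     adjacent_role = x$adjacent_role,
                     at_content = round(x$at_content, 4),
                     nearest_extremum_bp = if (nrow(x)) nearest else numeric(0))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (format == "bed") {
    df <- data.frame(chrom = rep(acc, nrow(x)), start = x$start, end = x$end,
                     name = sprintf("oriC_%d", seq_len(nrow(x))),
                     score = 0L,
                     strand = rep(".", nrow(x)))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines("##gff-version 3", con)
    for (i in seq_len(nrow(x))) {
      oid <- sprintf("oriC_%d", i)
      writeLines(sprintf("%s\tarchori\treplication_origin\t%d\t%d\t.\t.\t.\tID=%s;rule=%s;motif_count=%d",
                         acc, x$start[i] + 1L, x$end[i], oid, x$rule[i],
                         x$motif_count[i]), con)
      hits <- predictions$orb_hits[[i]]
      for (j in seq_len(NROW(hits))) {
        w <- nchar(hits$matched_sequence[j])
        writeLines(sprintf("%s\tarchori\tsequence_feature\t%d\t%d\t%.3f\t%s\t.\tID=%s.orb%d;Parent=%s;motif=%s;pvalue=%.3g",
                           acc, hits$genome_position[j] + 1L,
                           hits$genome_position[j] + w,
                           hits$score[j], hits$strand[j], oid, j, oid,
                           hits$motif_name[j], hits$p_value[j]), con)
      }
    }
  }
  invisible(path)
}
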