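# cli_report: the end-to-end pipeline behind the command-line interface.
# read -> annotate roles -> Z-curve -> intergenic extraction -> motif scan ->
# repeats -> predict; artifacts (TSV/BED/GFF3, curve table, optional plot,
# summary block) land in an output directory.

#' Run the full origin-prediction pipeline
#'
#' Reads an annotated genome (GenBank, or FASTA + PTT), annotates
#' replication roles, predicts origin regions, and writes the result
#' artifacts: `predictions.tsv` / `.bed` / `.gff3`, `orb_hits.tsv`,
#' `repeats.tsv`, `zcurve.tsv`, a plain-text `summary.txt` (genome size, GC
#' content, replication-gene locations, predictions and every threshold
#' used), and optionally `curves.png`. When a reference interval set is
#' given, sensitivity/precision are computed and included in the summary.
#'
#' @param genbank path to a GenBank file (or `NULL`).
#' @param fasta,ptt paths to a FASTA + PTT pair (used when `genbank` is
#'   `NULL`).
#' @param out_dir output directory (created if missing).
#' @param p_cutoff,min_intergenic,rule_b_min,adjacency see [predict_oric()].
#' @param role_table path to a role keyword table, or `NULL` for the default.
#' @param motif_set character vector of motif names to force (overrides
#'   taxonomy selection), or `NULL`.
#' @param reference path to a reference interval set (BED or TSV), or `NULL`.
#' @param plot also write `curves.png` (default FALSE).
#' @param zcurve_step thinning step for `zcurve.tsv` (`NULL`: about 10k rows).
#' @param verbose log progress messages.
#' @return invisibly, a list with `genome`, `predictions`, and `evaluation`
#'   (`NULL` without a reference).
#' @export
run_pipeline <- function(genbank = NULL, fasta = NULL, ptt = NULL,
                         out_dir = ".", p_cutoff = 1e-4,
                         min_intergenic = 50L, rule_b_min = 3L,
                         adjacency = 1L, role_table = NULL, motif_set = NULL,
                         reference = NULL, plot = FALSE, zcurve_step = NULL,
                         verbose = TRUE) {
  if (!(p_cutoff > 0 && p_cutoff < 1)) err_usage("p_cutoff must be in (0, 1)")
  if (is.null(genbank) && (is.null(fasta) || is.null(ptt)))
    err_usage("provide either a GenBank file or a FASTA + PTT pair")
  say <- function(...) if (verbose) message(sprintf(...))

  genome <- if (!is.null(genbank)) read_genbank(genbank)
            else read_fasta_ptt(fasta, ptt)
  say("read %s: %d bp, %d genes", genome$accession, genome_length(genome),
      nrow(genome$genes))

  rt <- if (is.null(role_table)) default_role_keywords()
        else read_role_table(role_table)
  genome <- annotate_roles(genome, rt)

  motifs <- if (is.null(motif_set)) select_motifs(genome) else {
    all <- builtin_motifs()
    missing <- setdiff(motif_set, names(all))
    if (length(missing))
      err_usage(sprintf("unknown motif(s): %s", paste(missing, collapse = ", ")))
    all[motif_set]
  }
  say("motif set: %s", paste(names(motifs), collapse = ", "))

  preds <- predict_oric(genome, motifs = motifs, p_cutoff = p_cutoff,
                        min_intergenic = min_intergenic,
                        rule_b_min = rule_b_min, adjacency = adjacency,
                        role_table = rt, reannotate = FALSE)
  say("%d origin region(s) predicted", nrow(preds))

  evaluation <- NULL
  if (!is.null(reference)) {
    evaluation <- evaluate_predictions(preds, read_reference(reference))
  }

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_predictions(preds, file.path(out_dir, "predictions.tsv"), "tsv")
  write_predictions(preds, file.path(out_dir, "predictions.bed"), "bed")
  write_predictions(preds, file.path(out_dir, "predictions.gff3"), "gff3")
  all_hits <- do.call(rbind, preds$orb_hits)
  if (is.null(all_hits)) all_hits <- empty_hits_df()
  write_hits(all_hits, file.path(out_dir, "orb_hits.tsv"), "tsv")
  all_reps <- do.call(rbind, preds$repeats)
  if (is.null(all_reps)) all_reps <- find_repeats("", min_len = 8L)
  write_repeats_tsv(all_reps, file.path(out_dir, "repeats.tsv"))
  profile <- compute_zcurve(genome$sequence)
  if (is.null(zcurve_step))
    zcurve_step <- max(1L, genome_length(genome) %/% 10000L)
  write_zcurve_tsv(profile, file.path(out_dir, "zcurve.tsv"),
                   step = zcurve_step)
  if (plot) plot_disparity_curves(genome, preds,
                                  file = file.path(out_dir, "curves.png"))
  write_summary(genome, preds, evaluation,
                list(p_cutoff = p_cutoff, min_intergenic = min_intergenic,
                     rule_b_min = rule_b_min, adjacency = adjacency,
                     motif_set = paste(names(motifs), collapse = ",")),
                file.path(out_dir, "summary.txt"))
  say("artifacts written to %s", out_dir)
  invisible(list(genome = genome, predictions = preds,
                 evaluation = evaluation))
}

write_summary <- function(genome, preds, evaluation, config, path) {
  con <- file(path, "w"); on.exit(close(con))
  v <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]
  gc <- sum(v %in% c("G", "C")) / max(1L, sum(v %in% c("A", "C", "G", "T")))
  writeLines(c(
    sprintf("accession\t%s", genome$accession),
    sprintf("genome_size_bp\t%d", genome_length(genome)),
    sprintf("gc_content\t%.4f", gc),
    sprintf("genes\t%d", nrow(genome$genes)),
    sprintf("replication_related_genes\t%d",
            sum(genome$genes$role != "none"))), con)
  rep_genes <- genome$genes[genome$genes$role != "none", , drop = FALSE]
  for (i in seq_len(nrow(rep_genes)))
    writeLines(sprintf("replication_gene\t%s\t%d\t%d\t%s\t%s",
                       rep_genes$id[i], rep_genes$start[i] + 1L,
                       rep_genes$end[i], rep_genes$role[i],
                       rep_genes$product[i]), con)
  for (nm in names(config))
    writeLines(sprintf("config_%s\t%s", nm, config[[nm]]), con)
  writeLines(sprintf("predicted_oriCs\t%d", nrow(preds)), con)
  for (i in seq_len(nrow(preds)))
    writeLines(sprintf("oriC\t%d\t%d\t%s\t%d", preds$start[i] + 1L,
                       preds$end[i], preds$rule[i], preds$motif_count[i]), con)
  if (!is.null(evaluation)) {
    writeLines(sprintf("sensitivity\t%.4f", evaluation$sensitivity), con)
    writeLines(sprintf("precision\t%s",
                       if (evaluation$precision_defined)
                         sprintf("%.4f", evaluation$precision) else "NA"), con)
  }
  invisible(path)
}

#' The bundled archaeal benchmark count table
#'
#' Per-chromosome origin counts for 13 annotated archaeal chromosomes whose
#' origins are recorded in DoriC: reference origin count, predicted origin
#' count and true positives. The totals (27 reference, 29 predicted, 18
#' true positives) drive the benchmark sensitivity/precision arithmetic.
#'
#' @return data.frame with columns `organism`, `refseq`, `reference_oriCs`,
#'   `predicted_oriCs`, `true_positives`.
#' @export
archaea_benchmark <- function() {
  utils::read.table(system.file("extdata", "archaea_benchmark.tsv",
                                package = "archori", mustWork = TRUE),
                    sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    comment.char = "#")
}
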