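# archori

Prediction of replication origins (oriCs) in archaeal genomes.

Archaeal chromosomes replicate from origins that share three sequence-level
signatures: they are intergenic and adjacent to replication-initiator genes
(Orc1/Cdc6, Whip, DNA primase); they carry conserved origin recognition
boxes (ORBs), the binding sites of the Orc1/Cdc6 proteins; and they sit
where the mirrored composition bias of the two replichores switches sign,
i.e. near the extrema of cumulative nucleotide disparity curves. archori is
for microbial genomics researchers who have an annotated archaeal genome
(GenBank, or FASTA plus an NCBI PTT protein table) and want origin
candidates with the evidence laid out.

## Method in brief

* **Z-curve analysis.** Cumulative components x (R−Y), y (M−K), z (W−S)
  and the disparity curves AT = (x+y)/2 = #A−#T and GC = (x−y)/2 = #G−#C,
  with extremum location and rotation of the genome to the GC-disparity
  maximum.
* **ORB motif scanning.** Eleven built-in ORB consensus motifs organized
  by taxonomic cluster plus a Common motif; position-specific scoring
  matrices derived from the consensus patterns; log-likelihood-ratio
  scores in bits with *exact* p-values from a dynamic program over a
  discretized score lattice; scan cutoff p ≤ 1e-4 on both strands.
* **Decision rules.** Rule A: an intergenic region flanked by a
  replication-related gene and containing ≥1 ORB hit. Rule B: any
  intergenic region containing ≥3 ORB hits. Each prediction carries its
  evidence bundle: ORB hits, flanking genes and roles, AT content, exact
  direct/palindromic repeats, and signed distances to the disparity-curve
  extrema (evidence only, never filters).
* **Evaluation.** Sensitivity = TP/reference and precision = TP/predicted
  under one-to-one greedy ≥1 bp overlap matching against a reference
  interval set.
* **Synthetic genomes.** A seeded generator plants an origin (two-replichore
  skew switch, orc1/cdc6-flanked intergenic region, verbatim ORB instances)
  so the whole pipeline is testable without downloads.

## Worked example

```r
library(archori)

truth <- make_toy_genome(toy_genome_spec(seed = 7L))   # 100 kb toy genome
genome <- annotate_roles(truth$genome)
preds <- predict_oric(genome)
print(preds)
#> oric_predictions: 1 predicted origin region(s) on TOY0001 (100000 bp)
#>   start   end length              rule motif_count  adjacent_role
#> 1 33083 33583    500 gene_adjacent_orb           1 orc1_cdc6,none

preds$orb_hits[[1]]
#>   motif_name region_offset genome_position strand    score      p_value     matched_sequence
#> 1     Common           240           33323      + 35.59313 1.455192e-11 TCCACTTGAAATGAAGGGGT

evaluate_predictions(preds, truth$true_origin_interval)
#> evaluation: TP 1 / reference 1 / predicted 1
#> sensitivity 100.0%, precision 100.0%
```

One region is predicted, spanning positions 33083–33583 (0-based half-open):
the planted origin. It fired the gene-adjacent rule — its left flanking gene
is the planted orc1/cdc6 initiator — on the strength of one Common-motif ORB
hit at 35.6 bits (p ≈ 1.5e-11, far below the 1e-4 cutoff). The GC-disparity
global maximum lands at 33342 bp, 9 bp from the planted origin at 33333.
Real genomes run the same way from files:

```r
res <- run_pipeline(genbank = "genome.gbk", out_dir = "out",
                    reference = "known_origins.bed")
```

which writes `predictions.tsv`/`.bed`/`.gff3`, `orb_hits.tsv`,
`repeats.tsv`, `zcurve.tsv` and a `summary.txt`. The same pipeline is
scriptable from a shell:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","archori.R",package="archori"))')" \
    predict --genbank genome.gbk --out out
```

with subcommands `predict`, `simulate`, `evaluate`, `zcurve` and `scan`.

## Layout

```
R/                      implementation (genome I/O, zcurve, motifs,
                        roles, repeats, predictor, synthetic, pipeline)
inst/cli/archori.R      command-line interface
inst/extdata/           role keyword table, benchmark count table
tests/testthat/         unit, property and acceptance tests with
                        independent oracles
vignettes/              methods vignette (model, parameters, design notes)
scripts/acceptance.R    headline-number reproduction script
```
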