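---
title: "Predicting archaeal replication origins: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting archaeal replication origins: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(archori)
```

## The prediction problem

Archaeal chromosomes are usually circular and replicate from one or a few
origins (oriCs). Three sequence-level signatures mark these loci. First,
replication imposes mirrored mutational pressure on the two replichores, so
cumulative base-composition curves change slope at the origin and the
terminus. Second, origins sit in intergenic regions next to the genes for
replication-initiation proteins, above all the Orc1/Cdc6 initiator family,
plus Whip (winged-helix initiator protein) and DNA primase. Third, origins
carry origin recognition boxes (ORBs) — conserved elements of roughly 15–21
bp bound by Orc1/Cdc6 — often with G-stretches at their ends, embedded in an
AT-rich duplex-unwinding context. archori integrates the three signals and
reports, per genome, the intergenic regions that behave like origins.

## Z-curve disparity analysis

A sequence is mapped to three cumulative components over prefix lengths
$0..n$: $x$ counts purines minus pyrimidines (R−Y), $y$ amino minus keto
bases (M−K), and $z$ weak minus strong hydrogen bonding (W−S). Per base the
increments for $(x, y, z)$ are A: $(+1,+1,+1)$, G: $(+1,-1,-1)$, C:
$(-1,+1,-1)$, T: $(-1,-1,+1)$; ambiguity codes contribute nothing. Two
linear combinations are the workhorses:

$$\mathrm{AT}_n = \frac{x_n + y_n}{2} = \#A - \#T, \qquad
  \mathrm{GC}_n = \frac{x_n - y_n}{2} = \#G - \#C .$$

Replichore asymmetry makes these curves ramp up on one arm and down on the
other, so origins lie near curve extrema. The convention used throughout is
that the GC disparity attains its global *maximum* at the origin-proximal
switch point; `rotate_to_gc_max()` rotates a circular genome so that this
maximum maps to position 0, which is how the curves are conventionally
displayed. One reading note: the z component is described in parts of the
literature with the order "S vs. W"; archori fixes the canonical sign
$z = (A+T) - (G+C)$. The choice is cosmetic here because the predictor never
consumes $z$ — extremum distances are reported for the AT/GC/RY/MK curves
only, and only as evidence.

Numerical choices: disparities are half-integers and exactly representable
in doubles, so no scaled integer storage is needed beyond using exact
increments. Extremum ties break to the smallest coordinate for determinism.
Smoothing defaults to none below 1 Mb (cumulative curves are already
integrals and stable) and to a window of $n/1000$ above. The local-extrema
list is computed on a curve downsampled to about 5000 points with a
prominence cut of 10% of the curve range; global extrema are always exact.

## ORB motifs, scoring and exact p-values

The built-in motif set holds the eleven ORB consensus patterns organized by
taxonomic cluster (Halobacteriaceae, Methanobacteriaceae, Methanomicrobia,
Methanococcaceae, three Sulfolobaceae motifs, three Thermococcaceae motifs)
plus a cluster-independent Common motif of width 20. The patterns are
degenerate consensus strings; the position-specific probability matrices the
original server used are not published, so archori derives a PSPM from each
pattern: at every position the unlisted bases receive a pseudo-probability
of $\varepsilon = 0.005$ each and the listed alternatives share the
remainder uniformly. This is a declared approximation — it preserves the
consensus and its degeneracy structure but not the original per-position
frequencies.

A window $w$ of motif width is scored by the log-likelihood ratio in bits,
$S(w) = \sum_i \log_2 \left( p_i(w_i) / b(w_i) \right)$, against a
background $b$ (uniform by default; deterministic and corpus-free, with a
genome-composition option). Windows containing a non-ACGT base are skipped
whole rather than part-scored. The p-value of a score is exact: the null
distribution of $S$ for a random background string is computed by dynamic
programming over positions on a score lattice with 1/1000-bit bins, giving
$P(S \ge s)$ for every attainable score; the tail is non-increasing and
equals 1 at the minimum attainable score. Because each position is rounded
to the lattice before summation, a real-valued score can drift from its
lattice point by up to `width` bins; the lookup snaps scores within that
slack to the nearest attainable lattice value, so window scores map to
exactly the DP tail. The scan cutoff defaults to $p \le 10^{-4}$, the
conventional motif-occurrence threshold. Both strands are scanned; minus
strand hits are reported at their forward-strand footprint with the matched
sequence in motif orientation. Overlapping hits are all kept — merging is a
prediction-level concern, and the decision rules only count hits.

Motif selection for a genome matches its taxonomy lineage against the
cluster names, and the Common motif is always active; with no lineage
information (e.g. FASTA+PTT input) the Common motif alone is used. Whether
the original system restricted scans to the matched cluster is not
documented; including Common always is the more sensitive default and can be
overridden with an explicit motif set.

## Gene roles and the decision rules

Gene products are classified into roles by case-insensitive substring
matching against a keyword table (priority orc1_cdc6 > whip > primase >
other_replication). The shipped table covers only the families named in the
archaeal origin literature plus conservative extensions (MCM, replication
factor/protein); the complete list of genes any given annotation pipeline
labels as replication-related is unknowable in advance, so the table is a
plain-text config and an explicit sensitivity knob.

Intergenic regions are the maximal gaps between merged annotated gene spans
on the circular chromosome, including the wrap-around gap; RNA genes count
as genes by default (configurable). Regions shorter than 50 bp are dropped
by default — an ORB alone is ~17–21 bp; the threshold is configurable.
Internally all coordinates are 0-based half-open on the forward strand,
which keeps circular arithmetic unambiguous; GenBank/PTT/TSV writers and
readers convert at the boundary, and a feature spanning the coordinate
origin is held as `end > genome length`.

Two rules fire, in line with the origin biology above:

* **Rule A (gene_adjacent_orb)** — the region's flanking genes (the two
  immediate neighbours by default; widenable to ±k) include at least one
  replication role, and the region contains ≥1 ORB hit at the p cutoff.
* **Rule B (multi_motif)** — the region contains ≥3 ORB hits regardless of
  its neighbours, catching origins next to unrecognized replication genes.
  The threshold reads "more than two conserved motifs" as ≥3 hits across
  the active motif set, not necessarily distinct motifs, consistent with
  known multi-ORB origins found this way.

A region satisfying both is reported once, under Rule A. Z-curve extremum
proximity, AT content and repeats are attached as evidence but are *not*
filters: the decision workflow gates only on genes and ORBs, and the curves
provide context. This matters for interpreting precision — extremum
distance is available for post-hoc ranking, and making it a hard filter
would change the operating point.

Exact repeats (direct and reverse-complement palindromic, min length 8 bp
by default) are annotated per region by seed-and-extend over k-mer buckets
with maximality trimming; regions are short, so a quadratic-oracle-checked
simple algorithm is preferred over suffix structures. Low-complexity
repeats (≤2 distinct bases) are flagged rather than removed, because
G-stretches at ORB ends are real origin features.

## Evaluation

`evaluate_predictions()` compares predictions with a reference interval
set: a reference is recovered when a prediction overlaps it by ≥1 bp
(default) or contains its midpoint (option). Matching is one-to-one and
greedy by overlap length, so a long prediction cannot recover two reference
origins, and sensitivity = TP / reference, precision = TP / predicted.
The ≥1 bp criterion is a choice, not an established standard — published
benchmark comparisons rarely state their TP rule — hence both rules are
provided and the default documented. On the bundled 13-chromosome archaeal
benchmark count table the totals (18 TP, 27 reference, 29 predicted) give
sensitivity 66.7% and precision 62.1%.

## The synthetic genome generator

`make_toy_genome()` builds the validation substrate: a circular chromosome
whose base composition follows the two-replichore model — on the arm
ascending into the origin $P(G) = P(A) = 0.25 + s$ and
$P(C) = P(T) = 0.25 - s$, mirrored on the other arm — so the GC and AT
disparities peak at the planted origin and trough at the antipodal
terminus. Genes tile the rest of the chromosome and a dedicated intergenic
origin region keeps the planted locus gene-free; the requested ORB
consensus copies are written in verbatim (the maximum-probability string,
which is guaranteed to pass the $10^{-4}$ scan cutoff) and initiator
products are assigned to chosen genes. Everything derives from one seed and
the caller's RNG state is restored.

Default study condition: 100 kb, skew strength 0.08, 900 bp genes with
150 bp gaps, a 500 bp origin region whose left flanking gene is an
orc1/cdc6 initiator, one Common-motif copy planted in the origin region.
The skew is at the strong end of what real archaeal replichores show, and
the gene density (~85% coding) is typical for archaea. With these settings
a 100-genome panel is recovered completely by Rule A, with GC-extremum
localization well inside ±2 kb — distances of a few tens of bp are typical,
since at skew 0.08 the drift dominates the random-walk noise.

What the generator does *not* emulate bounds what passing tests show:
real genomes have heterogeneous skew (strand-biased gene content, recent
inversions), origins with degenerate ORB variants rather than consensus
instances, multiple origins per chromosome, and annotation noise in product
strings. Recovery on toy genomes therefore validates the machinery —
coordinates, scanning, rules, evaluation — not field performance, which the
benchmark table summarizes independently. One formal note: with skew 0 the
generator draws i.i.d. uniform bases, so disparity curves are unbiased
random walks, not flat lines; the degenerate "flat" flag of
`find_extrema()` applies to genuinely constant curves (e.g. all-N input).

## Degenerate inputs and tie-breaks

Empty sequence yields the single-zero profile; all-ambiguous sequences give
flat curves flagged as such; regions shorter than a motif scan to nothing;
a genome whose genes cover every base has no intergenic regions and hence
no predictions; evaluation against an empty reference is an error
(sensitivity undefined), while zero predictions give sensitivity 0 and a
flagged undefined precision. Extremum and hit ordering ties resolve to the
smallest coordinate.

## Problem sizes and runtime

The validation suite uses 100 toy genomes of 100 kb for origin recovery,
20–30 kb genomes for round-trip and rule tests, exhaustive enumeration over
all $4^6$ windows for the p-value oracle at width 6, and 1000 random
sequences for the Z-curve identity suite. These sizes keep the whole suite
in the minutes range on one core while leaving each check statistically
meaningful; all are set in code, not tuned to hardware.

## Known limitations

* PSPMs are consensus-derived, not the original frequency matrices; scores
  and p-values are comparable in structure but not numerically identical to
  a FIMO run with the historical matrices.
* The role keyword table is intentionally minimal; genomes whose initiators
  are annotated under other names need a custom table.
* Genomes with many origins are under-called by construction (Rule A needs
  a recognized neighbour; Rule B needs three hits).
* Linear chromosomes are handled for extraction and scanning but rotation
  is undefined for them.
* Multi-record GenBank/EMBL files, GFF3 input and gene prediction for
  unannotated sequences are out of scope; annotation is a required input.
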