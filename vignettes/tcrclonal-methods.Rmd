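---
title: "Models and methods behind tcrclonal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tcrclonal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrclonal)
library(dplyr)
```

tcrclonal analyses plate-based single-cell paired TCRαβ amplicon data:
one tetramer-sorted CD4⁺ T cell per well of a 96-well plate, multiplex
PCR amplicons (~240–300 nt) covering the V(D)J region including the
CDR3 plus a 25-marker phenotyping panel, pooled and deep-sequenced with
plate–row–column barcodes. This vignette documents the models, the
tunable parameters and their defaults, the numerical choices, and what
the synthetic-data tests do and do not demonstrate.

## The consensus-calling model

Wells receive reads by exact barcode-triplet match; no barcode error
correction is attempted (8-nt barcodes in this design are mutually
distant, and keeping demultiplexing trivial isolates the consensus logic
from barcode repair). Within a well, reads are clustered greedily: the
most abundant unique sequence founds a cluster and sweeps in every read
within the identity radius; the remainder repeats the procedure.

* **Identity metric.** Global pairwise alignment identity =
  matches / alignment columns, with match +2, mismatch −3, linear gap
  −5. The clustering threshold is 0.95. Amplicons from the same primer
  pair have nearly equal lengths, so for equal-length pairs the optimal
  alignment under this scoring is the diagonal and identity reduces to
  1 − Hamming/length; the implementation uses that fast path and full
  alignment otherwise.
* **Consensus.** Per-column majority over a star alignment of members to
  the cluster centroid; insertions relative to the centroid are dropped
  and ties resolve to the centroid base (then alphabetically), making
  the consensus deterministic.
* **Chain thresholds.** The supporting-read fractions are computed over
  *chain-assigned* reads (β fraction over β reads, α over α reads), and
  the thresholds are strict: β assigned iff its top cluster exceeds 80%,
  dominant α iff it exceeds 30%, alternative α iff the second α cluster
  exceeds 10%. Whether the original percentages were taken over all
  reads in the well or over chain-assigned reads is not decidable from
  the published description; chain-assigned was chosen because it makes
  the β rule invariant to the (arbitrary) phenotype read share, and the
  threshold semantics are exercised directly in the tests.
* **Cluster classification.** A cluster consensus is classified by its
  best local-alignment score against the β V panel, the α V panel and
  the phenotype amplicon panel; it is a phenotype cluster only when the
  marker score beats the best TCR score.

## Annotation and the TRAJ24 allele

V and J segments are assigned per chain by best local alignment score
(ties broken alphabetically); an assignment is rejected below a floor of
60% of the maximum attainable score for the shorter of read and segment,
which is what turns a V-only fragment into an "unassignable J" rather
than a spurious call. The conserved anchors (V 2nd-CYS, J F/W of the
F/W-G-x-G motif) are mapped from germline coordinates onto the read
*through the alignment's gap structure*; a gapless extrapolation is used
only outside the aligned block. This matters: a one-base gap placed by
the aligner near the junction would otherwise shift the CDR3 frame.

The CDR3 includes both anchor residues (C…F/W), consistent with how
such junctions are conventionally reported; productivity is the minimal
rule — in frame, stop-free, anchored — with no additional framework
requirements. β D-segment assignment is not attempted: clonotype
identity already requires identical junction sequence, which subsumes
any D call at amplicon resolution.

For TRAJ24-bearing α chains, the rs1483979 site sits two codons upstream
of the J anchor inside the CDR3: `TTG` is called as the G allele
(leucine), `TTC` as the C allele (phenylalanine), and any other codon —
including synonymous leucine codons — as undetermined, because only the
TTG/TTC pair is diagnostic of the germline SNP.

## Clonotypes, expansion and sharing

A clonotype is the set of one donor's cells with identical V/J genes on
both chains and identical α and β CDR3 amino-acid sequences (nucleotide
identity is a toggle). Expansion (≥2 isolates) and high expansion (≥5)
are donor-scoped; cross-binding means isolation under more than one
tetramer; public partners are other donors carrying the identical paired
clonotype. Cells match clonotypes on their dominant α only — the
alternative α is annotated and carried on the cell but excluded from
identity, since clonotype tables conventionally list a single α.
Near-identical clonotypes (both CDR3s within Hamming distance 1) are
*reported* for manual review (`relaxed_clonotype_pairs()`), never merged
automatically.

Gene-usage enrichment compares per-gene frequencies in a subset (e.g.
cells of multi-isolate clonotypes) against a universe (all analyzed
cells or all wells returning sequence — both universes are computable,
and the choice is the caller's, because the published description is
ambiguous between them).

## Motif analysis

Global groups are connected components of same-length CDR3s differing at
no more than one *interior* position (interior = CDR3 minus the first 3
and last 2 residues). Local motifs are interior k-mers, k ∈ {2, 3, 4},
kept when (i) at least 3 sample CDR3s contain them, (ii) the sample
frequency exceeds 10× the reference frequency (a 0.5 pseudo-count keeps
the fold finite for reference-absent motifs), and (iii) the subsample
probability — the fraction of 1000 sample-sized reference draws
containing the motif at least as often — is below 0.001. These
parameter values are the published defaults of the motif-clustering
method this module follows; all are exposed in the API. CDR3s in no
global group and containing no enriched k-mer are *singles*, so every
CDR3 belongs to at least one group and kinds may overlap.

The default reference repertoire is generated by the package's naive
recombination model (uniform segment draw, 2–6 random stop-free insert
codons, random J trim, uniform SNP alleles), 10 000 sequences minimum,
since no standard public reference is bundled.

Scoring departs from resampling where an exact computation exists:
dominant-V enrichment is the exact tail P(max V-count ≥ observed) under
a multinomial draw from the sample's V distribution, evaluated by
truncated exponential-generating-function convolution; expansion
enrichment is an exact binomial tail. Both are deterministic, which
makes the significance calibration test sharp. The final score is
−log10 of the product of the two p-values — a presentation choice for
dot radii on the two-axis significance scatter — and a group is
significant only when both p-values fall below 0.05 and it has at least
two members.

## Cohort statistics

Skewing tests are 2×2 Pearson chi-squared without continuity
correction; the uncorrected variant is used because it reproduces
published repertoire-skewing p-values computed from their printed count
tables, while the Yates-corrected variant does not. Stacks of p-values
are adjusted by the Benjamini–Krieger–Yekutieli two-stage step-up
procedure at Q = 5%: stage one is BH at Q/(1+Q) (threshold 0.047619 for
Q = 0.05), giving the null-count estimate m₀ = m − r₁; stage two re-runs
BH at Q·m/((1+Q)·m₀). The *discovery decisions* are the contract of
this implementation. Reported q-values are adaptive BH adjusted
p-values (BH × m₀/m), a standard choice documented as reference output:
published q-values from commercial software could not be algebraically
reconciled with any standard two-stage adjusted-p formula, so no attempt
is made to reproduce them.

Counts behind percentage-only published comparisons are reconstructed
as round(percent × n), and fold changes with magnitude ≥2 are also
reported rounded to the nearest integer to match "by N fold" phrasing;
all printed-precision reproduction uses rounding half away from zero.
Tetramer-binding rank normalizes each cell's tetramer-channel
fluorescence by its forward scatter and divides by the
tetramer-negative population's MFI normalized by mean FSC; it is
scale-invariant to joint rescaling of all FI or all FSC values.

## The synthetic cohort

The generator emulates the study design: blinded case/control donor
pairs, one 96-well plate per donor–tetramer category, per-well read
depth from a negative binomial with mean 6091 and standard deviation
4556 (the printed overdispersed depth summary; Poisson when a caller's
variance is at most the mean), single-end full amplicons with constant
high qualities, error-free barcodes, and one cell per well (index
sorters deposit singlets; doublets are out of scope). Empty wells
(probability 0.163 by default, the complement of the 83.7% well
coverage) yield no reads; background cells suffer β/α amplicon dropout
(0.20/0.25) so that roughly 60% of covered wells yield paired calls,
matching the published accounting shape. Planted clones never drop out
— they model activated, RNA-rich expanded cells and are the ground
truth for round-trip tests. Phenotype emission probabilities default to
the published expanded/unexpanded marker frequencies (e.g. TBX21
0.89/0.183, IFNG 0.378/0.024, PRF1 0.516/0.047) with low background
rates for unlisted markers. The per-base substitution error rate
defaults to 0 (no platform error rate is published for this assay);
robustness properties are tested at 1% explicitly. Every amplicon
present in a well receives at least one read, so phenotype truth bits
are exactly recoverable — read counts after three rounds of nested PCR
carry no quantitative meaning in this assay, which is why presence (1)
versus absence (0) is the phenotype representation.

The default clonal plan plants the hallmark structure: two patients
with expanded, cross-binding TRAJ24-G (leucine) clonotypes on
TRBV29-1_TRBJ2-5 / TRAV6_TRAJ24 with conserved CDR3s (β carrying an
`E.DRGRSET`-type motif, α a `TDSWGK`-type motif), an expanded TRAJ24-C
(phenylalanine) clonotype in a control, a public single-isolate partner
in a second control, and a generic expanded clonotype on unrelated
genes.

What passing tests show: the pipeline's decision rules are implemented
exactly (zero-noise round trips are bit-exact; thresholds are strict;
clustering equals a brute-force oracle; statistics reproduce published
values from published counts). What they do not show: performance on
real reads with quality degradation, indel sequencing errors, PCR
chimeras, primer bias, barcode errors or sorter doublets — none of which
the generator models, by design.

## Problem sizes and numerical choices

Test and acceptance runs use desk-scale cohorts chosen as the smallest
sizes that exercise every code path: 2 donor pairs × 2 tetramers ×
24-well plates at ~40 reads/well for the zero-noise round trip, and 1
pair × 12-well plates at 200 reads/well for the 1% error robustness
property; clustering oracles run on 100 random bins of ≤20 reads; FDR
calibration uses 1000 stacks of 20 uniform p-values; motif calibration
draws 120 CDR3s from a 10 000-sequence reference. Ties are broken
deterministically everywhere (abundance then lexicographic order for
centroids; alphabetical for segment assignment; centroid base for
consensus columns), all randomness flows through explicit seeds, and
seeds derived from user seeds stay below 2³¹.

## Known limitations

Alternative α chains that happen to fall within 95% identity of the
dominant α (same V and J, very similar junction) merge into one cluster
and the alternative is lost; real paired-chain designs face the same
ambiguity. Anchor mapping assumes the aligner's gap placement near the
junction is locally parsimonious; pathological junctions surface as
non-productive calls rather than wrong CDR3s. The motif module's
reference repertoire is synthetic; absolute motif counts on real data
depend strongly on the reference choice and should be interpreted only
relative to a stated reference.
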