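# tcrclonal

Single-cell paired TCRαβ repertoire analysis for plate-based,
tetramer-sorted CD4⁺ T cells: from barcoded amplicon reads to consensus
TCR calls, V(D)J/CDR3 annotation with a TRAJ24 G/C (rs1483979) allele
read-out, clonal-expansion and public-clonotype detection, GLIPH-style
CDR3 motif scoring, phenotype binarization, and the cohort statistics
(Pearson chi-squared skewing tests under Benjamini–Krieger–Yekutieli
two-stage FDR, index-sort fluorescence tetramer-binding ranks) used to
compare cases and controls.

## Who this is for

Groups running index-sorted single-cell TCR sequencing on 96-well plates
— one sorted cell per well, plate–row–column barcoded amplicons covering
the V(D)J region plus a panel of phenotyping transcripts — who want a
tested, scriptable reimplementation of the standard analysis chain, plus
a synthetic-cohort generator so every stage can be validated against a
known ground truth without any sequencing data.

## The method in brief

* **Consensus calling.** Reads are demultiplexed by exact barcode
  triplets, clustered per well at ≥95% global alignment identity
  (matches / alignment columns), and a chain consensus is assigned under
  strict read-support thresholds: TCRβ iff the top β cluster holds
  >80% of β reads (*BetaConfi*), dominant TCRα iff >30% (*AlphaConfi*),
  and a second TCRα iff >10% (*altAlphaConfi*).
* **Annotation.** Germline V/J segments are assigned by local alignment
  (match +2, mismatch −3, gap −5); the CDR3 spans the V 2nd-CYS codon
  through the J F/W anchor, inclusive; productivity requires an in-frame,
  stop-free `C…F/W` junction. For TRAJ24⁺ α chains the SNP codon two
  codons before the anchor is read out: `TTG` → leucine (G allele),
  `TTC` → phenylalanine (C allele).
* **Clonotypes.** Cells are partitioned within each donor by identical
  V/J genes and identical α and β CDR3s; a clonotype is *expanded* with
  ≥2 isolates, *highly expanded* with ≥5, *cross-binding* when isolated
  under more than one tetramer, and *public* when the identical paired
  clonotype occurs in another donor.
* **Motifs.** CDR3s are grouped globally (same length, ≤1 interior
  difference) and locally (interior k-mers enriched ≥10-fold over a
  naive-recombination reference with subsample probability <0.001); each
  group is scored with exact tails for dominant-V concentration
  (multinomial maximum) and expanded-clone concentration (binomial).
* **Statistics.** 2×2 Pearson chi-squared without continuity correction;
  p-value stacks adjusted by the BKY two-stage step-up procedure at
  Q = 5% (stage-one threshold 0.047619); Welch, paired t and
  Mann–Whitney U helpers; tetramer-binding rank =
  (FI/FSC) / (negative-population MFI / mean FSC).

## Worked example

```r
library(tcrclonal)
library(dplyr)

cfg <- simulation_config(n_donor_pairs = 2, wells_per_plate = 24,
                         reads_per_well_mean = 40, reads_per_well_sd = 10,
                         per_base_error_rate = 0, seed = 7)
cohort <- simulate_cohort(cfg)
pipe   <- run_pipeline(cohort)
pipe
#> tcrclonal pipeline result
#>   wells: 192 (TCR coverage 83.9%)
#>   analyzed paired cells: 111
#>   clonotypes: 94 (expanded 4, cross-binding 2)
#>   skewing discoveries: 0 of 3
```

The cohort plants two patient clonotypes carrying the TRAJ24 G allele on
TRBV29-1_TRBJ2-5 / TRAV6_TRAJ24, an expanded C-allele clonotype in a
control, and a public single isolate; the pipeline recovers them exactly:

```r
tidy(pipe) |>
  filter(traj == "TRAJ24", expanded | lengths(public_partners) > 0) |>
  select(donor, cdr3b, cdr3a, n_isolates, cross_binding, allele_call)
#> # A tibble: 4 x 6
#>   donor cdr3b            cdr3a          n_isolates cross_binding allele_call
#> 1 P1    CASSEGDRGRSETQYF CALSDTDSWGKLQF          7 TRUE          G-allele/L
#> 2 C1    CASSLRTGETQYF    CALSDTDSWGKFQF          6 FALSE         C-allele/F
#> 3 P2    CASSEADRGRSETQYF CALSETDSWGKLQF          5 TRUE          G-allele/L
#> 4 C2    CASSEADRGRSETQYF CALSETDSWGKLQF          1 FALSE         G-allele/L
```

`n_isolates` is the donor-level clone size; `allele_call` is the
rs1483979 read-out from the CDR3α SNP codon. The statistics layer runs on
any positive/total count table; on the packaged example cohort counts:

```r
tab <- example_counts("expansion_contingency")
chi_squared_skew(tab$controls_expanded[5], tab$controls_total[5],
                 tab$cases_expanded[5], tab$cases_total[5])
#> # A tibble: 1 x 3
#>   statistic    df  p_value
#> 1      13.1     1 0.000299
```

i.e. expanded-cell detection under the HCRT87–100 tetramer is skewed
toward patients (3.51% vs 0.8%, p ≈ 0.0003). Plot helpers
(`plot_motif_scatter()`, `plot_jgene_heatmap()`,
`plot_phenotype_heatmap()`, `plot_expansion_contingency()`,
`autoplot()` on FDR objects) render the standard figures.

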