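# pioneerscan

Integrative analysis of transcription-factor ChIP-seq and ATAC-seq peak sets
to characterize **pioneer-factor** behaviour, built around the GATA6 /
cardiac-differentiation use case: a pioneer factor binds nucleosomal
("closed") chromatin — regions without measurable accessibility — and nearby
genes activate later in the differentiation time course.

The package is aimed at regulatory-genomics analysts who have peak sets,
count tables and an annotation (not raw reads) and want the full statistical
chain from peak overlap to cohort genetics as tested, seedable R functions.

## What it computes

Given ChIP peaks, ATAC peaks, per-peak counts per genotype, a gene
annotation and a gene × sample expression table:

1. **Chromatin classification** — a ChIP peak is *open* iff it overlaps an
   ATAC peak by ≥ `min_overlap` bp (default 1 bp):
   `frac_open = n_open / n_total`, with genomic-feature distributions
   (promoter > exon > intron > intergenic at the peak midpoint) per class.
2. **Motif enrichment by class** — PWM log-odds scanning of peak sequences
   on both strands (hit ⇔ score ≥ 0.8 × max attainable); one-sided
   hypergeometric test of "sequences with ≥ 1 hit" against a seeded
   dinucleotide-shuffled background; motifs ranked by p.
3. **Differential occupancy** — exact conditional Poisson test per peak
   (given n = a + b, a ~ Binomial(n, lib_a/(lib_a+lib_b))), BH adjustment,
   calls at adjusted p < 1e-4 and |log2FC| ≥ 1; LOST/GAINED fractions use
   the reference/other peak-set denominators, and the accessibility of the
   LOST and GAINED subsets is re-assessed against ATAC data.
4. **Pioneer integration** — each closed-chromatin peak is assigned to its
   nearest TSS within 50 kb; among genes differentially expressed between
   two adjacent days (pooled-variance t test on log2 normalized counts, BH,
   adjusted p < 0.05, |log2FC| ≥ 1), it reports the associated fraction and
   the fraction of associated genes that increase, plus a permutation
   enrichment p-value.
5. **Cohort statistics** — exact binomial upper-tail test
   `P(X ≥ k | n, q = w/L)` for missense clustering in the exon-4
   zinc-finger window (residues 435–477 of 595), Fisher exact tests for
   phenotype association, and count/percentage summaries.

A seeded synthetic-data module generates every input with planted ground
truth; the shipped profiles (`wt_day4`, `r456g_day4`, `het_day4`,
`wt_expression`, `cohort_paper`) pin the planted parameters to the headline
study conditions (20,932 ChIP peaks with 12% open; 39.3% reduced and 64.8%
increased peaks at 4-fold effects; 10.7% of heterozygote-diminished peaks
open; 2,878 DE genes with 36.4% associated and 56% activated; the 70-patient
variant cohort).

## Worked example

```r
library(pioneerscan)

# a scaled-down coordinated simulation (the shipped profile defaults to
# 20,932 peaks and 15,000 genes)
sim <- cmd_simulate("wt_expression", seed = 1,
                    overrides = list(genome = list(n_genes = 1500),
                                     peaks = list(n_chip = 2000,
                                                  n_atac = 4000),
                                     expression = list(n_de = 300)),
                    sequences = FALSE)
report <- cmd_pioneer(sim, n_perm = 199, seed = 1)
report
#> pioneer_report
#>   classification: 2000 peaks, 12.0% open
#>   integration: 290 DE genes, 37.6% associated with closed binding, 56.0% of those UP

report$pioneer$perm_p     # permutation p for the association enrichment
#> [1] 0.005

# cohort statistics from the exact-margins profile
cohort <- cmd_simulate("cohort_paper", seed = 1)
cmd_cohort(cohort$cohort)
#> cohort_report: 70 patients
#>   extracardiac: 29/70 (41.4%)
#>   pa_cdh: 23/70 (32.9%)
#>   neuro: 13/70 (18.6%)
#>   clustering: 11/43 missense in window 435-477, p = 0.000184
#>   pa_cdh x exon-4 missense: one-sided p = 9.75e-08, OR = 247
```

Reading it: 12.0% of simulated binding sits in open chromatin (the planted
fraction); 290 of the 300 planted DE genes are recovered, 37.6% of them have
a closed-chromatin binding peak within 50 kb of the TSS and 56.0% of those
are called UP at the later day — the pioneer signature. In the cohort, 11 of
43 missense variants fall in the 43-residue zinc-finger window
(p = 1.8e-4), and pancreatic agenesis / diaphragmatic hernia occurs in 9/11
exon-4 missense carriers versus 0/32 elsewhere (exact one-sided
p = 9.75e-8).

Each analysis stage is also available as a plain function
(`classify_open_closed`, `rank_motifs`, `call_differential_peaks`,
`differential_expression`, `associate_peaks_to_genes`,
`pioneer_association_stats`, `binomial_window_test`, `fisher_exact_2x2`,
...), and `inst/scripts/pioneerscan.R` is a thin command-line dispatcher
over `cmd_simulate` / `cmd_pioneer` / `cmd_cohort`.

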