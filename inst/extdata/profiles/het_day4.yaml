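# Heterozygote day-4 comparison: 39.3% of the reference peaks planted
# REDUCED, with only 10.7% of the reduced peaks in open chromatin; 47% of the
# 17,624 heterozygote peaks planted INCREASED.
name: het_day4
type: epigenome
seed: 1
day: 4
genome:
  n_chrom: 12
  chrom_length: 260000000
  n_genes: 15000
  min_tss_spacing: 120000
  gene_length_min: 5000
  gene_length_max: 50000
  margin: 100000
peaks:
  n_chip: 20932
  n_atac: 50000
  frac_open: 0.12
  frac_open_promoter: 0.21
  chip_len_min: 150
  chip_len_mode: 250
  chip_len_max: 400
  atac_extra_min: 200
  atac_extra_max: 600
  slot_bin: 2500
  slot_jitter: 500
  tss_exclusion: 55000
occupancy:
  depth: 100
  fold: 4
  dispersion: 0
  lib_size: 10000000
genotype:
  label: HET
  n_other: 17624
  frac_reduced: 0.393
  frac_increased: 0.47
  frac_open_reduced: 0.107
motifs:
  open_motif: GATA
  open_rate: 0.4
  closed_motif: MEF2
  closed_rate: 0.3
  gc: 0.41
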