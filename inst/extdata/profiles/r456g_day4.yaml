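# Missense-genotype day-4 comparison: 39.3% of the 20,932 reference peaks
# planted REDUCED (21% of them in open chromatin) and 64.8% of the 67,652
# mutant-genotype peaks planted INCREASED, at 4-fold occupancy effects.
name: r456g_day4
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
  label: R456G
  n_other: 67652
  frac_reduced: 0.393
  frac_increased: 0.648
  frac_open_reduced: 0.21
motifs:
  open_motif: GATA
  open_rate: 0.4
  closed_motif: MEF2
  closed_rate: 0.3
  gc: 0.41
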