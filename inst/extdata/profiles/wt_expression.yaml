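# Coordinated integration profile: the reference day-4 epigenome plus a
# 15,000-gene two-time-point expression table with 2,878 planted DE genes;
# 36.4% of DE genes are guaranteed a closed-chromatin binding peak within the
# 50-kb association window and 56% of those are planted as activated at the
# later time point. Non-DE genes carry nearby closed binding at a background
# rate of 0.25.
name: wt_expression
type: integration
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
  assoc_dist_min: 5000
  assoc_dist_max: 40000
occupancy:
  depth: 100
  fold: 4
  dispersion: 0
  lib_size: 10000000
expression:
  n_de: 2878
  lfc_min: 3
  lfc_max: 5
  frac_assoc: 0.364
  frac_up: 0.56
  bg_assoc_rate: 0.25
  replicates: 2
  meanlog: 6.6846
  sdlog: 0.8
  dispersion: 0.01
  de_min_base: 500
  lib_size: 10000000
  cond_a: day4
  cond_b: day5
motifs:
  open_motif: GATA
  open_rate: 0.4
  closed_motif: MEF2
  closed_rate: 0.3
  gc: 0.41
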