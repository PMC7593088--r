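# Patient cohort with the printed margins planted exactly: 70 patients
# (27 LoF, 43 missense, 11 of them in the exon-4 window 435-477);
# extracardiac 18/27 LoF and 11/43 missense; neuro 13/70; pancreatic
# agenesis / diaphragmatic hernia 9/11 exon-4 missense vs 0/32 elsewhere and
# 14/27 LoF (the class-stratified configuration).
name: cohort_paper
type: cohort
seed: 1
cohort:
  mode: exact
  n_lof: 27
  n_missense: 43
  n_exon4_missense: 11
  window: [435, 477]
  protein_length: 595
  extracardiac:
    LoF: 18
    missense: 11
  neuro:
    LoF: 7
    missense: 6
  pa_cdh:
    LoF: 14
    exon4_missense: 9
    other_missense: 0
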