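# Blood-arm style cohort: 5 case vs 3 control samples at ~250X with a small
# global downward shift in methylation probability in the cases.
seed: 1
simulate:
  n_case: 5
  n_control: 3
  case:
    contig: chrM
    contig_length: 16569
    truth: 0.027
    coverage: 250
  control:
    contig: chrM
    contig_length: 16569
    truth: 0.034
    coverage: 250
control:
  coverage_multiplier: 16
  fpr_call: 0.03
mf: {llr_upper: 2, llr_lower: -2, split_groups: true}
filters: {min_alignment_bp: 1000, qscore_cutoff: 7}
correction: {exclusion_threshold: 0.2, clamp_at_zero: true}
report: {high_mf_threshold: 0.2}
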