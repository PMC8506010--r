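# Long-range PCR amplicon of the mitochondrial genome: methylation-free
# baseline sequenced deep, used to estimate the caller false-positive rate.
contig: chrM
contig_length: 16569
coverage: 250
control:
  coverage_multiplier: 16   # amplicon runs are deep (~4000X)
  fpr_call: 0.03
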