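# Native-style sample with a 10% spike of short NUMT-like contaminant reads
# (alignment length 100-500 bp), all removed by the >1 kb alignment filter.
contig: chrM
contig_length: 16569
truth: 0.03
coverage: 100
numt_fraction: 0.1
filters: {min_alignment_bp: 1000}
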