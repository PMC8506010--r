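# Synthetic 897 bp fragment sequenced at three dilution ratios of fully
# methylated vs fully unmethylated molecules (0 / 50 / 100 % methylation).
# Reads span the whole fragment; molecules are drawn whole-molecule.
fragment:
  contig: D4505
  contig_length: 897
  cpg_positions: [30, 65, 100, 135, 170, 205, 240, 275, 310, 345, 380, 415,
                  450, 485, 520, 555, 590, 625, 660, 695, 730, 765, 800, 835, 870]
  molecule_mode: whole_molecule
  coverage: 5018
  read_length_mean: 897
  read_length_sdlog: 0
  circular: false
  qscore_delta: 4
dilutions:
  meth_0: {pi: 0.0}
  meth_50: {pi: 0.5}
  meth_100: {pi: 1.0}
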