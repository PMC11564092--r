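# Position-specific nucleotide weights for PspCas13b spacer scoring.
# Positions are 1-based from the spacer 5' end; every (base, position) pair
# not listed contributes 0. These defaults encode the published rules:
# G at position 1 or 2 -> +60 each; C at positions 1-4 -> -60/-60/-50/-40;
# C at positions 11, 12, 15, 16, 17 -> -5 each.
spacer_length: 30
weights:
  G:
    1: 60
    2: 60
  C:
    1: -60
    2: -60
    3: -50
    4: -40
    11: -5
    12: -5
    15: -5
    16: -5
    17: -5
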