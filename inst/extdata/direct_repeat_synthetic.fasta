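>direct_repeat_synthetic 36-nt synthetic stand-in for the PspCas13b direct repeat (correct length, not the biological sequence)
GUUGUAGAAGGACAACGCUUCGUUGUCCAAUUUCAC
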