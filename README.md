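# cas13design

Rule-based design and specificity analysis of PspCas13b CRISPR RNAs.

PspCas13b is an RNA-guided RNA nuclease with a 30-nt spacer and no
protospacer-flanking-sequence requirement. Guide potency is driven by the
nucleotide composition of the spacer itself, above all at its 5' end, and
guide specificity by a sharply limited mismatch tolerance (~4 mismatches
out of 30). This package is for anyone designing PspCas13b knockdown
experiments or analysing tiled crRNA screens: it turns a target sequence
into a ranked list of spacers, explains each score, designs 5' G rescue
variants for poor guides, predicts whether a given spacer–target mismatch
pattern still silences, scans a transcriptome for off-target sites, and
reproduces the cohort analytics (PWMs, delta nucleotide probabilities, PFS
composition) from which the design rules were derived.

## The model

Candidate spacers are the reverse complements of all single-base-stepped
30-nt windows of the target (a target of length L gives L − 29 candidates).
Spacers whose DNA form contains ≥4 consecutive T are removed (Pol III
terminator in a U6 cassette). The remaining spacers are scored as a sum of
independent positional weights,

S(s) = Σᵢ w(sᵢ, i),

with G at positions 1–2 earning +60 each, C at positions 1–4 penalised
−60/−60/−50/−40, C at positions 11, 12, 15, 16, 17 penalised −5 each, and
everything else 0 (attainable range −235 … +120). Spacers matching the
potent consensus `GGNNNNNNNNDDNNDDDNNNNNNNNNNNNN` (G-G start, no central
C) are flagged `predicted_potent`; C-rich spacers matching the ineffective
consensus are flagged `predicted_ineffective`.

Specificity is modelled as a rule engine over mismatch patterns: scattered
mismatches are tolerated up to four (runs of ≤2, away from the 5' end);
consecutive blocks of ≥4 generally kill silencing except in the spacer
centre; ≥5 scattered or ≥6 consecutive mismatches abolish it. Off-target
windows found by an exact Hamming scan are categorised by mismatch count:
≤4 `likely_silenced`, 5–15 `unlikely_silenced`, >15 suppressed as
nonexistent.

## Worked example

```r
library(cas13design)

set.seed(7)
target <- NucleotideSeq(paste(sample(c("A","C","G","U"), 120,
                                     replace = TRUE), collapse = ""),
                        id = "demo")

sc <- generateCandidates(target)
sc
#> SpacerCandidates for 'demo' (120 nt target)
#>   91 candidates of 30 nt: 91 retained, 0 polyT, 0 ambiguous

rk <- rankSpacers(sc)
head(rk[, c("rank", "spacer_seq", "start_1based", "score", "motif_class")], 5)
#>  rank                     spacer_seq start_1based score   motif_class
#>     1 GGGACGAUAAGCUCUAGUUAUUCUAGCUAA           42   115 indeterminate
#>     2 GGUAGGAAACGAAUUCGAUCGACAGGGACG           66   115 indeterminate
#>     3 GGAAACGAAUUCGAUCGACAGGGACGAUAA           62   110 indeterminate
#>     4 GGACGAUAAGCUCUAGUUAUUCUAGCUAAC           41    75 indeterminate
#>     5 GGCAUCGAGCCGAACAGCACGAACAAGGCG            6    60 indeterminate
```

The 120-nt target yields 91 candidates, none filtered. The winner starts
G-G (+60 +60) and carries one central C (−5), hence 115; it is
`indeterminate` rather than `predicted_potent` precisely because of that
central C. The breakdown makes this explicit:

```r
scoreSpacer(rk$spacer_seq[1])
#> ScoreBreakdown: GGGACGAUAAGCUCUAGUUAUUCUAGCUAA
#>   total +115 (indeterminate)
#>   pos 1 (G): +60
#>   pos 2 (G): +60
#>   pos 12 (C): -5
```

A full crRNA is the spacer plus the 3' direct repeat (30 + 36 = 66 nt;
the bundled repeat is a synthetic length-correct stand-in — substitute
your expression system's scaffold):

```r
assembleCrRNA(rk$spacer_seq[1])
#> NucleotideSeq 'crRNA' (RNA, 66 nt)
#>   GGGACGAUAAGCUCUAGUUAUUCUAGCUAAGUUGUAGAAGGACAACGCUUCGUUGUC...
```

Will a guide with a 4-nt central mismatch block still silence?

```r
classifyMismatchPattern(c(9, 10, 11, 12))
#> PARTIAL_LOSS (rule: block4_central)

maxToleratedScattered()   # enumerated from the rule engine, not a constant
#> [1] 4
minRequiredPairing()
#> [1] 26
```

Off-target scanning and the cohort analytics follow the same pattern; see
`?scanOffTargets`, `?splitCohorts`, `?deltaProbabilities` and the vignette
(`vignettes/crrna-design-methods.Rmd`). A thin command-line wrapper
(`inst/exec/cas13design`) exposes the design → rank → off-target workflow,
the tolerance classifier and the cohort pipeline with documented exit
codes (0 ok, 1 usage/validation error, 2 empty result).

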