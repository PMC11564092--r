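---
title: "Rule-based PspCas13b crRNA design: models, parameters and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based PspCas13b crRNA design: models, parameters and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cas13design)
```

## The design problem

PspCas13b is an RNA-guided RNA nuclease whose 30-nt spacer base-pairs a
target transcript; silencing efficiency varies enormously between guides
targeting neighbouring positions, and the enzyme has no protospacer-flanking
sequence (PFS) requirement. Potency is instead governed by the nucleotide
composition of the spacer itself, most strongly at its 5' end. This package
implements the resulting rule-based design procedure: tile the target at
single-base resolution, drop spacers that would terminate Pol III
transcription prematurely, score the rest with position-specific nucleotide
weights, and rank. It also implements the companion specificity tools — a
mismatch-tolerance classifier distilled from systematic spacer mutagenesis,
and an ungapped transcriptome off-target scan categorised by mismatch count —
and the cohort analytics from which the scoring rules were derived.

## Tiling and the poly-T filter

A target of length $L$ yields exactly $L - 29$ candidate windows; the spacer
is the reverse complement of the sense window, so spacer position 1 (5' end)
pairs with the window's last base. Windows containing N are flagged
`ambiguous_base` and never scored: every downstream rule is defined only
over A/C/G/U.

The poly-T filter removes spacers whose DNA representation contains a run of
**four or more** consecutive T (three is permitted). The rationale is the
expression system, not the enzyme: a TTTT run in a U6-driven crRNA cassette
acts as an RNA polymerase III terminator and would truncate the crRNA. The
filter is evaluated on the spacer portion only, not across the
spacer/direct-repeat junction — the repeat is constant, so any junction
terminator would be a property of the scaffold, and the scaffold shipped
here is a synthetic stand-in anyway (see below).

Internally all coordinates are 1-based inclusive, the R and Bioconductor
convention (IRanges-style); the TSV outputs are likewise 1-based and say so
in their column names (`start_1based`).

## Positional scoring

The score of a spacer is a sum of independent per-position terms
$S(s) = \sum_{i=1}^{30} w(s_i, i)$ with all non-zero weights listed below;
every other (base, position) pair contributes 0.

| feature | positions | weight |
|---|---|---|
| G bonus | 1, 2 | +60 each |
| 5' C penalty | 1, 2, 3, 4 | −60, −60, −50, −40 |
| central C penalty | 11, 12, 15, 16, 17 | −5 each |

The attainable range is $[-235, +120]$: the minimum is an all-C spacer
(−60−60−50−40 plus five −5 terms), the maximum a spacer with G at positions
1–2 and no penalised C. Weights live in a YAML config
(`inst/extdata/scoring_weights.yaml`) so they can be overridden without
touching code; the shipped file reproduces the defaults. Ranking sorts by
score descending with ties broken by window start ascending (the 5'-most
design wins a tie), which makes output deterministic.

Consensus classification is intentionally coarser than the score. A spacer
is `predicted_potent` iff it has G at positions 1 and 2 and no C at
positions 11, 12, 15, 16, 17 (the D positions of the potent consensus).
The ineffective consensus ("C at positions 1, 2, 3, 4, 11, 12, 15, 16,
17") is ambiguous as a predicate — *any* C versus *all* C. We call a spacer
`predicted_ineffective` when it has C at position 1 or 2 (the −60
positions), or C at ≥6 of the nine penalised positions; this captures the
C-rich consensus without flagging every spacer carrying a single mid-spacer
C. Everything else is `indeterminate`, and the numeric score is always
reported so users can apply their own cut-off — the source screen did not
publish a numeric potency threshold, only the ranked list.

Rescue design encodes the observation that forcing G at the 5' end of an
ineffective spacer boosts its activity even though it introduces deliberate
target mismatches: `INS_G` (prepend G; a 31-nt spacer retaining full 30-nt
complementarity with one unpaired 5' base), `SUB_1G` and `SUB_12GG`.
Insertion variants are scored 5'-anchored: weight column $i$ applies to
spacer position $i$, position 31 is unscored.

## Mismatch tolerance

The tolerance engine is a total function from a set of mismatched spacer
positions to {TOLERATED, PARTIAL_LOSS, LOST}, encoding the mutagenesis
outcomes. Single consecutive blocks are looked up in a serialisable rule
table (`toleranceRules()`): 3-nt blocks are tolerated everywhere except
positions 1–3, where the loss tracks removal of the 5' G-G-G motif rather
than the mismatch itself; 4-nt blocks starting at 9–17 and 5-nt blocks
within 6–15 or 26–30 give partial loss; all other 4/5-nt placements and
every block of ≥6 lose activity. Placements not directly assayed inherit
the label of the tested span they fall inside; blocks straddling two tested
spans take the worse label, and their rule ids are flagged `interp`.

Scattered patterns (≥2 maximal runs) are tolerated when the total is ≤4,
every run is ≤2 long, and no run of ≥2 touches positions 1–3. A *single*
mismatch at positions 1–3 is deliberately permitted: single 5'
substitutions showed no significant effect, so treating any 5' contact as
fatal would be wrong. Two or more runs of length 2–3, or ≥5 total
mismatches, lose activity. Anything unmatched falls back to LOST — a
conservative default, visible as `rule_id = "fallback"`. Blocks of length
1–2 (below the smallest assayed block) are tolerated for the same reason
as single 5' substitutions.

`maxToleratedScattered()` re-derives the headline "up to four mismatches"
by enumerating all scattered patterns (runs ≤2, positions ≥4) of growing
size against the rule engine — it is a consistency check of the engine,
not a constant. `minRequiredPairing()` is its complement
(30 − 4 = 26 paired bases).

The optional 27-nt rule set is stricter — shortened spacers exacerbate
mismatch intolerance: any scattered pattern of ≥2 loses activity, 3-blocks
are tolerated only at 13–21, and even a single mismatch at position 21
costs activity partially.

Truncations are classified separately (`classifyTruncation`): ≥3 nt off
the 5' end is fatal; 3 nt off the 3' end is free, 4–15 nt lose activity
gradually (PARTIAL_LOSS).

## Off-target scanning

The scan is ungapped Hamming matching of the spacer's reverse complement
against every window of the sense strand of each transcript. The published
web tool wraps BLAST, but its categorisation is phrased purely in mismatch
counts, so an exact Hamming scan reproduces the categories while being
fully deterministic; indel-tolerant alignment is intentionally out of
scope. Categories: ≤4 mismatches `likely_silenced` (within the tolerance
budget), 5–15 `unlikely_silenced`, >15 `nonexistent` and suppressed from
the report. `percent_match` uses the spacer length (30) as denominator.
Hits in the likely-silenced class are cross-annotated with the tolerance
engine's label for their exact mismatch pattern, which refines 3–4-mismatch
hits into tolerated/partial/lost.

Two search paths return provably identical hit sets and are tested against
each other and an all-windows oracle: a sliding-window count (30 vectorised
comparisons per transcript) and a pigeonhole-seeded scan — the 30-mer
complement is cut into `cap + 1` contiguous exact seeds, so any window
within the cap must match one seed exactly; seed hits are verified by
direct counting. Seeding needs seeds of ≥3 nt to be selective, so it is
used automatically only for caps ≤4 (the biologically actionable class);
the default cap of 15 mirrors the report cut-off above.

## Cohort analytics

`splitCohorts` applies the strict thresholds used to derive the rules:
potent iff efficiency >90%, ineffective iff <50%, boundaries excluded.
PWMs are plain per-position frequencies; delta matrices subtract a baseline
composition so columns sum to 0. The source figures do not state their
baseline; the default here is the cohort's own pooled nucleotide frequency
(so deltas show positional deviation from the cohort's overall
composition), with `uniform` (0.25) and custom baselines available, and
the baseline used is recorded in the object and in `cmdCohort`'s JSON
summary. PFS matrices are 4×4 PWMs of the 4-nt flanks on either side of
the protospacer; for PspCas13b the expectation is *no* positional bias.
`evaluatePredictions` reports cohort-conditional accuracy (the fraction of
predicted-potent guides measured above the potent threshold, and the
converse) plus a confusion table. Correlations with precomputed covariates
(e.g. folding energies from external tools) are supported via
`covariateCorrelation`; computing folding energies is out of scope.

## Synthetic data

The generators exist so the whole pipeline is testable offline, and they
are first-class tested code. `makeTranscriptome` draws i.i.d. bases at a
requested GC fraction; `plantOffTarget` writes a reverse-complement site
into a transcript, mutating the stated spacer positions to a
deterministically chosen non-complementary base so the planted window's
mismatch count is exact by construction; `makeEfficiencyTable` emulates the
*structure* of a 201-guide tiled-screen dataset — 30-nt spacers, percent
efficiencies, 4-nt flanks — with a planted compositional signal (potent
records forced to G1-G2 and central-C-free around a class mean of 95%;
ineffective records forced to C1-C2 around 30%; intermediates at 70%;
Gaussian noise sd 5, truncated to [0, 100]). The class means and noise are
chosen so the >90/<50 split recovers the planted classes cleanly, which is
what the parameter-recovery tests require.

What the generators do **not** emulate: real transcriptome composition
(codon structure, repeats, isoforms), measurement error structure of
fluorescence assays, target-site secondary structure, or any coupling
between spacer sequence and efficiency beyond the planted 5'/central
motifs. Passing tests therefore demonstrate the algorithms' correctness
and internal consistency, not biological prediction accuracy on new data.

All generators take an explicit seed and run in a local RNG scope (the
caller's `.Random.seed` is untouched); identical arguments give identical
output.

## Numerical and degenerate-input choices

* Probability/delta matrix column sums are validated at 1e−9.
* Empty candidate sets rank to an empty table with a warning; an empty
  transcriptome scans to an empty hit set with a warning; an empty rule
  table is a hard error (misconfiguration, not data).
* Ties in ranking break by window start; hit tables sort by mismatch
  count, transcript id, position — all outputs are byte-stable.
* Problem sizes used by the checked examples: 1e5 random spacers for the
  score-bound property, 1e3 random targets for the tiling/poly-T oracle,
  a 50-transcript ≈100-kb transcriptome with 20 planted sites (0–16
  mismatches) for scanner equivalence, and a 201-record planted-bias
  efficiency table for cohort recovery.
* The bundled 36-nt direct repeat is a synthetic stand-in of the correct
  length (the scaffold sequence is not printed in the source literature);
  `assembleCrRNA` enforces the 30 + 36 = 66 nt invariant and users supply
  their own repeat for cloning-ready output.

## Known limitations

* No thermodynamics: folding/hybridisation energies are deliberately
  excluded; they correlate only moderately with potency and require
  external tools.
* The off-target scan is mismatch-only (no indels) and scans the sense
  strand only (Cas13 binds the transcript).
* Tolerance labels for untested block placements are interpolations and
  are flagged as such in their rule ids.
* The consensus classifier is a heuristic readout of the score table; the
  score itself is the primary ranking signal.
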