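Package: cas13design
Title: Design and Specificity Analysis of PspCas13b CRISPR RNAs
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Rule-based design of PspCas13b crRNA spacers from a target RNA
    sequence. Generates single-nucleotide tiled 30-nt spacer candidates,
    removes candidates carrying poly-T transcription-termination signals,
    scores candidates with position-specific nucleotide weights, classifies
    them against the potent/ineffective consensus motifs and designs 5' G-G
    rescue variants for ineffective spacers. Also provides a mutagenesis-derived
    mismatch-tolerance classifier, an ungapped transcriptome off-target scanner
    with mismatch-count categorisation, cohort analytics (position weight
    matrices, delta nucleotide probabilities, protospacer-flanking-sequence
    composition, prediction-accuracy evaluation) and deterministic synthetic
    data generators for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: CRISPR, SequenceMatching, Sequencing, DesignTool
RoxygenNote: 7.3.3
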