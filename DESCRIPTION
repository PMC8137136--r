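Package: pombeCRISPRi
Title: Guide Design and Repression Quantification for dCas9 CRISPRi in Fission Yeast
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Design tools for dCas9-mediated transcriptional interference
    (CRISPRi) in Schizosaccharomyces pombe. Enumerates 20-nt targeting
    sequences with NGG protospacer-adjacent motifs near a gene's
    transcription start site, classifies their orientation and TSS offset,
    ranks them by a strand-aware two-peak efficacy rule, screens exact
    genome-wide off-target matches, and emits cloning-ready oligo pairs with
    BbsI Golden-Gate overhangs and an annealing thermal program. Also
    implements the repression-index / percent-repression statistic for
    RT-qPCR knockdown measurements, plus seeded simulators for synthetic
    genomes with planted guide sites and synthetic Cq tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
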