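Package: arrestseq
Title: Starvation-Arrest Transcriptome Dynamics: Simulation, Normalization,
    Differential Expression, Clustering and Transcription-Dependence Analysis
Version: 0.1.0
Authors@R:
    person("arrestseq", "developers", email = "arrestseq@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing bulk mRNA-seq time courses of developmentally
    arrested C. elegans L1 larvae. Implements time-course and pairwise
    differential expression with negative-binomial likelihood-ratio tests,
    correlation-distance diameter-constrained clustering with a
    peak/centroid-based display ordering, hypergeometric gene-group enrichment,
    ERCC-style spike-in regression for absolute quantification in attomoles
    per worm, a control-gene SVD factor of unwanted variation, and the
    set-logic classification separating transcription-driven from
    transcript-stability-driven expression changes. Ships a synthetic-data
    generator with full ground truth emulating soma/germline starvation
    biology (ongoing somatic transcription, quiescent but stable germline
    transcripts, declining total RNA per worm) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
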