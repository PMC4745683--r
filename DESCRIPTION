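Package: gwtm
Title: Genome-Wide Transcriptional Modelling of Expression and Degradation Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a discrete kinetic model of transcription (basal production,
    sensitivity to a shared hidden regulator activity, and first-order
    degradation) jointly to expression and transcription-shutoff time courses
    for all gene pairs, and uses the minimized residual sum of squares as a
    co-regulation dissimilarity for Ward clustering into principal
    transcriptional activities. Includes iterative normalization of
    transcription-shutoff arrays against a stable gene set, empirical decay
    rate estimation, fold-change censuses and gene-selection filters,
    Pearson-correlation clustering of down-regulated genes into waves,
    moderated-t differential expression with empirical-Bayes variance
    shrinkage, canonical correspondence analysis for staging samples along a
    differentiation gradient, and a synthetic-data generator that emulates the
    statistical structure of stimulated-thymocyte time-course microarrays for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    deSolve,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    vegan,
    mclust,
    ape,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
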