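Package: recseq
Title: Analysis of 48S Preinitiation Complex Recruitment Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing in vitro 48S preinitiation complex (PIC)
    footprint sequencing experiments in transcript coordinates: P-site
    assignment and region counting (main-AUG, upstream, internal and CDS
    footprints), metagene matrices and wiggle tracks, spike-in
    geometric-mean size factors, negative-binomial Wald tests of
    differential recruitment with fixed size factors, recruitment
    efficiency (RE) and relative ribosome occupancy (RRO) statistics,
    PARS-style structure summaries, equal-size feature binning, and
    classifiers for leaky scanning and upstream-initiation reciprocity.
    Includes a synthetic-data generator that emulates competition of
    transcripts for a limiting PIC pool, helicase-dependent relief of
    5'UTR length and structure penalties, context-dependent leaky
    scanning, rare upstream initiation and spike-in controls, so that
    every stage of the pipeline can be validated against planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
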