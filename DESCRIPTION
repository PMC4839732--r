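Package: screenfuse
Title: Fusion of RNAi Screen Hits and Transcriptome Changes for
    Pathway-Level Survival Analysis
Version: 1.0.0
Authors@R:
    person("screenfuse", "authors", email = "screenfuse@example.org",
           role = c("aut", "cre"))
Description: Integrates phenome (RNAi survival screen) and transcriptome
    (expression time course) gene lists by set-union "fusion" prior to
    pathway enrichment analysis.  Implements the differential-expression
    rule (Welch t-test with signed fold-change thresholds on a
    low-abundance-filtered matrix), right-tailed Fisher exact enrichment
    against GMT gene-set collections with Benjamini-Hochberg FDR control,
    cross-platform and cross-species pathway comparison statistics,
    STRING-style interaction-network annotation with mass-conserving
    expression landscapes, and a planted-signal synthetic-data generator
    emulating a genome-wide screen paired with a replicated expression
    time course.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    optparse,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
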