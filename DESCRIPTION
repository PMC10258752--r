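Package: repari
Title: Immune Repertoire Metrics and Respiratory Infection Episodes in Infant Cohorts
Version: 0.1.0
Authors@R:
    person("repari", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing adaptive immune receptor repertoires
    (AIRR-seq clonotype tables) alongside daily infection symptom diaries
    in birth-cohort studies. Reads AIRR rearrangement TSV clonotype tables,
    applies productivity and read-count filters, rarefies repertoires to a
    common read depth, and computes per-repertoire summary statistics:
    clonality (1 minus Pielou's evenness), Shannon and Simpson diversity,
    richness, mean CDR3 length, somatic hypermutation fraction, V-gene
    usage with principal component analysis, and V(D)J generation
    probability (Pgen) under a simplified, exactly enumerable recombination
    model. Calls acute respiratory infection (ARI) episodes from daily
    A/B-symptom diaries, computes diary completeness and cumulative
    infection counts, and fits adjusted linear and Poisson regressions of
    infection counts on standardized repertoire metrics. A synthetic-data
    module simulates repertoires, diaries and covariates with known ground
    truth so every stage of the pipeline can be validated without cohort
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
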