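Package: lignoReg
Title: Regulon Classification and Secretome Comparison for Fungal
    Lignocellulolytic CAZymes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers how carbohydrate-active enzyme (CAZyme) genes of a
    lignocellulolytic fungus are regulated from a knockout-by-carbon-source
    induction transcriptome design. Converts read counts to RPKM, calls
    significant induction against a glucose baseline with a
    max-over-timepoints rule, classifies genes into five regulatory groups
    (carbon-starvation controlled, regulator-specific, other-factor specific
    and the two co-controlled groups) from wild-type versus xyr1-knockout
    induction patterns, and derives the absolutely regulator-controlled set
    and the starvation-within-polysaccharide containment summary. Also
    reproduces a label-free (SWATH-style) secretome comparison between
    cellulose- and xylan-induced cultures (peptide-to-protein abundance,
    median normalization, relative abundance with a high-abundance flag,
    fold-enrichment calls and functional-group summaries) and small
    enzymology statistics. A negative-binomial synthetic-data generator with
    planted regulatory architecture makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
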