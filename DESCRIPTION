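Package: npnet
Title: Nitrogen-Phosphorus Coupling Classification and Signed Co-Occurrence
    Networks for Soil Microbial Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers which soil microbial taxa couple nitrogen (N) and
    phosphorus (P) cycling from amplicon count tables (16S, ITS, phoD) and
    seven soil nutrient-cycling variables. Sites are labelled N-P coupled or
    decoupled from stoichiometric ratios (TN/TP and net N mineralization over
    available P); taxa are labelled coupled or decoupled from sign-consistent
    Bonferroni-corrected Pearson correlations with the N- and P-cycling
    variable families; paired signed co-occurrence networks are built from
    FDR-filtered pairwise correlations, with connectance, positive:negative
    edge ratios, and composite-score keystone taxa. Includes averaged
    rarefaction and abundance/prevalence filtering of feature tables, and a
    synthetic community generator with planted taxon-nutrient correlations
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
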