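Package: ssunovel
Title: Phylogenetic Novelty Detection in SSU rRNA Microbiome Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and ranks phylogenetically novel clades in small-subunit
    rRNA gene amplicon surveys. OTU tables (BIOM v1.0 JSON or tab-separated)
    are filtered for OTUs unclassified at a chosen taxonomic rank, screened
    for sequence artifacts, and placed on a reference-seeded phylogeny.
    Maximal monophyletic clades consisting entirely of unclassified query
    OTUs are delimited, scored by abundance-weighted mean patristic distance
    to the nearest taxonomic reference, and ranked by combined novelty and
    abundance. Per-clade alignments, position frequency profiles, bubble-plot
    summaries, and a synthetic fixture generator with planted novel clades
    are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    biomformat,
    ggplot2,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
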