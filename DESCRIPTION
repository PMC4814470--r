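Package: spacerscope
Title: CRISPR Spacer Repertoire Profiling from Repeat-Anchored Amplicons
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A pipeline for profiling CRISPR spacer repertoires in
    environmental samples from amplicon sequencing anchored on a direct
    repeat. Extracts spacers from repeat-flanked reads with mismatch-tolerant
    repeat matching, clusters them into groups of biologically similar
    sequences under a fixed substitution radius, estimates spacer richness
    (Chao1, ACE) and library coverage, compares spacer repertoires across
    sampling sites, detects self-complementary spacers and internal direct
    repeat variants, scans target sequences for protospacers under a
    mismatch bound, and infers protospacer adjacent motifs (PAMs) from
    protospacer flanks. A fully ground-truthed synthetic community
    generator supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
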