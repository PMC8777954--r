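Package: phagenet
Title: Defense Systems, CRISPR Spaceromes and Virus-Host Networks from
    Assembled Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Interpretation layer for assembled multi-community metagenomes:
    calls antiphage defense systems and defense islands from per-ORF HMM
    profile hits, quantifies them with a depth- and library-size-normalized
    weight, builds non-redundant CRISPR spacer and viral-contig sets by
    greedy incremental clustering, finds protospacers with a short-query
    seed-and-extend matcher and extracts flanking PAM dinucleotides, and
    assembles a bipartite community-community virus-host interaction
    network. Ships a synthetic-community generator with planted ground
    truth so the whole pipeline is testable end-to-end without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
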