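Package: circontig
Title: Detection of Complete Circular DNA Elements in Metagenomic Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Post-assembly identification of complete circular DNA elements
    (putative small plasmids) among metagenome or metamobilome contigs.
    Implements terminal-overlap detection and trimming for contigs derived
    from rolling-circle (MDA) amplified templates, junction confirmation by
    paired-end read pairs mapping to opposite contig ends, single-end
    junction-window read-span confirmation, rotation- and strand-invariant
    deduplication of circular sequences, replicon-domain (Pfam) classification
    of elements into putative plasmids, and an in-silico inverse-PCR
    mispriming screen on doubled templates. Ships a synthetic-data generator
    that emulates the sequencing geometry of a plasmid-enriched metamobilome
    so every stage is testable at desk scale with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    withr,
    Biostrings,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
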