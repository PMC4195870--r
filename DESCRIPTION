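Package: strscreen
Title: Polymorphic Microsatellite Marker Discovery from Assemblies and
    Pooled-Library Variant Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Screens a draft genome assembly for perfect short tandem
    repeats (STRs, unit sizes 2-5 bp) and intersects them with indel
    polymorphisms called from barcoded population sequencing pools to
    identify STR loci that are already known to vary in the target
    populations. Each surviving locus is classified per population as
    polymorphic or fixed from pooled allele depths, filtered for
    primer-design suitability (motif size, variant quality, N-free
    flanks), ranked by repeat count, and written as primer-ready FASTA
    records carrying 300 bp of flanking sequence. Includes a synthetic
    genome and VCF simulator with a known truth table for end-to-end
    validation, and a command-line interface with scan, discover and
    simulate subcommands.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
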