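Package: strainpaint
Title: Variant Triage, Private-Variant Cataloging and Windowed Ancestry
    Painting for Inbred Mouse Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-alignment analyses for whole-genome sequencing of
    wild-derived inbred mouse strains: hard filtering of candidate SNV and
    short-indel calls on depth, mapping quality, alternate-allele support,
    indel proximity and homozygosity; classification of passing variants as
    private to a strain, shared exclusively between two strains, or
    previously known in a strain panel, with transition:transversion
    summaries; outgroup-polarized local-ancestry painting of fixed-width
    genomic windows by exclusive derived-allele sharing with subspecies
    representatives; and windowed read-depth utilities covering depth
    normalization, genetic-sex inference from the X:autosome depth ratio,
    callable-genome fractions, copy-number screening and a
    centromere-proximal check for Robertsonian-fusion chromosomes.  A fully
    deterministic synthetic-data generator emits variant panels with a known
    ancestry mosaic, known privacy categories and depth tracks with known
    sex and injected copy-number events, so the whole pipeline is testable
    end to end against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    vcfR,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
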