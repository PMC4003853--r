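Package: osdhaplomap
Title: Haplotype Mapping from Observed Strain Differences in Inbred Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Distinguishes identity-by-descent genome segments from
    divergent-ancestry segments between closely related inbred strains using
    the windowed density of homozygous sequence differences (Observed Strain
    Differences, OSD). Per-window OSD values are smoothed with a binned
    Gaussian kernel density estimate, a Polymorphism Enrichment Threshold
    (PET) is located at the first density valley, and contiguous supra-PET
    windows are merged into divergent haplotype blocks. Includes QTL
    fine-mapping by block intersection, genotyping-panel block comparison,
    variant-consequence filtering, Fisher exact enrichment across
    phenotype-grouped strain panels, and a mosaic-genome simulator for
    validation at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    KernSmooth,
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
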