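Package: breedbox
Title: Embedded Breeding-Program Data Management and Genomic Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale digital ecosystem for plant breeding programs:
    a single-file store of germplasm accessions with synonyms and passport
    properties, breeding programs, locations, users and roles; approximate
    string matching for germplasm name resolution; typed lists, saved
    datasets and a faceted dimension-intersection query engine; phenotyping
    trials with statistical design generation (alpha lattice, lattice,
    augmented, split-plot, partially replicated and Westcott designs),
    field coordinates, plant and tissue entries, ontology-validated
    phenotype collection-file round-tripping; crossing experiments with
    typed crosses, cross properties, families and automatic pedigrees;
    genotyping protocols with plate tracking, VCF-backed dosage storage,
    genomic relationship matrices (VanRaden method 1) and VCF export; and
    the analyses such platforms expose: trait summaries, robust outlier
    flagging, range filtering, correlations, adjusted means, broad-sense
    heritability, GBLUP breeding values and selection indices. A
    deterministic synthetic breeding-program simulator with known variance
    components and breeding values supports testing end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
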