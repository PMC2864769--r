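Package: eqmatrix
Title: Entity-Quality Annotation of Character-by-Taxon Matrices
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Headless curation toolkit for ontology-backed Entity-Quality (EQ)
    phenotype annotation of phylogenetic character-by-taxon matrices. Parses
    OBO-format ontologies (anatomy, quality, taxonomy, units, museum
    collections) with filtered term search and transitive-closure reasoning;
    imports taxa, characters, states and matrices from NEXUS; models EQ
    phenotypes including post-composed entities, counts, measurements and
    voucher specimens; validates annotations against the loaded ontologies;
    serializes datasets as NeXML with Dublin Core, Darwin Core and PhenoXML
    metadata and reads them back losslessly; and derives taxon-to-phenotype
    "exhibits" annotations from the matrix for ontology-closure queries.
    Includes a command-line interface and a deterministic synthetic fixture
    generator for fully offline testing.
License: MIT
Encoding: UTF-8
Imports:
    xml2,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
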