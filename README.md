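# eqmatrix

Ontology-backed Entity–Quality annotation of phylogenetic
character-by-taxon matrices, headless.

## The problem

Systematists describe morphological variation as free-text *characters*
("opercle shape") with *character states* ("triangular", "round"), coded
numerically in a character-by-taxon matrix. That prose is unambiguous to a
trained reader and opaque to a computer: nothing links "opercle shape" in
one monograph to "operculum form" in another, so phenotype data cannot be
compared across studies or connected to the mutant-phenotype data of model
organisms.

The Entity–Quality (EQ) formalism fixes this by re-expressing each state
as one or more statements **E** (an anatomical entity term, e.g. *opercle*,
TAO:0000250) plus **Q** (a quality term from a generic quality ontology,
e.g. *triangular*, PATO:0001875), optionally with a related entity **RE**
(for relational qualities such as *fused_with*) and a literal count **C**
or measurement with unit. Because value qualities are subtypes of
attribute qualities (*triangular* `is_a` *shape*), the character's
attribute needs no separate encoding, and because the terms live in
ontologies, queries can exploit `is_a`/`part_of` closure: annotations on
the *dorsal arrector* and on the *posterior pectoral-spine serrae* are
both retrievable as pectoral-fin phenotypes.

`eqmatrix` is an R toolkit for curating such annotations end to end:

* **ontology** — parse OBO 1.2 files, merge multiple sources, ranked
  autocomplete-style term search with namespace/subset/ancestor filters,
  and transitive-closure reasoning (`parse_obo`, `merge_ontologies`,
  `search_terms`, `ancestors`);
* **data model** — EQ phenotypes with post-composed entities
  (`compose(process, part_of epiotic)` for an "epiotic process"), count
  ranges, measurements, voucher specimens, taxa with
  publication/valid/matrix names, and ontology-aware validation
  (`phenotype`, `compose`, `validate_dataset`, `classify_state`);
* **NEXUS import** — taxa, characters, CHARSTATELABELS and matrices
  (with polymorphic, missing and gap cells, interleaving) from the
  dialect emitted by matrix editors (`parse_nexus`, `nexus_to_dataset`);
* **NeXML I/O** — the native file format: deterministic NeXML with
  Dublin Core / Darwin Core / RDF-Schema metadata and EQ phenotypes
  embedded as PhenoXML, read back losslessly (`write_nexml`,
  `read_nexml`);
* **queries** — matrix-derived taxon→phenotype "exhibits" triples and
  entity queries under ontology closure (`exhibits`,
  `phenotypes_of_entity`, `summarize_datasets`);
* **CLI + fixtures** — `convert`, `validate`, `query`, `stats` and
  `fixtures` verbs (`eq_main`, `inst/cli/eqmatrix.R`) and a deterministic
  synthetic fixture bundle for fully offline work
  (`generate_fixtures`).

## Worked example

The classic composite state — a catfish caudal fin "forked with pointed
lobes" — needs three EQ statements:

```r
library(eqmatrix)
fx <- fixture_ids()                 # CURIE shorthands for the toy ontologies

st <- eq_state("0", "forked with pointed lobes")
st <- attach_phenotype(st, phenotype(fx$caudal_fin, fx$bifurcated))
st <- attach_phenotype(st, phenotype(fx$upper_lobe,  fx$sharp))
st <- attach_phenotype(st, phenotype(fx$lower_lobe,  fx$sharp))

print(st$phenotypes[[1]])
#> <eq_phenotype> E: TAO:0100007, Q: PATO:0001784

classify_state(st, fixture_quality())
#> [1] "composite" "monadic"
```

A fully annotated example dataset ships with the package; deriving the
taxon→phenotype links from its matrix and querying them under part-of
closure:

```r
onto <- fixture_merged_ontology()
ds   <- fixture_examples_dataset()
print(ds)
#> <eq_dataset> 3 taxa x 8 characters; 22 EQ phenotype(s) attached

tr <- exhibits(ds)                  # one triple per (cell, state, phenotype)
length(tr)
#> [1] 27

hits <- phenotypes_of_entity(tr, onto, fx$pectoral_fin, include_parts = TRUE)
triples_to_table(hits)[, c("taxon", "character", "state", "entity", "quality")]
#>                     taxon character state      entity      quality
#> 1     Ictalurus punctatus         6     0 TAO:0100004 PATO:0001865
#> 2     Ictalurus punctatus         7     0 TAO:0100006 PATO:0001419
#> 3          Noturus flavus         6     1 TAO:0100004 PATO:0001875
#> 4          Noturus flavus         7     1 TAO:0100006 PATO:0000070
#> 5 Gonorynchus gonorynchus         6     0 TAO:0100004 PATO:0001865
#> 6 Gonorynchus gonorynchus         7     0 TAO:0100006 PATO:0001419
```

No triple mentions the pectoral fin itself: the dorsal arrector
(TAO:0100004) and the pectoral-spine serrae (TAO:0100006) are retrieved
because the anatomy ontology knows they are *parts of* the fin. With
`include_parts = FALSE` the same query returns nothing.

Round-tripping through the native format is lossless and deterministic:

```r
x <- write_nexml(ds)
dataset_equal(ds, read_nexml(x))
#> [1] TRUE
```

From a shell, the same pipeline:

```sh
Rscript inst/cli/eqmatrix.R fixtures /tmp/fix
Rscript inst/cli/eqmatrix.R convert /tmp/fix/matrix.nex /tmp/fix/config.yaml /tmp/out.xml
Rscript inst/cli/eqmatrix.R query /tmp/fix/config.yaml TAO:0100003 /tmp/fix/examples.xml
```

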