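---
title: "Entity–Quality annotation of character matrices: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entity–Quality annotation of character matrices: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eqmatrix)
```

## The annotation model

A curated study is an `eq_dataset`: publication metadata (curators,
citation, notes), an ordered list of taxa, an ordered list of numbered
characters each carrying symbolically coded states, and the
character-by-taxon matrix. Annotation attaches *EQ phenotypes* to states:
each phenotype is an entity (an anatomy-ontology term, or a
post-composition such as *process* `part_of` *epiotic*), a quality term,
and optionally a related entity, an integer count range, or a decimal
measurement with a unit term.

The model leans on two structural facts about quality ontologies. First,
value qualities subtype attribute qualities (*triangular* `is_a`
*shape*), so the attribute of a traditional character description is
implicit in the quality's position in the hierarchy and is never stored.
Second, qualities partition into those inhering in a single entity and
those relating two entities; `classify_state()` uses descent from these
two roots — together with the presence of a related entity, a count, a
measurement, and the number of phenotypes on the state — to sort states
into the four categories curators recognise: *monadic*, *relational*,
*quantitative*, *composite*. A state may be several at once, and the
categories of a multi-phenotype state are exactly the union of its
phenotypes' categories plus *composite*.

The matrix is not annotated directly. `exhibits()` derives the
taxon-to-phenotype links mechanically: every non-missing, non-gap cell
links its taxon to every phenotype of the state(s) it codes. This is the
step that turns one curation pass over states into per-taxon annotations
without further curator effort, and it is deliberately a pure function of
the dataset so it can be re-derived at any time.

## Ontology handling

Only the OBO 1.2 flat-file syntax is read (`[Term]` stanzas; `id`,
`name`, `namespace`, `def`, `synonym`, `subset`, `is_a`, `relationship`,
`is_obsolete`, `replaced_by`). OWL input is out of scope: OBO remains the
dominant distribution format for the anatomy/quality/taxonomy ontologies
this tool targets. Unknown tags are ignored with a notice rather than an
error, because real ontology files carry many housekeeping tags
irrelevant here. Edge targets missing from the file produce warnings, not
errors: merged multi-ontology configurations routinely cross-reference.

Obsolete terms are kept in the graph but excluded from search. This is a
deliberate asymmetry: a stored annotation pointing at an obsolete term
must be *flaggable* (validation reports it, with the `replaced_by` hint)
rather than silently unresolvable, but no new annotation should be
offered an obsolete suggestion.

`search_terms()` ranks case-insensitively in five tiers — exact name,
name prefix, synonym prefix, name substring, synonym substring — with
ties broken lexicographically by term id, making results deterministic.
Synonym scopes (EXACT/BROAD/...) are parsed and preserved but do not
influence ranking; no published ranking rule exists for the original
interactive tool, so the tiering here is this package's own contract.
Case folding is plain `tolower()`; no further Unicode normalization is
attempted.

`ancestors()` is plain reachability over the union of the selected
relations: a chain mixing `is_a` and `part_of` counts as a part-ancestor
whenever both relations are selected. There is no reasoner beyond this
relation-chain closure.

## NEXUS import

The reader targets the dialect emitted by matrix editors: TAXA /
CHARACTERS / DATA blocks, DIMENSIONS, FORMAT (SYMBOLS, MISSING, GAP,
INTERLEAVE), TAXLABELS, CHARSTATELABELS (or CHARLABELS + STATELABELS) and
MATRIX. Keywords are case-insensitive, bracketed comments (including
nested ones) are stripped outside quotes, quoted labels are kept
verbatim, and underscores in unquoted labels become spaces. Other blocks
(TREES, ASSUMPTIONS, editor-private blocks) are skipped with a notice.
State symbols are single characters; multi-character state tokens are
rejected, matching the universal `0`/`1`/`a`/`b` coding practice.

Two choices deserve a note. Matrix rows are parsed line-wise — a row (or,
under INTERLEAVE, a row segment) is one line, with the taxon label first.
This is what every matrix editor writes; a non-interleaved row wrapped
across lines is not supported and surfaces as a row-length error naming
the line. And where state labels conflict with the SYMBOLS order, labels
are aligned positionally with SYMBOLS and extras are dropped with a
warning; characters with no labels at all get one unlabeled state per
symbol observed in their column.

Imported datasets have empty phenotype lists everywhere — annotation is
downstream work — so validation reports unannotated states as warnings,
never errors: partially curated files are a legitimate working state.

## The NeXML dialect

NeXML is the native format. The skeleton is standard
(`otus`/`otu`, `characters`/`format`/`states`/`state`,
`matrix`/`row`/`cell`); annotations ride on RDFa-style `meta` elements:
literal values in a `content` attribute, resource values in an `href`
attribute, and phenotype blocks as embedded XML children. The metadata
vocabulary is fixed: `dc:creator`, `dc:references`, `dc:description` at
the document level; `dwc:taxonID`, `ps:hasMatrixName`,
`dwc:individualID` (a blank resource node nesting `dwc:collectionID` and
`dwc:catalogNumber` per voucher specimen), `rdfs:comment` and
`ps:inFigure` on taxa; comments and figures likewise on characters and
states; and `ps:describesPhenotype` on states, whose payload is a
PhenoXML `phenotype` element holding one `phenotype_character` per EQ
statement with `bearer`, `quality` and optional `related_entity`
children, each wrapping a `typeref`. Term ids appear as CURIEs in
`typeref` `about` attributes and as OBO PURLs
(`http://purl.obolibrary.org/obo/PREFIX_LOCAL`) in resource-valued
metadata. The publication taxon name is the `otu` label — the natural
NeXML home, as no metadata identifier exists for it.

Several details of the embedded PhenoXML have no published normative
attribute syntax, so this package defines a documented dialect and
guarantees it round-trips: post-composition differentia are `qualifier`
children of the genus `typeref` (relation id attribute, filler as a
nested `typeref`); count ranges are `count_min`/`count_max` integer
attributes on the `quality` element; measurements are a verbatim decimal
string attribute plus a `unit` CURIE attribute. Measurements are kept as
strings end to end deliberately — re-parsing a decimal through floating
point could change the bytes on the next write. Count ranges render with
an ASCII hyphen (`40-42`) rather than a typographic en-dash, for format
robustness.

Writing is deterministic: the same dataset yields a byte-identical
document (fixed element order, fixed prefix declarations, ids generated
positionally). `read_nexml()` is the full inverse; unrecognized metadata
properties are warned about and preserved verbatim in an `extras` field
that is re-emitted on the next write, so foreign annotations survive an
edit cycle. Matrix cells reference state ids; polymorphic combinations,
missing, and gap cells get per-character `polymorphic_state_set` /
`uncertain_state_set` elements, so every cell of a complete matrix is
explicit in the file. Polymorphic cells are modelled as symbol *sets*
(canonically sorted), and their semantics downstream is the permissive
one: the taxon is linked to the phenotypes of *every* listed symbol,
flagged `polymorphic` in the derived triples, since no published rule
exists. Schema validation against the NeXML XSD is not performed (the
schema is not bundled); structural well-formedness and the round-trip
property are what the tests enforce.

## Validation

`validate_dataset()` is pure and returns a data.frame of findings, each
with a severity, a stable code, and a location. Errors (unknown terms,
measurement without unit, matrix rows of the wrong length, cells citing
undefined symbols) block `write_nexml()` when an ontology is supplied;
warnings (obsolete terms, field-filter violations, a related entity
alongside a single-entity quality, a count on a non-count quality,
unannotated states) do not. Field filters mirror the per-field term
filters of interactive curation setups: namespaces, subsets, or an
ancestor constraint per entry field, configured declaratively in the
YAML config.

## Queries

`phenotypes_of_entity()` matches a triple when the phenotype's entity —
the *genus*, for post-compositions — equals the target or has it among
its ancestors via `is_a` (always) and `part_of` (opt-in). Differentia
fillers are deliberately not traversed: a "process that is part of the
epiotic" is a statement about the process, and treating filler mentions
as matches would conflate aboutness with location. Related entities are
likewise not matched. Both are documented extension points rather than
defaults.

## The fixture generator

`generate_fixtures()` emits a deterministic offline bundle: five OBO
files (anatomy with a pectoral-fin and caudal-fin partonomy, qualities,
taxonomy, museum collections, units), a toy NEXUS matrix whose first
character is "opercle shape" with states "triangular"/"round", the fully
annotated examples dataset as NeXML, and a wired-up config. The toy
quality ontology mirrors the real attribute/value structure — *shape*
under *quality of single physical entity*, *fused_with* under *quality
of related physical entities* — but places *count* directly under the
root *quality*. That placement is a fixture design choice: it makes
purely quantitative states classify as exactly `{quantitative}`, keeping
the four canonical worked examples in one category set each, which is
the behaviour curators expect of the category labels.

A handful of real, widely known CURIEs (TAO:0000250 *opercle*,
PATO:0001875 *triangular*, the two PATO quality roots) are reused so the
examples read naturally; all other fixture ids are synthetic. What the
fixtures do **not** emulate: the scale of real ontologies (tens of
thousands of terms), cross-ontology `xref`s, non-trivial synonym scopes
in ranking, taxonomically deep matrices, or historically produced files
from other tools — so green tests here demonstrate contract correctness,
not drop-in byte compatibility with any legacy corpus.

The random generators (`random_ontology`, `random_dataset`,
`random_nexus`, `random_postcomp`) draw from the current RNG state so
test files control them with explicit seeds. `random_ontology` builds
DAGs by construction (edges always point to lower-numbered terms).

## Test problem sizes

Property tests run at sizes chosen to exercise the combinatorics while
keeping the whole suite interactive: 100 random datasets for NeXML
round-trip identity, 50 random DAGs of 20–200 terms for closure oracles
against an independent breadth-first search, randomized NEXUS files up
to 50 taxa × 100 characters for cell conservation against a text-scan
oracle, and 100 random post-compositions for render/parse identity. The
acceptance script re-runs the same computations from scratch under a
caller-supplied seed.

## Known limitations

* OBO 1.2 only; no OWL, no ontology editing, no reasoning beyond
  relation-chain closure.
* NEXUS: standard (discrete) characters only — no continuous characters,
  step matrices, or tree blocks; NEXUS export is intentionally absent
  (NeXML is the native output).
* The PhenoXML attribute dialect for qualifiers/counts/measurements is
  round-trip-safe but not certified byte-compatible with files written
  by historical desktop curation tools.
* Higher-taxon matrix rows are annotated as given; expanding a
  genus-level row to its member species is left to consumers.
* No persistent knowledgebase or cross-dataset taxonomic reconciliation
  beyond shared valid-taxon identifiers; corpus-scale annotation counts
  are out of scope and summaries are instead verified additively over
  fixtures.
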