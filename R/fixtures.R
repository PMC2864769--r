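#' @title Synthetic fixtures: toy ontologies, matrices and datasets
#' @name fixtures
#' @description
#' Deterministic, fully offline stand-ins for the real curation inputs: a
#' toy fish anatomy ontology with a pectoral-fin partonomy, a toy quality
#' ontology mirroring the attribute/value hierarchy of PATO (value
#' qualities such as *triangular* are subtypes of attribute qualities
#' such as *shape*, under single-entity and relational quality roots), a
#' toy taxonomy, a museum-collection code list, a unit ontology, a toy
#' NEXUS matrix, and fully annotated example datasets covering the four
#' character categories (monadic, relational, quantitative, composite)
#' plus a post-composed entity. All identifiers are synthetic except the
#' handful of widely known anatomy/quality ids reused verbatim so the
#' examples read naturally. Also provides seeded random generators used
#' by the property-based tests.
NULL

# -- term id shorthands used across fixtures and examples ----------------
fx <- list(
  # anatomy
  structure_ = "TAO:0100001", fin = "TAO:0100002",
  pectoral_fin = "TAO:0100003", dorsal_arrector = "TAO:0100004",
  pectoral_spine = "TAO:0100005", spine_serrae = "TAO:0100006",
  caudal_fin = "TAO:0100007", upper_lobe = "TAO:0100008",
  lower_lobe = "TAO:0100009", muscle = "TAO:0100010",
  hypural = "TAO:0100011", hypural2 = "TAO:0100012",
  hypural3 = "TAO:0100013", bone = "TAO:0100014",
  vertebra = "TAO:0100015", epiotic = "TAO:0100016",
  skull = "TAO:0100017", process = "TAO:0100018",
  opercle = "TAO:0000250",
  # qualities
  quality = "PATO:0000001", monadic_root = "PATO:0001237",
  relational_root = "PATO:0001238", shape = "PATO:0000052",
  triangular = "PATO:0001875", round = "PATO:0001865",
  bifurcated = "PATO:0001784", sharp = "PATO:0001419",
  pointed = "PATO:0002258", fused_with = "PATO:0000642",
  separated_from = "PATO:0001110", count = "PATO:0000070",
  # taxa
  teleostei = "TTO:0000001", danio = "TTO:0000002",
  siluriformes = "TTO:0001001", ictalurus = "TTO:0001002",
  noturus = "TTO:0001003", gonorynchus = "TTO:0001004",
  # collections and units
  ummz = "COLLECTION:UMMZ", ansp = "COLLECTION:ANSP",
  usnm = "COLLECTION:USNM",
  unit_root = "UO:0000000", millimeter = "UO:0000016")

#' Term-id shorthands for the fixture vocabulary
#' @return named list of CURIEs.
#' @export
fixture_ids <- function() fx

build_fixture_ontology <- function(rows, namespace) {
  terms <- list()
  es <- character(); ep <- character(); eo <- character()
  for (r in rows) {
    terms[[r$id]] <- eq_term(r$id, r$name, namespace = namespace,
                             synonyms = r$synonyms %||% character(),
                             subsets = r$subsets %||% character(),
                             obsolete = isTRUE(r$obsolete),
                             replaced_by = r$replaced_by)
    for (e in r$edges %||% list()) {
      es <- c(es, r$id); ep <- c(ep, e[[1]]); eo <- c(eo, e[[2]])
    }
  }
  new_ontology(terms, data.frame(subject = es, predicate = ep, object = eo,
                                 stringsAsFactors = FALSE),
               sources = paste0("fixture:", namespace))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Toy anatomy ontology (partonomy around the pectoral and caudal fins)
#' @return an `eq_ontology` with namespace "teleost_anatomy".
#' @export
fixture_anatomy <- function() {
  isa <- function(x) list("is_a", x)
  po <- function(x) list("part_of", x)
  build_fixture_ontology(list(
    list(id = fx$structure_, name = "anatomical structure"),
    list(id = fx$fin, name = "fin", edges = list(isa(fx$structure_))),
    list(id = fx$pectoral_fin, name = "pectoral fin",
         edges = list(isa(fx$fin))),
    list(id = fx$muscle, name = "muscle", edges = list(isa(fx$structure_))),
    list(id = fx$dorsal_arrector, name = "dorsal arrector",
         synonyms = "arrector dorsalis",
         edges = list(isa(fx$muscle), po(fx$pectoral_fin))),
    list(id = fx$pectoral_spine, name = "pectoral fin spine",
         edges = list(isa(fx$structure_), po(fx$pectoral_fin))),
    list(id = fx$spine_serrae, name = "posterior pectoral-spine serrae",
         edges = list(isa(fx$structure_), po(fx$pectoral_spine))),
    list(id = fx$caudal_fin, name = "caudal fin",
         edges = list(isa(fx$fin))),
    list(id = fx$upper_lobe, name = "caudal fin upper lobe",
         edges = list(isa(fx$structure_), po(fx$caudal_fin))),
    list(id = fx$lower_lobe, name = "caudal fin lower lobe",
         edges = list(isa(fx$structure_), po(fx$caudal_fin))),
    list(id = fx$bone, name = "bone", edges = list(isa(fx$structure_))),
    list(id = fx$hypural, name = "hypural", edges = list(isa(fx$bone))),
    list(id = fx$hypural2, name = "hypural 2",
         edges = list(isa(fx$hypural))),
    list(id = fx$hypural3, name = "hypural 3",
         edges = list(isa(fx$hypural))),
    list(id = fx$vertebra, name = "vertebra", edges = list(isa(fx$bone))),
    list(id = fx$skull, name = "skull", edges = list(isa(fx$structure_))),
    list(id = fx$epiotic, name = "epiotic",
         edges = list(isa(fx$bone), po(fx$skull))),
    list(id = fx$process, name = "process",
         edges = list(isa(fx$structure_))),
    list(id = fx$opercle, name = "opercle", synonyms = "gill cover",
         subsets = "toy_slim",
         edges = list(isa(fx$bone)))
  ), namespace = "teleost_anatomy")
}

#' Toy quality ontology mirroring the PATO attribute/value hierarchy
#'
#' Value qualities (*triangular*, *round*, ...) subtype the attribute
#' quality *shape* under the single-entity quality root; relational
#' qualities (*fused_with*, *separated_from*) sit under the
#' related-entities root. The *count* quality hangs directly under the
#' root *quality* so quantitative states do not also classify as
#' monadic.
#'
#' @return an `eq_ontology` with namespace "quality".
#' @export
fixture_quality <- function() {
  isa <- function(x) list("is_a", x)
  build_fixture_ontology(list(
    list(id = fx$quality, name = "quality"),
    list(id = fx$monadic_root, name = "quality of single physical entity",
         edges = list(isa(fx$quality))),
    list(id = fx$relational_root,
         name = "quality of related physical entities",
         edges = list(isa(fx$quality))),
    list(id = fx$shape, name = "shape",
         edges = list(isa(fx$monadic_root))),
    list(id = fx$triangular, name = "triangular",
         synonyms = "three-sided", edges = list(isa(fx$shape))),
    list(id = fx$round, name = "round", edges = list(isa(fx$shape))),
    list(id = fx$bifurcated, name = "bifurcated", synonyms = "forked",
         edges = list(isa(fx$shape))),
    list(id = fx$sharp, name = "sharp", edges = list(isa(fx$shape))),
    list(id = fx$pointed, name = "pointed", edges = list(isa(fx$sharp))),
    list(id = fx$fused_with, name = "fused with",
         edges = list(isa(fx$relational_root))),
    list(id = fx$separated_from, name = "separated from",
         edges = list(isa(fx$relational_root))),
    list(id = fx$count, name = "count", edges = list(isa(fx$quality)))
  ), namespace = "quality")
}

#' Toy taxonomy ontology
#' @return an `eq_ontology` with namespace "taxonomy".
#' @export
fixture_taxonomy <- function() {
  isa <- function(x) list("is_a", x)
  build_fixture_ontology(list(
    list(id = fx$teleostei, name = "Teleostei"),
    list(id = fx$danio, name = "Danio rerio",
         edges = list(isa(fx$teleostei))),
    list(id = fx$siluriformes, name = "Siluriformes",
         edges = list(isa(fx$teleostei))),
    list(id = fx$ictalurus, name = "Ictalurus punctatus",
         edges = list(isa(fx$siluriformes))),
    list(id = fx$noturus, name = "Noturus flavus",
         edges = list(isa(fx$siluriformes))),
    list(id = fx$gonorynchus, name = "Gonorynchus gonorynchus",
         edges = list(isa(fx$teleostei)))
  ), namespace = "taxonomy")
}

#' Toy museum-collection code list
#' @return an `eq_ontology` with namespace "museum_collection".
#' @export
fixture_collections <- function() {
  build_fixture_ontology(list(
    list(id = fx$ummz, name = "University of Michigan Museum of Zoology"),
    list(id = fx$ansp, name = "Academy of Natural Sciences Philadelphia"),
    list(id = fx$usnm, name = "National Museum of Natural History")
  ), namespace = "museum_collection")
}

#' Toy unit ontology
#' @return an `eq_ontology` with namespace "unit".
#' @export
fixture_units <- function() {
  isa <- function(x) list("is_a", x)
  build_fixture_ontology(list(
    list(id = fx$unit_root, name = "unit"),
    list(id = fx$millimeter, name = "millimeter", synonyms = "mm",
         edges = list(isa(fx$unit_root)))
  ), namespace = "unit")
}

#' All fixture ontologies merged
#' @return an `eq_ontology`.
#' @export
fixture_merged_ontology <- function() {
  merge_ontologies(list(fixture_anatomy(), fixture_quality(),
                        fixture_taxonomy(), fixture_collections(),
                        fixture_units()))
}

#' Toy NEXUS matrix text
#'
#' Three taxa by two characters; the first character is "opercle shape"
#' with states "triangular" and "round".
#'
#' @return a single NEXUS string.
#' @export
fixture_nexus_text <- function() {
  paste(
    "#NEXUS",
    "BEGIN TAXA;",
    "  DIMENSIONS NTAX=3;",
    "  TAXLABELS 'Danio rerio' Ictalurus_punctatus Noturus_flavus;",
    "END;",
    "BEGIN CHARACTERS;",
    "  DIMENSIONS NCHAR=2;",
    "  FORMAT DATATYPE=STANDARD SYMBOLS=\"0 1 2\" MISSING=? GAP=-;",
    "  CHARSTATELABELS",
    "    1 'opercle shape' / triangular round,",
    "    2 'caudal fin shape' / 'forked with pointed lobes'",
    "      'forked with rounded lobes' 'scarcely emarginate to rounded';",
    "  MATRIX",
    "    'Danio rerio'        00",
    "    Ictalurus_punctatus  1{12}",
    "    Noturus_flavus       ?1",
    "  ;",
    "END;",
    sep = "\n")
}

#' Fully annotated example dataset
#'
#' One dataset exercising every character category: a monadic caudal-fin
#' shape character, a relational hypural-fusion character, a
#' quantitative vertebral-count character, a composite catfish
#' caudal-fin character whose state 0 carries three EQ phenotypes, a
#' post-composed "epiotic process" character, and two pectoral-fin
#' characters (on the dorsal arrector and the pectoral-spine serrae)
#' supporting part-closure queries.
#'
#' @return an `eq_dataset` that validates cleanly (warnings only)
#'   against [fixture_merged_ontology()].
#' @export
fixture_examples_dataset <- function() {
  ep_process <- compose(fx$process,
                        list(list(relation = "part_of",
                                  filler = fx$epiotic)))
  chars <- list(
    eq_character(1, "caudal fin margin", states = list(
      eq_state("0", "deeply forked", phenotypes = list(
        phenotype(fx$caudal_fin, fx$bifurcated))),
      eq_state("1", "rounded", phenotypes = list(
        phenotype(fx$caudal_fin, fx$round))))),
    eq_character(2, "hypural 2 and hypural 3", states = list(
      eq_state("0", "fused", phenotypes = list(
        phenotype(fx$hypural2, fx$fused_with,
                  related_entity = fx$hypural3))),
      eq_state("1", "separate", phenotypes = list(
        phenotype(fx$hypural2, fx$separated_from,
                  related_entity = fx$hypural3))))),
    eq_character(3, "number of vertebrae", states = list(
      eq_state("0", "40-42", phenotypes = list(
        phenotype(fx$vertebra, fx$count, count = count_range(40, 42)))),
      eq_state("1", "43", phenotypes = list(
        phenotype(fx$vertebra, fx$count, count = count_range(43)))),
      eq_state("2", "44-45", phenotypes = list(
        phenotype(fx$vertebra, fx$count, count = count_range(44, 45)))))),
    eq_character(4, "caudal fin shape", states = list(
      eq_state("0", "forked with pointed lobes", phenotypes = list(
        phenotype(fx$caudal_fin, fx$bifurcated),
        phenotype(fx$upper_lobe, fx$sharp),
        phenotype(fx$lower_lobe, fx$sharp))),
      eq_state("1", "forked with rounded lobes", phenotypes = list(
        phenotype(fx$caudal_fin, fx$bifurcated),
        phenotype(fx$upper_lobe, fx$round),
        phenotype(fx$lower_lobe, fx$round))),
      eq_state("2", "scarcely emarginate to rounded", phenotypes = list(
        phenotype(fx$caudal_fin, fx$round))))),
    eq_character(5, "epiotic process", states = list(
      eq_state("0", "pointed", phenotypes = list(
        phenotype(entity_ref(composed = ep_process), fx$pointed))),
      eq_state("1", "bifurcated distally", phenotypes = list(
        phenotype(entity_ref(composed = ep_process), fx$bifurcated))))),
    eq_character(6, "dorsal arrector form", states = list(
      eq_state("0", "expanded", phenotypes = list(
        phenotype(fx$dorsal_arrector, fx$round))),
      eq_state("1", "not expanded", phenotypes = list(
        phenotype(fx$dorsal_arrector, fx$triangular))))),
    eq_character(7, "posterior pectoral-spine serrae", states = list(
      eq_state("0", "sharp", phenotypes = list(
        phenotype(fx$spine_serrae, fx$sharp))),
      eq_state("1", "absent", comment = "serrae lacking entirely",
               phenotypes = list(
        phenotype(fx$spine_serrae, fx$count,
                  count = count_range(0)))))),
    eq_character(8, "opercle shape", states = list(
      eq_state("0", "triangular", phenotypes = list(
        phenotype(fx$opercle, fx$triangular))),
      eq_state("1", "round", phenotypes = list(
        phenotype(fx$opercle, fx$round))))))
  taxa <- list(
    taxon("Ictalurus punctatus", valid_taxon = fx$ictalurus,
          specimens = list(specimen(fx$ummz, "177000")),
          figures = "Fig. 2"),
    taxon("Noturus flavus", valid_taxon = fx$noturus,
          matrix_name = "Noturus",
          specimens = list(specimen(fx$ansp, "23511"),
                           specimen(fx$usnm, "104051"))),
    taxon("Gonorynchus gonorynchus", valid_taxon = fx$gonorynchus,
          comment = "examined from literature"))
  s <- function(x) cell_value("single", x)
  m <- list(
    "Ictalurus punctatus" = list(s("0"), s("0"), s("0"), s("0"), s("0"),
                                 s("0"), s("0"), s("0")),
    "Noturus flavus" = list(s("1"), s("1"),
                            cell_value("polymorphic", c("1", "2")),
                            s("1"), s("1"), s("1"), s("1"), s("1")),
    "Gonorynchus gonorynchus" = list(s("0"), cell_value("missing"),
                                     s("2"), s("2"), cell_value("gap"),
                                     s("0"), s("0"), s("1")))
  eq_dataset(
    curators = c("A. Curator", "B. Annotator"),
    publication = "Example, A. & Example, B. (2009). Phylogeny of toy catfishes. J. Toy Syst. 1:1-10.",
    publication_notes = "Synthetic example dataset for offline testing.",
    taxa = taxa, characters = chars, matrix = m)
}

#' Write the complete fixture bundle to a directory
#'
#' Emits the five fixture ontologies as OBO files, the toy NEXUS matrix,
#' the annotated example dataset as NeXML, and a ready-to-use
#' configuration file wiring them together. Output is deterministic:
#' the same seed always produces a byte-identical bundle.
#'
#' @param seed integer seed (reserved for future randomized bundle
#'   content; current bundle content is fully deterministic).
#' @param dir output directory, created if needed.
#' @return invisibly, a character vector of the files written.
#' @export
generate_fixtures <- function(seed = 1L, dir) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character()
  emit <- function(name, text) {
    p <- file.path(dir, name)
    writeLines(text, p, sep = "")
    files <<- c(files, p)
  }
  emit("anatomy.obo", write_obo(fixture_anatomy(),
                                default_namespace = "teleost_anatomy"))
  emit("quality.obo", write_obo(fixture_quality(),
                                default_namespace = "quality"))
  emit("taxonomy.obo", write_obo(fixture_taxonomy(),
                                 default_namespace = "taxonomy"))
  emit("collections.obo", write_obo(fixture_collections(),
                                    default_namespace = "museum_collection"))
  emit("units.obo", write_obo(fixture_units(),
                              default_namespace = "unit"))
  emit("matrix.nex", paste0(fixture_nexus_text(), "\n"))
  emit("examples.xml", write_nexml(fixture_examples_dataset()))
  cfg <- list(
    ontology_sources = list(
      list(path = "anatomy.obo", role = "entity"),
      list(path = "quality.obo", role = "quality"),
      list(path = "taxonomy.obo", role = "taxonomy"),
      list(path = "units.obo", role = "unit"),
      list(path = "collections.obo", role = "collection")),
    field_filters = list(
      entity = list(namespaces = list("teleost_anatomy")),
      quality = list(namespaces = list("quality")),
      related_entity = list(namespaces = list("teleost_anatomy")),
      taxon = list(namespaces = list("taxonomy")),
      unit = list(namespaces = list("unit")),
      collection = list(namespaces = list("museum_collection"))))
  emit("config.yaml", yaml::as.yaml(cfg))
  invisible(files)
}

# ------------------------------------------------------- random generators

#' Random acyclic ontology for property tests
#'
#' Terms `T:0000001..n`; edges always point from a higher-numbered term
#' to a lower-numbered one, so the graph is a DAG by construction.
#'
#' @param n_terms number of terms.
#' @param edge_prob per-pair probability of an edge (thinned for large n).
#' @param relations relation ids to sample edges from.
#' @return an `eq_ontology`.
#' @export
random_ontology <- function(n_terms = 50,
                            edge_prob = min(0.1, 4 / n_terms),
                            relations = c("is_a", "part_of")) {
  ids <- sprintf("T:%07d", seq_len(n_terms))
  terms <- lapply(seq_len(n_terms), function(i) {
    eq_term(ids[i], name = paste("term", i),
            namespace = sample(c("nsA", "nsB"), 1),
            synonyms = if (stats::runif(1) < 0.3)
              paste("syn", i) else character(),
            subsets = if (stats::runif(1) < 0.2) "slim1" else character())
  })
  names(terms) <- ids
  es <- character(); ep <- character(); eo <- character()
  for (i in seq_len(n_terms)) {
    if (i == 1) next
    targets <- which(stats::runif(i - 1) < edge_prob)
    for (t in targets) {
      es <- c(es, ids[i])
      ep <- c(ep, sample(relations, 1))
      eo <- c(eo, ids[t])
    }
  }
  new_ontology(terms,
               data.frame(subject = es, predicate = ep, object = eo,
                          stringsAsFactors = FALSE),
               sources = "random")
}

#' Random post-composition
#' @param ids pool of term ids to draw genus and fillers from.
#' @param depth maximum nesting depth.
#' @return an `eq_postcomp`.
#' @export
random_postcomp <- function(ids, depth = 2) {
  n_diff <- sample(1:2, 1)
  differentia <- lapply(seq_len(n_diff), function(i) {
    filler <- if (depth > 0 && stats::runif(1) < 0.3) {
      random_postcomp(ids, depth - 1)
    } else sample(ids, 1)
    list(relation = sample(c("part_of", "connected_to"), 1),
         filler = filler)
  })
  compose(sample(ids, 1), differentia)
}

random_phenotype <- function(entity_ids, quality_ids, unit_id) {
  e <- if (stats::runif(1) < 0.2) {
    entity_ref(composed = random_postcomp(entity_ids, 1),
               comment = if (stats::runif(1) < 0.3) "pc note" else NULL)
  } else entity_ref(term = sample(entity_ids, 1))
  q <- sample(quality_ids, 1)
  re <- if (stats::runif(1) < 0.3) {
    entity_ref(term = sample(entity_ids, 1))
  } else NULL
  cnt <- if (stats::runif(1) < 0.25) {
    lo <- sample(0:50, 1)
    count_range(lo, lo + sample(0:5, 1))
  } else NULL
  meas <- NULL; unit <- NULL
  if (stats::runif(1) < 0.2) {
    meas <- sprintf("%.2f", stats::runif(1, 0, 100))
    unit <- unit_id
  }
  phenotype(e, q, related_entity = re, count = cnt, measurement = meas,
            unit = unit,
            comment = if (stats::runif(1) < 0.2) "phenotype note" else NULL)
}

#' Random annotated dataset for round-trip and query property tests
#'
#' Draws entity/quality/taxon/collection/unit ids from the fixture
#' ontologies, builds randomized taxa (with optional valid names,
#' matrix names, specimens, comments and figures), characters with
#' two to four states carrying zero to three random phenotypes
#' (including post-compositions, counts and measurements), and a full
#' matrix with single, polymorphic, missing and gap cells.
#'
#' @param n_taxa,n_chars dimensions.
#' @return an `eq_dataset`.
#' @export
random_dataset <- function(n_taxa = sample(2:6, 1),
                           n_chars = sample(1:5, 1)) {
  anat <- fixture_anatomy()
  qual <- fixture_quality()
  entity_ids <- names(anat$terms)
  quality_ids <- names(qual$terms)
  taxonomy_ids <- names(fixture_taxonomy()$terms)
  coll_ids <- names(fixture_collections()$terms)

  taxa <- lapply(seq_len(n_taxa), function(i) {
    taxon(paste("Taxon", i),
          valid_taxon = if (stats::runif(1) < 0.7)
            sample(taxonomy_ids, 1) else NULL,
          matrix_name = if (stats::runif(1) < 0.3)
            paste("MatrixTaxon", i) else NULL,
          specimens = if (stats::runif(1) < 0.5) {
            lapply(seq_len(sample(1:2, 1)), function(k)
              specimen(sample(coll_ids, 1),
                       as.character(sample(1e5, 1))))
          } else list(),
          comment = if (stats::runif(1) < 0.3) paste("note", i) else NULL,
          figures = if (stats::runif(1) < 0.3)
            paste("Fig.", sample(9, 1)) else character())
  })
  chars <- lapply(seq_len(n_chars), function(j) {
    n_states <- sample(2:4, 1)
    states <- lapply(seq_len(n_states), function(k) {
      n_ph <- sample(0:3, 1)
      eq_state(as.character(k - 1),
               label = paste("state", k - 1, "of char", j),
               comment = if (stats::runif(1) < 0.2) "state note" else NULL,
               figures = if (stats::runif(1) < 0.2)
                 paste("Fig.", sample(9, 1)) else character(),
               phenotypes = lapply(seq_len(n_ph), function(z)
                 random_phenotype(entity_ids, quality_ids,
                                  fx$millimeter)))
    })
    eq_character(j, label = paste("character", j),
                 comment = if (stats::runif(1) < 0.2) "char note" else NULL,
                 states = states)
  })
  m <- list()
  for (tx in taxa) {
    row <- lapply(chars, function(ch) {
      syms <- vapply(ch$states, `[[`, character(1), "symbol")
      u <- stats::runif(1)
      if (u < 0.1) cell_value("missing")
      else if (u < 0.15) cell_value("gap")
      else if (u < 0.3 && length(syms) >= 2) {
        cell_value("polymorphic", sample(syms, 2))
      } else cell_value("single", sample(syms, 1))
    })
    m[[tx$publication_name]] <- row
  }
  eq_dataset(curators = paste("Curator", seq_len(sample(1:2, 1))),
             publication = "Randomized fixture publication",
             publication_notes = if (stats::runif(1) < 0.5)
               "random notes" else "",
             taxa = taxa, characters = chars, matrix = m)
}

#' Random NEXUS file text plus its ground truth
#'
#' @param n_taxa,n_chars dimensions (kept modest for test budgets).
#' @param interleave write the matrix in interleaved blocks.
#' @return list with `text`, `ntax`, `nchar`, `cells` (list of rows of
#'   [cell_value()] ground truth, in taxon order) and `taxa` labels.
#' @export
random_nexus <- function(n_taxa = sample(2:8, 1),
                         n_chars = sample(2:12, 1),
                         interleave = stats::runif(1) < 0.3) {
  symbols <- as.character(0:2)
  taxa <- paste0("Taxon_", seq_len(n_taxa))         # unquoted: _ -> space
  cells <- lapply(seq_len(n_taxa), function(i) {
    lapply(seq_len(n_chars), function(j) {
      u <- stats::runif(1)
      if (u < 0.1) cell_value("missing")
      else if (u < 0.15) cell_value("gap")
      else if (u < 0.3) cell_value("polymorphic", sample(symbols, 2))
      else cell_value("single", sample(symbols, 1))
    })
  })
  fmt_cell <- function(cell) format(cell)
  rows <- vapply(cells, function(row)
    paste0(vapply(row, fmt_cell, character(1)), collapse = ""),
    character(1))
  mat_lines <- if (interleave && n_chars >= 2) {
    cut_at <- ceiling(n_chars / 2)
    first <- vapply(cells, function(row)
      paste0(vapply(row[seq_len(cut_at)], fmt_cell, character(1)),
             collapse = ""), character(1))
    second <- vapply(cells, function(row)
      paste0(vapply(row[(cut_at + 1):n_chars], fmt_cell, character(1)),
             collapse = ""), character(1))
    c(paste(taxa, first), "", paste(taxa, second))
  } else paste(taxa, rows)
  text <- paste(c(
    "#NEXUS",
    "BEGIN TAXA;",
    paste0("DIMENSIONS NTAX=", n_taxa, ";"),
    paste0("TAXLABELS ", paste(taxa, collapse = " "), ";"),
    "END;",
    "BEGIN CHARACTERS;",
    paste0("DIMENSIONS NCHAR=", n_chars, ";"),
    paste0("FORMAT DATATYPE=STANDARD SYMBOLS=\"",
           paste(symbols, collapse = " "), "\" MISSING=? GAP=-",
           if (interleave && n_chars >= 2) " INTERLEAVE" else "", ";"),
    "MATRIX",
    mat_lines,
    ";",
    "END;"), collapse = "\n")
  list(text = text, ntax = n_taxa, nchar = n_chars, cells = cells,
       taxa = gsub("_", " ", taxa, fixed = TRUE))
}
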