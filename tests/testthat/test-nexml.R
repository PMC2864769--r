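test_that("taxon metadata lands in the right vocabulary", {
  ds <- fixture_examples_dataset()
  x <- write_nexml(ds)
  doc <- xml2::read_xml(x)
  # the valid-name identifier uses the Darwin Core taxonID property
  expect_match(x, 'rel="dwc:taxonID"', fixed = TRUE)
  expect_match(x, "http://rs.tdwg.org/dwc/terms/", fixed = TRUE)
  expect_match(x, curie_to_purl(fxid$ictalurus), fixed = TRUE)
  # specimens: individualID node nesting collectionID + catalogNumber
  expect_match(x, 'rel="dwc:individualID"', fixed = TRUE)
  expect_match(x, 'property="dwc:catalogNumber" content="177000"',
               fixed = TRUE)
  expect_match(x, curie_to_purl(fxid$ummz), fixed = TRUE)
  # publication name is the otu label
  xml2::xml_ns_strip(doc)
  labels <- xml2::xml_attr(xml2::xml_find_all(doc, "//otu"), "label")
  expect_setequal(labels, vapply(ds$taxa, `[[`, character(1),
                                 "publication_name"))
})

test_that("the opercle/triangular EQ serializes with its known identifiers", {
  ds <- fixture_examples_dataset()
  doc <- xml2::read_xml(write_nexml(ds))
  xml2::xml_ns_strip(doc)
  bearers <- xml2::xml_find_all(
    doc, "//*[local-name()='bearer']/*[local-name()='typeref']")
  quals <- xml2::xml_find_all(
    doc, "//*[local-name()='quality']/*[local-name()='typeref']")
  expect_true("TAO:0000250" %in% xml2::xml_attr(bearers, "about"))
  expect_true("PATO:0001875" %in% xml2::xml_attr(quals, "about"))
  # one phenotype_character element per EQ statement
  n_expected <- sum(vapply(ds$characters, function(ch)
    sum(vapply(ch$states, function(s) length(s$phenotypes), integer(1))),
    integer(1)))
  expect_length(
    xml2::xml_find_all(doc, "//*[local-name()='phenotype_character']"),
    n_expected)
})

test_that("unannotated datasets carry no phenotype metadata at all", {
  ds <- nexus_to_dataset(parse_nexus(fixture_nexus_text()))
  x <- write_nexml(ds)
  expect_false(grepl("describesPhenotype", x, fixed = TRUE))
  expect_false(grepl("bioontologies.org/obd/schema/pheno",
                     sub('xmlns:pheno="[^"]*"', "", x), fixed = TRUE))
})

test_that("emitted metadata vocabulary is confined to the standard table", {
  allowed <- data.frame(
    local_name = c("creator", "references", "description", "taxonID",
                   "individualID", "collectionID", "catalogNumber",
                   "comment", "hasMatrixName", "inFigure",
                   "describesPhenotype"),
    namespace_uri = c(rep("http://purl.org/dc/terms/", 3),
                      rep("http://rs.tdwg.org/dwc/terms/", 4),
                      "http://www.w3.org/2000/01/rdf-schema#",
                      rep("http://vocab.phenoscape.org/", 3)),
    stringsAsFactors = FALSE)
  docs <- list(write_nexml(fixture_examples_dataset()))
  set.seed(17)
  for (i in 1:10) docs[[i + 1]] <- write_nexml(random_dataset())
  for (x in docs) {
    vocab <- nexml_meta_vocabulary(x)
    key <- paste(vocab$local_name, vocab$namespace_uri)
    expect_true(all(key %in% paste(allowed$local_name,
                                   allowed$namespace_uri)),
                info = paste("unexpected metadata:",
                             paste(setdiff(key, paste(allowed$local_name,
                                                      allowed$namespace_uri)),
                                   collapse = "; ")))
  }
  # and PhenoXML element names stay within the schema's element set
  doc <- xml2::read_xml(write_nexml(fixture_examples_dataset()))
  pheno_els <- xml2::xml_find_all(
    doc, "//*[namespace-uri()='http://www.bioontologies.org/obd/schema/pheno']")
  expect_true(all(xml2::xml_name(pheno_els) %in%
                    c("phenotype", "phenotype_character", "bearer",
                      "quality", "related_entity", "typeref",
                      "qualifier")))
})

test_that("writing is deterministic and refuses invalid datasets", {
  ds <- fixture_examples_dataset()
  expect_identical(write_nexml(ds), write_nexml(ds))

  bad <- ds
  bad$characters[[1]]$states[[1]]$phenotypes[[1]]$quality <- "PATO:0999999"
  expect_error(write_nexml(bad, ontology = fixture_merged_ontology()),
               "validation errors")
  # warnings alone (e.g. unannotated states) do not block writing
  plain <- nexus_to_dataset(parse_nexus(fixture_nexus_text()))
  expect_no_error(write_nexml(plain, ontology = fixture_merged_ontology()))
})

test_that("the examples and the empty dataset survive a full round trip", {
  ds <- fixture_examples_dataset()
  expect_true(dataset_equal(ds, read_nexml(write_nexml(ds))))

  empty <- eq_dataset()
  expect_true(dataset_equal(empty, read_nexml(write_nexml(empty))))
})

test_that("post-composition typerefs decode to the structure they encode", {
  set.seed(23)
  ids <- names(fixture_anatomy()$terms)
  for (i in 1:50) {
    pc <- random_postcomp(ids, depth = 3)
    root <- xml2::xml_new_root("wrap",
                               "xmlns:pheno" = nexml_namespaces()[["pheno"]])
    encode_postcomposition(root, pc)
    node <- xml2::xml_child(root)
    xml2::xml_ns_strip(root)
    expect_identical(eqmatrix:::decode_typeref(node), pc)
  }
})

test_that("randomized datasets round-trip through NeXML unchanged", {
  set.seed(101)
  for (i in 1:40) {
    ds <- random_dataset()
    ds2 <- read_nexml(write_nexml(ds))
    expect_true(dataset_equal(ds, ds2),
                info = paste("round-trip failure at case", i))
  }
})

test_that("unknown metadata is warned about, preserved and re-emitted", {
  ds <- fixture_examples_dataset()
  x <- write_nexml(ds)
  doc <- xml2::read_xml(x)
  root <- xml2::xml_root(doc)
  xml2::xml_add_child(root, "meta", "xsi:type" = "LiteralMeta",
                      property = "dc:title", content = "mystery title",
                      .where = 0)
  patched <- as.character(doc)
  expect_warning(ds2 <- read_nexml(patched), "dc:title")
  expect_true(any(grepl("mystery title", ds2$extras)))
  rewritten <- write_nexml(ds2)
  expect_match(rewritten, "mystery title", fixed = TRUE)
})
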