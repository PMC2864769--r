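test_that("post-composition renders canonically and parses back", {
  pc <- compose(fxid$process,
                list(list(relation = "part_of", filler = fxid$epiotic)))
  expect_equal(render_postcomp(pc),
               paste0(fxid$process, "^part_of(", fxid$epiotic, ")"))
  expect_identical(parse_postcomp(render_postcomp(pc)), pc)

  nested <- compose("A:1", list(list(
    relation = "part_of",
    filler = compose("B:2", list(list(relation = "part_of",
                                      filler = "C:3"))))))
  expect_identical(parse_postcomp(render_postcomp(nested)), nested)

  expect_error(compose("A:1", list()), "non-empty")

  set.seed(99)
  ids <- names(fixture_anatomy()$terms)
  for (i in 1:100) {
    rpc <- random_postcomp(ids, depth = 3)
    expect_identical(parse_postcomp(render_postcomp(rpc)), rpc)
  }
})

test_that("count ranges render with an ASCII hyphen and parse back", {
  expect_equal(format(count_range(43)), "43")
  expect_equal(format(count_range(40, 42)), "40-42")
  expect_identical(parse_count_range("40-42"), count_range(40, 42))
  expect_identical(parse_count_range("43"), count_range(43, 43))
  expect_error(count_range(5, 3), "min <= max")
})

test_that("phenotype construction enforces its invariants", {
  expect_error(phenotype(fxid$vertebra, fxid$count, measurement = "3.5"),
               "unit")
  p <- phenotype(fxid$vertebra, fxid$count, measurement = "3.50",
                 unit = fxid$millimeter)
  expect_identical(p$measurement, "3.50")   # verbatim decimal string
  expect_error(entity_ref(), "exactly one")
  expect_error(entity_ref(term = fxid$opercle,
                          composed = compose(fxid$process, list(
                            list(relation = "part_of",
                                 filler = fxid$epiotic)))),
               "exactly one")
})

test_that("attach_phenotype appends in order", {
  st <- eq_state("0", "forked with pointed lobes")
  st <- attach_phenotype(st, phenotype(fxid$caudal_fin, fxid$bifurcated))
  st <- attach_phenotype(st, phenotype(fxid$upper_lobe, fxid$sharp))
  st <- attach_phenotype(st, phenotype(fxid$lower_lobe, fxid$sharp))
  expect_length(st$phenotypes, 3)
  expect_equal(st$phenotypes[[2]]$entity$term, fxid$upper_lobe)

  set.seed(3)
  n <- 17
  ids <- names(fixture_anatomy()$terms)
  st2 <- eq_state("1")
  ents <- sample(ids, n, replace = TRUE)
  for (e in ents) {
    st2 <- attach_phenotype(st2, phenotype(e, fxid$round))
  }
  expect_length(st2$phenotypes, n)
  expect_equal(vapply(st2$phenotypes, function(p) p$entity$term,
                      character(1)), ents)
})

test_that("the four worked-example states classify into their categories", {
  q <- fixture_quality()
  monadic <- eq_state("0", "deeply forked", phenotypes = list(
    phenotype(fxid$caudal_fin, fxid$bifurcated)))
  relational <- eq_state("0", "fused", phenotypes = list(
    phenotype(fxid$hypural2, fxid$fused_with,
              related_entity = fxid$hypural3)))
  quantitative <- eq_state("0", "40-42", phenotypes = list(
    phenotype(fxid$vertebra, fxid$count, count = count_range(40, 42))))
  composite <- eq_state("0", "forked with pointed lobes", phenotypes = list(
    phenotype(fxid$caudal_fin, fxid$bifurcated),
    phenotype(fxid$upper_lobe, fxid$sharp),
    phenotype(fxid$lower_lobe, fxid$sharp)))

  expect_equal(classify_state(monadic, q), "monadic")
  expect_equal(classify_state(relational, q), "relational")
  expect_equal(classify_state(quantitative, q), "quantitative")
  expect_equal(classify_state(composite, q), c("composite", "monadic"))
})

test_that("classification distributes over phenotype attachment", {
  q <- fixture_quality()
  set.seed(21)
  entity_ids <- names(fixture_anatomy()$terms)
  quality_ids <- names(q$terms)
  for (rep in 1:20) {
    n <- sample(1:4, 1)
    phs <- lapply(seq_len(n), function(i)
      eqmatrix:::random_phenotype(entity_ids, quality_ids,
                                  fxid$millimeter))
    st <- eq_state("0", phenotypes = phs)
    whole <- classify_state(st, q)
    parts <- unique(unlist(lapply(phs, function(p)
      classify_state(eq_state("0", phenotypes = list(p)), q))))
    expected <- sort(unique(c(setdiff(parts, "composite"),
                              if (n >= 2) "composite")))
    expect_equal(whole, expected)
  }
})

test_that("classify_state errors on a quality missing from the ontology", {
  q <- fixture_quality()
  st <- eq_state("0", phenotypes = list(
    phenotype(fxid$caudal_fin, "PATO:0999999")))
  expect_error(classify_state(st, q), "not in ontology")
})

test_that("validate_dataset is clean on the examples and finds corruption", {
  o <- fixture_merged_ontology()
  ds <- fixture_examples_dataset()
  expect_equal(nrow(validate_dataset(ds, o)), 0)

  bad <- ds
  bad$characters[[1]]$states[[1]]$phenotypes[[1]]$entity$term <-
    "TAO:9999999"
  iss <- validate_dataset(bad, o)
  expect_equal(nrow(iss), 1)
  expect_equal(iss$code, "unknown-term")
  expect_equal(iss$severity, "error")
  expect_equal(iss$character, 1L)

  # validation is pure: same result twice, input untouched
  before <- bad
  expect_identical(validate_dataset(bad, o), iss)
  expect_identical(bad, before)
})

test_that("k randomized term corruptions yield exactly k unknown-term issues", {
  o <- fixture_merged_ontology()
  set.seed(5)
  for (rep in 1:5) {
    ds <- fixture_examples_dataset()
    slots <- list()       # (char, state, pheno) coordinates of qualities
    for (j in seq_along(ds$characters)) {
      for (k in seq_along(ds$characters[[j]]$states)) {
        for (p in seq_along(ds$characters[[j]]$states[[k]]$phenotypes)) {
          slots[[length(slots) + 1L]] <- c(j, k, p)
        }
      }
    }
    k_corrupt <- sample(1:5, 1)
    pick <- sample(length(slots), k_corrupt)
    for (z in seq_along(pick)) {
      co <- slots[[pick[z]]]
      ds$characters[[co[1]]]$states[[co[2]]]$phenotypes[[co[3]]]$quality <-
        sprintf("PATO:09999%02d", z)
    }
    iss <- validate_dataset(ds, o)
    expect_equal(sum(iss$code == "unknown-term"), k_corrupt)
  }
})

test_that("validation flags obsolete terms, filter and matrix violations", {
  o <- merge_ontologies(list(fixture_merged_ontology(), parse_obo(paste(
    "[Term]", "id: TAO:0888888", "name: deprecated bone",
    "is_obsolete: true", "replaced_by: TAO:0100014", sep = "\n"),
    quiet = TRUE)))
  ds <- fixture_examples_dataset()
  ds$characters[[1]]$states[[1]]$phenotypes[[1]]$entity$term <-
    "TAO:0888888"
  iss <- validate_dataset(ds, o)
  ob <- iss[iss$code == "obsolete-term", ]
  expect_equal(nrow(ob), 1)
  expect_match(ob$message, "TAO:0100014")   # replaced_by hint
  expect_equal(ob$severity, "warning")

  # filter violation: entity field restricted to the anatomy namespace
  ds2 <- fixture_examples_dataset()
  ds2$characters[[1]]$states[[1]]$phenotypes[[1]]$entity$term <-
    fxid$triangular       # a quality used as an entity
  iss2 <- validate_dataset(ds2, fixture_merged_ontology(),
                           filters = list(entity = term_filter(
                             namespaces = "teleost_anatomy")))
  expect_true(any(iss2$code == "filter-violation"))

  # related entity with a single-entity quality
  ds3 <- fixture_examples_dataset()
  ds3$characters[[1]]$states[[1]]$phenotypes[[1]]$related_entity <-
    entity_ref(term = fxid$hypural3)
  iss3 <- validate_dataset(ds3, fixture_merged_ontology())
  expect_true(any(iss3$code == "relational-mismatch"))

  # count on a non-count quality
  ds4 <- fixture_examples_dataset()
  ds4$characters[[1]]$states[[1]]$phenotypes[[1]]$count <-
    count_range(2)
  iss4 <- validate_dataset(ds4, fixture_merged_ontology())
  expect_true(any(iss4$code == "count-mismatch"))

  # undefined matrix symbol
  ds5 <- fixture_examples_dataset()
  ds5$matrix[["Ictalurus punctatus"]][[1]] <- cell_value("single", "9")
  iss5 <- validate_dataset(ds5, fixture_merged_ontology())
  expect_true(any(iss5$code == "undefined-symbol" &
                    iss5$severity == "error"))
})
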