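test_that("parse_obo reads terms, synonyms, namespaces and edges", {
  obo <- paste(
    "format-version: 1.2",
    "default-namespace: teleost_anatomy",
    "",
    "[Term]",
    "id: TAO:0000250",
    "name: opercle",
    'def: "A flat bone of the gill cover." [TAO:curator]',
    'synonym: "gill cover bone" EXACT []',
    "subset: toy_slim",
    "is_a: TAO:0100014 ! bone",
    "",
    "[Term]",
    "id: TAO:0100014",
    "name: bone",
    "namespace: skeletal",
    "relationship: part_of TAO:0100001",
    "",
    "[Term]",
    "id: TAO:0100001",
    "name: anatomical structure",
    sep = "\n")
  o <- parse_obo(obo)
  expect_length(o$terms, 3)
  expect_equal(o$terms[["TAO:0000250"]]$name, "opercle")
  expect_equal(o$terms[["TAO:0000250"]]$namespace, "teleost_anatomy")
  expect_equal(o$terms[["TAO:0000250"]]$synonyms, "gill cover bone")
  expect_equal(o$terms[["TAO:0000250"]]$synonym_scopes, "EXACT")
  expect_equal(o$terms[["TAO:0000250"]]$subsets, "toy_slim")
  expect_equal(o$terms[["TAO:0000250"]]$definition,
               "A flat bone of the gill cover.")
  expect_equal(o$terms[["TAO:0100014"]]$namespace, "skeletal")
  expect_equal(nrow(o$edges), 2)
  expect_setequal(o$edges$predicate, c("is_a", "part_of"))
})

test_that("parse_obo handles the empty, obsolete and error cases", {
  o <- parse_obo("format-version: 1.2\n")
  expect_length(o$terms, 0)
  expect_equal(nrow(o$edges), 0)

  obs <- parse_obo(paste(
    "[Term]", "id: X:1", "name: old thing", "is_obsolete: true",
    "replaced_by: X:2", "", "[Term]", "id: X:2", "name: new thing",
    sep = "\n"))
  expect_true(obs$terms[["X:1"]]$obsolete)
  expect_equal(obs$terms[["X:1"]]$replaced_by, "X:2")

  expect_error(parse_obo("[Term]\nname: nameless\n"), "no id")
  expect_message(parse_obo("[Term]\nid: X:1\nname: x\nxref: Y:2\n"),
                 "unknown tag")
  expect_warning(parse_obo("[Term]\nid: X:1\nname: x\nis_a: X:99\n"),
                 "dangling")
})

test_that("OBO edge count matches a raw text-scan oracle", {
  set.seed(42)
  for (rep in 1:3) {
    o <- random_ontology(n_terms = 50)
    txt <- write_obo(o)
    lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
    n_edge_lines <- sum(grepl("^(is_a|relationship):", lines))
    reparsed <- parse_obo(txt, quiet = TRUE)
    expect_equal(nrow(reparsed$edges), n_edge_lines)
    expect_equal(nrow(o$edges), n_edge_lines)
  }
})

test_that("OBO write/parse round-trip preserves content", {
  set.seed(7)
  for (rep in 1:5) {
    o <- random_ontology(n_terms = 30)
    o2 <- parse_obo(write_obo(o), quiet = TRUE)
    expect_setequal(names(o2$terms), names(o$terms))
    for (id in names(o$terms)) {
      expect_equal(o2$terms[[id]]$name, o$terms[[id]]$name)
      expect_equal(o2$terms[[id]]$synonyms, o$terms[[id]]$synonyms)
      expect_equal(o2$terms[[id]]$subsets, o$terms[[id]]$subsets)
      expect_equal(o2$terms[[id]]$namespace, o$terms[[id]]$namespace)
    }
    key <- function(e) sort(paste(e$subject, e$predicate, e$object))
    expect_equal(key(o2$edges), key(o$edges))
  }
})

test_that("parse_obo agrees with an independent OBO reader on the fixtures", {
  skip_if_not(nzchar(Sys.which("python")))
  td <- withr::local_tempdir()
  generate_fixtures(1, td)
  out <- tryCatch(
    system2("python", c("-c", shQuote(paste0(
      "import obonet; g = obonet.read_obo(open('",
      file.path(td, "anatomy.obo"),
      "')); print(len(g.nodes)); print(len(g.edges))"))),
      stdout = TRUE, stderr = FALSE),
    warning = function(w) NULL, error = function(e) NULL)
  skip_if(is.null(out) || length(out) < 2, "obonet unavailable")
  anat <- fixture_anatomy()
  expect_equal(as.integer(out[1]), length(anat$terms))
  expect_equal(as.integer(out[2]), nrow(anat$edges))
})

test_that("merge_ontologies unions terms and edges, last wins on clash", {
  a <- fixture_anatomy()
  q <- fixture_quality()
  expect_identical(merge_ontologies(list(a))$terms, a$terms)

  m <- merge_ontologies(list(a, q))
  expect_length(m$terms, length(a$terms) + length(q$terms))
  expect_equal(nrow(m$edges), nrow(a$edges) + nrow(q$edges))

  dup_warnings <- character()
  m2 <- withCallingHandlers(
    merge_ontologies(list(a, a)),
    warning = function(w) {
      dup_warnings <<- c(dup_warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  expect_identical(m2$terms, a$terms)
  expect_equal(nrow(m2$edges), nrow(a$edges))
  expect_length(dup_warnings, length(a$terms))
})

test_that("search ranks exact > prefix > synonym > substring and is stable", {
  o <- fixture_merged_ontology()
  r <- search_terms(o, "triangular")
  expect_equal(r[[1]]$id, fxid$triangular)

  expect_length(search_terms(o, "zzz-not-present"), 0)

  # name-prefix beats substring; synonym matching works case-insensitively
  r2 <- search_terms(o, "caudal fin")
  expect_equal(r2[[1]]$id, fxid$caudal_fin)        # exact
  expect_true(all(c(fxid$upper_lobe, fxid$lower_lobe) %in%
                    vapply(r2, `[[`, character(1), "id")))
  r3 <- search_terms(o, "GILL COVER")
  expect_equal(r3[[1]]$id, fxid$opercle)           # via synonym

  expect_identical(search_terms(o, "fin"), search_terms(o, "fin"))
  expect_lte(length(search_terms(o, "a", limit = 3)), 3)
})

test_that("search respects filters and excludes obsolete terms", {
  o <- fixture_merged_ontology()
  f <- term_filter(namespaces = "teleost_anatomy")
  res <- search_terms(o, "fin", f, limit = 100)
  expect_true(length(res) > 0)
  # linear-scan oracle: every admitted term is from the namespace and
  # nothing matching outside the result set was missed
  expect_true(all(vapply(res, `[[`, character(1), "namespace") ==
                    "teleost_anatomy"))
  brute <- Filter(function(t) {
    !t$obsolete && t$namespace == "teleost_anatomy" &&
      (grepl("fin", tolower(t$name), fixed = TRUE) ||
         any(grepl("fin", tolower(t$synonyms), fixed = TRUE)))
  }, o$terms)
  expect_setequal(vapply(res, `[[`, character(1), "id"),
                  vapply(brute, `[[`, character(1), "id"))

  withob <- merge_ontologies(list(o, parse_obo(paste(
    "[Term]", "id: TAO:0999999", "name: finlike obsolete thing",
    "is_obsolete: true", sep = "\n"), quiet = TRUE)))
  ids <- vapply(search_terms(withob, "finlike", limit = 100), `[[`,
                character(1), "id")
  expect_false("TAO:0999999" %in% ids)

  # subset filter
  fsub <- term_filter(subsets = "toy_slim")
  ids2 <- vapply(search_terms(o, "opercle", fsub), `[[`, character(1),
                 "id")
  expect_equal(ids2, fxid$opercle)

  # ancestor-constraint filter soundness by exhaustive scan
  fanc <- term_filter(ancestor = list(id = fxid$pectoral_fin,
                                      relations = c("is_a", "part_of")))
  got <- search_terms(o, "a", fanc, limit = 100)
  for (t in got) {
    expect_true(fxid$pectoral_fin %in%
                  ancestors(o, t$id, c("is_a", "part_of")))
  }
})

test_that("ancestors follows selected relations and matches a BFS oracle", {
  o <- fixture_merged_ontology()
  a <- ancestors(o, fxid$dorsal_arrector, c("is_a", "part_of"))
  expect_true(fxid$pectoral_fin %in% a)
  # is_a only: the part_of link to the fin must not be followed
  expect_false(fxid$pectoral_fin %in%
                 ancestors(o, fxid$dorsal_arrector, "is_a"))

  expect_length(ancestors(o, fxid$structure_), 0)   # root
  expect_error(ancestors(o, "TAO:0999999"), "unknown term")

  set.seed(11)
  for (rep in 1:10) {
    ro <- random_ontology(n_terms = sample(20:200, 1))
    start <- sample(names(ro$terms), 1)
    for (rels in list("is_a", c("is_a", "part_of"))) {
      expect_equal(sort(ancestors(ro, start, rels)),
                   bfs_ancestors_oracle(ro, start, rels))
    }
    # monotonicity: enlarging the relation set never shrinks the result
    expect_true(all(ancestors(ro, start, "is_a") %in%
                      ancestors(ro, start, c("is_a", "part_of"))))
  }
})
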