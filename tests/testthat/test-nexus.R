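test_that("the toy NEXUS parses with labels, symbols and defaults", {
  doc <- parse_nexus(fixture_nexus_text())
  expect_equal(doc$ntax, 3)
  expect_equal(doc$nchar, 2)
  expect_equal(doc$symbols, c("0", "1", "2"))
  expect_equal(doc$taxa_labels,
               c("Danio rerio", "Ictalurus punctatus", "Noturus flavus"))
  expect_equal(doc$charstatelabels[[1]]$label, "opercle shape")
  expect_equal(doc$charstatelabels[[1]]$states, c("triangular", "round"))

  # "?" -> missing, "-" -> gap, polymorphism group -> one cell
  row <- doc$matrix_cells[["Noturus flavus"]]
  expect_equal(row[[1]]$type, "missing")
  poly <- doc$matrix_cells[["Ictalurus punctatus"]][[2]]
  expect_equal(poly$type, "polymorphic")
  expect_setequal(poly$symbols, c("1", "2"))
})

test_that("parsing is case-insensitive and strips bracketed comments", {
  txt <- paste(
    "#nexus",
    "begin taxa; dimensions ntax=2; taxlabels A_a 'B b'; end;",
    "begin characters;",
    "dimensions nchar=4; [a comment",
    "spanning lines] format symbols=\"01\" missing=? gap=-;",
    "matrix",
    "A_a 0{01}1?",
    "'B b' 01-1",
    ";",
    "end;", sep = "\n")
  doc <- parse_nexus(txt, quiet = TRUE)
  expect_equal(doc$taxa_labels, c("A a", "B b"))   # underscore + quoted
  row <- doc$matrix_cells[["A a"]]
  expect_length(row, 4)
  expect_equal(row[[2]]$type, "polymorphic")
  expect_equal(row[[4]]$type, "missing")
  expect_equal(doc$matrix_cells[["B b"]][[3]]$type, "gap")
})

test_that("structural errors are reported with line numbers", {
  expect_error(parse_nexus("BEGIN TAXA; END;"), "#NEXUS")
  bad_len <- paste(
    "#NEXUS",
    "BEGIN CHARACTERS;",
    "DIMENSIONS NCHAR=3;",
    "FORMAT SYMBOLS=\"01\";",
    "MATRIX",
    "TaxA 01",
    ";", "END;", sep = "\n")
  expect_error(parse_nexus(bad_len, quiet = TRUE), "line 6.*3")
  dup <- paste(
    "#NEXUS",
    "BEGIN TAXA; DIMENSIONS NTAX=2;",
    "TAXLABELS A A;",
    "END;", sep = "\n")
  expect_error(parse_nexus(dup, quiet = TRUE), "duplicate taxon")
  dup_row <- paste(
    "#NEXUS",
    "BEGIN CHARACTERS;",
    "DIMENSIONS NCHAR=1; FORMAT SYMBOLS=\"01\";",
    "MATRIX", "A 0", "A 1", ";", "END;", sep = "\n")
  expect_error(parse_nexus(dup_row, quiet = TRUE),
               "duplicate taxon label in matrix")
})

test_that("interleaved matrices concatenate per-taxon segments", {
  txt <- paste(
    "#NEXUS",
    "BEGIN CHARACTERS;",
    "DIMENSIONS NCHAR=4;",
    "FORMAT SYMBOLS=\"01\" INTERLEAVE;",
    "MATRIX",
    "A 01",
    "B 10",
    "",
    "A 11",
    "B 00",
    ";", "END;", sep = "\n")
  doc <- parse_nexus(txt, quiet = TRUE)
  expect_equal(vapply(doc$matrix_cells[["A"]], format, character(1)),
               c("0", "1", "1", "1"))
  expect_equal(vapply(doc$matrix_cells[["B"]], format, character(1)),
               c("1", "0", "0", "0"))
})

test_that("randomized NEXUS files conserve ntax x nchar cells", {
  set.seed(31)
  for (rep in 1:20) {
    rx <- random_nexus()
    doc <- parse_nexus(rx$text, quiet = TRUE)
    expect_equal(doc$ntax, rx$ntax)
    expect_equal(doc$nchar, rx$nchar)
    total <- sum(vapply(doc$matrix_cells, length, integer(1)))
    expect_equal(total, rx$ntax * rx$nchar)
    # text-scan oracle over the raw matrix rows
    lines <- strsplit(rx$text, "\n", fixed = TRUE)[[1]]
    m0 <- which(lines == "MATRIX")
    m1 <- which(lines == ";")
    m1 <- min(m1[m1 > m0])
    rows <- lines[(m0 + 1):(m1 - 1)]
    rows <- rows[nzchar(rows)]
    oracle <- sum(vapply(rows, function(r) {
      count_cells_in_row_text(sub("^\\S+\\s+", "", r))
    }, integer(1)))
    expect_equal(total, oracle)
    # ground-truth cells are reproduced exactly
    for (i in seq_along(rx$taxa)) {
      expect_identical(doc$matrix_cells[[rx$taxa[i]]], rx$cells[[i]])
    }
  }
})

test_that("parsed matrices agree with ape::read.nexus.data on plain files", {
  skip_if_not_installed("ape")
  set.seed(8)
  rx <- random_nexus(n_taxa = 5, n_chars = 10, interleave = FALSE)
  tf <- withr::local_tempfile(fileext = ".nex")
  writeLines(rx$text, tf)
  ours <- parse_nexus(tf, quiet = TRUE)
  theirs <- ape::read.nexus.data(tf)
  expect_setequal(names(theirs), gsub(" ", "_", names(ours$matrix_cells)))
  for (tn in names(ours$matrix_cells)) {
    ape_row <- theirs[[gsub(" ", "_", tn)]]
    our_row <- ours$matrix_cells[[tn]]
    for (j in seq_along(our_row)) {
      cell <- our_row[[j]]
      ape_syms <- toupper(unlist(strsplit(unlist(ape_row[j]), "/",
                                          fixed = TRUE)))
      if (cell$type == "single") {
        expect_equal(ape_syms, cell$symbols)
      } else if (cell$type == "polymorphic") {
        expect_setequal(ape_syms, cell$symbols)
      }
    }
  }
})

test_that("nexus_to_dataset maps labels, fallbacks and cells", {
  doc <- parse_nexus(fixture_nexus_text())
  ds <- nexus_to_dataset(doc)
  expect_length(ds$taxa, 3)
  expect_length(ds$characters, 2)
  expect_equal(sum(vapply(ds$matrix, length, integer(1))), 6)
  expect_equal(ds$characters[[1]]$label, "opercle shape")
  expect_equal(ds$characters[[1]]$states[[1]]$label, "triangular")
  # every phenotype list starts empty: annotation happens downstream
  expect_true(all(vapply(ds$characters, function(ch)
    all(vapply(ch$states, function(s) length(s$phenotypes) == 0,
               logical(1))), logical(1))))

  no_label <- paste(
    "#NEXUS",
    "BEGIN CHARACTERS;",
    "DIMENSIONS NCHAR=2; FORMAT SYMBOLS=\"01\";",
    "CHARSTATELABELS 1 'opercle shape' / triangular round;",
    "MATRIX", "A 01", ";", "END;", sep = "\n")
  ds2 <- nexus_to_dataset(parse_nexus(no_label, quiet = TRUE))
  expect_equal(ds2$characters[[2]]$label, "Character 2")

  # extra state labels beyond the symbol list are dropped with a warning
  extra <- paste(
    "#NEXUS",
    "BEGIN CHARACTERS;",
    "DIMENSIONS NCHAR=1; FORMAT SYMBOLS=\"01\";",
    "CHARSTATELABELS 1 shape / a b c;",
    "MATRIX", "A 0", ";", "END;", sep = "\n")
  expect_warning(ds3 <- nexus_to_dataset(parse_nexus(extra, quiet = TRUE)),
                 "extra labels dropped")
  expect_length(ds3$characters[[1]]$states, 2)
})

test_that("to_dataset round-trips labels from generated documents", {
  set.seed(13)
  for (rep in 1:5) {
    rx <- random_nexus(interleave = FALSE)
    ds <- nexus_to_dataset(parse_nexus(rx$text, quiet = TRUE))
    expect_equal(vapply(ds$taxa, `[[`, character(1), "publication_name"),
                 rx$taxa)
    for (i in seq_along(rx$taxa)) {
      expect_identical(ds$matrix[[rx$taxa[i]]], rx$cells[[i]])
    }
  }
})
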