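#' @title The Entity-Quality data model
#' @name datamodel
#' @description
#' In-memory model for annotated character-by-taxon matrices: EQ phenotypes
#' (entity, quality, optional related entity, optional count range or
#' measurement with unit), post-composed entity terms, character states,
#' numbered characters, taxa with voucher specimens, and the matrix itself.
NULL

#' Post-compose an entity term
#'
#' A post-composition is a new term built on the fly as a genus term
#' constrained by one or more relation-filler differentia, e.g. an
#' "epiotic process" as *process* `part_of` *epiotic*. Fillers may
#' themselves be post-compositions.
#'
#' @param genus term id of the genus.
#' @param differentia non-empty list; each element is
#'   `list(relation = <relation id>, filler = <term id or eq_postcomp>)`.
#' @return object of class `eq_postcomp`.
#' @export
compose <- function(genus, differentia) {
  if (!is_term_id(genus)) stop("invalid genus id: ", genus, call. = FALSE)
  if (!is.list(differentia) || length(differentia) == 0) {
    stop("differentia must be a non-empty list", call. = FALSE)
  }
  differentia <- lapply(differentia, function(d) {
    if (is.null(d$relation) || !nzchar(d$relation)) {
      stop("each differentia needs a relation id", call. = FALSE)
    }
    f <- d$filler
    if (!(inherits(f, "eq_postcomp") ||
          (is.character(f) && length(f) == 1 && is_term_id(f)))) {
      stop("filler must be a term id or eq_postcomp", call. = FALSE)
    }
    list(relation = d$relation, filler = f)
  })
  structure(list(genus = genus, differentia = differentia),
            class = "eq_postcomp")
}

#' Canonical string rendering of a post-composition
#'
#' `GENUS^rel(FILLER)` with one `^rel(...)` clause per differentia and
#' nested fillers parenthesized recursively. This string is the canonical
#' form used for equality and serialization.
#'
#' @param pc an `eq_postcomp` (a bare term id renders as itself).
#' @return single string.
#' @export
render_postcomp <- function(pc) {
  if (is.character(pc)) return(pc)
  stopifnot(inherits(pc, "eq_postcomp"))
  clauses <- vapply(pc$differentia, function(d) {
    paste0("^", d$relation, "(", render_postcomp(d$filler), ")")
  }, character(1))
  paste0(pc$genus, paste0(clauses, collapse = ""))
}

#' @export
format.eq_postcomp <- function(x, ...) render_postcomp(x)

#' @export
print.eq_postcomp <- function(x, ...) {
  cat("<post-composition> ", render_postcomp(x), "\n", sep = "")
  invisible(x)
}

#' Parse the canonical post-composition rendering
#'
#' Inverse of [render_postcomp()]: a bare CURIE yields the CURIE string, a
#' `GENUS^rel(FILLER)...` expression yields an `eq_postcomp`.
#'
#' @param x string.
#' @return term id string or `eq_postcomp`.
#' @export
parse_postcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  x <- trimws(x)
  caret <- find_top_caret(x)
  if (is.na(caret)) {
    if (!is_term_id(x)) stop("not a term id: ", x, call. = FALSE)
    return(x)
  }
  genus <- substr(x, 1L, caret - 1L)
  rest <- substr(x, caret, nchar(x))
  differentia <- list()
  while (nzchar(rest)) {
    if (substr(rest, 1L, 1L) != "^") {
      stop("malformed post-composition: ", x, call. = FALSE)
    }
    open <- regexpr("(", rest, fixed = TRUE)[1]
    if (open < 0) stop("malformed post-composition: ", x, call. = FALSE)
    rel <- substr(rest, 2L, open - 1L)
    close <- matching_paren(rest, open)
    filler <- parse_postcomp(substr(rest, open + 1L, close - 1L))
    differentia <- c(differentia, list(list(relation = rel, filler = filler)))
    rest <- substr(rest, close + 1L, nchar(rest))
  }
  compose(genus, differentia)
}

find_top_caret <- function(x) {
  depth <- 0L
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    else if (chars[i] == ")") depth <- depth - 1L
    else if (chars[i] == "^" && depth == 0L) return(i)
  }
  NA_integer_
}

matching_paren <- function(x, open) {
  depth <- 0L
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  for (i in open:length(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    else if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth == 0L) return(i)
    }
  }
  stop("unbalanced parentheses in: ", x, call. = FALSE)
}

#' Reference to an entity: plain term or post-composition
#'
#' Exactly one of `term` and `composed` is populated. A free-text comment
#' may accompany either form (used e.g. to record interpretation
#' difficulties with a post-composition).
#'
#' @param term term id string, or NULL.
#' @param composed an `eq_postcomp`, or NULL.
#' @param comment optional string.
#' @return object of class `eq_entity_ref`.
#' @export
entity_ref <- function(term = NULL, composed = NULL, comment = NULL) {
  if (is.null(term) == is.null(composed)) {
    stop("exactly one of term/composed must be given", call. = FALSE)
  }
  if (!is.null(term) && !is_term_id(term)) {
    stop("invalid term id: ", term, call. = FALSE)
  }
  if (!is.null(composed)) stopifnot(inherits(composed, "eq_postcomp"))
  structure(list(term = term, composed = composed, comment = comment),
            class = "eq_entity_ref")
}

# genus term for matching/validation: the term itself or the pc genus
entity_genus <- function(e) {
  if (!is.null(e$term)) e$term else e$composed$genus
}

#' Integer count range
#'
#' A single value is `min == max`. Renders as `"40"` or `"40-42"` (ASCII
#' hyphen, chosen for format robustness over the typographic en-dash often
#' printed in publications).
#'
#' @param min,max integers with `min <= max`.
#' @return object of class `eq_count_range`.
#' @export
count_range <- function(min, max = min) {
  min <- as.integer(min); max <- as.integer(max)
  if (is.na(min) || is.na(max) || min > max) {
    stop("count range requires min <= max", call. = FALSE)
  }
  structure(list(min = min, max = max), class = "eq_count_range")
}

#' @export
format.eq_count_range <- function(x, ...) {
  if (x$min == x$max) as.character(x$min) else paste0(x$min, "-", x$max)
}

#' Parse a count-range string ("40" or "40-42")
#' @param x string.
#' @return `eq_count_range`.
#' @export
parse_count_range <- function(x) {
  x <- trimws(x)
  if (grepl("^-?[0-9]+$", x)) return(count_range(as.integer(x)))
  m <- regmatches(x, regexec("^(-?[0-9]+)\\s*-\\s*(-?[0-9]+)$", x))[[1]]
  if (length(m) != 3) stop("cannot parse count range: ", x, call. = FALSE)
  count_range(as.integer(m[2]), as.integer(m[3]))
}

#' An EQ phenotype statement
#'
#' The atomic annotation: an entity bears a quality, optionally relative
#' to a related entity (relational qualities such as *fused_with*),
#' optionally with a literal count range or a measurement. Measurements
#' are kept as decimal strings verbatim so files round-trip without
#' floating-point drift; a measurement requires a unit term.
#'
#' @param entity an `eq_entity_ref`, or a term id (coerced).
#' @param quality quality term id.
#' @param related_entity optional `eq_entity_ref` or term id.
#' @param count optional `eq_count_range` (or "min-max" string).
#' @param measurement optional decimal value as a string.
#' @param unit optional unit term id; required when measurement is given.
#' @param comment optional string.
#' @return object of class `eq_phenotype`.
#' @export
phenotype <- function(entity, quality, related_entity = NULL, count = NULL,
                      measurement = NULL, unit = NULL, comment = NULL) {
  if (is.character(entity)) entity <- entity_ref(term = entity)
  stopifnot(inherits(entity, "eq_entity_ref"))
  if (!is_term_id(quality)) stop("invalid quality id: ", quality, call. = FALSE)
  if (!is.null(related_entity)) {
    if (is.character(related_entity)) {
      related_entity <- entity_ref(term = related_entity)
    }
    stopifnot(inherits(related_entity, "eq_entity_ref"))
  }
  if (!is.null(count)) {
    if (is.character(count)) count <- parse_count_range(count)
    stopifnot(inherits(count, "eq_count_range"))
  }
  if (!is.null(measurement)) {
    measurement <- as.character(measurement)
    if (is.null(unit)) {
      stop("a measurement requires a unit term", call. = FALSE)
    }
  }
  structure(list(entity = entity, quality = quality,
                 related_entity = related_entity, count = count,
                 measurement = measurement, unit = unit, comment = comment),
            class = "eq_phenotype")
}

#' @export
format.eq_phenotype <- function(x, ...) {
  parts <- c(paste0("E: ", format_entity(x$entity)),
             paste0("Q: ", x$quality))
  if (!is.null(x$related_entity)) {
    parts <- c(parts, paste0("RE: ", format_entity(x$related_entity)))
  }
  if (!is.null(x$count)) parts <- c(parts, paste0("C: ", format(x$count)))
  if (!is.null(x$measurement)) {
    parts <- c(parts, paste0("M: ", x$measurement, " ", x$unit))
  }
  paste(parts, collapse = ", ")
}

format_entity <- function(e) {
  if (!is.null(e$term)) e$term else render_postcomp(e$composed)
}

#' @export
print.eq_phenotype <- function(x, ...) {
  cat("<eq_phenotype> ", format(x), "\n", sep = "")
  invisible(x)
}

#' A character state
#'
#' @param symbol single-token state symbol ("0", "1", "a", ...).
#' @param label free-text state description.
#' @param comment optional string.
#' @param figures character vector of figure references.
#' @param phenotypes ordered list of `eq_phenotype`.
#' @return object of class `eq_state`.
#' @export
eq_state <- function(symbol, label = "", comment = NULL,
                     figures = character(), phenotypes = list()) {
  stopifnot(is.character(symbol), length(symbol) == 1, nzchar(symbol))
  if (grepl("[[:space:]]", symbol)) {
    stop("state symbol must be a single token: ", symbol, call. = FALSE)
  }
  structure(list(symbol = symbol, label = label, comment = comment,
                 figures = as.character(figures),
                 phenotypes = phenotypes),
            class = "eq_state")
}

#' Append a phenotype to a state
#'
#' Supports composite character states carrying multiple EQ statements;
#' the order of previously attached phenotypes is preserved.
#'
#' @param state an `eq_state`.
#' @param p an `eq_phenotype`.
#' @return the updated state.
#' @export
attach_phenotype <- function(state, p) {
  stopifnot(inherits(state, "eq_state"), inherits(p, "eq_phenotype"))
  state$phenotypes <- c(state$phenotypes, list(p))
  state
}

#' A numbered character
#'
#' @param index 1-based position in the dataset's character list (matches
#'   publication numbering).
#' @param label free-text character description.
#' @param comment optional string.
#' @param figures character vector.
#' @param states ordered list of `eq_state`; symbols must be unique.
#' @return object of class `eq_character`.
#' @export
eq_character <- function(index, label = "", comment = NULL,
                         figures = character(), states = list()) {
  index <- as.integer(index)
  stopifnot(!is.na(index), index >= 1)
  syms <- vapply(states, `[[`, character(1), "symbol")
  if (anyDuplicated(syms)) {
    stop("duplicate state symbol within character ", index, call. = FALSE)
  }
  structure(list(index = index, label = label, comment = comment,
                 figures = as.character(figures), states = states),
            class = "eq_character")
}

#' A voucher specimen
#'
#' @param collection museum/institution code as a term id from the
#'   collections list.
#' @param catalog_number accession code string.
#' @return object of class `eq_specimen`.
#' @export
specimen <- function(collection, catalog_number) {
  if (!is_term_id(collection)) {
    stop("collection must be a term id, got: ", collection, call. = FALSE)
  }
  stopifnot(is.character(catalog_number), nzchar(catalog_number))
  structure(list(collection = collection, catalog_number = catalog_number),
            class = "eq_specimen")
}

#' A taxon row
#'
#' Distinguishes the name used in the source publication
#' (`publication_name`), the currently valid name as a taxonomy-ontology
#' id (`valid_taxon`), and the examined-species label (`matrix_name`)
#' used when a row stands for a higher taxon.
#'
#' @param publication_name non-empty string, unique within a dataset.
#' @param valid_taxon optional term id.
#' @param matrix_name optional string.
#' @param specimens list of `eq_specimen`.
#' @param comment optional string.
#' @param figures character vector.
#' @return object of class `eq_taxon`.
#' @export
taxon <- function(publication_name, valid_taxon = NULL, matrix_name = NULL,
                  specimens = list(), comment = NULL, figures = character()) {
  stopifnot(is.character(publication_name), nzchar(publication_name))
  if (!is.null(valid_taxon) && !is_term_id(valid_taxon)) {
    stop("invalid valid_taxon id: ", valid_taxon, call. = FALSE)
  }
  structure(list(publication_name = publication_name,
                 valid_taxon = valid_taxon, matrix_name = matrix_name,
                 specimens = specimens, comment = comment,
                 figures = as.character(figures)),
            class = "eq_taxon")
}

#' A matrix cell value
#'
#' One of: a single state symbol, a polymorphism over two or more
#' symbols, missing (`?`), or gap (`-`).
#'
#' @param type one of "single", "polymorphic", "missing", "gap".
#' @param symbols character vector: length 1 for single, >= 2 for
#'   polymorphic, empty otherwise.
#' @return object of class `eq_cell`.
#' @export
cell_value <- function(type = c("single", "polymorphic", "missing", "gap"),
                       symbols = character()) {
  type <- match.arg(type)
  symbols <- as.character(symbols)
  if (type == "single" && length(symbols) != 1) {
    stop("single cell needs exactly one symbol", call. = FALSE)
  }
  if (type == "polymorphic") {
    symbols <- sort(unique(symbols), method = "radix")  # canonical set form
    if (length(symbols) < 2) {
      stop("polymorphic cell needs >= 2 symbols", call. = FALSE)
    }
  }
  if (type %in% c("missing", "gap")) symbols <- character()
  structure(list(type = type, symbols = symbols), class = "eq_cell")
}

#' @export
format.eq_cell <- function(x, ...) {
  switch(x$type, single = x$symbols, missing = "?", gap = "-",
         polymorphic = paste0("{", paste0(x$symbols, collapse = ""), "}"))
}

#' An annotated dataset
#'
#' The full unit of curation: publication metadata, taxa, numbered
#' characters with their states (and attached EQ phenotypes), and the
#' character-by-taxon matrix. The matrix is a named list keyed by taxon
#' publication name; each element is a list of `eq_cell` of length equal
#' to the number of characters.
#'
#' @param curators character vector of curator names.
#' @param publication citation string.
#' @param publication_notes free-text notes.
#' @param taxa ordered list of `eq_taxon`; publication names unique.
#' @param characters ordered list of `eq_character`; indices must equal
#'   list positions.
#' @param matrix named list of cell-lists as described above.
#' @return object of class `eq_dataset`.
#' @export
eq_dataset <- function(curators = character(), publication = "",
                       publication_notes = "", taxa = list(),
                       characters = list(), matrix = list()) {
  tn <- vapply(taxa, `[[`, character(1), "publication_name")
  if (anyDuplicated(tn)) stop("duplicate taxon publication names", call. = FALSE)
  for (i in seq_along(characters)) {
    if (characters[[i]]$index != i) {
      stop("character index ", characters[[i]]$index,
           " does not match its position ", i, call. = FALSE)
    }
  }
  if (length(matrix)) {
    bad <- setdiff(names(matrix), tn)
    if (length(bad)) stop("matrix rows for unknown taxa: ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(curators = as.character(curators),
                 publication = publication,
                 publication_notes = publication_notes,
                 taxa = taxa, characters = characters, matrix = matrix),
            class = "eq_dataset")
}

#' @export
print.eq_dataset <- function(x, ...) {
  np <- sum(vapply(x$characters, function(ch) {
    sum(vapply(ch$states, function(s) length(s$phenotypes), integer(1)))
  }, integer(1)))
  cat("<eq_dataset> ", length(x$taxa), " taxa x ", length(x$characters),
      " characters; ", np, " EQ phenotype(s) attached\n", sep = "")
  invisible(x)
}

#' Classify a character state into annotation categories
#'
#' Categories follow standard systematics usage: *monadic* states involve
#' a single anatomical entity (quality descends from the single-entity
#' quality root), *relational* states involve two entities (a related
#' entity is present, or the quality descends from the relational-quality
#' root), *composite* states carry two or more EQ phenotypes, and
#' *quantitative* states carry a literal count or measurement. A state may
#' fall into several categories.
#'
#' @param state an `eq_state`.
#' @param quality_ontology the quality ontology (PATO or an analog).
#' @param monadic_root term id of the single-entity quality root.
#' @param relational_root term id of the related-entities quality root.
#' @return character vector, a subset of
#'   `c("monadic", "relational", "composite", "quantitative")`.
#' @export
classify_state <- function(state, quality_ontology,
                           monadic_root = "PATO:0001237",
                           relational_root = "PATO:0001238") {
  stopifnot(inherits(state, "eq_state"))
  cats <- character()
  have_roots <- !is.null(quality_ontology$terms[[monadic_root]]) ||
    !is.null(quality_ontology$terms[[relational_root]])
  for (p in state$phenotypes) {
    if (is.null(quality_ontology$terms[[p$quality]])) {
      stop("quality term not in ontology: ", p$quality, call. = FALSE)
    }
    anc <- ancestors(quality_ontology, p$quality, "is_a")
    q_monadic <- monadic_root %in% anc
    q_relational <- relational_root %in% anc
    if (!is.null(p$related_entity) || q_relational) {
      cats <- c(cats, "relational")
    }
    if (is.null(p$related_entity) &&
        (q_monadic || (!have_roots && !q_relational))) {
      cats <- c(cats, "monadic")
    }
    if (!is.null(p$count) || !is.null(p$measurement)) {
      cats <- c(cats, "quantitative")
    }
  }
  if (length(state$phenotypes) >= 2) cats <- c(cats, "composite")
  sort(unique(cats))
}
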