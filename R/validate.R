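#' @title Ontology-aware dataset validation
#' @name validation
NULL

new_issue <- function(severity, code, message, taxon = NA_character_,
                      character = NA_integer_, state = NA_character_) {
  data.frame(severity = severity, code = code, message = message,
             taxon = taxon, character = as.integer(character), state = state,
             stringsAsFactors = FALSE)
}

no_issues <- function() {
  new_issue(character(), character(), character(), character(), integer(),
            character())[0, ]
}

# all term ids referenced by an entity ref, incl. post-composition fillers
entity_term_ids <- function(e) {
  if (!is.null(e$term)) return(e$term)
  pc_ids <- function(pc) {
    if (is.character(pc)) return(pc)
    c(pc$genus, unlist(lapply(pc$differentia, function(d) pc_ids(d$filler))))
  }
  pc_ids(e$composed)
}

#' Validate a dataset against loaded ontologies
#'
#' Pure function returning its findings; nothing is modified. Checks
#' every term id used anywhere in the dataset (entities including
#' post-composition genus and fillers, qualities, related entities,
#' units, valid taxa, specimen collections) against the ontology;
#' reports obsolete terms with their replacement hint; enforces
#' per-field term filters; flags semantic mismatches (a related entity
#' alongside a single-entity quality, a count on a non-count quality);
#' and checks matrix structure (row lengths, undefined state symbols).
#' States with no phenotypes are reported as warnings, since partially
#' curated files are legitimate.
#'
#' @param dataset an `eq_dataset`.
#' @param ontology a (usually merged) `eq_ontology` resolving every
#'   vocabulary in use.
#' @param filters named list of `eq_term_filter` keyed by field:
#'   any of "entity", "quality", "related_entity", "unit", "taxon",
#'   "collection".
#' @param monadic_root,relational_root quality-ontology root ids used for
#'   the relational/monadic semantic checks.
#' @return data.frame of issues with columns severity ("error" or
#'   "warning"), code, message, taxon, character, state.
#' @export
validate_dataset <- function(dataset, ontology, filters = list(),
                             monadic_root = "PATO:0001237",
                             relational_root = "PATO:0001238") {
  stopifnot(inherits(dataset, "eq_dataset"), inherits(ontology, "eq_ontology"))
  issues <- list()
  add <- function(...) issues[[length(issues) + 1L]] <<- new_issue(...)

  check_term <- function(id, field, taxon = NA, character = NA, state = NA) {
    t <- ontology$terms[[id]]
    if (is.null(t)) {
      add("error", "unknown-term",
          paste0(field, " term ", id, " not found in ontology"),
          taxon, character, state)
      return(invisible())
    }
    if (t$obsolete) {
      hint <- if (!is.null(t$replaced_by)) {
        paste0(" (replaced by ", t$replaced_by, ")")
      } else ""
      add("warning", "obsolete-term",
          paste0(field, " term ", id, " is obsolete", hint),
          taxon, character, state)
    }
    f <- filters[[field]]
    if (!is.null(f) && !filter_admits(ontology, id, f)) {
      add("warning", "filter-violation",
          paste0(field, " term ", id, " violates the ", field,
                 " field filter"),
          taxon, character, state)
    }
    invisible()
  }

  # find the "count" quality (by name) for the count/quality coherence check
  count_id <- NULL
  for (t in ontology$terms) {
    if (!t$obsolete && identical(tolower(t$name), "count")) {
      count_id <- t$id
      break
    }
  }

  for (tx in dataset$taxa) {
    if (!is.null(tx$valid_taxon)) {
      check_term(tx$valid_taxon, "taxon", taxon = tx$publication_name)
    }
    for (sp in tx$specimens) {
      check_term(sp$collection, "collection", taxon = tx$publication_name)
    }
  }

  for (ch in dataset$characters) {
    for (st in ch$states) {
      loc <- list(character = ch$index, state = st$symbol)
      if (length(st$phenotypes) == 0) {
        add("warning", "empty-state",
            paste0("state ", st$symbol, " of character ", ch$index,
                   " has no phenotypes"),
            character = ch$index, state = st$symbol)
      }
      for (p in st$phenotypes) {
        for (id in entity_term_ids(p$entity)) {
          check_term(id, "entity", character = ch$index, state = st$symbol)
        }
        check_term(p$quality, "quality", character = ch$index,
                   state = st$symbol)
        if (!is.null(p$related_entity)) {
          for (id in entity_term_ids(p$related_entity)) {
            check_term(id, "related_entity", character = ch$index,
                       state = st$symbol)
          }
        }
        if (!is.null(p$unit)) {
          check_term(p$unit, "unit", character = ch$index, state = st$symbol)
        }
        if (!is.null(p$measurement) && is.null(p$unit)) {
          add("error", "measurement-without-unit",
              "measurement value given without a unit term",
              character = ch$index, state = st$symbol)
        }
        qt <- ontology$terms[[p$quality]]
        if (!is.null(qt) && !qt$obsolete) {
          anc <- ancestors(ontology, p$quality, "is_a")
          if (!is.null(p$related_entity) && monadic_root %in% anc) {
            add("warning", "relational-mismatch",
                paste0("related entity given but quality ", p$quality,
                       " is a single-entity quality"),
                character = ch$index, state = st$symbol)
          }
          if (!is.null(p$count) && !is.null(count_id) &&
              p$quality != count_id && !(count_id %in% anc)) {
            add("warning", "count-mismatch",
                paste0("count given but quality ", p$quality,
                       " is not a count quality"),
                character = ch$index, state = st$symbol)
          }
        }
      }
    }
  }

  nchar_ <- length(dataset$characters)
  for (tn in names(dataset$matrix)) {
    row <- dataset$matrix[[tn]]
    if (length(row) != nchar_) {
      add("error", "row-length",
          paste0("matrix row for ", tn, " has ", length(row),
                 " cells; expected ", nchar_),
          taxon = tn)
      next
    }
    for (j in seq_along(row)) {
      cell <- row[[j]]
      if (!length(cell$symbols)) next
      legal <- vapply(dataset$characters[[j]]$states, `[[`, character(1),
                      "symbol")
      bad <- setdiff(cell$symbols, legal)
      if (length(bad)) {
        add("error", "undefined-symbol",
            paste0("cell (", tn, ", ", j, ") references undefined state ",
                   "symbol(s): ", paste(bad, collapse = ", ")),
            taxon = tn, character = j)
      }
    }
  }

  if (length(issues)) do.call(rbind, issues) else no_issues()
}

#' Keep only the errors from an issue report
#' @param issues data.frame returned by [validate_dataset()].
#' @return subset with severity == "error".
#' @export
validation_errors <- function(issues) {
  issues[issues$severity == "error", , drop = FALSE]
}
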