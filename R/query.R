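#' @title Matrix-derived "exhibits" annotations and closure queries
#' @name query
#' @description
#' The character-by-taxon matrix implicitly links every taxon to the EQ
#' phenotypes of the state recorded in each of its cells. This module
#' makes those links explicit as (taxon, state, phenotype) annotation
#' triples and answers ontology-closure queries over them, so that
#' lexically dissimilar phenotype descriptions attached to parts of the
#' same anatomical structure can be retrieved together.
NULL

#' Derive taxon-to-phenotype annotation triples from the matrix
#'
#' One triple per (cell, matching state, attached phenotype). Missing and
#' gap cells contribute nothing; polymorphic cells contribute triples for
#' every contained symbol, flagged `polymorphic = TRUE`. Output order is
#' stable: taxa in dataset order, characters in index order, phenotypes
#' in attachment order.
#'
#' @param dataset a validated `eq_dataset`.
#' @return list of annotation triples, each a list with fields `taxon`
#'   (publication name), `valid_taxon`, `character_index`,
#'   `state_symbol`, `phenotype`, `polymorphic`, `source` (the dataset's
#'   publication citation).
#' @export
exhibits <- function(dataset) {
  stopifnot(inherits(dataset, "eq_dataset"))
  out <- list()
  for (tx in dataset$taxa) {
    tn <- tx$publication_name
    row <- dataset$matrix[[tn]]
    if (is.null(row)) next
    for (j in seq_along(row)) {
      cell <- row[[j]]
      if (!length(cell$symbols)) next
      ch <- dataset$characters[[j]]
      for (sym in cell$symbols) {
        for (st in ch$states) {
          if (st$symbol != sym) next
          for (p in st$phenotypes) {
            out[[length(out) + 1L]] <- list(
              taxon = tn, valid_taxon = tx$valid_taxon,
              character_index = ch$index, state_symbol = sym,
              phenotype = p,
              polymorphic = cell$type == "polymorphic",
              source = dataset$publication)
          }
        }
      }
    }
  }
  out
}

#' Filter annotation triples by anatomical entity, with closure
#'
#' Keeps triples whose phenotype entity (the genus, for post-composed
#' entities) either equals `target` or has `target` among its ancestors
#' via `is_a` (always) and `part_of` (when `include_parts` is TRUE).
#' Related entities are not considered, and post-composition differentia
#' fillers are not traversed.
#'
#' @param triples list of triples from [exhibits()].
#' @param ontology the entity (anatomy) ontology.
#' @param target term id to query; must exist in the ontology.
#' @param include_parts also follow `part_of` chains.
#' @return the matching subset, in input order.
#' @export
phenotypes_of_entity <- function(triples, ontology, target,
                                 include_parts = TRUE) {
  if (is.null(ontology$terms[[target]])) {
    stop("unknown term: ", target, call. = FALSE)
  }
  rels <- if (include_parts) c("is_a", "part_of") else "is_a"
  keep <- vapply(triples, function(tr) {
    g <- entity_genus(tr$phenotype$entity)
    if (identical(g, target)) return(TRUE)
    if (is.null(ontology$terms[[g]])) return(FALSE)
    target %in% ancestors(ontology, g, rels)
  }, logical(1))
  triples[keep]
}

#' Summarize a collection of annotated datasets
#'
#' @param datasets list of `eq_dataset`.
#' @param quality_ontology optional quality ontology enabling the
#'   per-category character tallies (a character is tallied under every
#'   category any of its states falls into).
#' @return list with counts: `datasets`, `taxa`, `characters`, `states`,
#'   `phenotypes` (distinct EQ statements by canonical rendering),
#'   `annotations` (exhibits triples), and `categories` (named integer
#'   vector over monadic/relational/composite/quantitative, when a
#'   quality ontology is given).
#' @export
summarize_datasets <- function(datasets, quality_ontology = NULL) {
  n_taxa <- 0L; n_chars <- 0L; n_states <- 0L; n_annot <- 0L
  pheno_keys <- character()
  cats <- c(monadic = 0L, relational = 0L, composite = 0L,
            quantitative = 0L)
  for (d in datasets) {
    stopifnot(inherits(d, "eq_dataset"))
    n_taxa <- n_taxa + length(d$taxa)
    n_chars <- n_chars + length(d$characters)
    for (ch in d$characters) {
      n_states <- n_states + length(ch$states)
      ch_cats <- character()
      for (st in ch$states) {
        for (p in st$phenotypes) {
          pheno_keys <- c(pheno_keys, phenotype_key(p))
        }
        if (!is.null(quality_ontology)) {
          ch_cats <- union(ch_cats,
                           classify_state(st, quality_ontology))
        }
      }
      for (cc in ch_cats) cats[[cc]] <- cats[[cc]] + 1L
    }
    n_annot <- n_annot + length(exhibits(d))
  }
  list(datasets = length(datasets), taxa = n_taxa, characters = n_chars,
       states = n_states, phenotypes = length(unique(pheno_keys)),
       annotations = n_annot,
       categories = if (is.null(quality_ontology)) NULL else cats)
}

# canonical identity of an EQ statement, for distinct-phenotype counting
phenotype_key <- function(p) {
  paste(
    format_entity(p$entity), p$quality,
    if (is.null(p$related_entity)) "" else format_entity(p$related_entity),
    if (is.null(p$count)) "" else format(p$count),
    if (is.null(p$measurement)) "" else paste0(p$measurement, p$unit),
    sep = "|")
}

#' Export annotation triples as a tab-separated table
#'
#' Columns: taxon, valid-taxon CURIE, character index, state symbol,
#' entity (canonical rendering), quality, related entity, count,
#' polymorphic flag, source.
#'
#' @param triples list from [exhibits()].
#' @param path optional file to write to.
#' @return data.frame (invisibly when `path` is given).
#' @export
triples_to_table <- function(triples, path = NULL) {
  df <- data.frame(
    taxon = vapply(triples, `[[`, character(1), "taxon"),
    valid_taxon = vapply(triples, function(t)
      if (is.null(t$valid_taxon)) "" else t$valid_taxon, character(1)),
    character = vapply(triples, `[[`, integer(1), "character_index"),
    state = vapply(triples, `[[`, character(1), "state_symbol"),
    entity = vapply(triples, function(t)
      format_entity(t$phenotype$entity), character(1)),
    quality = vapply(triples, function(t) t$phenotype$quality,
                     character(1)),
    related_entity = vapply(triples, function(t)
      if (is.null(t$phenotype$related_entity)) "" else
        format_entity(t$phenotype$related_entity), character(1)),
    count = vapply(triples, function(t)
      if (is.null(t$phenotype$count)) "" else format(t$phenotype$count),
      character(1)),
    polymorphic = vapply(triples, `[[`, logical(1), "polymorphic"),
    source = vapply(triples, `[[`, character(1), "source"),
    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(df))
  }
  df
}
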