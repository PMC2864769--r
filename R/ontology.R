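#' @title OBO ontologies: parsing, merging, search and closure
#' @name ontology
#' @description
#' Minimal in-memory ontology model backing Entity-Quality annotation:
#' terms with synonyms, namespaces, subsets ("slims") and obsolescence,
#' plus a typed edge list (`is_a`, `part_of`, and any other OBO
#' relationship). Only the OBO 1.2 flat-file syntax is supported.
NULL

#' Validate a CURIE-style term identifier
#'
#' A term id has the form `PREFIX:LOCAL` where the prefix is non-empty and
#' colon-free and the local part is non-empty (e.g. `"TAO:0000250"`).
#'
#' @param x character vector of candidate ids.
#' @return logical vector.
#' @export
is_term_id <- function(x) {
  grepl("^[^:[:space:]]+:[^[:space:]]+$", x) & !grepl("^.+:.*:", x)
}

#' Construct an ontology term record
#'
#' @param id term id (CURIE string).
#' @param name term name; required for non-obsolete terms.
#' @param namespace OBO namespace, may be `""`.
#' @param synonyms character vector of synonym strings.
#' @param synonym_scopes character vector parallel to `synonyms`
#'   (EXACT/BROAD/NARROW/RELATED); parsed but not used in ranking.
#' @param subsets character vector of subset (slim) names.
#' @param obsolete logical flag.
#' @param replaced_by replacement term id, only for obsolete terms.
#' @param definition optional definition string.
#' @return a list of class `eq_term`.
#' @export
eq_term <- function(id, name = "", namespace = "", synonyms = character(),
                    synonym_scopes = rep("RELATED", length(synonyms)),
                    subsets = character(), obsolete = FALSE,
                    replaced_by = NULL, definition = NULL) {
  if (!is_term_id(id)) stop("invalid term id: ", id, call. = FALSE)
  if (!obsolete && !nzchar(name)) {
    stop("non-obsolete term ", id, " must have a name", call. = FALSE)
  }
  if (!is.null(replaced_by) && !obsolete) {
    stop("replaced_by is only valid on obsolete terms (", id, ")", call. = FALSE)
  }
  structure(list(id = id, name = name, namespace = namespace,
                 synonyms = as.character(synonyms),
                 synonym_scopes = as.character(synonym_scopes),
                 subsets = as.character(subsets),
                 obsolete = isTRUE(obsolete),
                 replaced_by = replaced_by, definition = definition),
            class = "eq_term")
}

new_ontology <- function(terms = list(), edges = empty_edges(), sources = character()) {
  structure(list(terms = terms, edges = edges, sources = sources),
            class = "eq_ontology")
}

empty_edges <- function() {
  data.frame(subject = character(), predicate = character(),
             object = character(), stringsAsFactors = FALSE)
}

#' @export
print.eq_ontology <- function(x, ...) {
  cat("<eq_ontology> ", length(x$terms), " terms, ", nrow(x$edges),
      " edges (", paste(unique(x$edges$predicate), collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

# strip an OBO trailing comment ("! ...") that is outside quotes
strip_obo_comment <- function(x) {
  in_q <- FALSE
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "\\") i <- i + 1L
    else if (ch == "\"") in_q <- !in_q
    else if (ch == "!" && !in_q) return(trimws(substr(x, 1L, i - 1L)))
    i <- i + 1L
  }
  trimws(x)
}

# first double-quoted string in x, honoring backslash escapes; NA if none
first_quoted <- function(x) {
  m <- regmatches(x, regexpr('"(\\\\.|[^"\\\\])*"', x))
  if (length(m) == 0) return(NA_character_)
  body <- substr(m, 2L, nchar(m) - 1L)
  gsub("\\\\(.)", "\\1", body)
}

#' Parse an OBO 1.2 flat file
#'
#' Supported stanza: `[Term]`. Supported tags: `id`, `name`, `namespace`,
#' `def`, `synonym`, `subset`, `is_a`, `relationship`, `is_obsolete`,
#' `replaced_by`. Unknown tags are ignored with a logged notice. The
#' header's `default-namespace` applies to terms lacking an explicit
#' namespace. Edge targets that do not resolve to a parsed term are
#' reported as dangling-reference warnings (common when a multi-ontology
#' configuration cross-references), never as errors.
#'
#' @param source path to an OBO file, or a character vector of lines, or a
#'   single string containing newlines.
#' @param quiet suppress unknown-tag notices.
#' @return an object of class `eq_ontology`.
#' @export
parse_obo <- function(source, quiet = FALSE) {
  lines <- read_text_lines(source)
  src <- if (length(source) == 1 && !grepl("\n", source) && file.exists(source))
    source else "<memory>"

  default_ns <- ""
  terms <- list()
  edges_s <- character(); edges_p <- character(); edges_o <- character()
  unknown_tags <- character()

  in_term <- FALSE
  in_other_stanza <- FALSE
  cur <- NULL
  cur_line <- 0L

  flush_term <- function() {
    if (is.null(cur)) return()
    if (is.null(cur$id)) {
      stop("OBO parse error: [Term] stanza starting at line ", cur_line,
           " has no id", call. = FALSE)
    }
    ns <- if (nzchar(cur$namespace)) cur$namespace else default_ns
    t <- eq_term(cur$id, name = cur$name, namespace = ns,
                 synonyms = cur$synonyms, synonym_scopes = cur$scopes,
                 subsets = cur$subsets, obsolete = cur$obsolete,
                 replaced_by = cur$replaced_by, definition = cur$definition)
    terms[[cur$id]] <<- t
    if (length(cur$edge_p)) {
      edges_s <<- c(edges_s, rep(cur$id, length(cur$edge_p)))
      edges_p <<- c(edges_p, cur$edge_p)
      edges_o <<- c(edges_o, cur$edge_o)
    }
  }
  blank_term <- function() list(id = NULL, name = "", namespace = "",
                                synonyms = character(), scopes = character(),
                                subsets = character(), obsolete = FALSE,
                                replaced_by = NULL, definition = NULL,
                                edge_p = character(), edge_o = character())

  for (i in seq_along(lines)) {
    raw <- lines[[i]]
    line <- strip_obo_comment(raw)
    if (!nzchar(line)) next
    if (grepl("^\\[", line)) {
      flush_term()
      cur <- NULL
      if (identical(line, "[Term]")) {
        in_term <- TRUE; in_other_stanza <- FALSE
        cur <- blank_term(); cur_line <- i
      } else {
        in_term <- FALSE; in_other_stanza <- TRUE
      }
      next
    }
    kv <- regmatches(line, regexec("^([A-Za-z_-]+):\\s*(.*)$", line))[[1]]
    if (length(kv) != 3) next
    tag <- kv[2]; val <- trimws(kv[3])
    if (!in_term && !in_other_stanza) {              # header
      if (tag == "default-namespace") default_ns <- val
      next
    }
    if (!in_term) next                               # skip [Typedef] etc.
    switch(tag,
      id = {
        if (!is.null(cur$id))
          stop("OBO parse error at line ", i, ": duplicate id tag", call. = FALSE)
        cur$id <- val
      },
      name = cur$name <- val,
      namespace = cur$namespace <- val,
      def = cur$definition <- first_quoted(val),
      synonym = {
        syn <- first_quoted(val)
        if (!is.na(syn)) {
          rest <- sub('^"(\\\\.|[^"\\\\])*"\\s*', "", val)
          scope <- regmatches(rest, regexpr("^[A-Z]+", rest))
          cur$synonyms <- c(cur$synonyms, syn)
          cur$scopes <- c(cur$scopes,
                          if (length(scope)) scope else "RELATED")
        }
      },
      subset = cur$subsets <- c(cur$subsets, val),
      is_a = {
        cur$edge_p <- c(cur$edge_p, "is_a")
        cur$edge_o <- c(cur$edge_o, strsplit(val, "\\s+")[[1]][1])
      },
      relationship = {
        parts <- strsplit(val, "\\s+")[[1]]
        if (length(parts) >= 2) {
          cur$edge_p <- c(cur$edge_p, parts[1])
          cur$edge_o <- c(cur$edge_o, parts[2])
        }
      },
      is_obsolete = cur$obsolete <- tolower(val) == "true",
      replaced_by = cur$replaced_by <- val,
      unknown_tags <- c(unknown_tags, tag)
    )
  }
  flush_term()

  if (length(unknown_tags) && !quiet) {
    message("parse_obo: ignored unknown tag(s): ",
            paste(sort(unique(unknown_tags)), collapse = ", "))
  }
  edges <- data.frame(subject = edges_s, predicate = edges_p,
                      object = edges_o, stringsAsFactors = FALSE)
  onto <- new_ontology(terms, edges, sources = src)
  dangling <- setdiff(edges$object, names(terms))
  if (length(dangling)) {
    warning("parse_obo: ", length(dangling),
            " dangling edge target(s): ",
            paste(utils::head(sort(dangling), 5), collapse = ", "),
            call. = FALSE)
  }
  if (has_isa_cycle(onto)) {
    warning("parse_obo: is_a edge set contains a cycle", call. = FALSE)
  }
  onto
}

read_text_lines <- function(source) {
  if (length(source) == 1 && grepl("\n", source)) {
    strsplit(source, "\n", fixed = TRUE)[[1]]
  } else if (length(source) == 1 && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    as.character(source)
  }
}

has_isa_cycle <- function(ontology) {
  isa <- ontology$edges[ontology$edges$predicate == "is_a", , drop = FALSE]
  if (!nrow(isa)) return(FALSE)
  adj <- split(isa$object, isa$subject)
  color <- new.env(parent = emptyenv())
  visit <- function(v) {
    st <- get0(v, color, ifnotfound = 0L)
    if (st == 1L) return(TRUE)
    if (st == 2L) return(FALSE)
    assign(v, 1L, color)
    for (w in adj[[v]]) if (visit(w)) return(TRUE)
    assign(v, 2L, color)
    FALSE
  }
  for (v in names(adj)) if (visit(v)) return(TRUE)
  FALSE
}

#' Serialize an ontology to OBO 1.2 text
#'
#' Terms are emitted sorted by id for deterministic output; each term's
#' outgoing edges appear inside its stanza (`is_a:` lines for subsumption,
#' `relationship:` lines otherwise) in their stored order.
#'
#' @param ontology an `eq_ontology`.
#' @param default_namespace optional header default-namespace.
#' @return a single string of OBO text.
#' @export
write_obo <- function(ontology, default_namespace = NULL) {
  out <- c("format-version: 1.2")
  if (!is.null(default_namespace)) {
    out <- c(out, paste0("default-namespace: ", default_namespace))
  }
  q <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')
  for (id in sort(names(ontology$terms), method = "radix")) {
    t <- ontology$terms[[id]]
    out <- c(out, "", "[Term]", paste0("id: ", t$id))
    if (nzchar(t$name)) out <- c(out, paste0("name: ", t$name))
    if (nzchar(t$namespace) && !identical(t$namespace, default_namespace)) {
      out <- c(out, paste0("namespace: ", t$namespace))
    }
    if (!is.null(t$definition)) {
      out <- c(out, paste0("def: ", q(t$definition), " []"))
    }
    for (j in seq_along(t$synonyms)) {
      out <- c(out, paste0("synonym: ", q(t$synonyms[j]), " ",
                           t$synonym_scopes[j], " []"))
    }
    for (s in t$subsets) out <- c(out, paste0("subset: ", s))
    e <- ontology$edges[ontology$edges$subject == id, , drop = FALSE]
    for (j in seq_len(nrow(e))) {
      out <- c(out, if (e$predicate[j] == "is_a") {
        paste0("is_a: ", e$object[j])
      } else {
        paste0("relationship: ", e$predicate[j], " ", e$object[j])
      })
    }
    if (t$obsolete) out <- c(out, "is_obsolete: true")
    if (!is.null(t$replaced_by)) out <- c(out, paste0("replaced_by: ", t$replaced_by))
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Merge several ontologies into one
#'
#' Terms and edges are unioned. A term id occurring in more than one source
#' is resolved last-loaded-wins, with one warning per duplicated id.
#' Duplicate edges collapse to a single edge.
#'
#' @param ontologies list of `eq_ontology` objects.
#' @return a merged `eq_ontology`.
#' @export
merge_ontologies <- function(ontologies) {
  stopifnot(is.list(ontologies))
  if (length(ontologies) == 0) return(new_ontology())
  terms <- list()
  edges <- empty_edges()
  sources <- character()
  for (o in ontologies) {
    stopifnot(inherits(o, "eq_ontology"))
    dup <- intersect(names(terms), names(o$terms))
    for (d in dup) {
      warning("merge_ontologies: duplicate term ", d,
              " (last loaded wins)", call. = FALSE)
    }
    terms[names(o$terms)] <- o$terms
    edges <- rbind(edges, o$edges)
    sources <- c(sources, o$sources)
  }
  edges <- unique(edges)
  rownames(edges) <- NULL
  new_ontology(terms, edges, unique(sources))
}

#' Term filter for entry fields
#'
#' Restricts which terms an annotation field may draw on: by namespace,
#' by subset (slim), and/or by requiring a given ancestor via a set of
#' relations. An empty filter admits every non-obsolete term.
#'
#' @param namespaces optional character vector of admissible namespaces.
#' @param subsets optional character vector of admissible subset names.
#' @param ancestor optional list(`id` = TermId, `relations` = character
#'   vector of relation ids) requiring `id` among the term's ancestors.
#' @return object of class `eq_term_filter`.
#' @export
term_filter <- function(namespaces = NULL, subsets = NULL, ancestor = NULL) {
  if (!is.null(ancestor)) {
    stopifnot(is.list(ancestor), !is.null(ancestor$id))
    if (is.null(ancestor$relations)) ancestor$relations <- c("is_a", "part_of")
  }
  structure(list(namespaces = namespaces, subsets = subsets,
                 ancestor = ancestor),
            class = "eq_term_filter")
}

#' Does a term pass a filter?
#'
#' @param ontology the ontology the term lives in (needed for ancestor
#'   constraints).
#' @param term an `eq_term` or a term id present in `ontology`.
#' @param filter an `eq_term_filter`.
#' @return TRUE/FALSE.
#' @export
filter_admits <- function(ontology, term, filter) {
  if (is.character(term)) term <- ontology$terms[[term]]
  if (is.null(term)) return(FALSE)
  if (!is.null(filter$namespaces) && !(term$namespace %in% filter$namespaces)) {
    return(FALSE)
  }
  if (!is.null(filter$subsets) && !any(term$subsets %in% filter$subsets)) {
    return(FALSE)
  }
  if (!is.null(filter$ancestor)) {
    anc <- ancestors(ontology, term$id, filter$ancestor$relations)
    if (!(filter$ancestor$id %in% anc)) return(FALSE)
  }
  TRUE
}

#' Ranked term search
#'
#' Case-insensitive matching over names and synonyms with tiered ranking:
#' exact name match, then name prefix, synonym prefix, name substring,
#' synonym substring. Ties within a tier break lexicographically by term
#' id, so ranking is deterministic. Obsolete terms are never returned.
#'
#' @param ontology an `eq_ontology`.
#' @param query non-empty query string.
#' @param filter an `eq_term_filter`; defaults to the empty filter.
#' @param limit maximum number of results.
#' @return list of `eq_term`, best first.
#' @export
search_terms <- function(ontology, query, filter = term_filter(), limit = 10L) {
  query <- trimws(query)
  if (!nzchar(query)) stop("query must be non-empty", call. = FALSE)
  q <- tolower(query)
  ids <- character(); tiers <- integer()
  for (t in ontology$terms) {
    if (t$obsolete) next
    if (!filter_admits(ontology, t, filter)) next
    nm <- tolower(t$name)
    sy <- tolower(t$synonyms)
    tier <- if (nm == q) 1L
      else if (startsWith(nm, q)) 2L
      else if (any(startsWith(sy, q))) 3L
      else if (grepl(q, nm, fixed = TRUE)) 4L
      else if (any(grepl(q, sy, fixed = TRUE))) 5L
      else NA_integer_
    if (!is.na(tier)) { ids <- c(ids, t$id); tiers <- c(tiers, tier) }
  }
  if (!length(ids)) return(list())
  ord <- order(tiers, ids, method = "radix")
  ids <- ids[ord][seq_len(min(limit, length(ids)))]
  lapply(ids, function(i) ontology$terms[[i]])
}

#' Transitive ancestors via selected relations
#'
#' All terms reachable from `start` along edge chains whose predicates all
#' lie in `relations` (so a chain mixing `is_a` and `part_of` links yields
#' a part-ancestor whenever both relations are selected). The start term
#' itself is excluded.
#'
#' @param ontology an `eq_ontology`.
#' @param start a term id present in the ontology.
#' @param relations character vector of relation ids to traverse.
#' @return character vector of ancestor term ids (unordered set).
#' @export
ancestors <- function(ontology, start, relations = c("is_a", "part_of")) {
  if (is.null(ontology$terms[[start]])) {
    stop("unknown term: ", start, call. = FALSE)
  }
  e <- ontology$edges[ontology$edges$predicate %in% relations, , drop = FALSE]
  if (!nrow(e)) return(character())
  adj <- split(e$object, e$subject)
  seen <- new.env(parent = emptyenv())
  queue <- start
  out <- character()
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (is.null(get0(w, seen))) {
        assign(w, TRUE, seen)
        out <- c(out, w)
        queue <- c(queue, w)
      }
    }
  }
  setdiff(out, start)
}
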