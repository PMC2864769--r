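#' @title NeXML serialization with embedded EQ metadata
#' @name nexml
#' @description
#' The native on-disk format: a NeXML (http://www.nexml.org) document
#' carrying the taxa/characters/matrix skeleton plus RDFa-style metadata
#' annotations. Literal values live in a `content` attribute, resource
#' values (ontology identifiers) in an `href` attribute as OBO PURLs, and
#' EQ phenotypes are embedded as PhenoXML fragments under a
#' `describesPhenotype` annotation on each character state. Metadata
#' vocabulary: Dublin Core for document provenance (creator, references,
#' description), Darwin Core for taxa and voucher specimens (taxonID,
#' individualID, collectionID, catalogNumber), RDF-Schema comments, and
#' curation-specific identifiers (hasMatrixName, inFigure,
#' describesPhenotype) in the http://vocab.phenoscape.org/ namespace.
#' Writing is deterministic: the same dataset always yields byte-identical
#' output.
NULL

#' Fixed namespace prefixes used in NeXML output
#' @return named character vector prefix -> namespace URI.
#' @export
nexml_namespaces <- function() {
  c(dc    = "http://purl.org/dc/terms/",
    dwc   = "http://rs.tdwg.org/dwc/terms/",
    rdfs  = "http://www.w3.org/2000/01/rdf-schema#",
    ps    = "http://vocab.phenoscape.org/",
    pheno = "http://www.bioontologies.org/obd/schema/pheno")
}

obo_purl_prefix <- "http://purl.obolibrary.org/obo/"

#' Convert a CURIE to an OBO PURL and back
#'
#' `"TAO:0000250"` maps to `"http://purl.obolibrary.org/obo/TAO_0000250"`.
#'
#' @param curie term id string.
#' @return PURL string.
#' @export
curie_to_purl <- function(curie) {
  paste0(obo_purl_prefix, sub(":", "_", curie, fixed = TRUE))
}

#' @rdname curie_to_purl
#' @param purl OBO PURL string.
#' @export
purl_to_curie <- function(purl) {
  local <- sub(obo_purl_prefix, "", purl, fixed = TRUE)
  sub("_", ":", local, fixed = TRUE)
}

add_literal_meta <- function(parent, property, content) {
  xml2::xml_add_child(parent, "meta", "xsi:type" = "LiteralMeta",
                      property = property, content = content)
}

add_resource_meta <- function(parent, rel, href = NULL) {
  if (is.null(href)) {
    xml2::xml_add_child(parent, "meta", "xsi:type" = "ResourceMeta",
                        rel = rel)
  } else {
    xml2::xml_add_child(parent, "meta", "xsi:type" = "ResourceMeta",
                        rel = rel, href = href)
  }
}

add_comment_figures <- function(parent, comment, figures) {
  if (!is.null(comment)) add_literal_meta(parent, "rdfs:comment", comment)
  for (f in figures) add_literal_meta(parent, "ps:inFigure", f)
  invisible()
}

add_extras <- function(parent, x) {
  for (s in x$extras) {
    # re-parse inside a wrapper that declares the standard prefixes, so
    # fragments serialized out of context stay namespace-well-formed
    ns <- nexml_namespaces()
    wrap <- paste0(
      '<wrap xmlns:xsi="http://www.w3.org/2001/XMLSchema-instance"',
      ' xmlns:dc="', ns[["dc"]], '" xmlns:dwc="', ns[["dwc"]],
      '" xmlns:rdfs="', ns[["rdfs"]], '" xmlns:ps="', ns[["ps"]],
      '" xmlns:pheno="', ns[["pheno"]], '">', s, "</wrap>")
    node <- xml2::xml_child(xml2::read_xml(wrap))
    xml2::xml_add_child(parent, node)
  }
  invisible()
}

#' Encode an entity reference or post-composition as a PhenoXML typeref
#'
#' A plain term becomes `<typeref about="CURIE"/>`; a post-composition
#' becomes a typeref on the genus with one nested `qualifier` child per
#' differentia, each holding the relation id and the filler (recursively
#' a typeref).
#'
#' @param parent xml node to attach to.
#' @param pc a term id string or an `eq_postcomp`.
#' @param comment optional comment attribute.
#' @return the new typeref node, invisibly.
#' @export
encode_postcomposition <- function(parent, pc, comment = NULL) {
  about <- if (is.character(pc)) pc else pc$genus
  attrs <- list(parent, "pheno:typeref", about = about)
  if (!is.null(comment)) attrs$comment <- comment
  node <- do.call(xml2::xml_add_child, attrs)
  if (!is.character(pc)) {
    for (d in pc$differentia) {
      q <- xml2::xml_add_child(node, "pheno:qualifier", relation = d$relation)
      encode_postcomposition(q, d$filler)
    }
  }
  invisible(node)
}

encode_entity_ref <- function(parent, wrapper, e) {
  w <- xml2::xml_add_child(parent, paste0("pheno:", wrapper))
  pc <- if (!is.null(e$term)) e$term else e$composed
  encode_postcomposition(w, pc, comment = e$comment)
  invisible(w)
}

encode_phenotype_block <- function(parent, phenotypes) {
  blk <- xml2::xml_add_child(parent, "pheno:phenotype")
  for (p in phenotypes) {
    attrs <- list(blk, "pheno:phenotype_character")
    if (!is.null(p$comment)) attrs$comment <- p$comment
    pcn <- do.call(xml2::xml_add_child, attrs)
    encode_entity_ref(pcn, "bearer", p$entity)
    qattrs <- list(pcn, "pheno:quality")
    if (!is.null(p$count)) {
      qattrs$count_min <- as.character(p$count$min)
      qattrs$count_max <- as.character(p$count$max)
    }
    if (!is.null(p$measurement)) qattrs$measurement <- p$measurement
    if (!is.null(p$unit)) qattrs$unit <- p$unit
    qn <- do.call(xml2::xml_add_child, qattrs)
    encode_postcomposition(qn, p$quality)
    if (!is.null(p$related_entity)) {
      encode_entity_ref(pcn, "related_entity", p$related_entity)
    }
  }
  invisible(blk)
}

state_id <- function(j, k) paste0("c", j, "s", k)

#' Serialize a dataset as NeXML
#'
#' When an ontology is supplied the dataset is validated first and
#' writing refuses if any validation *errors* are present (warnings are
#' allowed); without an ontology only structural invariants are checked.
#'
#' @param dataset an `eq_dataset`.
#' @param path optional output file path.
#' @param ontology optional `eq_ontology` for pre-write validation.
#' @param filters optional field filters forwarded to
#'   [validate_dataset()].
#' @return the document as a single string (invisibly when `path` is
#'   given).
#' @export
write_nexml <- function(dataset, path = NULL, ontology = NULL,
                        filters = list()) {
  stopifnot(inherits(dataset, "eq_dataset"))
  if (!is.null(ontology)) {
    issues <- validate_dataset(dataset, ontology, filters)
    errs <- validation_errors(issues)
    if (nrow(errs)) {
      stop("dataset has validation errors; refusing to write:\n",
           paste0("  - ", errs$message, collapse = "\n"), call. = FALSE)
    }
  }
  ns <- nexml_namespaces()
  root <- xml2::xml_new_root(
    "nexml",
    xmlns = "http://www.nexml.org/2009",
    "xmlns:xsi" = "http://www.w3.org/2001/XMLSchema-instance",
    "xmlns:dc" = ns[["dc"]], "xmlns:dwc" = ns[["dwc"]],
    "xmlns:rdfs" = ns[["rdfs"]], "xmlns:ps" = ns[["ps"]],
    "xmlns:pheno" = ns[["pheno"]],
    version = "0.9")

  for (cu in dataset$curators) add_literal_meta(root, "dc:creator", cu)
  if (nzchar(dataset$publication)) {
    add_literal_meta(root, "dc:references", dataset$publication)
  }
  if (nzchar(dataset$publication_notes)) {
    add_literal_meta(root, "dc:description", dataset$publication_notes)
  }
  add_extras(root, dataset)

  otus <- xml2::xml_add_child(root, "otus", id = "otus1")
  for (i in seq_along(dataset$taxa)) {
    tx <- dataset$taxa[[i]]
    otu <- xml2::xml_add_child(otus, "otu", id = paste0("t", i),
                               label = tx$publication_name)
    if (!is.null(tx$valid_taxon)) {
      add_resource_meta(otu, "dwc:taxonID", curie_to_purl(tx$valid_taxon))
    }
    if (!is.null(tx$matrix_name)) {
      add_literal_meta(otu, "ps:hasMatrixName", tx$matrix_name)
    }
    for (sp in tx$specimens) {
      node <- add_resource_meta(otu, "dwc:individualID")
      add_resource_meta(node, "dwc:collectionID",
                        curie_to_purl(sp$collection))
      add_literal_meta(node, "dwc:catalogNumber", sp$catalog_number)
    }
    add_comment_figures(otu, tx$comment, tx$figures)
    add_extras(otu, tx)
  }

  chars_el <- xml2::xml_add_child(root, "characters", id = "chars1",
                                  otus = "otus1",
                                  "xsi:type" = "StandardCells")
  fmt <- xml2::xml_add_child(chars_el, "format")
  for (j in seq_along(dataset$characters)) {
    ch <- dataset$characters[[j]]
    states_el <- xml2::xml_add_child(fmt, "states",
                                     id = paste0("states", j))
    for (k in seq_along(ch$states)) {
      st <- ch$states[[k]]
      st_el <- xml2::xml_add_child(states_el, "state",
                                   id = state_id(j, k),
                                   symbol = st$symbol, label = st$label)
      add_comment_figures(st_el, st$comment, st$figures)
      if (length(st$phenotypes)) {
        m <- xml2::xml_add_child(st_el, "meta",
                                 "xsi:type" = "LiteralMeta",
                                 property = "ps:describesPhenotype",
                                 datatype = "rdf:XMLLiteral")
        encode_phenotype_block(m, st$phenotypes)
      }
      add_extras(st_el, st)
    }
    # polymorphic / missing / gap cell targets for this character
    syms <- vapply(ch$states, `[[`, character(1), "symbol")
    combos <- poly_combos(dataset, j, syms)
    for (combo in combos) {
      pid <- poly_id(j, combo)
      pel <- xml2::xml_add_child(states_el, "polymorphic_state_set",
                                 id = pid,
                                 symbol = paste0(syms[combo],
                                                 collapse = ""))
      for (k in combo) {
        xml2::xml_add_child(pel, "member", state = state_id(j, k))
      }
    }
    if (cell_type_used(dataset, j, "missing")) {
      xml2::xml_add_child(states_el, "uncertain_state_set",
                          id = paste0("c", j, "missing"), symbol = "?")
    }
    if (cell_type_used(dataset, j, "gap")) {
      xml2::xml_add_child(states_el, "uncertain_state_set",
                          id = paste0("c", j, "gap"), symbol = "-")
    }
  }
  for (j in seq_along(dataset$characters)) {
    ch <- dataset$characters[[j]]
    ch_el <- xml2::xml_add_child(fmt, "char", id = paste0("ch", j),
                                 states = paste0("states", j),
                                 label = ch$label)
    add_comment_figures(ch_el, ch$comment, ch$figures)
    add_extras(ch_el, ch)
  }

  mat_el <- xml2::xml_add_child(chars_el, "matrix")
  taxa_names <- vapply(dataset$taxa, `[[`, character(1), "publication_name")
  for (i in seq_along(taxa_names)) {
    tn <- taxa_names[i]
    row <- dataset$matrix[[tn]]
    if (is.null(row)) next
    row_el <- xml2::xml_add_child(mat_el, "row", id = paste0("r", i),
                                  otu = paste0("t", i))
    for (j in seq_along(row)) {
      cell <- row[[j]]
      syms <- vapply(dataset$characters[[j]]$states, `[[`, character(1),
                     "symbol")
      ref <- switch(cell$type,
        single = state_id(j, match(cell$symbols, syms)),
        polymorphic = poly_id(j, sort(match(cell$symbols, syms))),
        missing = paste0("c", j, "missing"),
        gap = paste0("c", j, "gap"))
      xml2::xml_add_child(row_el, "cell", char = paste0("ch", j),
                          state = ref)
    }
  }

  out <- as.character(root)
  if (!is.null(path)) {
    writeLines(out, path, sep = "")
    return(invisible(out))
  }
  out
}

# distinct polymorphic symbol combinations used for character j, as
# sorted state-position vectors, ordered deterministically
poly_combos <- function(dataset, j, syms) {
  seen <- character()
  combos <- list()
  for (row in dataset$matrix) {
    if (j > length(row)) next
    cell <- row[[j]]
    if (cell$type != "polymorphic") next
    pos <- sort(match(cell$symbols, syms))
    key <- paste(pos, collapse = "_")
    if (!(key %in% seen)) {
      seen <- c(seen, key)
      combos[[length(combos) + 1L]] <- pos
    }
  }
  combos[order(vapply(combos, function(p) paste(sprintf("%04d", p),
                                                collapse = "_"),
                      character(1)), method = "radix")]
}

poly_id <- function(j, positions) {
  paste0("c", j, "p", paste(positions, collapse = "_"))
}

cell_type_used <- function(dataset, j, type) {
  for (row in dataset$matrix) {
    if (j <= length(row) && row[[j]]$type == type) return(TRUE)
  }
  FALSE
}

# ---------------------------------------------------------------- reading

known_meta_names <- c("dc:creator", "dc:references", "dc:description",
                      "dwc:taxonID", "dwc:individualID", "dwc:collectionID",
                      "dwc:catalogNumber", "rdfs:comment",
                      "ps:hasMatrixName", "ps:inFigure",
                      "ps:describesPhenotype")

meta_key <- function(node) {
  p <- xml2::xml_attr(node, "property")
  if (!is.na(p)) p else xml2::xml_attr(node, "rel")
}

child_metas <- function(node) {
  kids <- xml2::xml_children(node)
  kids[xml2::xml_name(kids) == "meta"]
}

# collect comment/figures/extras from a node's meta children
read_common_meta <- function(node) {
  out <- list(comment = NULL, figures = character(), extras = character())
  for (m in child_metas(node)) {
    key <- meta_key(m)
    if (identical(key, "rdfs:comment")) {
      out$comment <- xml2::xml_attr(m, "content")
    } else if (identical(key, "ps:inFigure")) {
      out$figures <- c(out$figures, xml2::xml_attr(m, "content"))
    }
  }
  out
}

decode_typeref <- function(node) {
  about <- xml2::xml_attr(node, "about")
  quals <- xml2::xml_children(node)
  quals <- quals[xml2::xml_name(quals) == "qualifier"]
  if (!length(quals)) return(about)
  differentia <- lapply(quals, function(q) {
    filler_node <- xml2::xml_children(q)
    filler_node <- filler_node[xml2::xml_name(filler_node) == "typeref"][[1]]
    list(relation = xml2::xml_attr(q, "relation"),
         filler = decode_typeref(filler_node))
  })
  compose(about, differentia)
}

decode_entity_ref <- function(wrapper_node) {
  tr <- xml2::xml_children(wrapper_node)
  tr <- tr[xml2::xml_name(tr) == "typeref"][[1]]
  pc <- decode_typeref(tr)
  cm <- xml2::xml_attr(tr, "comment")
  if (is.character(pc) && length(pc) == 1 && !inherits(pc, "eq_postcomp")) {
    entity_ref(term = pc, comment = if (is.na(cm)) NULL else cm)
  } else {
    entity_ref(composed = pc, comment = if (is.na(cm)) NULL else cm)
  }
}

decode_phenotype_block <- function(meta_node) {
  blk <- xml2::xml_children(meta_node)
  blk <- blk[xml2::xml_name(blk) == "phenotype"]
  if (!length(blk)) return(list())
  out <- list()
  for (pcn in xml2::xml_children(blk[[1]])) {
    if (xml2::xml_name(pcn) != "phenotype_character") next
    kids <- xml2::xml_children(pcn)
    bearer <- decode_entity_ref(kids[[which(xml2::xml_name(kids) == "bearer")[1]]])
    qn <- kids[[which(xml2::xml_name(kids) == "quality")[1]]]
    qtr <- xml2::xml_children(qn)
    qtr <- qtr[xml2::xml_name(qtr) == "typeref"][[1]]
    quality <- xml2::xml_attr(qtr, "about")
    cmin <- xml2::xml_attr(qn, "count_min")
    cmax <- xml2::xml_attr(qn, "count_max")
    meas <- xml2::xml_attr(qn, "measurement")
    unit <- xml2::xml_attr(qn, "unit")
    re_idx <- which(xml2::xml_name(kids) == "related_entity")
    re <- if (length(re_idx)) decode_entity_ref(kids[[re_idx[1]]]) else NULL
    cm <- xml2::xml_attr(pcn, "comment")
    out[[length(out) + 1L]] <- phenotype(
      entity = bearer, quality = quality, related_entity = re,
      count = if (!is.na(cmin)) count_range(as.integer(cmin),
                                            as.integer(cmax)) else NULL,
      measurement = if (!is.na(meas)) meas else NULL,
      unit = if (!is.na(unit)) unit else NULL,
      comment = if (is.na(cm)) NULL else cm)
  }
  out
}

collect_extras <- function(node, extra_known = character()) {
  extras <- character()
  for (m in child_metas(node)) {
    key <- meta_key(m)
    if (is.na(key) || !(key %in% c(known_meta_names, extra_known))) {
      warning("read_nexml: unrecognized metadata property '", key,
              "'; preserved verbatim", call. = FALSE)
      extras <- c(extras, as.character(m))
    }
  }
  extras
}

set_extras <- function(obj, extras) {
  if (length(extras)) obj$extras <- extras
  obj
}

#' Read a NeXML document back into a dataset
#'
#' Full inverse of [write_nexml()]: taxa (with valid-taxon ids, matrix
#' names, specimens, comments and figures), characters and states (with
#' comments, figures and embedded EQ phenotypes including
#' post-compositions, counts, measurements and units), the matrix, and
#' the document-level curation metadata are all reconstructed.
#' Unrecognized metadata properties produce a warning and are preserved
#' verbatim in an `extras` field, re-emitted on the next write.
#'
#' @param source path to a NeXML file or a string of XML.
#' @return an `eq_dataset`.
#' @export
read_nexml <- function(source) {
  doc <- xml2::read_xml(source)
  xml2::xml_ns_strip(doc)
  root <- xml2::xml_root(doc)

  curators <- character(); publication <- ""; notes <- ""
  for (m in child_metas(root)) {
    key <- meta_key(m)
    if (identical(key, "dc:creator")) {
      curators <- c(curators, xml2::xml_attr(m, "content"))
    } else if (identical(key, "dc:references")) {
      publication <- xml2::xml_attr(m, "content")
    } else if (identical(key, "dc:description")) {
      notes <- xml2::xml_attr(m, "content")
    }
  }
  doc_extras <- collect_extras(root)

  taxa <- list()
  otu_id2name <- character()
  otus_el <- xml2::xml_find_first(root, "./otus")
  if (!inherits(otus_el, "xml_missing")) {
    for (otu in xml2::xml_children(otus_el)) {
      if (xml2::xml_name(otu) != "otu") next
      label <- xml2::xml_attr(otu, "label")
      valid <- NULL; mname <- NULL; specimens <- list()
      for (m in child_metas(otu)) {
        key <- meta_key(m)
        if (identical(key, "dwc:taxonID")) {
          valid <- purl_to_curie(xml2::xml_attr(m, "href"))
        } else if (identical(key, "ps:hasMatrixName")) {
          mname <- xml2::xml_attr(m, "content")
        } else if (identical(key, "dwc:individualID")) {
          coll <- NULL; cat_no <- NULL
          for (sm in child_metas(m)) {
            skey <- meta_key(sm)
            if (identical(skey, "dwc:collectionID")) {
              coll <- purl_to_curie(xml2::xml_attr(sm, "href"))
            } else if (identical(skey, "dwc:catalogNumber")) {
              cat_no <- xml2::xml_attr(sm, "content")
            }
          }
          if (!is.null(coll) && !is.null(cat_no)) {
            specimens[[length(specimens) + 1L]] <- specimen(coll, cat_no)
          }
        }
      }
      common <- read_common_meta(otu)
      tx <- taxon(publication_name = label, valid_taxon = valid,
                  matrix_name = mname, specimens = specimens,
                  comment = common$comment, figures = common$figures)
      tx <- set_extras(tx, collect_extras(otu))
      taxa[[length(taxa) + 1L]] <- tx
      otu_id2name[[xml2::xml_attr(otu, "id")]] <- label
    }
  }

  characters <- list()
  matrix_rows <- list()
  chars_el <- xml2::xml_find_first(root, "./characters")
  state_lookup <- list()    # state element id -> eq_cell prototype
  if (!inherits(chars_el, "xml_missing")) {
    fmt <- xml2::xml_find_first(chars_el, "./format")
    states_sets <- list()   # states element id -> list(states=..., lookup=...)
    if (!inherits(fmt, "xml_missing")) {
      for (sset in xml2::xml_children(fmt)) {
        if (xml2::xml_name(sset) != "states") next
        sid <- xml2::xml_attr(sset, "id")
        sts <- list(); lookup <- list(); symbols_by_id <- character()
        for (el in xml2::xml_children(sset)) {
          nm <- xml2::xml_name(el)
          if (nm == "state") {
            phenos <- list()
            for (m in child_metas(el)) {
              if (identical(meta_key(m), "ps:describesPhenotype")) {
                phenos <- decode_phenotype_block(m)
              }
            }
            common <- read_common_meta(el)
            st <- eq_state(symbol = xml2::xml_attr(el, "symbol"),
                           label = xml2::xml_attr(el, "label"),
                           comment = common$comment,
                           figures = common$figures,
                           phenotypes = phenos)
            st <- set_extras(st, collect_extras(el))
            sts[[length(sts) + 1L]] <- st
            eid <- xml2::xml_attr(el, "id")
            symbols_by_id[[eid]] <- st$symbol
            lookup[[eid]] <- cell_value("single", st$symbol)
          } else if (nm == "polymorphic_state_set") {
            members <- xml2::xml_children(el)
            members <- members[xml2::xml_name(members) == "member"]
            msyms <- vapply(members, function(mm) {
              symbols_by_id[[xml2::xml_attr(mm, "state")]]
            }, character(1))
            lookup[[xml2::xml_attr(el, "id")]] <-
              cell_value("polymorphic", msyms)
          } else if (nm == "uncertain_state_set") {
            sym <- xml2::xml_attr(el, "symbol")
            lookup[[xml2::xml_attr(el, "id")]] <-
              cell_value(if (identical(sym, "-")) "gap" else "missing")
          }
        }
        states_sets[[sid]] <- list(states = sts, lookup = lookup)
      }
      char_idx <- 0L
      char_id2idx <- integer()
      for (el in xml2::xml_children(fmt)) {
        if (xml2::xml_name(el) != "char") next
        char_idx <- char_idx + 1L
        sid <- xml2::xml_attr(el, "states")
        common <- read_common_meta(el)
        ch <- eq_character(index = char_idx,
                           label = xml2::xml_attr(el, "label"),
                           comment = common$comment,
                           figures = common$figures,
                           states = states_sets[[sid]]$states)
        ch <- set_extras(ch, collect_extras(el))
        characters[[char_idx]] <- ch
        char_id2idx[[xml2::xml_attr(el, "id")]] <- char_idx
        for (eid in names(states_sets[[sid]]$lookup)) {
          state_lookup[[eid]] <- states_sets[[sid]]$lookup[[eid]]
        }
      }
      mat <- xml2::xml_find_first(chars_el, "./matrix")
      if (!inherits(mat, "xml_missing")) {
        for (row_el in xml2::xml_children(mat)) {
          if (xml2::xml_name(row_el) != "row") next
          tn <- otu_id2name[[xml2::xml_attr(row_el, "otu")]]
          row <- vector("list", char_idx)
          for (cell_el in xml2::xml_children(row_el)) {
            if (xml2::xml_name(cell_el) != "cell") next
            j <- char_id2idx[[xml2::xml_attr(cell_el, "char")]]
            row[[j]] <- state_lookup[[xml2::xml_attr(cell_el, "state")]]
          }
          matrix_rows[[tn]] <- row
        }
      }
    }
  }

  ds <- eq_dataset(curators = curators, publication = publication,
                   publication_notes = notes, taxa = taxa,
                   characters = characters, matrix = matrix_rows)
  set_extras(ds, doc_extras)
}

#' Enumerate the metadata vocabulary used by a NeXML document
#'
#' Scans every RDFa `meta` element and resolves its `property`/`rel`
#' prefix against the document's namespace declarations.
#'
#' @param source NeXML path or XML string.
#' @return data.frame with columns `local_name`, `namespace_uri`.
#' @export
nexml_meta_vocabulary <- function(source) {
  doc <- xml2::read_xml(source)
  xml2::xml_ns_strip(doc)
  metas <- xml2::xml_find_all(doc, "//meta")
  keys <- vapply(metas, meta_key, character(1))
  keys <- keys[!is.na(keys)]
  if (!length(keys)) {
    return(data.frame(local_name = character(),
                      namespace_uri = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(keys, ":", fixed = TRUE)
  prefix <- vapply(parts, `[[`, character(1), 1)
  local <- vapply(parts, function(p) paste(p[-1], collapse = ":"),
                  character(1))
  # prefixes in our documents are fixed; resolve via the canonical table
  tbl <- c(nexml_namespaces(),
           rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#")
  uri <- unname(tbl[prefix])
  unique(data.frame(local_name = local, namespace_uri = uri,
                    stringsAsFactors = FALSE))
}

#' Structural equality of two datasets
#'
#' Field-for-field comparison after canonicalization: matrix rows are
#' reordered to taxa order (row order in the matrix list carries no
#' meaning).
#'
#' @param a,b `eq_dataset` objects.
#' @return TRUE/FALSE.
#' @export
dataset_equal <- function(a, b) {
  canon <- function(d) {
    tn <- vapply(d$taxa, `[[`, character(1), "publication_name")
    d$matrix <- d$matrix[intersect(tn, names(d$matrix))]
    d
  }
  identical(canon(a), canon(b))
}
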