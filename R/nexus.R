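#' @title NEXUS import
#' @name nexus
#' @description
#' Reader for the NEXUS dialect emitted by matrix editors such as
#' Mesquite: TAXA, CHARACTERS and DATA blocks with DIMENSIONS, FORMAT
#' (SYMBOLS / MISSING / GAP / INTERLEAVE), TAXLABELS, CHARSTATELABELS
#' (or CHARLABELS + STATELABELS) and MATRIX commands. Square-bracket
#' comments are stripped, quoted labels are preserved verbatim, and
#' underscores in unquoted labels become spaces per NEXUS convention.
#' Other blocks (TREES, ASSUMPTIONS, ...) are skipped with a notice.
NULL

# Replace [...] comments (which may nest) with spaces, preserving line
# structure; comments do not start inside single-quoted tokens.
strip_nexus_comments <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  in_quote <- FALSE
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (depth > 0L) {
      if (ch == "[") depth <- depth + 1L
      else if (ch == "]") depth <- depth - 1L
      if (ch != "\n") chars[i] <- " "
    } else if (in_quote) {
      if (ch == "'") in_quote <- FALSE
    } else {
      if (ch == "'") in_quote <- TRUE
      else if (ch == "[") { depth <- 1L; chars[i] <- " " }
    }
    i <- i + 1L
  }
  paste0(chars, collapse = "")
}

nexus_punct <- c(";", "=", ",", "/", "{", "}", "(", ")")

# Tokenize cleaned NEXUS text. Returns data.frame(text, quoted, line).
tokenize_nexus <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  toks <- list()
  push <- function(txt, quoted, line) {
    toks[[length(toks) + 1L]] <<- list(text = txt, quoted = quoted,
                                       line = line)
  }
  line <- 1L
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "\n") { line <- line + 1L; i <- i + 1L; next }
    if (grepl("[[:space:]]", ch)) { i <- i + 1L; next }
    if (ch == "'") {
      start_line <- line
      buf <- character()
      i <- i + 1L
      repeat {
        if (i > n) stop("NEXUS parse error: unterminated quote starting ",
                        "at line ", start_line, call. = FALSE)
        if (chars[i] == "\n") line <- line + 1L
        if (chars[i] == "'") {
          if (i + 1L <= n && chars[i + 1L] == "'") {   # escaped ''
            buf <- c(buf, "'"); i <- i + 2L
          } else { i <- i + 1L; break }
        } else { buf <- c(buf, chars[i]); i <- i + 1L }
      }
      push(paste0(buf, collapse = ""), TRUE, start_line)
      next
    }
    if (ch == "\"") {                       # double-quoted value (SYMBOLS)
      start_line <- line
      j <- i + 1L
      while (j <= n && chars[j] != "\"") {
        if (chars[j] == "\n") line <- line + 1L
        j <- j + 1L
      }
      if (j > n) stop("NEXUS parse error: unterminated quote starting ",
                      "at line ", start_line, call. = FALSE)
      push(paste0(chars[(i + 1L):(j - 1L)], collapse = ""), TRUE,
           start_line)
      i <- j + 1L
      next
    }
    if (ch %in% nexus_punct) {
      push(ch, FALSE, line)
      i <- i + 1L
      next
    }
    j <- i
    while (j <= n && !grepl("[[:space:]]", chars[j]) &&
           chars[j] != "'" && !(chars[j] %in% nexus_punct)) {
      j <- j + 1L
    }
    push(paste0(chars[i:(j - 1L)], collapse = ""), FALSE, line)
    i <- j
  }
  toks
}

# unquoted labels: underscores become spaces
nexus_label <- function(tok) {
  if (tok$quoted) tok$text else gsub("_", " ", tok$text, fixed = TRUE)
}

tok_is <- function(tok, what) {
  !tok$quoted && toupper(tok$text) == toupper(what)
}

#' Parse a NEXUS file
#'
#' @param source path, character vector of lines, or a single string with
#'   embedded newlines.
#' @param quiet suppress skipped-block notices.
#' @return object of class `eq_nexus_doc` with fields `taxa_labels`,
#'   `ntax`, `nchar`, `symbols`, `missing`, `gap`, `interleave`,
#'   `charstatelabels` (per-character `list(label, states)` or NULL) and
#'   `matrix_cells` (named list: taxon label -> list of [cell_value()]).
#' @export
parse_nexus <- function(source, quiet = FALSE) {
  lines <- read_text_lines(source)
  text <- paste(lines, collapse = "\n")
  if (!grepl("^[[:space:]]*#NEXUS", text, ignore.case = TRUE)) {
    stop("NEXUS parse error at line 1: file does not begin with #NEXUS",
         call. = FALSE)
  }
  text <- sub("#NEXUS", "      ", text, ignore.case = TRUE)
  text <- strip_nexus_comments(text)
  toks <- tokenize_nexus(text)

  doc <- list(taxa_labels = character(), ntax = NA_integer_,
              nchar = NA_integer_, symbols = as.character(0:9),
              missing = "?", gap = "-", interleave = FALSE,
              charstatelabels = list(), matrix_cells = list(),
              matrix_row_line = integer())

  i <- 1L
  np <- length(toks)
  peek <- function() if (i <= np) toks[[i]] else NULL
  advance <- function() { t <- toks[[i]]; i <<- i + 1L; t }
  expect_semi_skip <- function() {           # skip to just past next ";"
    while (i <= np && !tok_is(toks[[i]], ";")) i <<- i + 1L
    i <<- i + 1L
  }

  while (i <= np) {
    t <- advance()
    if (!tok_is(t, "BEGIN")) next
    bt <- advance()
    block <- toupper(bt$text)
    expect_semi_skip()
    if (block %in% c("TAXA", "CHARACTERS", "DATA")) {
      doc_env <- list2env(doc, new.env(parent = emptyenv()))
      i <- parse_nexus_block(toks, i, block, doc_env)
      doc <- mget(names(doc), doc_env)
    } else {
      if (!quiet) message("parse_nexus: skipping ", block, " block")
      # skip to END;
      while (i <= np) {
        t2 <- advance()
        if (tok_is(t2, "END") || tok_is(t2, "ENDBLOCK")) {
          expect_semi_skip()
          break
        }
      }
    }
  }

  # row-length validation
  for (tx in names(doc$matrix_cells)) {
    got <- length(doc$matrix_cells[[tx]])
    if (!is.na(doc$nchar) && got != doc$nchar) {
      stop("NEXUS parse error at line ", doc$matrix_row_line[[tx]],
           ": row for '", tx, "' has ", got, " cells; NCHAR is ",
           doc$nchar, call. = FALSE)
    }
  }
  if (!length(doc$taxa_labels)) doc$taxa_labels <- names(doc$matrix_cells)
  doc$ntax <- length(doc$taxa_labels)
  structure(doc, class = "eq_nexus_doc")
}

# Parses commands of one TAXA/CHARACTERS/DATA block, mutating env; returns
# the token index just past END;.
parse_nexus_block <- function(toks, i, block, env) {
  np <- length(toks)
  advance <- function() { t <- toks[[i]]; i <<- i + 1L; t }
  until_semi <- function() {
    out <- list()
    while (i <= np && !tok_is(toks[[i]], ";")) out[[length(out) + 1L]] <- advance()
    if (i <= np) i <<- i + 1L                 # consume ";"
    out
  }
  while (i <= np) {
    t <- advance()
    if (tok_is(t, "END") || tok_is(t, "ENDBLOCK")) {
      while (i <= np && !tok_is(toks[[i]], ";")) i <- i + 1L
      i <- i + 1L
      break
    }
    cmd <- toupper(t$text)
    if (cmd == "DIMENSIONS") {
      body <- until_semi()
      j <- 1L
      while (j <= length(body)) {
        key <- toupper(body[[j]]$text)
        if (key %in% c("NTAX", "NCHAR") && j + 2L <= length(body) &&
            tok_is(body[[j + 1L]], "=")) {
          val <- suppressWarnings(as.integer(body[[j + 2L]]$text))
          if (key == "NTAX") env$ntax <- val else env$nchar <- val
          j <- j + 3L
        } else j <- j + 1L
      }
    } else if (cmd == "FORMAT") {
      body <- until_semi()
      j <- 1L
      while (j <= length(body)) {
        key <- toupper(body[[j]]$text)
        has_val <- j + 2L <= length(body) && tok_is(body[[j + 1L]], "=")
        if (key == "SYMBOLS" && has_val) {
          env$symbols <- strsplit(gsub("[[:space:]]", "",
                                       body[[j + 2L]]$text), "")[[1]]
          j <- j + 3L
        } else if (key == "MISSING" && has_val) {
          env$missing <- body[[j + 2L]]$text; j <- j + 3L
        } else if (key == "GAP" && has_val) {
          env$gap <- body[[j + 2L]]$text; j <- j + 3L
        } else if (key == "INTERLEAVE") {
          env$interleave <- !(has_val &&
                                toupper(body[[j + 2L]]$text) == "NO")
          j <- if (has_val) j + 3L else j + 1L
        } else if (has_val) j <- j + 3L else j <- j + 1L
      }
    } else if (cmd == "TAXLABELS") {
      body <- until_semi()
      labs <- vapply(body, nexus_label, character(1))
      dup <- labs[duplicated(labs)]
      if (length(dup)) {
        stop("NEXUS parse error at line ", body[[1]]$line,
             ": duplicate taxon label: ", dup[1], call. = FALSE)
      }
      env$taxa_labels <- labs
    } else if (cmd == "CHARSTATELABELS") {
      body <- until_semi()
      parse_charstatelabels(body, env)
    } else if (cmd == "CHARLABELS") {
      body <- until_semi()
      for (k in seq_along(body)) {
        cur <- env$charstatelabels
        ent <- if (k <= length(cur) && !is.null(cur[[k]])) cur[[k]] else
          list(label = NULL, states = character())
        ent$label <- nexus_label(body[[k]])
        cur[[k]] <- ent
        env$charstatelabels <- cur
      }
    } else if (cmd == "STATELABELS") {
      body <- until_semi()
      # entries "N lab lab ..." separated by ","
      k <- 1L
      while (k <= length(body)) {
        idx <- suppressWarnings(as.integer(body[[k]]$text))
        k <- k + 1L
        labs <- character()
        while (k <= length(body) && !tok_is(body[[k]], ",")) {
          labs <- c(labs, nexus_label(body[[k]]))
          k <- k + 1L
        }
        k <- k + 1L                            # skip ","
        if (!is.na(idx)) {
          cur <- env$charstatelabels
          ent <- if (idx <= length(cur) && !is.null(cur[[idx]])) cur[[idx]]
            else list(label = NULL, states = character())
          ent$states <- labs
          length(cur) <- max(length(cur), idx)
          cur[[idx]] <- ent
          env$charstatelabels <- cur
        }
      }
    } else if (cmd == "MATRIX") {
      body <- until_semi()
      parse_nexus_matrix(body, env)
    } else {
      until_semi()                             # unknown command: skip
    }
  }
  i
}

parse_charstatelabels <- function(body, env) {
  cur <- env$charstatelabels
  k <- 1L
  while (k <= length(body)) {
    idx <- suppressWarnings(as.integer(body[[k]]$text))
    if (is.na(idx)) {
      stop("NEXUS parse error at line ", body[[k]]$line,
           ": CHARSTATELABELS entry must start with a character number",
           call. = FALSE)
    }
    k <- k + 1L
    lab <- NULL
    if (k <= length(body) && !tok_is(body[[k]], "/") &&
        !tok_is(body[[k]], ",")) {
      lab <- nexus_label(body[[k]])
      k <- k + 1L
    }
    states <- character()
    if (k <= length(body) && tok_is(body[[k]], "/")) {
      k <- k + 1L
      while (k <= length(body) && !tok_is(body[[k]], ",")) {
        states <- c(states, nexus_label(body[[k]]))
        k <- k + 1L
      }
    }
    if (k <= length(body) && tok_is(body[[k]], ",")) k <- k + 1L
    length(cur) <- max(length(cur), idx)
    cur[[idx]] <- list(label = lab, states = states)
  }
  env$charstatelabels <- cur
}

# MATRIX body tokens -> cells per taxon. Rows are line-based: each line's
# first token is the taxon label, the rest of the line is cell text.
# Interleaved blocks contribute additional segments per taxon.
parse_nexus_matrix <- function(body, env) {
  if (!length(body)) return(invisible())
  lns <- vapply(body, `[[`, integer(1), "line")
  by_line <- split(body, lns)
  by_line <- by_line[order(as.integer(names(by_line)))]  # file order
  cells <- env$matrix_cells
  row_line <- env$matrix_row_line
  for (ln in names(by_line)) {
    seg <- by_line[[ln]]
    label <- nexus_label(seg[[1]])
    celltext <- paste0(vapply(seg[-1], `[[`, character(1), "text"),
                       collapse = "")
    new_cells <- parse_cell_string(celltext, env$symbols, env$missing,
                                   env$gap, as.integer(ln))
    if (!is.null(cells[[label]])) {
      if (!env$interleave) {
        stop("NEXUS parse error at line ", ln,
             ": duplicate taxon label in matrix: ", label, call. = FALSE)
      }
      cells[[label]] <- c(cells[[label]], new_cells)
    } else {
      cells[[label]] <- new_cells
      row_line[[label]] <- as.integer(ln)
    }
  }
  env$matrix_cells <- cells
  env$matrix_row_line <- row_line
}

parse_cell_string <- function(x, symbols, missing_ch, gap_ch, line) {
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  cells <- list()
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c("{", "(")) {
      closer <- if (ch == "{") "}" else ")"
      j <- i + 1L
      grp <- character()
      while (j <= n && chars[j] != closer) {
        if (!grepl("[[:space:]]", chars[j])) grp <- c(grp, chars[j])
        j <- j + 1L
      }
      if (j > n) stop("NEXUS parse error at line ", line,
                      ": unterminated polymorphism group", call. = FALSE)
      grp <- unique(grp)
      bad <- setdiff(grp, symbols)
      if (length(bad)) {
        stop("NEXUS parse error at line ", line, ": symbol '", bad[1],
             "' not in SYMBOLS", call. = FALSE)
      }
      cells[[length(cells) + 1L]] <- if (length(grp) >= 2) {
        cell_value("polymorphic", grp)
      } else cell_value("single", grp)
      i <- j + 1L
    } else if (ch == missing_ch) {
      cells[[length(cells) + 1L]] <- cell_value("missing"); i <- i + 1L
    } else if (ch == gap_ch) {
      cells[[length(cells) + 1L]] <- cell_value("gap"); i <- i + 1L
    } else {
      if (!(ch %in% symbols)) {
        stop("NEXUS parse error at line ", line, ": symbol '", ch,
             "' not in SYMBOLS", call. = FALSE)
      }
      cells[[length(cells) + 1L]] <- cell_value("single", ch)
      i <- i + 1L
    }
  }
  cells
}

#' @export
print.eq_nexus_doc <- function(x, ...) {
  cat("<eq_nexus_doc> ", x$ntax, " taxa x ", x$nchar, " characters; symbols ",
      paste(x$symbols, collapse = ""), "\n", sep = "")
  invisible(x)
}

#' Convert a parsed NEXUS document to a dataset
#'
#' Taxa become [taxon()] records with the NEXUS label as publication
#' name. Characters are numbered 1..nchar with labels from
#' CHARSTATELABELS (fallback `"Character N"`). Where state labels exist
#' they are aligned positionally with the SYMBOLS order (extra labels
#' beyond the symbol list are dropped with a warning); characters
#' without state labels get one unlabeled state per symbol observed in
#' their matrix column. All phenotype lists start empty: EQ annotation
#' happens downstream.
#'
#' @param doc an `eq_nexus_doc`.
#' @return an `eq_dataset`.
#' @export
nexus_to_dataset <- function(doc) {
  stopifnot(inherits(doc, "eq_nexus_doc"))
  nchar_ <- doc$nchar
  if (is.na(nchar_)) {
    nchar_ <- if (length(doc$matrix_cells)) {
      length(doc$matrix_cells[[1]])
    } else 0L
  }
  taxa <- lapply(doc$taxa_labels, function(l) taxon(publication_name = l))
  characters <- vector("list", nchar_)
  for (j in seq_len(nchar_)) {
    csl <- if (j <= length(doc$charstatelabels)) doc$charstatelabels[[j]]
      else NULL
    lab <- if (!is.null(csl) && !is.null(csl$label)) csl$label
      else paste("Character", j)
    if (!is.null(csl) && length(csl$states)) {
      st_labels <- csl$states
      if (length(st_labels) > length(doc$symbols)) {
        warning("character ", j, ": ", length(st_labels),
                " state labels but only ", length(doc$symbols),
                " symbols; extra labels dropped", call. = FALSE)
        st_labels <- st_labels[seq_along(doc$symbols)]
      }
      states <- lapply(seq_along(st_labels), function(k) {
        eq_state(symbol = doc$symbols[k], label = st_labels[k])
      })
    } else {
      used <- unique(unlist(lapply(doc$matrix_cells, function(row) {
        if (j <= length(row)) row[[j]]$symbols else character()
      })))
      used <- doc$symbols[doc$symbols %in% used]
      states <- lapply(used, function(s) eq_state(symbol = s))
    }
    characters[[j]] <- eq_character(index = j, label = lab, states = states)
  }
  m <- doc$matrix_cells[intersect(doc$taxa_labels, names(doc$matrix_cells))]
  eq_dataset(taxa = taxa, characters = characters, matrix = m)
}
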