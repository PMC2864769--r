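# Independent oracles used across test files. These deliberately avoid the
# package's own traversal/parsing code paths.

# reachability oracle: iterative edge relaxation over a plain edge table
bfs_ancestors_oracle <- function(ontology, start, relations) {
  e <- ontology$edges[ontology$edges$predicate %in% relations, ,
                      drop = FALSE]
  reach <- character()
  frontier <- start
  repeat {
    nxt <- unique(e$object[e$subject %in% frontier])
    nxt <- setdiff(nxt, c(reach, start))
    if (!length(nxt)) break
    reach <- c(reach, nxt)
    frontier <- nxt
  }
  sort(reach)
}

# text-scan oracle: number of cells encoded in one matrix row string
# (a brace/paren group is one cell; every other non-space char is one cell)
count_cells_in_row_text <- function(x) {
  n <- 0L
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch %in% c("{", "(")) {
      closer <- if (ch == "{") "}" else ")"
      while (i <= length(chars) && chars[i] != closer) i <- i + 1L
      n <- n + 1L
    } else if (!grepl("[[:space:]]", ch)) {
      n <- n + 1L
    }
    i <- i + 1L
  }
  n
}

# nested-loop oracle for exhibits(): literal restatement of the contract
exhibits_count_oracle <- function(dataset) {
  total <- 0L
  for (tx in dataset$taxa) {
    row <- dataset$matrix[[tx$publication_name]]
    for (j in seq_along(row)) {
      for (sym in row[[j]]$symbols) {
        for (st in dataset$characters[[j]]$states) {
          if (st$symbol == sym) total <- total + length(st$phenotypes)
        }
      }
    }
  }
  total
}

fxid <- eqmatrix::fixture_ids()
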