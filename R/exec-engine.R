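# Instantiate the cursor tree of an optimized QEP and drain it.

#' Execute an optimized query plan
#'
#' Builds the operator cursors for a `qep` (leaf scans, candidate
#' generation + verification, joins), drains the root with `get_next()`
#' until exhaustion, and returns the binding rows.
#'
#' @param qep a plan from [optimize_query()].
#' @param db the `triple_db`.
#' @param indexes a `gram_index_set`.
#' @param regex_semantics how FILTER patterns match: `"anchored"` (whole
#'   string) or `"search"` (substring, SPARQL behavior).
#' @return list of binding rows (named integer vectors, variable -> string
#'   ID), in plan order (bag semantics; no deduplication).
#' @export
execute_qep <- function(qep, db, indexes,
                        regex_semantics = c("anchored", "search")) {
  regex_semantics <- match.arg(regex_semantics)
  collect_stream(qep_cursor(qep, db, indexes, regex_semantics))
}

qep_cursor <- function(node, db, indexes, semantics, sort_to = NULL) {
  cur <- if (node$type == "leaf") {
    leaf_cursor(node, db, indexes, semantics)
  } else {
    keys <- node$keys
    if (node$algo == "mgjn") {
      l <- qep_cursor(node$left, db, indexes, semantics, sort_to = keys)
      r <- qep_cursor(node$right, db, indexes, semantics, sort_to = keys)
      mgjn_cursor(l, r, keys)
    } else {
      l <- qep_cursor(node$left, db, indexes, semantics)
      r <- qep_cursor(node$right, db, indexes, semantics)
      hsjn_cursor(l, r, keys)
    }
  }
  if (!is.null(sort_to) && !sorted_for(node, sort_to)) {
    cur <- sort_rows_cursor(cur, sort_to)
  }
  cur
}

sorted_for <- function(node, keys) {
  length(keys) == 1L && identical(node$sorted_by, keys[1L])
}

leaf_cursor <- function(leaf, db, indexes, semantics) {
  if (leaf$access == "regscan") {
    part <- leaf$regscan$part
    f <- leaf$regscan$filter
    cur <- regscan_cursor(leaf$regscan$plan, db, indexes[[part]])
    cur <- filter_verify_cursor(cur, f$pattern, part, db, semantics)
    cur <- bind_pattern_cursor(cur, db, leaf$pattern)
    rest <- Filter(function(g) !identical(g, f), leaf$filters)
  } else {
    cur <- tscan_cursor(db, leaf$pattern)
    rest <- leaf$filters
  }
  for (f in rest) {
    cur <- filter_row_cursor(cur, f$var, f$pattern, db, semantics)
  }
  cur
}

# Regex verification applied to an already-bound variable of a row stream.
filter_row_cursor <- function(child, var, pattern, db, semantics) {
  force(child); force(var); force(db)
  rx <- verify_regex(pattern, semantics)
  make_cursor(function() {
    repeat {
      row <- get_next(child)
      if (is.null(row)) return(NULL)
      if (grepl(rx, db$strings[row[[var]]], perl = TRUE)) return(row)
    }
  })
}

#' Parse, optimize, execute and format a query
#'
#' The end-to-end entry point: parses the SPARQL text, picks the cheapest
#' plan, executes it, resolves string IDs back to lexical forms, projects
#' the SELECT variables and sorts the rows lexicographically by the
#' projected strings (C collation), so output is reproducible for a fixed
#' database and query.
#'
#' @param db a `triple_db`.
#' @param indexes a `gram_index_set` built on `db`.
#' @param query SPARQL text or a pre-parsed `sparql_query`.
#' @inheritParams optimize_query
#' @return a data.frame of character columns, one per projected variable,
#'   with attributes `summary` (list: `n_rows`, `elapsed_sec`, `plan`) and
#'   `qep`.
#' @examples
#' db <- read_triple_db(text = c(
#'   '<Gpr64> <mnemonic> "GPR64_MOUSE" .',
#'   '<Ccdc80> <mnemonic> "CCD80_MOUSE" .'))
#' ix <- build_gram_indexes(db, alpha = 2, beta = 4, c = 0.6)
#' run_query(db, ix, 'SELECT * WHERE { ?x <mnemonic> ?m
#'                    FILTER regex(?m, ".*MOUSE.*") . }')
#' @export
run_query <- function(db, indexes, query,
                      regex_semantics = c("anchored", "search"),
                      positional = c("exact", "ordered"),
                      unit_cost = 1) {
  t0 <- proc.time()[["elapsed"]]
  regex_semantics <- match.arg(regex_semantics)
  positional <- match.arg(positional)
  if (is.character(query)) query <- parse_sparql(query)
  qep <- optimize_query(query, db, indexes, unit_cost = unit_cost,
                        positional = positional,
                        regex_semantics = regex_semantics)
  rows <- execute_qep(qep, db, indexes, regex_semantics = regex_semantics)
  vars <- if (identical(query$select, "*")) {
    unique(unlist(lapply(query$patterns, pattern_vars)))
  } else query$select
  out <- as.data.frame(
    stats::setNames(lapply(vars, function(v) {
      vapply(rows, function(r) db$strings[r[[v]]], character(1))
    }), vars),
    stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(out) > 0L) {
    out <- out[do.call(order, c(unname(out), list(method = "radix"))), ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "qep") <- qep
  attr(out, "summary") <- list(n_rows = nrow(out),
                               elapsed_sec = proc.time()[["elapsed"]] - t0,
                               plan = serialize_qep(qep))
  out
}

#' Print the chosen plan for a query without executing it
#'
#' The textual `explain` output: the optimized operator tree with, for each
#' index scan, the gram, its posting size and page count, and per-operator
#' cost estimates.
#'
#' @inheritParams run_query
#' @return the `qep`, invisibly.
#' @export
explain_query <- function(db, indexes, query,
                          regex_semantics = c("anchored", "search"),
                          positional = c("exact", "ordered"),
                          unit_cost = 1) {
  if (is.character(query)) query <- parse_sparql(query)
  qep <- optimize_query(query, db, indexes, unit_cost = unit_cost,
                        positional = match.arg(positional),
                        regex_semantics = match.arg(regex_semantics))
  print(qep, indexes = indexes)
  invisible(qep)
}
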