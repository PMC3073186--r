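#' Parse the supported SPARQL subset
#'
#' Grammar: optional `PREFIX name: <iri>` lines; `SELECT` with a variable
#' list or `*`; a `WHERE { ... }` block of triple patterns separated by `.`
#' (or `;`), each position a variable (`?x`), an IRI (`<...>` or
#' `prefix:local`, or the keyword `a` for `rdf:type`), or a quoted literal.
#' A pattern may carry regex filters in either of two spellings:
#' `FILTER regex(?v, "pat")` or `filter(?v, "pat")`. Typographic quotes are
#' accepted and treated as ASCII quotes. The prefixes `rdf:`, `rdfs:` and
#' `go:` are built in (they expand to themselves, matching the compact IRIs
#' the synthetic corpora use); any other prefix must be declared.
#'
#' Validation: at least one pattern; every filter variable occurs in the
#' pattern it is attached to; the pattern graph is connected through shared
#' variables (a disconnected product query is rejected).
#'
#' @param text the query string.
#' @return an object of class `sparql_query`: list with `select` (variable
#'   names or `"*"`), `patterns` (list of triple patterns of terms
#'   `list(type, value)`), `filters` (list of `list(var, pattern,
#'   pattern_idx)`), `prefixes`.
#' @export
parse_sparql <- function(text) {
  stopifnot(is.character(text))
  text <- paste(text, collapse = "\n")
  # typographic quotes from copy-pasted queries
  text <- gsub("“|”", "\"", enc2utf8(text))

  prefixes <- c("rdf" = "rdf:", "rdfs" = "rdfs:", "go" = "go:")
  pm <- gregexpr("(?i)PREFIX\\s+([A-Za-z][A-Za-z0-9_-]*):\\s*<([^>]*)>",
                 text, perl = TRUE)
  for (decl in regmatches(text, pm)[[1L]]) {
    parts <- regmatches(decl, regexec(
      "(?i)PREFIX\\s+([A-Za-z][A-Za-z0-9_-]*):\\s*<([^>]*)>", decl,
      perl = TRUE))[[1L]]
    prefixes[parts[2L]] <- parts[3L]
  }
  text <- gsub("(?i)PREFIX\\s+[A-Za-z][A-Za-z0-9_-]*:\\s*<[^>]*>", "", text,
               perl = TRUE)

  m <- regexec("(?is)^\\s*SELECT\\s+(\\*|(?:\\?[A-Za-z0-9_]+\\s*)+)\\s*WHERE\\s*\\{(.*)\\}\\s*$",
               text, perl = TRUE)
  parts <- regmatches(text, m)[[1L]]
  if (length(parts) == 0L) {
    stop("SPARQL syntax error: expected 'SELECT ... WHERE { ... }'")
  }
  select <- if (trimws(parts[2L]) == "*") "*" else {
    sub("^\\?", "", strsplit(trimws(parts[2L]), "\\s+")[[1L]])
  }
  body <- parts[3L]

  toks <- sparql_tokens(body)
  q <- sparql_patterns(toks, prefixes)
  q$select <- select
  q$prefixes <- prefixes
  class(q) <- "sparql_query"
  validate_sparql(q)
  q
}

# Token scanner for the WHERE body.
sparql_tokens <- function(body) {
  specs <- c(var    = "\\?[A-Za-z0-9_]+",
             iri    = "<[^<>\"]*>",
             lit    = "\"(?:[^\"\\\\]|\\\\.)*\"",
             filter = "(?i)FILTER\\s+regex|(?i)filter",
             pname  = "[A-Za-z][A-Za-z0-9_-]*:[A-Za-z0-9_.-]*[A-Za-z0-9_-]",
             kw_a   = "\\ba\\b",
             punct  = "[().,;]")
  master <- paste0("(", paste(specs, collapse = ")|("), ")")
  pos <- 1L
  n <- nchar(body)
  toks <- list()
  while (pos <= n) {
    rest <- substr(body, pos, n)
    ws <- regmatchlen(rest, "^\\s+")
    if (ws > 0L) { pos <- pos + ws; next }
    m <- regexpr(paste0("^(?:", master, ")"), rest, perl = TRUE)
    if (m == -1L) {
      stop("SPARQL syntax error near position ", pos, ": '",
           substr(rest, 1L, 20L), "'")
    }
    tok <- regmatches(rest, m)
    toks <- c(toks, list(tok))
    pos <- pos + attr(m, "match.length")
  }
  unlist(toks)
}

regmatchlen <- function(x, rx) {
  m <- regexpr(rx, x, perl = TRUE)
  if (m == -1L) 0L else attr(m, "match.length")
}

sparql_patterns <- function(toks, prefixes) {
  patterns <- list()
  filters <- list()
  terms <- list()
  i <- 1L
  n <- length(toks)
  flush_pattern <- function() {
    if (length(terms) == 0L) return()
    if (length(terms) != 3L) {
      stop("SPARQL syntax error: a triple pattern needs 3 terms, got ",
           length(terms))
    }
    patterns[[length(patterns) + 1L]] <<- list(s = terms[[1L]],
                                               p = terms[[2L]],
                                               o = terms[[3L]])
    terms <<- list()
  }
  while (i <= n) {
    tok <- toks[i]
    if (tok %in% c(".", ";")) { flush_pattern(); i <- i + 1L; next }
    if (grepl("^(?i)filter", tok, perl = TRUE)) {
      # FILTER regex ( ?v , "pat" )   or   filter ( ?v , "pat" )
      if (length(terms) == 3L) flush_pattern()
      expect <- function(j, what, rx) {
        if (j > n || !grepl(rx, toks[j], perl = TRUE)) {
          stop("SPARQL syntax error in FILTER: expected ", what)
        }
      }
      expect(i + 1L, "'('", "^\\($")
      expect(i + 2L, "a variable", "^\\?")
      expect(i + 3L, "','", "^,$")
      expect(i + 4L, "a quoted pattern", "^\"")
      expect(i + 5L, "')'", "^\\)$")
      pat_idx <- length(patterns)
      if (pat_idx == 0L) stop("SPARQL syntax error: FILTER before any pattern")
      filters[[length(filters) + 1L]] <-
        list(var = sub("^\\?", "", toks[i + 2L]),
             pattern = nt_unescape(substr(toks[i + 4L], 2L,
                                          nchar(toks[i + 4L]) - 1L)),
             pattern_idx = pat_idx)
      i <- i + 6L
      next
    }
    terms <- c(terms, list(sparql_term(tok, prefixes)))
    if (length(terms) == 3L) {
      # a FILTER may follow before the closing '.'; flush happens on
      # separator, FILTER, or end of input
      if (i == n) flush_pattern()
    }
    i <- i + 1L
  }
  flush_pattern()
  list(patterns = patterns, filters = filters)
}

sparql_term <- function(tok, prefixes) {
  if (startsWith(tok, "?")) {
    return(list(type = "var", value = sub("^\\?", "", tok)))
  }
  if (startsWith(tok, "<")) {
    return(list(type = "const", value = substr(tok, 2L, nchar(tok) - 1L)))
  }
  if (startsWith(tok, "\"")) {
    return(list(type = "const",
                value = nt_unescape(substr(tok, 2L, nchar(tok) - 1L))))
  }
  if (tok == "a") {
    return(list(type = "const", value = paste0(prefixes[["rdf"]], "type")))
  }
  if (grepl(":", tok, fixed = TRUE)) {
    pfx <- sub(":.*$", "", tok)
    local <- sub("^[^:]*:", "", tok)
    if (!pfx %in% names(prefixes)) stop("unknown prefix '", pfx, ":'")
    return(list(type = "const", value = paste0(prefixes[[pfx]], local)))
  }
  stop("SPARQL syntax error: unexpected token '", tok, "'")
}

validate_sparql <- function(q) {
  if (length(q$patterns) == 0L) {
    stop("SPARQL query has an empty WHERE block")
  }
  pat_vars <- lapply(q$patterns, pattern_vars)
  for (f in q$filters) {
    if (!f$var %in% pat_vars[[f$pattern_idx]]) {
      stop("filter variable ?", f$var,
           " does not occur in its triple pattern")
    }
  }
  # connectivity through shared variables
  k <- length(q$patterns)
  if (k > 1L) {
    seen <- c(1L)
    frontier <- c(1L)
    while (length(frontier)) {
      nxt <- integer(0)
      for (i in setdiff(seq_len(k), seen)) {
        if (any(vapply(frontier, function(j) {
          length(intersect(pat_vars[[i]], pat_vars[[j]])) > 0L
        }, logical(1)))) nxt <- c(nxt, i)
      }
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    if (length(seen) < k) {
      stop("disconnected query: patterns do not share variables")
    }
  }
  if (!identical(q$select, "*")) {
    allv <- unique(unlist(pat_vars))
    missing <- setdiff(q$select, allv)
    if (length(missing)) {
      stop("projected variable(s) not bound by any pattern: ",
           paste0("?", missing, collapse = ", "))
    }
  }
  invisible(q)
}

#' @export
print.sparql_query <- function(x, ...) {
  sel <- if (identical(x$select, "*")) "*" else {
    paste0("?", x$select, collapse = " ")
  }
  cat(sprintf("<sparql_query> SELECT %s; %d pattern(s), %d regex filter(s)\n",
              sel, length(x$patterns), length(x$filters)))
  invisible(x)
}
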