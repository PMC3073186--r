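#' Parse N-Triples statements into lexical-form triples
#'
#' Reads a restricted N-Triples dialect: one statement per line terminated by
#' `.`, with IRIs in angle brackets, blank nodes (`_:name`, kept as opaque
#' strings), and plain, typed (`^^<iri>`) or language-tagged (`@lang`)
#' literals. Comment lines starting with `#` and blank lines are skipped.
#'
#' The returned lexical forms are what a user of the data "sees": IRIs are
#' stripped of their angle brackets and literals of their enclosing quotes
#' (standard string escapes are decoded); a datatype or language tag is kept
#' verbatim after the closing quote, attached to the lexical form.
#'
#' @param file path to an N-Triples file (read as UTF-8). Ignored when `text`
#'   is given.
#' @param text optional character vector of N-Triples lines, parsed instead of
#'   `file`.
#' @return a data.frame with character columns `s`, `p`, `o`, one row per
#'   statement, in input order.
#' @examples
#' parse_ntriples(text = '<Gpr64> <mnemonic> "GPR64_MOUSE" .')
#' @export
parse_ntriples <- function(file = NULL, text = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stop("either 'file' or 'text' must be given")
    text <- readLines(file, encoding = "UTF-8", warn = FALSE)
  } else if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  }
  lineno <- seq_along(text)
  keep <- !grepl("^\\s*(#|$)", text)
  lines <- text[keep]
  lineno <- lineno[keep]
  if (length(lines) == 0L) {
    return(data.frame(s = character(), p = character(), o = character(),
                      stringsAsFactors = FALSE))
  }

  iri    <- "<[^<>\"]*>"
  bnode  <- "_:[A-Za-z][A-Za-z0-9_.-]*"
  lit    <- "\"(?:[^\"\\\\]|\\\\.)*\"(?:\\^\\^<[^<>\"]*>|@[A-Za-z][A-Za-z0-9-]*)?"
  stmt <- paste0("^\\s*(", iri, "|", bnode, ")\\s+(", iri, ")\\s+(",
                 iri, "|", bnode, "|", lit, ")\\s*\\.\\s*$")

  m <- regexec(stmt, lines, perl = TRUE)
  parts <- regmatches(lines, m)
  bad <- lengths(parts) == 0L
  if (any(bad)) {
    stop(sprintf("malformed N-Triples statement at line %d: %s",
                 lineno[which(bad)[1L]],
                 substr(lines[which(bad)[1L]], 1L, 80L)))
  }
  mat <- do.call(rbind, parts)
  data.frame(s = vapply(mat[, 2L], nt_lexical, character(1), USE.NAMES = FALSE),
             p = vapply(mat[, 3L], nt_lexical, character(1), USE.NAMES = FALSE),
             o = vapply(mat[, 4L], nt_lexical, character(1), USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}

# Lexical form of one RDF term: strip <...> from IRIs and quotes from
# literals (decoding escapes); blank-node labels pass through untouched.
nt_lexical <- function(term) {
  c1 <- substr(term, 1L, 1L)
  if (c1 == "<") return(substr(term, 2L, nchar(term) - 1L))
  if (c1 != "\"") return(term)
  # literal: locate the closing quote (last unescaped quote before any tag)
  endq <- nt_closing_quote(term)
  body <- substr(term, 2L, endq - 1L)
  tag <- substr(term, endq + 1L, nchar(term))
  paste0(nt_unescape(body), tag)
}

nt_closing_quote <- function(term) {
  chars <- strsplit(term, "", fixed = TRUE)[[1L]]
  i <- 2L
  while (i <= length(chars)) {
    if (chars[i] == "\\") { i <- i + 2L; next }
    if (chars[i] == "\"") return(i)
    i <- i + 1L
  }
  stop("unterminated literal: ", term)
}

nt_unescape <- function(s) {
  if (!grepl("\\", s, fixed = TRUE)) return(s)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  out <- character(0)
  i <- 1L
  while (i <= length(chars)) {
    if (chars[i] != "\\") { out <- c(out, chars[i]); i <- i + 1L; next }
    esc <- chars[i + 1L]
    if (esc %in% c("\"", "\\", "'")) { out <- c(out, esc); i <- i + 2L }
    else if (esc == "n") { out <- c(out, "\n"); i <- i + 2L }
    else if (esc == "t") { out <- c(out, "\t"); i <- i + 2L }
    else if (esc == "r") { out <- c(out, "\r"); i <- i + 2L }
    else if (esc == "u") {
      code <- paste0(chars[(i + 2L):(i + 5L)], collapse = "")
      out <- c(out, intToUtf8(strtoi(code, 16L)))
      i <- i + 6L
    } else if (esc == "U") {
      code <- paste0(chars[(i + 2L):(i + 9L)], collapse = "")
      out <- c(out, intToUtf8(strtoi(code, 16L)))
      i <- i + 10L
    } else stop("unknown escape \\", esc)
  }
  enc2utf8(paste0(out, collapse = ""))
}
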