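#' Dictionary-encoded RDF triple database
#'
#' Builds the in-memory triple table: every distinct string (across all three
#' parts) gets one integer string ID, and each triple is stored as the ID
#' triple `(s, p, o)` under a dense triple ID `1..n` assigned in input order.
#' Duplicate triples keep distinct triple IDs; the dictionary deduplicates
#' strings across subjects, predicates and objects.
#'
#' @param triples a data.frame with character columns `s`, `p`, `o` of lexical
#'   forms, as returned by [parse_ntriples()].
#' @return an object of class `triple_db` with fields `n` (triple count),
#'   integer vectors `s`, `p`, `o` (string IDs per triple) and `strings`
#'   (the dictionary: string ID -> string).
#' @seealso [read_triple_db()] to go straight from an N-Triples file.
#' @export
triple_db <- function(triples) {
  stopifnot(is.data.frame(triples), all(c("s", "p", "o") %in% names(triples)))
  s <- enc2utf8(as.character(triples$s))
  p <- enc2utf8(as.character(triples$p))
  o <- enc2utf8(as.character(triples$o))
  strings <- unique(c(s, p, o))
  db <- list(n = length(s),
             s = match(s, strings),
             p = match(p, strings),
             o = match(o, strings),
             strings = strings)
  class(db) <- "triple_db"
  db
}

#' Read an N-Triples file into a triple database
#'
#' @inheritParams parse_ntriples
#' @return a [triple_db()] object.
#' @export
read_triple_db <- function(file = NULL, text = NULL) {
  triple_db(parse_ntriples(file = file, text = text))
}

#' Resolve a triple ID back to its three lexical strings
#'
#' @param db a `triple_db`.
#' @param tid a triple ID in `1..db$n`.
#' @return named character vector `c(s=, p=, o=)`.
#' @export
resolve_triple <- function(db, tid) {
  stopifnot(inherits(db, "triple_db"))
  if (length(tid) != 1L || is.na(tid) || tid < 1L || tid > db$n) {
    stop("unknown triple ID: ", tid)
  }
  c(s = db$strings[db$s[tid]],
    p = db$strings[db$p[tid]],
    o = db$strings[db$o[tid]])
}

#' Look up a string's dictionary ID
#'
#' @param db a `triple_db`.
#' @param s character vector of strings.
#' @return integer string IDs (NA for strings absent from the dictionary).
#' @export
string_id <- function(db, s) {
  match(enc2utf8(s), db$strings)
}

#' Part strings of the whole database
#'
#' The lexical strings of one triple part, aligned with triple IDs: element
#' `i` is the subject/predicate/object string of triple `i`.
#'
#' @param db a `triple_db`.
#' @param part one of `"s"`, `"p"`, `"o"`.
#' @return character vector of length `db$n`.
#' @export
part_strings <- function(db, part = c("s", "p", "o")) {
  part <- match.arg(part)
  db$strings[db[[part]]]
}

#' @export
print.triple_db <- function(x, ...) {
  cat(sprintf("<triple_db> %d triples, %d dictionary strings\n",
              x$n, length(x$strings)))
  invisible(x)
}

#' @export
format.triple_db <- function(x, ...) {
  sprintf("<triple_db: %d triples>", x$n)
}

DB_FORMAT_TAG <- "gramtriple-db"
DB_FORMAT_VERSION <- 1L

#' Persist / load a triple database
#'
#' The on-disk container is R serialization wrapped with a format tag and a
#' version field; loading a file with a different tag or version fails.
#'
#' @param db a `triple_db`.
#' @param path file path.
#' @return `load_database()` returns the `triple_db`; `save_database()`
#'   returns `path` invisibly.
#' @export
save_database <- function(db, path) {
  stopifnot(inherits(db, "triple_db"))
  saveRDS(list(tag = DB_FORMAT_TAG, version = DB_FORMAT_VERSION, db = db),
          path)
  invisible(path)
}

#' @rdname save_database
#' @export
load_database <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("cannot read database file '", path, "': ", conditionMessage(e))
  })
  if (!is.list(obj) || !identical(obj$tag, DB_FORMAT_TAG)) {
    stop("not a gramtriple database file: ", path)
  }
  if (!identical(obj$version, DB_FORMAT_VERSION)) {
    stop("database format version mismatch: found ", obj$version,
         ", expected ", DB_FORMAT_VERSION)
  }
  obj$db
}
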