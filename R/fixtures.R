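#' Specification for a synthetic GO-like N-Triples corpus
#'
#' Describes a deterministic generator of corpora whose strings have the
#' statistical shape of a GeneOntology RDF dump: GO-accession-like subjects
#' (`go:0005739`), a small predicate vocabulary (`rdf:type`, `rdfs:label`,
#' `rdfs:comment`, `mnemonic`, `go:consider`, `isbn`), UniProt-style
#' mnemonic objects (`GPR64_MOUSE`), phrase labels built from a biological
#' word pool (so words like "spliceosomal" or "activity" occur with
#' controlled frequency), comment sentences, and ISBN-like digit strings.
#'
#' Two knobs matter for exercising gram selection: `rare_gram` is injected
#' into a `rare_fraction` of mnemonics (so that gram falls below the
#' selectivity threshold and gets indexed), while the mnemonic suffixes
#' (`_MOUSE` etc.) are common enough to stay above it (exercising
#' redundant-gram removal). A small fraction of labels carries non-ASCII
#' characters so code-point offset handling is exercised.
#'
#' @param seed integer RNG seed; identical specs give byte-identical output.
#' @param n_triples number of triples to emit.
#' @param suffixes mnemonic suffix set.
#' @param rare_gram a short string made rare by construction.
#' @param rare_fraction fraction of mnemonics containing `rare_gram`.
#' @param go_id_fraction fraction of subjects shaped `go:0005NNN`.
#' @param unicode_fraction fraction of labels with a non-ASCII word.
#' @param label_words phrase pool for labels and comments.
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_triples = 1000L,
                         suffixes = c("_MOUSE", "_HUMAN", "_YEAST"),
                         rare_gram = "XQZ", rare_fraction = 0.05,
                         go_id_fraction = 0.4, unicode_fraction = 0.02,
                         label_words = c(
                           "spliceosomal", "complex", "activity", "binding",
                           "molecular", "cellular", "component", "membrane",
                           "nucleus", "mRNA", "tRNA", "splicing", "protein",
                           "transport", "kinase", "receptor", "regulation",
                           "biosynthetic", "process", "transferase")) {
  structure(list(seed = as.integer(seed), n_triples = as.integer(n_triples),
                 suffixes = suffixes, rare_gram = rare_gram,
                 rare_fraction = rare_fraction,
                 go_id_fraction = go_id_fraction,
                 unicode_fraction = unicode_fraction,
                 label_words = label_words),
            class = "fixture_spec")
}

#' Generate a synthetic N-Triples corpus
#'
#' Deterministic given the specification object; the caller's RNG state is
#' left untouched.
#'
#' @param spec a [fixture_spec()].
#' @return character vector of N-Triples lines (length `spec$n_triples`).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (spec$n_triples == 0L) return(character(0))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(spec$seed)

  n <- spec$n_triples
  n_entities <- max(ceiling(n / 4), 1L)
  subjects <- vapply(seq_len(n_entities), function(i) {
    if (runif(1) < spec$go_id_fraction) {
      sprintf("go:0005%03d", sample.int(1000L, 1L) - 1L)
    } else {
      sprintf("go:%07d", sample.int(9999999L, 1L))
    }
  }, character(1))
  types <- c("go:molecular_function", "go:biological_process",
             "go:cellular_component")

  mk_mnemonic <- function() {
    prefix <- paste0(sample(LETTERS, sample(3:5, 1L), replace = TRUE),
                     collapse = "")
    if (runif(1) < spec$rare_fraction) {
      prefix <- paste0(spec$rare_gram, prefix)
    }
    paste0(prefix, sample.int(99L, 1L), sample(spec$suffixes, 1L))
  }
  mk_label <- function() {
    words <- sample(spec$label_words, sample(2:4, 1L), replace = FALSE)
    if (runif(1) < spec$unicode_fraction) {
      words <- c(words, "α-glucosidase")
    }
    paste(words, collapse = " ")
  }
  mk_comment <- function() {
    paste("Note:", mk_label(), "of the", sample(types, 1L))
  }
  mk_isbn <- function() {
    core <- if (runif(1) < 0.3) "19857" else {
      paste0(sample(0:9, 5L, replace = TRUE), collapse = "")
    }
    paste0(sample(0:9, 1L), core, paste0(sample(0:9, 4L, replace = TRUE),
                                         collapse = ""))
  }

  lines <- character(0)
  ei <- 0L
  while (length(lines) < n) {
    ei <- ei + 1L
    subj <- subjects[((ei - 1L) %% n_entities) + 1L]
    batch <- c(
      sprintf("<%s> <rdf:type> <%s> .", subj, sample(types, 1L)),
      sprintf("<%s> <rdfs:label> \"%s\" .", subj, mk_label()),
      sprintf("<%s> <rdfs:comment> \"%s\" .", subj, mk_comment()),
      sprintf("<%s> <mnemonic> \"%s\" .", subj, mk_mnemonic()))
    if (runif(1) < 0.3) {
      batch <- c(batch, sprintf("<%s> <go:consider> <%s> .", subj,
                                sample(subjects, 1L)))
    }
    if (runif(1) < 0.2) {
      batch <- c(batch, sprintf("<%s> <isbn> \"%s\" .", subj, mk_isbn()))
    }
    lines <- c(lines, batch)
  }
  lines[seq_len(n)]
}

#' Write a generated corpus to an .nt file
#'
#' @param spec a [fixture_spec()].
#' @param path output file path (UTF-8).
#' @return `path`, invisibly.
#' @export
write_corpus <- function(spec, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(generate_corpus(spec), con, useBytes = TRUE)
  invisible(path)
}

# ---- brute-force oracles ----------------------------------------------
# Ground-truth re-derivations used in property tests. Deliberately naive
# and independent of the index/planner/engine code paths.

#' Oracle: exact regex answer set by full scan
#'
#' Matches the pattern against every part string with the stock regex
#' engine; the returned triple IDs are the exact answer set that the
#' candidate-then-verify pipeline must reproduce.
#'
#' @param db a `triple_db`.
#' @param pattern regex pattern.
#' @param part `"s"`, `"p"` or `"o"`.
#' @param semantics `"anchored"` (whole-string) or `"search"`.
#' @return integer vector of matching triple IDs, ascending.
#' @export
oracle_regex_scan <- function(db, pattern, part = c("s", "p", "o"),
                              semantics = c("anchored", "search")) {
  part <- match.arg(part)
  semantics <- match.arg(semantics)
  rx <- if (semantics == "anchored") paste0("^(?:", pattern, ")$") else pattern
  which(grepl(rx, db$strings[db[[part]]], perl = TRUE))
}

#' Oracle: selective grams by exhaustive enumeration
#'
#' Independent re-derivation of the selective-gram definition: enumerate
#' every substring of every part string in the length window with nested
#' loops, count containing triples one gram at a time, threshold by
#' selectivity, and drop any gram that contains a shorter infrequent gram.
#'
#' @param db a `triple_db`.
#' @param part `"s"`, `"p"` or `"o"`.
#' @param alpha,beta gram length window.
#' @param c selectivity threshold.
#' @return character vector of selective grams, sorted (C collation).
#' @export
oracle_selective_grams <- function(db, part = c("s", "p", "o"),
                                   alpha = 2L, beta = 4L, c = 0.1) {
  part <- match.arg(part)
  strings <- db$strings[db[[part]]]
  grams <- character(0)
  for (s in strings) {
    L <- nchar(s)
    for (len in alpha:beta) {
      if (len > L) next
      for (st in 1:(L - len + 1L)) {
        grams <- c(grams, substr(s, st, st + len - 1L))
      }
    }
  }
  grams <- unique(grams)
  infreq <- grams[vapply(grams, function(g) {
    sum(vapply(strings, function(s) grepl(g, s, fixed = TRUE),
               logical(1))) / db$n <= c
  }, logical(1))]
  keep <- vapply(infreq, function(g) {
    L <- nchar(g)
    if (L == alpha) return(TRUE)
    for (len in alpha:(L - 1L)) {
      for (st in 1:(L - len + 1L)) {
        if (substr(g, st, st + len - 1L) %in% infreq) return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  out <- infreq[keep]
  out[order(out, method = "radix")]
}

#' Generate a random supported regex pattern
#'
#' Draws a pattern from the supported grammar, biased toward literal
#' substrings of the given corpus strings so a useful share of patterns
#' actually matches something. Used by property tests; uses the caller's
#' RNG stream.
#'
#' @param strings corpus strings literals are sampled from.
#' @param depth maximum nesting depth.
#' @return a pattern string.
#' @export
random_regex <- function(strings, depth = 2L) {
  lit <- function() {
    s <- sample(strings, 1L)
    L <- nchar(s)
    if (L < 1L) return("X")
    len <- min(sample(1:6, 1L), L)
    st <- sample.int(L - len + 1L, 1L)
    gsub("([\\\\.|*+?()\\[\\]{}^$])", "\\\\\\1",
         substr(s, st, st + len - 1L), perl = TRUE)
  }
  atom <- function(d) {
    r <- runif(1)
    if (d <= 0L || r < 0.45) return(lit())
    if (r < 0.55) return(".")
    if (r < 0.65) return(sample(c("[0-9]", "[A-Z]", "[a-z]", "[A-Za-z]"), 1L))
    if (r < 0.80) return(paste0("(", alt(d - 1L), ")"))
    # quantify only star-free bodies: nesting unbounded quantifiers invites
    # catastrophic backtracking in the verification engine
    paste0("(", lit(), ")", sample(c("*", "+", "?"), 1L))
  }
  cat_expr <- function(d) {
    paste0(vapply(seq_len(sample(1:3, 1L)), function(i) atom(d),
                  character(1)), collapse = "")
  }
  alt <- function(d) {
    paste0(vapply(seq_len(sample(1:2, 1L)), function(i) cat_expr(d),
                  character(1)), collapse = "|")
  }
  p <- alt(depth)
  if (runif(1) < 0.5) p <- paste0(".*", p, ".*")
  p
}
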