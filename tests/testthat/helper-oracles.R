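# Shared test helpers: tiny corpora and independent brute-force evaluators.

# The two-triple mnemonic corpus used by the worked examples.
two_triple_db <- function() {
  read_triple_db(text = c(
    '<Gpr64> <mnemonic> "GPR64_MOUSE" .',
    '<Ccdc80> <mnemonic> "CCD80_MOUSE" .'))
}

# Canonical form of a list of binding rows, for multiset comparison.
canon_rows <- function(rows) {
  sort(vapply(rows, function(x) {
    paste(paste0(sort(names(x)), "=", x[sort(names(x))]), collapse = ",")
  }, character(1)))
}

# Brute-force query evaluator: scan all triples per pattern, nested-loop
# natural join, then regex-filter rows with the stock engine. Independent
# of the optimizer/executor code paths.
bf_query <- function(db, q, semantics = "anchored") {
  binds <- lapply(q$patterns, function(p) collect_stream(tscan_cursor(db, p)))
  rows <- binds[[1L]]
  if (length(binds) > 1L) {
    for (i in 2:length(binds)) {
      new <- list()
      for (a in rows) {
        for (b in binds[[i]]) {
          sh <- intersect(names(a), names(b))
          if (length(sh) == 0L || all(a[sh] == b[sh])) {
            new <- c(new, list(c(a, b[setdiff(names(b), names(a))])))
          }
        }
      }
      rows <- new
    }
  }
  for (f in q$filters) {
    rx <- if (semantics == "anchored") {
      paste0("^(?:", f$pattern, ")$")
    } else f$pattern
    rows <- Filter(function(r) {
      grepl(rx, db$strings[r[[f$var]]], perl = TRUE)
    }, rows)
  }
  rows
}

# tids produced by a candidate plan (REGSCAN without verification).
plan_tids <- function(plan, db, index) {
  vapply(collect_stream(regscan_cursor(plan, db, index)), `[[`,
         numeric(1), "tid")
}

# tids surviving verification.
verified_tids <- function(plan, db, index, pattern, semantics = "anchored") {
  cur <- filter_verify_cursor(regscan_cursor(plan, db, index),
                              pattern, index$part, db, semantics)
  vapply(collect_stream(cur), `[[`, numeric(1), "tid")
}

# independent exhaustive enumerator over all bushy join trees, recomputing
# costs with the same leaf/join conventions but none of the DP code
enum_all_plans <- function(query, db, indexes) {
  k <- length(query$patterns)
  leaves <- lapply(seq_len(k), function(i) {
    gramtriple:::best_leaf(i, query, db, indexes, 1, "exact", "anchored")
  })
  pat_vars <- lapply(query$patterns, gramtriple:::pattern_vars)
  build <- function(set) {
    if (length(set) == 1L) return(list(leaves[[set]]))
    out <- list()
    # enumerate all ways to split `set` into two nonempty halves
    for (mask in 1:(2^length(set) - 2L)) {
      lset <- set[bitwAnd(bitwShiftR(mask, seq_along(set) - 1L), 1L) == 1L]
      rset <- setdiff(set, lset)
      keys <- intersect(unlist(pat_vars[lset]), unlist(pat_vars[rset]))
      if (length(keys) == 0L) next
      keys <- keys[order(keys, method = "radix")]
      keys <- unique(keys)
      for (l in build(lset)) for (r in build(rset)) {
        for (algo in c("mgjn", "hsjn")) {
          out <- c(out, list(gramtriple:::make_join(algo, l, r, keys,
                                                    indexes$entries_per_page)))
        }
      }
    }
    out
  }
  build(seq_len(k))
}

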