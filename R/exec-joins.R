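# Binding rows are named integer vectors: variable name -> string ID.
# All rows produced by one operator bind the same variable set.

#' TSCAN: scan a triple pattern into binding rows
#'
#' Finds every triple matching the pattern's constants (a repeated variable
#' must bind the same string ID in all its positions) and emits one binding
#' row per match. Rows are emitted sorted by the first variable's string ID,
#' which makes the output directly consumable by a merge join on that
#' variable.
#'
#' @param db a `triple_db`.
#' @param pattern triple pattern: list `s`, `p`, `o` of terms
#'   `list(type = "var"|"const", value = )`.
#' @export
tscan_cursor <- function(db, pattern) {
  force(db); force(pattern)
  tids <- match_pattern_tids(db, pattern)
  vars <- pattern_vars(pattern)
  first_var <- if (length(vars)) vars[1L] else NULL
  if (!is.null(first_var) && length(tids)) {
    pos <- var_positions(pattern, first_var)[1L]
    tids <- tids[order(db[[pos]][tids])]
  }
  i <- 0L
  make_cursor(function() {
    if (i >= length(tids)) return(NULL)
    i <<- i + 1L
    bind_row(db, pattern, tids[i])
  })
}

match_pattern_tids <- function(db, pattern) {
  ok <- rep(TRUE, db$n)
  for (part in c("s", "p", "o")) {
    t <- pattern[[part]]
    if (t$type == "const") {
      id <- string_id(db, t$value)
      ok <- ok & if (is.na(id)) FALSE else db[[part]] == id
    }
  }
  vars <- pattern_vars(pattern)
  for (v in vars) {
    pos <- var_positions(pattern, v)
    if (length(pos) > 1L) {
      for (j in seq_along(pos)[-1L]) {
        ok <- ok & db[[pos[1L]]] == db[[pos[j]]]
      }
    }
  }
  which(ok)
}

pattern_vars <- function(pattern) {
  v <- character(0)
  for (part in c("s", "p", "o")) {
    t <- pattern[[part]]
    if (t$type == "var" && !(t$value %in% v)) v <- c(v, t$value)
  }
  v
}

var_positions <- function(pattern, var) {
  c("s", "p", "o")[vapply(c("s", "p", "o"), function(part) {
    t <- pattern[[part]]
    t$type == "var" && t$value == var
  }, logical(1))]
}

bind_row <- function(db, pattern, tid) {
  vars <- pattern_vars(pattern)
  row <- vapply(vars, function(v) {
    db[[var_positions(pattern, v)[1L]]][tid]
  }, integer(1))
  names(row) <- vars
  row
}

#' Bind verified candidate triples to a pattern's variables
#'
#' Adapter between the candidate pipeline (REGSCAN then FILTER, which
#' streams whole triples) and the join layer: drops candidates that violate
#' the pattern's constant positions or repeated-variable equalities, and
#' emits binding rows for the rest.
#'
#' @param child cursor of candidate items `list(tid=, s=, p=, o=)`.
#' @inheritParams tscan_cursor
#' @export
bind_pattern_cursor <- function(child, db, pattern) {
  force(child); force(db); force(pattern)
  const_ids <- lapply(c(s = "s", p = "p", o = "o"), function(part) {
    t <- pattern[[part]]
    if (t$type == "const") string_id(db, t$value) else NA_integer_
  })
  vars <- pattern_vars(pattern)
  make_cursor(function() {
    repeat {
      v <- get_next(child)
      if (is.null(v)) return(NULL)
      ok <- TRUE
      for (part in c("s", "p", "o")) {
        cid <- const_ids[[part]]
        if (!is.na(cid) && v[[part]] != cid) { ok <- FALSE; break }
        t <- pattern[[part]]
        if (is.na(cid) && t$type == "const") { ok <- FALSE; break }
      }
      if (ok) {
        for (vn in vars) {
          pos <- var_positions(pattern, vn)
          if (length(pos) > 1L &&
              length(unique(vapply(pos, function(p) v[[p]], integer(1)))) > 1L) {
            ok <- FALSE; break
          }
        }
      }
      if (ok) return(bind_row(db, pattern, v$tid))
    }
  })
}

#' Materializing sort of a binding-row stream
#'
#' Drains the child, orders rows by the given key variables' string IDs, and
#' re-streams them; used to feed MGJN when an input is not already sorted on
#' the join key.
#'
#' @param child a binding-row cursor.
#' @param keys character vector of variable names to sort by.
#' @export
sort_rows_cursor <- function(child, keys) {
  force(child); force(keys)
  rows <- collect_stream(child)
  if (length(rows)) {
    keymat <- lapply(keys, function(k) {
      vapply(rows, `[[`, integer(1), k)
    })
    rows <- rows[do.call(order, keymat)]
  }
  i <- 0L
  make_cursor(function() {
    if (i >= length(rows)) return(NULL)
    i <<- i + 1L
    rows[[i]]
  })
}

row_key <- function(row, keys) unname(row[keys])

key_cmp <- function(a, b) {
  for (j in seq_along(a)) {
    if (a[j] < b[j]) return(-1L)
    if (a[j] > b[j]) return(1L)
  }
  0L
}

join_rows <- function(left, right) {
  extra <- setdiff(names(right), names(left))
  c(left, right[extra])
}

#' MGJN: merge join of two sorted binding-row streams
#'
#' Natural join on the shared variables. Both inputs must arrive sorted on
#' the join key (ascending string IDs); a violation detected while
#' consuming an input is an error, not silently wrong output. Duplicate
#' keys on both sides produce the full cross product of the matching
#' groups (bag semantics).
#'
#' @param left,right binding-row cursors sorted on `keys`.
#' @param keys character vector of shared variable names.
#' @export
mgjn_cursor <- function(left, right, keys) {
  force(left); force(right)
  stopifnot(length(keys) >= 1L)
  lrow <- get_next(left); rrow <- get_next(right)
  llast <- NULL; rlast <- NULL
  pending <- list(); pi <- 0L
  adv_l <- function() {
    if (!is.null(lrow) && !is.null(llast) &&
        key_cmp(row_key(lrow, keys), llast) < 0L) {
      stop("MGJN left input is not sorted on the join key")
    }
    llast <<- if (is.null(lrow)) llast else row_key(lrow, keys)
    v <- lrow; lrow <<- get_next(left); v
  }
  adv_r <- function() {
    if (!is.null(rrow) && !is.null(rlast) &&
        key_cmp(row_key(rrow, keys), rlast) < 0L) {
      stop("MGJN right input is not sorted on the join key")
    }
    rlast <<- if (is.null(rrow)) rlast else row_key(rrow, keys)
    v <- rrow; rrow <<- get_next(right); v
  }
  make_cursor(function() {
    if (pi < length(pending)) { pi <<- pi + 1L; return(pending[[pi]]) }
    repeat {
      if (!is.null(lrow) && !is.null(llast) &&
          key_cmp(row_key(lrow, keys), llast) < 0L) {
        stop("MGJN left input is not sorted on the join key")
      }
      if (!is.null(rrow) && !is.null(rlast) &&
          key_cmp(row_key(rrow, keys), rlast) < 0L) {
        stop("MGJN right input is not sorted on the join key")
      }
      if (is.null(lrow) || is.null(rrow)) return(NULL)
      cmp <- key_cmp(row_key(lrow, keys), row_key(rrow, keys))
      if (cmp < 0L) adv_l()
      else if (cmp > 0L) adv_r()
      else {
        key <- row_key(lrow, keys)
        lgroup <- list()
        while (!is.null(lrow) && key_cmp(row_key(lrow, keys), key) == 0L) {
          lgroup <- c(lgroup, list(adv_l()))
        }
        rgroup <- list()
        while (!is.null(rrow) && key_cmp(row_key(rrow, keys), key) == 0L) {
          rgroup <- c(rgroup, list(adv_r()))
        }
        out <- list()
        for (lr in lgroup) for (rr in rgroup) {
          out <- c(out, list(join_rows(lr, rr)))
        }
        if (length(out)) {
          pending <<- out; pi <<- 1L
          return(pending[[1L]])
        }
      }
    }
  })
}

#' HSJN: hash join of two binding-row streams
#'
#' Builds a hash table over the left input keyed by the shared variables,
#' then probes with the right input. No ordering requirement on either
#' input; produces the same multiset of joined rows as [mgjn_cursor()].
#'
#' @inheritParams mgjn_cursor
#' @export
hsjn_cursor <- function(left, right, keys) {
  force(left); force(right)
  stopifnot(length(keys) >= 1L)
  ht <- NULL
  pending <- list(); pi <- 0L
  build <- function() {
    ht <<- new.env(parent = emptyenv())
    while (!is.null(r <- get_next(left))) {
      k <- paste(row_key(r, keys), collapse = "\r")
      ht[[k]] <- c(if (!is.null(ht[[k]])) ht[[k]], list(r))
    }
  }
  make_cursor(function() {
    if (is.null(ht)) build()
    if (pi < length(pending)) { pi <<- pi + 1L; return(pending[[pi]]) }
    repeat {
      rr <- get_next(right)
      if (is.null(rr)) return(NULL)
      k <- paste(row_key(rr, keys), collapse = "\r")
      matches <- ht[[k]]
      if (!is.null(matches)) {
        pending <<- lapply(matches, join_rows, rr)
        pi <<- 1L
        return(pending[[1L]])
      }
    }
  })
}
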