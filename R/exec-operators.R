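#' GetNext iterator protocol
#'
#' Every operator in a query execution plan is a cursor: `get_next()` returns
#' the operator's next result, or `NULL` when the stream is exhausted.
#' Exhaustion is idempotent -- once a cursor has returned `NULL` it keeps
#' returning `NULL`.
#'
#' @param step a function of no arguments producing the next item or `NULL`.
#' @return `make_cursor()` returns an object of class `op_cursor`;
#'   `get_next()` returns the next item or `NULL`.
#' @name getnext
NULL

#' @rdname getnext
#' @export
make_cursor <- function(step) {
  done <- FALSE
  structure(list(getnext = function() {
    if (done) return(NULL)
    v <- step()
    if (is.null(v)) done <<- TRUE
    v
  }), class = "op_cursor")
}

#' @rdname getnext
#' @param cursor an `op_cursor`.
#' @export
get_next <- function(cursor) cursor$getnext()

#' Drain a cursor into a list
#' @param cursor an `op_cursor`.
#' @return list of all items produced until exhaustion.
#' @export
collect_stream <- function(cursor) {
  out <- vector("list", 16L)
  n <- 0L
  while (!is.null(v <- get_next(cursor))) {
    n <- n + 1L
    if (n > length(out)) out <- c(out, vector("list", length(out)))
    out[[n]] <- v
  }
  out[seq_len(n)]
}

# ---- candidate sub-plan operators -------------------------------------

#' IDXSCAN: stream a gram's posting list
#'
#' Emits the posting entries of `gram` one per call, in ascending triple-ID
#' order, as `list(tid =, offs =)`. An absent gram yields an empty stream
#' (the planner only emits index keys; this is defensive).
#'
#' @param index a `gram_index`.
#' @param gram the gram to scan.
#' @export
idxscan_cursor <- function(index, gram) {
  p <- gram_lookup(index, gram)
  i <- 0L
  n <- if (is.null(p)) 0L else length(p$tids)
  make_cursor(function() {
    if (i >= n) return(NULL)
    i <<- i + 1L
    list(tid = p$tids[i], offs = p$offs[[i]])
  })
}

#' IDXAND: offset-aware intersection of candidate streams
#'
#' N-ary merge-intersection of tid-ascending child streams. A tid is emitted
#' only when, in addition to appearing in every child, its offsets satisfy
#' the positional constraint: under `"exact"` with gaps, some start offset
#' `f` exists with child `k` matching at `f + cumgap_k`; under `"ordered"`,
#' a strictly increasing offset selection across children exists (left
#' before right). Children without offset information (IDXOR output,
#' nested operators that discarded offsets) only contribute the tid
#' intersection. Emitted offsets are the combined-match start(s): all
#' satisfying starts under `"exact"`, the leftmost under `"ordered"`.
#'
#' @param children list of child `op_cursor`s, each tid-ascending.
#' @param constraint `"ordered"` or `"exact"`.
#' @param gaps for `"exact"`: integer vector, `gaps[k]` the offset gap
#'   between child `k` and child `k+1`.
#' @export
idxand_cursor <- function(children, constraint = c("ordered", "exact"),
                          gaps = NULL) {
  force(children)
  constraint <- match.arg(constraint)
  k <- length(children)
  stopifnot(k >= 2L)
  cumgap <- if (constraint == "exact") cumsum(c(0L, gaps)) else NULL
  cur <- lapply(children, get_next)
  make_cursor(function() {
    repeat {
      if (any(vapply(cur, is.null, logical(1)))) return(NULL)
      tids <- vapply(cur, `[[`, numeric(1), "tid")
      m <- max(tids)
      if (all(tids == m)) {
        offs <- and_match_offsets(cur, constraint, cumgap)
        cur <<- lapply(children, get_next)
        if (!is.null(offs)) return(list(tid = m, offs = offs))
        # constraint failed: keep scanning
      } else {
        for (j in seq_len(k)) {
          while (!is.null(cur[[j]]) && cur[[j]]$tid < m) {
            cur[j] <<- list(get_next(children[[j]]))
          }
        }
      }
    }
  })
}

# Offset feasibility for one shared tid. Returns the combined-match start
# offsets, integer(0) when no offsets are available to check, or NULL when
# the positional constraint rules the tid out.
and_match_offsets <- function(items, constraint, cumgap) {
  has <- vapply(items, function(x) !is.null(x$offs), logical(1))
  if (!any(has)) return(integer(0))
  if (constraint == "exact" && !is.null(cumgap)) {
    idx <- which(has)
    starts <- Reduce(intersect, lapply(idx, function(j) {
      items[[j]]$offs - cumgap[j]
    }))
    if (length(starts) == 0L) return(NULL)
    return(sort(starts))
  }
  # ordered: greedy strictly-increasing selection across offset-bearing
  # children, in child order
  prev <- -Inf
  first_start <- NULL
  for (j in which(has)) {
    o <- items[[j]]$offs[items[[j]]$offs > prev]
    if (length(o) == 0L) return(NULL)
    prev <- min(o)
    if (is.null(first_start)) first_start <- prev
  }
  as.integer(first_start)
}

#' IDXOR: union of candidate streams
#'
#' K-way merge of tid-ascending child streams into their sorted,
#' duplicate-free union. Offset information is discarded (a union has no
#' single positional interpretation).
#'
#' @param children list of child `op_cursor`s.
#' @export
idxor_cursor <- function(children) {
  force(children)
  cur <- lapply(children, get_next)
  make_cursor(function() {
    alive <- !vapply(cur, is.null, logical(1))
    if (!any(alive)) return(NULL)
    m <- min(vapply(cur[alive], `[[`, numeric(1), "tid"))
    for (j in which(alive)) {
      if (cur[[j]]$tid == m) cur[j] <<- list(get_next(children[[j]]))
    }
    list(tid = m, offs = NULL)
  })
}

#' FULLSCAN: stream every triple ID of the part
#'
#' The fallback candidate generator when the merged parse tree is ALL: no
#' gram constrains the pattern, so every triple is a candidate.
#'
#' @param n_triples corpus size.
#' @export
fullscan_cursor <- function(n_triples) {
  i <- 0L
  make_cursor(function() {
    if (i >= n_triples) return(NULL)
    i <<- i + 1L
    list(tid = i, offs = NULL)
  })
}

# Instantiate the cursor tree of a candidate plan.
plan_cursor <- function(node, index, n_triples) {
  switch(node$op,
    idxscan = idxscan_cursor(index, node$gram),
    idxand = idxand_cursor(lapply(node$children, plan_cursor, index,
                                  n_triples),
                           constraint = node$constraint, gaps = node$gaps),
    idxor = idxor_cursor(lapply(node$children, plan_cursor, index,
                                n_triples)),
    fullscan = fullscan_cursor(n_triples),
    stop("unknown plan operator: ", node$op))
}

#' REGSCAN: candidate triples from a compiled sub-plan
#'
#' Pulls candidate triple IDs from the root of the candidate sub-plan and
#' resolves each through the dictionary into its three string IDs, emitting
#' `list(tid=, s=, p=, o=)`. An empty (NULL-root) plan yields an empty
#' stream.
#'
#' @param plan a `candidate_plan`.
#' @param db the `triple_db`.
#' @param index the `gram_index` the plan was compiled against.
#' @export
regscan_cursor <- function(plan, db, index) {
  force(db); force(index)
  stopifnot(inherits(plan, "candidate_plan"))
  if (is.null(plan$root)) return(make_cursor(function() NULL))
  sub <- plan_cursor(plan$root, index, db$n)
  make_cursor(function() {
    v <- get_next(sub)
    if (is.null(v)) return(NULL)
    tid <- v$tid
    list(tid = tid, s = db$s[tid], p = db$p[tid], o = db$o[tid])
  })
}

#' FILTER: verify candidates against the original pattern
#'
#' The exact re-check that removes REGSCAN's false positives: a candidate
#' passes iff the full lexical string of the bound part matches the
#' original (un-normalized) pattern under the stock regex engine. Under
#' anchored semantics the pattern must match the whole string; under search
#' semantics a substring match suffices (SPARQL `regex()` behavior).
#'
#' @param child a candidate `op_cursor` (REGSCAN output items).
#' @param pattern the original regex pattern.
#' @param part which part string the filter is bound to.
#' @param db the `triple_db`.
#' @param semantics `"anchored"` or `"search"`.
#' @export
filter_verify_cursor <- function(child, pattern, part, db,
                                 semantics = c("anchored", "search")) {
  force(child); force(part); force(db)
  semantics <- match.arg(semantics)
  rx <- verify_regex(pattern, semantics)
  make_cursor(function() {
    repeat {
      v <- get_next(child)
      if (is.null(v)) return(NULL)
      str <- db$strings[v[[part]]]
      if (grepl(rx, str, perl = TRUE)) return(v)
    }
  })
}

verify_regex <- function(pattern, semantics) {
  if (semantics == "anchored") paste0("^(?:", pattern, ")$") else pattern
}
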