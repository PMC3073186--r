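#' I/O cost of a candidate sub-plan
#'
#' The page-access cost model: evaluating a candidate plan touches, for each
#' distinct gram `g` in the plan's gram set `G`, one root-to-leaf descent of
#' the index tree plus the pages of `g`'s posting list, so
#'
#'   `Cost = OnePageAccessCost * (|G| * Height(I) + sum_g NumPages(g))`.
#'
#' A FULLSCAN plan instead reads every triple of the part:
#' `OnePageAccessCost * ceiling(n / entries_per_page)`. CPU cost of
#' verification is ignored (negligible next to I/O). An empty plan (no
#' grams, no fullscan) costs 0.
#'
#' @param plan a `candidate_plan` (or `NULL` root for the empty plan).
#' @param index the `gram_index` the plan was compiled against.
#' @param unit_cost cost of one page access (only ratios matter for plan
#'   choice; default 1).
#' @return an object of class `cost_estimate`: list with `total` and a named
#'   `breakdown` vector summing to `total`.
#' @export
cost_regscan <- function(plan, index, unit_cost = 1) {
  stopifnot(inherits(index, "gram_index"), unit_cost > 0)
  node <- if (inherits(plan, "candidate_plan")) plan$root else plan
  if (is.null(node)) {
    return(new_cost_estimate(numeric(0)))
  }
  if (identical(node$op, "fullscan")) {
    return(new_cost_estimate(c(fullscan = unit_cost * index$part_pages)))
  }
  G <- plan_grams(node)
  pages <- vapply(G, function(g) gram_lookup(index, g)$num_pages, numeric(1))
  breakdown <- c(btree_descents = unit_cost * length(G) * index$height,
                 stats::setNames(unit_cost * pages, paste0("pages:", G)))
  new_cost_estimate(breakdown)
}

new_cost_estimate <- function(breakdown) {
  structure(list(total = sum(breakdown), breakdown = breakdown),
            class = "cost_estimate")
}

#' @export
print.cost_estimate <- function(x, ...) {
  cat(sprintf("<cost_estimate> total=%g page accesses\n", x$total))
  for (nm in names(x$breakdown)) {
    cat(sprintf("  %-20s %g\n", nm, x$breakdown[[nm]]))
  }
  invisible(x)
}

# ---- query optimization ------------------------------------------------

#' Choose the cheapest query execution plan
#'
#' Bottom-up, cost-based: for every triple pattern the access-path choices
#' are enumerated (TSCAN; for each attached regex filter, a REGSCAN over the
#' compiled candidate plan when its estimated cost beats scanning), then all
#' bushy join orders over connected subsets with both MGJN and HSJN are
#' enumerated by dynamic programming over pattern subsets, which yields the
#' same optimum as exhaustive enumeration because costs combine bottom-up.
#' Ties are broken by the lexicographically smallest plan serialization, so
#' the chosen plan is deterministic.
#'
#' The candidate-plan cost is the page model of [cost_regscan()]. Join costs
#' (not covered by that model) use a minimal convention: the children's
#' costs plus one page-counted pass over each input's estimated cardinality,
#' plus, for MGJN, a sort pass over any input not already sorted on the join
#' key. Cardinalities are estimated from posting-list/scan sizes, with
#' constant positions discounted by the number of distinct strings in that
#' part and join output estimated as the smaller input (no value-frequency
#' statistics are kept).
#'
#' @param query a `sparql_query` from [parse_sparql()].
#' @param db the `triple_db`.
#' @param indexes a `gram_index_set`.
#' @param unit_cost page-access unit cost.
#' @param positional positional-constraint mode for candidate plans.
#' @param regex_semantics `"anchored"` or `"search"`; search-mode patterns
#'   are wrapped in `.*(...).*` before planning.
#' @return an object of class `qep`: a tree of `leaf` and `join` nodes with
#'   cost and cardinality annotations.
#' @export
optimize_query <- function(query, db, indexes, unit_cost = 1,
                           positional = c("exact", "ordered"),
                           regex_semantics = c("anchored", "search")) {
  stopifnot(inherits(query, "sparql_query"), inherits(db, "triple_db"),
            inherits(indexes, "gram_index_set"))
  positional <- match.arg(positional)
  regex_semantics <- match.arg(regex_semantics)
  k <- length(query$patterns)
  if (k > 8L) {
    stop("queries with more than 8 triple patterns are not supported ",
         "(exhaustive join enumeration only; no heuristic search)")
  }
  epp <- indexes$entries_per_page
  leaves <- lapply(seq_len(k), function(i) {
    best_leaf(i, query, db, indexes, unit_cost, positional, regex_semantics)
  })
  if (k == 1L) return(structure(leaves[[1L]], class = "qep"))

  pat_vars <- lapply(query$patterns, pattern_vars)
  best <- vector("list", 2^k - 1L)
  for (i in seq_len(k)) best[[bitwShiftL(1L, i - 1L)]] <- leaves[[i]]
  masks <- order(vapply(seq_len(2^k - 1L), bitcount, integer(1)))
  for (mask in masks) {
    if (!is.null(best[[mask]])) next
    sub <- mask_bits(mask)
    cand <- NULL
    m <- bitwAnd(mask - 1L, mask)   # iterate non-empty proper submasks
    while (m > 0L) {
      other <- bitwAnd(mask, bitwNot(m))
      l <- best[[m]]; r <- best[[other]]
      if (!is.null(l) && !is.null(r)) {
        keys <- intersect(unlist(pat_vars[mask_bits(m)]),
                          unlist(pat_vars[mask_bits(other)]))
        if (length(keys)) {
          keys <- c_sort(unique(keys))
          for (algo in c("mgjn", "hsjn")) {
            j <- make_join(algo, l, r, keys, epp)
            cand <- better_plan(cand, j)
          }
        }
      }
      m <- bitwAnd(m - 1L, mask)
    }
    best[mask] <- list(cand)   # may be NULL for disconnected subsets
  }
  full <- best[[2^k - 1L]]
  if (is.null(full)) stop("disconnected query: no join path covers all patterns")
  structure(full, class = "qep")
}

bitcount <- function(x) sum(bitwAnd(bitwShiftR(x, 0:30), 1L))
mask_bits <- function(mask) which(bitwAnd(bitwShiftR(mask, 0:30), 1L) == 1L)

best_leaf <- function(i, query, db, indexes, unit_cost, positional,
                      regex_semantics) {
  pattern <- query$patterns[[i]]
  filters <- Filter(function(f) f$pattern_idx == i, query$filters)
  epp <- indexes$entries_per_page
  scan_pages <- pages_of(db$n, epp)
  card <- estimate_tscan_card(db, pattern)
  leaf <- list(type = "leaf", pattern_idx = i, pattern = pattern,
               access = "tscan", filters = filters,
               cost = unit_cost * scan_pages, card = card,
               sorted_by = {
                 v <- pattern_vars(pattern)
                 if (length(v)) v[1L] else NULL
               })
  for (f in filters) {
    part <- tryCatch(choose_index_part(pattern, f$var),
                     error = function(e) NULL)
    if (is.null(part)) next
    plan_pat <- if (regex_semantics == "search") {
      paste0(".*(", f$pattern, ").*")
    } else f$pattern
    cp <- tryCatch(compile_regex_plan(plan_pat, indexes[[part]],
                                      positional = positional),
                   error = function(e) NULL)
    if (is.null(cp)) next
    cost <- cost_regscan(cp, indexes[[part]], unit_cost)$total
    if (cost < leaf$cost) {
      cand <- estimate_plan_card(cp$root, indexes[[part]], db$n)
      leaf <- list(type = "leaf", pattern_idx = i, pattern = pattern,
                   access = "regscan", filters = filters,
                   regscan = list(plan = cp, part = part, filter = f),
                   cost = cost,
                   card = min(card, cand),
                   sorted_by = NULL)
    }
  }
  leaf
}

estimate_tscan_card <- function(db, pattern) {
  card <- db$n
  for (part in c("s", "p", "o")) {
    if (pattern[[part]]$type == "const") {
      card <- card / max(length(unique(db[[part]])), 1L)
    }
  }
  max(card, 1)
}

estimate_plan_card <- function(node, index, n) {
  if (is.null(node)) return(0)
  switch(node$op,
    idxscan = {
      p <- gram_lookup(index, node$gram)
      if (is.null(p)) 0 else length(p$tids)
    },
    idxand = min(vapply(node$children, estimate_plan_card, numeric(1),
                        index, n)),
    idxor = min(sum(vapply(node$children, estimate_plan_card, numeric(1),
                           index, n)), n),
    fullscan = n)
}

make_join <- function(algo, l, r, keys, epp) {
  pass <- pages_of(l$card, epp) + pages_of(r$card, epp)
  sort_cost <- 0
  if (algo == "mgjn") {
    if (!sorted_on(l, keys)) sort_cost <- sort_cost + pages_of(l$card, epp)
    if (!sorted_on(r, keys)) sort_cost <- sort_cost + pages_of(r$card, epp)
  }
  list(type = "join", algo = algo, left = l, right = r, keys = keys,
       cost = l$cost + r$cost + pass + sort_cost,
       card = max(min(l$card, r$card), 1),
       sorted_by = if (algo == "mgjn") keys[1L] else NULL)
}

sorted_on <- function(plan, keys) {
  length(keys) == 1L && identical(plan$sorted_by, keys[1L])
}

better_plan <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (b$cost < a$cost) return(b)
  if (b$cost > a$cost) return(a)
  if (serialize_qep(b) < serialize_qep(a)) b else a
}

#' Canonical one-line serialization of a QEP
#'
#' Used for deterministic tie-breaking and for stable plan identifiers in
#' query summaries.
#'
#' @param plan a `qep` or plan subtree.
#' @return a character scalar.
#' @export
serialize_qep <- function(plan) {
  if (plan$type == "leaf") {
    if (plan$access == "tscan") {
      sprintf("TSCAN(p%d)", plan$pattern_idx)
    } else {
      sprintf("REGSCAN(p%d,%s,%s)", plan$pattern_idx,
              toupper(plan$regscan$part),
              serialize_plan_node(plan$regscan$plan$root))
    }
  } else {
    sprintf("%s[%s](%s,%s)", toupper(plan$algo),
            paste(plan$keys, collapse = ","),
            serialize_qep(plan$left), serialize_qep(plan$right))
  }
}

serialize_plan_node <- function(node) {
  switch(node$op,
    idxscan = sprintf("IDXSCAN(%s)", node$gram),
    fullscan = "FULLSCAN",
    idxand = sprintf("IDXAND(%s)", paste(vapply(node$children,
      serialize_plan_node, character(1)), collapse = ",")),
    idxor = sprintf("IDXOR(%s)", paste(vapply(node$children,
      serialize_plan_node, character(1)), collapse = ",")))
}

#' @export
print.qep <- function(x, db = NULL, indexes = NULL, ...) {
  cat("<qep> estimated cost", x$cost, "\n")
  print_qep_node(x, 1L, indexes)
  invisible(x)
}

print_qep_node <- function(node, indent, indexes = NULL) {
  pad <- strrep("  ", indent)
  if (node$type == "leaf") {
    if (node$access == "tscan") {
      cat(sprintf("%sTSCAN pattern #%d  [cost=%g, card~%g]\n", pad,
                  node$pattern_idx, node$cost, node$card))
      for (f in node$filters) {
        cat(sprintf("%s  FILTER regex(?%s, \"%s\")\n", pad, f$var, f$pattern))
      }
    } else {
      cat(sprintf("%sFILTER+REGSCAN pattern #%d on I_%s  [cost=%g, card~%g]\n",
                  pad, node$pattern_idx, toupper(node$regscan$part),
                  node$cost, node$card))
      idx <- if (!is.null(indexes)) indexes[[node$regscan$part]] else NULL
      print_plan_node(node$regscan$plan$root, indent + 1L, idx)
    }
  } else {
    cat(sprintf("%s%s on (%s)  [cost=%g, card~%g]\n", pad,
                toupper(node$algo), paste0("?", node$keys, collapse = ", "),
                node$cost, node$card))
    print_qep_node(node$left, indent + 1L, indexes)
    print_qep_node(node$right, indent + 1L, indexes)
  }
}
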