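#' Choose the part index for a regex filter
#'
#' The filter variable's position in its triple pattern decides which of the
#' subject/predicate/object indexes can evaluate the pattern.
#'
#' @param pattern a triple pattern: list with elements `s`, `p`, `o`, each a
#'   term `list(type = "var"|"const", value = ...)`.
#' @param var the filter variable name (without the `?`).
#' @return `"s"`, `"p"` or `"o"`.
#' @export
choose_index_part <- function(pattern, var) {
  pos <- c("s", "p", "o")[vapply(c("s", "p", "o"), function(part) {
    t <- pattern[[part]]
    identical(t$type, "var") && identical(t$value, var)
  }, logical(1))]
  if (length(pos) == 0L) {
    stop("filter variable ?", var, " does not occur in the triple pattern")
  }
  if (length(pos) > 1L) {
    stop("filter variable ?", var,
         " occurs in more than one position of the triple pattern")
  }
  pos
}

plan_idxscan <- function(gram) {
  structure(list(op = "idxscan", gram = gram), class = "plan_node")
}
plan_idxand <- function(children, constraint = c("ordered", "exact"),
                        gaps = NULL) {
  constraint <- match.arg(constraint)
  structure(list(op = "idxand", children = children,
                 constraint = constraint, gaps = gaps),
            class = "plan_node")
}
plan_idxor <- function(children) {
  structure(list(op = "idxor", children = children), class = "plan_node")
}
plan_fullscan <- function() structure(list(op = "fullscan"),
                                      class = "plan_node")

#' Compile a candidate parse tree against a gram index
#'
#' Emits the candidate-generation sub-plan: GRAM leaves become IDXSCAN when
#' the gram is an index key; an unindexed gram with indexed substrings
#' becomes an IDXAND over the IDXSCANs of a greedy interval cover of the
#' gram by indexed substrings (the children carry exact offset gaps, or
#' ordering-only constraints under `positional = "ordered"`); a gram with no
#' indexed substring is unconstraining, so it becomes ALL and the merging
#' rules are re-applied upward. AND/OR nodes become IDXAND/IDXOR. If the
#' whole tree collapses to ALL, the plan is a FULLSCAN of the part. The
#' resulting candidate set is always a superset of the true match set;
#' verification removes the false positives.
#'
#' @param tree a merged parse tree from [to_parse_tree()].
#' @param index the `gram_index` of the part being filtered.
#' @param positional `"exact"`: substring-decomposition children must sit at
#'   their exact relative offsets; `"ordered"`: only left-before-right is
#'   enforced (both are sound; exact prunes more).
#' @return an object of class `candidate_plan`: list with `root` (a plan
#'   node or `NULL` for an empty plan), `part`, `positional`.
#' @export
compile_candidate_plan <- function(tree, index,
                                   positional = c("exact", "ordered")) {
  positional <- match.arg(positional)
  stopifnot(inherits(index, "gram_index"))
  root <- compile_node(tree, index, positional)
  if (identical(root, "ALL")) root <- plan_fullscan()
  structure(list(root = root, part = index$part, positional = positional),
            class = "candidate_plan")
}

compile_node <- function(tree, index, positional) {
  switch(tree$kind,
    all = "ALL",
    gram = compile_gram(tree$gram, index, positional),
    and = {
      kids <- lapply(tree$children, compile_node, index, positional)
      kids <- Filter(function(k) !identical(k, "ALL"), kids)
      if (length(kids) == 0L) "ALL"
      else if (length(kids) == 1L) kids[[1L]]
      else plan_idxand(kids, constraint = "ordered")
    },
    or = {
      kids <- lapply(tree$children, compile_node, index, positional)
      if (any(vapply(kids, identical, logical(1), "ALL"))) return("ALL")
      plan_idxor(kids)
    },
    stop("unknown parse-tree node kind: ", tree$kind))
}

# The three cases for a leaf gram g:
# 1) indexed -> IDXSCAN(g);
# 2) unindexed but substrings indexed -> IDXAND over a cover;
# 3) nothing indexed -> ALL.
compile_gram <- function(g, index, positional) {
  if (!is.na(match(g, index$grams))) return(plan_idxscan(g))
  cover <- cover_with_indexed(g, index)
  if (nrow(cover) == 0L) return("ALL")
  if (nrow(cover) == 1L) return(plan_idxscan(cover$gram[1L]))
  plan_idxand(lapply(cover$gram, plan_idxscan),
              constraint = positional,
              gaps = if (positional == "exact") diff(cover$start) else NULL)
}

# Greedy interval cover of g by indexed substrings: repeatedly take, among
# substrings starting at or before the first uncovered position, the one
# reaching furthest right; uncoverable positions are skipped. Overlaps are
# allowed; any subset of substring constraints is sound.
cover_with_indexed <- function(g, index) {
  n <- nchar(g)
  empty0 <- data.frame(gram = character(0), start = integer(0))
  if (n < 2L) return(empty0)
  occ <- gram_occurrences(g, 1L, n - 1L)
  occ <- occ[occ$gram %in% index$grams, , drop = FALSE]
  empty <- data.frame(gram = character(0), start = integer(0))
  if (nrow(occ) == 0L) return(empty)
  occ$start <- occ$offset
  occ$end <- occ$start + nchar(occ$gram)        # exclusive, 0-based
  picked <- integer(0)
  covered_to <- 0L
  repeat {
    cand <- which(occ$start <= covered_to & occ$end > covered_to)
    if (length(cand) == 0L) {
      nxt <- occ$start[occ$start > covered_to]
      if (length(nxt) == 0L) break
      covered_to <- min(nxt)
      next
    }
    best <- cand[which.max(occ$end[cand])]
    picked <- c(picked, best)
    covered_to <- occ$end[best]
    if (covered_to >= n) break
  }
  picked <- picked[order(occ$start[picked])]
  data.frame(gram = occ$gram[picked], start = occ$start[picked],
             stringsAsFactors = FALSE)
}

#' Compile a regex pattern straight to a candidate plan
#'
#' Convenience pipeline: parse, normalize, build and merge the parse tree,
#' compile against the index.
#'
#' @inheritParams parse_regex
#' @inheritParams compile_candidate_plan
#' @export
compile_regex_plan <- function(pattern, index,
                               positional = c("exact", "ordered")) {
  tree <- to_parse_tree(normalize_regex(parse_regex(pattern)))
  plan <- compile_candidate_plan(tree, index, positional = match.arg(positional))
  attr(plan, "pattern") <- pattern
  plan
}

#' Distinct grams referenced by a candidate plan
#'
#' The set `G` charged by the cost model.
#'
#' @param plan a `candidate_plan` or plan node.
#' @return character vector of distinct grams (empty for FULLSCAN).
#' @export
plan_grams <- function(plan) {
  node <- if (inherits(plan, "candidate_plan")) plan$root else plan
  if (is.null(node)) return(character(0))
  collect <- function(nd) {
    switch(nd$op,
      idxscan = nd$gram,
      fullscan = character(0),
      unlist(lapply(nd$children, collect)))
  }
  unique(collect(node))
}

#' @export
print.candidate_plan <- function(x, index = NULL, ...) {
  cat(sprintf("<candidate_plan> part=%s positional=%s\n",
              toupper(x$part), x$positional))
  if (is.null(x$root)) cat("  (empty plan)\n")
  else print_plan_node(x$root, 1L, index)
  invisible(x)
}

print_plan_node <- function(node, indent, index = NULL) {
  pad <- strrep("  ", indent)
  if (node$op == "idxscan") {
    extra <- ""
    if (!is.null(index)) {
      p <- gram_lookup(index, node$gram)
      if (!is.null(p)) {
        extra <- sprintf("  [postings=%d, pages=%d]",
                         length(p$tids), p$num_pages)
      }
    }
    cat(pad, "IDXSCAN(\"", node$gram, "\")", extra, "\n", sep = "")
  } else if (node$op == "fullscan") {
    cat(pad, "FULLSCAN\n", sep = "")
  } else {
    lab <- toupper(node$op)
    if (node$op == "idxand") {
      lab <- paste0(lab, " [", node$constraint,
                    if (!is.null(node$gaps))
                      paste0(", gaps=", paste(node$gaps, collapse = ",")),
                    "]")
    }
    cat(pad, lab, "\n", sep = "")
    for (k in node$children) print_plan_node(k, indent + 1L, index)
  }
}
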