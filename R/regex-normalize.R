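#' Normalize a regex AST to the OR/STAR core
#'
#' Rewrites the parsed pattern so that the only remaining operators are
#' concatenation, alternation (`|`) and Kleene star: `X+` becomes `XX*`,
#' `X?` becomes `(X | eps)`, and a character class becomes the alternation
#' over its member characters. The any-character `.` is kept as a symbolic
#' node rather than being materialized as an alternation over the whole
#' alphabet; since every `.` (starred or not) contributes no indexable
#' constraint downstream, this is observationally equivalent and avoids an
#' alphabet-sized blowup. All rewrites preserve the matched language
#' exactly.
#'
#' @param ast output of [parse_regex()] (an already-normalized AST passes
#'   through unchanged).
#' @return a normalized AST containing only `lit`, `any`, `eps`, `concat`,
#'   `or`, `star` nodes, with nested concat/or flattened.
#' @export
normalize_regex <- function(ast) {
  out <- rx_norm(ast)
  attr(out, "pattern") <- attr(ast, "pattern")
  out
}

rx_norm <- function(node) {
  switch(node$kind,
    lit = , any = , eps = node,
    class = {
      if (length(node$chars) == 1L) re_lit(node$chars)
      else re_or(lapply(node$chars, re_lit))
    },
    plus = {
      x <- rx_norm(node$child)
      rx_flat_concat(list(x, re_star(x)))
    },
    opt = re_or(list(rx_norm(node$child), re_eps())),
    star = re_star(rx_norm(node$child)),
    concat = {
      kids <- lapply(node$children, rx_norm)
      rx_flat_concat(kids)
    },
    or = {
      kids <- lapply(node$children, rx_norm)
      flat <- list()
      for (k in kids) {
        if (k$kind == "or") flat <- c(flat, k$children)
        else flat <- c(flat, list(k))
      }
      if (length(flat) == 1L) flat[[1L]] else re_or(flat)
    },
    stop("unknown AST node kind: ", node$kind))
}

# Flatten nested concats and drop eps children (concat identity).
rx_flat_concat <- function(kids) {
  flat <- list()
  for (k in kids) {
    if (k$kind == "concat") flat <- c(flat, k$children)
    else if (k$kind == "eps") next
    else flat <- c(flat, list(k))
  }
  if (length(flat) == 0L) re_eps()
  else if (length(flat) == 1L) flat[[1L]]
  else re_concat(flat)
}

#' Convert a normalized regex into the AND/OR candidate parse tree
#'
#' The constraint tree used for candidate generation: runs of adjacent
#' literal characters collapse into multi-character GRAM leaves,
#' concatenation becomes AND, alternation becomes OR, and every starred
#' subtree becomes the unconstraining ALL node (a star matches all
#' combinations of its body, including the empty string, so it cannot
#' contribute a required gram). A bare `.` and an epsilon alternative are
#' likewise unconstraining and become ALL. Merging is then applied to a
#' fixpoint (see [merge_parse_tree()]): an AND drops ALL children, an OR
#' with an ALL child collapses to ALL, so the final tree has only AND/OR
#' internal nodes and GRAM leaves -- or is the single node ALL.
#'
#' The tree is an over-approximation by construction: every string matching
#' the pattern satisfies the tree's gram constraints (never the converse),
#' which is what makes candidate generation sound.
#'
#' @param ast a normalized AST from [normalize_regex()].
#' @return a parse tree of nodes with `kind` in `gram`, `and`, `or`, `all`.
#' @export
to_parse_tree <- function(ast) {
  merge_parse_tree(rx_tree(ast))
}

pt_gram <- function(g) structure(list(kind = "gram", gram = g),
                                 class = "parse_tree")
pt_all <- function() structure(list(kind = "all"), class = "parse_tree")
pt_and <- function(children) structure(list(kind = "and", children = children),
                                       class = "parse_tree")
pt_or <- function(children) structure(list(kind = "or", children = children),
                                      class = "parse_tree")

rx_tree <- function(node) {
  switch(node$kind,
    lit = pt_gram(node$ch),
    any = , eps = , star = pt_all(),
    concat = {
      # adjacency is only known here: runs of consecutive literal children
      # collapse into one multi-character GRAM leaf. An intervening ALL
      # (from '.', a star, or an eps alternative) keeps runs apart, and the
      # merge rules never re-join them.
      kids <- lapply(node$children, rx_tree)
      out <- list()
      for (k in kids) {
        last <- if (length(out)) out[[length(out)]] else NULL
        if (!is.null(last) && last$kind == "gram" && k$kind == "gram") {
          out[[length(out)]] <- pt_gram(paste0(last$gram, k$gram))
        } else out <- c(out, list(k))
      }
      if (length(out) == 1L) out[[1L]] else pt_and(out)
    },
    or = pt_or(lapply(node$children, rx_tree)),
    class = stop("to_parse_tree() expects a normalized AST (found a class node)"),
    plus = , opt = stop("to_parse_tree() expects a normalized AST (found '",
                        node$kind, "')"),
    stop("unknown AST node kind: ", node$kind))
}

#' Apply the ALL-merging rules to a candidate parse tree
#'
#' Rules, applied bottom-up: an AND drops its ALL children (ALL imposes no
#' constraint), unwraps if a single child remains, and becomes ALL if none
#' remains; an OR with an ALL child becomes ALL; single-child internal
#' nodes unwrap; nested ANDs and ORs flatten. Idempotent: merging an
#' already-merged tree returns it unchanged. (Literal-run concatenation is
#' not a merge rule -- it happens once during tree conversion, where
#' adjacency still means contiguity; after an intervening ALL is dropped,
#' its two neighbors are ordered but not contiguous.)
#'
#' @param tree a parse tree (see [to_parse_tree()]).
#' @return the merged tree.
#' @export
merge_parse_tree <- function(tree) {
  switch(tree$kind,
    gram = , all = tree,
    and = {
      kids <- lapply(tree$children, merge_parse_tree)
      flat <- list()
      for (k in kids) {
        if (k$kind == "and") flat <- c(flat, k$children)
        else flat <- c(flat, list(k))
      }
      out <- Filter(function(k) k$kind != "all", flat)
      if (length(out) == 0L) pt_all()
      else if (length(out) == 1L) out[[1L]]
      else pt_and(out)
    },
    or = {
      kids <- lapply(tree$children, merge_parse_tree)
      if (any(vapply(kids, function(k) k$kind == "all", logical(1)))) {
        return(pt_all())
      }
      flat <- list()
      for (k in kids) {
        if (k$kind == "or") flat <- c(flat, k$children)
        else flat <- c(flat, list(k))
      }
      if (length(flat) == 1L) flat[[1L]] else pt_or(flat)
    },
    stop("unknown parse-tree node kind: ", tree$kind))
}

#' @export
print.parse_tree <- function(x, indent = 0, ...) {
  pad <- strrep("  ", indent)
  switch(x$kind,
    gram = cat(pad, "GRAM(\"", x$gram, "\")\n", sep = ""),
    all = cat(pad, "ALL\n", sep = ""),
    and = , or = {
      cat(pad, toupper(x$kind), "\n", sep = "")
      for (k in x$children) print(k, indent = indent + 1L)
    })
  invisible(x)
}
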