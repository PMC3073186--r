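#' Parse a restricted regular expression into an AST
#'
#' Supported constructs: literal characters, `.` (any character), alternation
#' `|`, quantifiers `*`, `+`, `?`, grouping `( )`, character classes like
#' `[a-z0-9]` or enumerated sets, and backslash escapes of metacharacters
#' (plus `\d` digits, `\w` word characters, `\s` whitespace). Operator
#' precedence is quantifier > concatenation > alternation.
#'
#' Constructs outside the candidate-generation fragment -- anchors `^`/`$`,
#' backreferences, lookaround, negated classes, counted repetition `{m,n}` --
#' raise an "unsupported regex feature" error rather than being silently
#' mishandled.
#'
#' @param pattern the regular-expression string.
#' @return a raw AST: nested lists with a `kind` field in `lit`, `any`,
#'   `class`, `concat`, `or`, `star`, `plus`, `opt`, `eps`; the original
#'   pattern is kept in attribute `"pattern"`.
#' @export
parse_regex <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L)
  chars <- strsplit(enc2utf8(pattern), "", fixed = TRUE)[[1L]]
  st <- new.env(parent = emptyenv())
  st$chars <- chars; st$pos <- 1L; st$n <- length(chars)
  ast <- rx_alt(st)
  if (st$pos <= st$n) {
    stop("regex parse error at position ", st$pos, ": unexpected '",
         st$chars[st$pos], "'")
  }
  attr(ast, "pattern") <- pattern
  ast
}

rx_peek <- function(st) if (st$pos <= st$n) st$chars[st$pos] else NA_character_
rx_take <- function(st) { ch <- st$chars[st$pos]; st$pos <- st$pos + 1L; ch }
rx_unsupported <- function(what) {
  stop("unsupported regex feature: ", what, call. = FALSE)
}

re_node <- function(kind, ...) structure(list(kind = kind, ...), class = "regex_ast")
re_lit <- function(ch) re_node("lit", ch = ch)
re_any <- function() re_node("any")
re_eps <- function() re_node("eps")
re_class <- function(chars) re_node("class", chars = chars)
re_concat <- function(children) re_node("concat", children = children)
re_or <- function(children) re_node("or", children = children)
re_star <- function(x) re_node("star", child = x)
re_plus <- function(x) re_node("plus", child = x)
re_opt <- function(x) re_node("opt", child = x)

rx_alt <- function(st) {
  branches <- list(rx_concat(st))
  while (identical(rx_peek(st), "|")) {
    rx_take(st)
    branches <- c(branches, list(rx_concat(st)))
  }
  if (length(branches) == 1L) branches[[1L]] else re_or(branches)
}

rx_concat <- function(st) {
  parts <- list()
  while (!is.na(ch <- rx_peek(st)) && ch != "|" && ch != ")") {
    parts <- c(parts, list(rx_repeat(st)))
  }
  if (length(parts) == 0L) re_eps()
  else if (length(parts) == 1L) parts[[1L]]
  else re_concat(parts)
}

rx_repeat <- function(st) {
  node <- rx_atom(st)
  repeat {
    ch <- rx_peek(st)
    if (identical(ch, "*")) { rx_take(st); node <- re_star(node) }
    else if (identical(ch, "+")) { rx_take(st); node <- re_plus(node) }
    else if (identical(ch, "?")) { rx_take(st); node <- re_opt(node) }
    else break
  }
  node
}

rx_atom <- function(st) {
  ch <- rx_peek(st)
  if (is.na(ch)) stop("regex parse error: unexpected end of pattern")
  if (ch == "(") {
    rx_take(st)
    if (identical(rx_peek(st), "?")) rx_unsupported("group modifier '(?'")
    inner <- rx_alt(st)
    if (!identical(rx_peek(st), ")")) stop("regex parse error: missing ')'")
    rx_take(st)
    return(inner)
  }
  if (ch == "[") return(rx_class(st))
  if (ch == ".") { rx_take(st); return(re_any()) }
  if (ch == "\\") return(rx_escape(st))
  if (ch %in% c("^", "$")) rx_unsupported(paste0("anchor '", ch, "'"))
  if (ch %in% c("{", "}")) rx_unsupported("counted repetition '{m,n}'")
  if (ch %in% c("*", "+", "?", ")")) {
    stop("regex parse error at position ", st$pos, ": unexpected '", ch, "'")
  }
  re_lit(rx_take(st))
}

rx_escape <- function(st) {
  rx_take(st)                       # the backslash
  ch <- rx_peek(st)
  if (is.na(ch)) stop("regex parse error: dangling backslash")
  rx_take(st)
  if (ch %in% c("\\", ".", "|", "*", "+", "?", "(", ")", "[", "]",
                "{", "}", "^", "$", "-", "/")) return(re_lit(ch))
  if (ch == "d") return(re_class(strsplit("0123456789", "")[[1L]]))
  if (ch == "w") return(re_class(c(strsplit(
    "abcdefghijklmnopqrstuvwxyzABCDEFGHIJKLMNOPQRSTUVWXYZ0123456789_",
    "")[[1L]])))
  if (ch == "s") return(re_class(c(" ", "\t", "\n", "\r")))
  if (ch == "t") return(re_lit("\t"))
  if (ch == "n") return(re_lit("\n"))
  if (ch %in% as.character(0:9)) rx_unsupported("backreference")
  if (ch %in% c("b", "B")) rx_unsupported("word-boundary assertion")
  rx_unsupported(paste0("escape '\\", ch, "'"))
}

rx_class <- function(st) {
  rx_take(st)                       # '['
  if (identical(rx_peek(st), "^")) rx_unsupported("negated character class")
  members <- character(0)
  first <- TRUE
  repeat {
    ch <- rx_peek(st)
    if (is.na(ch)) stop("regex parse error: missing ']'")
    if (ch == "]" && !first) { rx_take(st); break }
    first <- FALSE
    if (ch == "\\") {
      node <- rx_escape(st)
      members <- c(members, if (node$kind == "lit") node$ch else node$chars)
      next
    }
    rx_take(st)
    if (identical(rx_peek(st), "-") && st$pos + 1L <= st$n &&
        st$chars[st$pos + 1L] != "]") {
      rx_take(st)                   # '-'
      hi <- rx_take(st)
      lo_i <- utf8ToInt(ch); hi_i <- utf8ToInt(hi)
      if (hi_i < lo_i) stop("regex parse error: invalid class range ",
                            ch, "-", hi)
      members <- c(members, vapply(lo_i:hi_i, intToUtf8, character(1)))
    } else {
      members <- c(members, ch)
    }
  }
  re_class(unique(members))
}

#' Render an AST back to a PCRE pattern string
#'
#' Inverse-direction helper used to check that rewrites preserve the matched
#' language: the rendered pattern can be handed to the stock regex engine and
#' compared against the original.
#'
#' @param ast a regex AST ([parse_regex()] or [normalize_regex()] output).
#' @return a pattern string.
#' @export
regex_deparse <- function(ast) {
  esc <- function(ch) {
    if (ch %in% c("\\", ".", "|", "*", "+", "?", "(", ")", "[", "]",
                  "{", "}", "^", "$")) paste0("\\", ch) else ch
  }
  switch(ast$kind,
    lit = esc(ast$ch),
    any = ".",
    eps = "",
    class = paste0("[", paste0(vapply(ast$chars, function(c) {
      if (c %in% c("\\", "]", "^", "-")) paste0("\\", c) else c
    }, character(1)), collapse = ""), "]"),
    concat = paste0(vapply(ast$children, function(x) {
      s <- regex_deparse(x)
      if (x$kind %in% c("or")) paste0("(?:", s, ")") else s
    }, character(1)), collapse = ""),
    or = paste0("(?:", paste0(vapply(ast$children, regex_deparse,
                                     character(1)), collapse = "|"), ")"),
    star = paste0(rx_deparse_group(ast$child), "*"),
    plus = paste0(rx_deparse_group(ast$child), "+"),
    opt = paste0(rx_deparse_group(ast$child), "?"),
    stop("unknown AST node kind: ", ast$kind))
}

rx_deparse_group <- function(x) {
  s <- regex_deparse(x)
  if (x$kind %in% c("lit", "any", "class")) s else paste0("(?:", s, ")")
}
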