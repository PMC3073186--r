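# helpers to build expected ASTs/trees compactly
lit_run <- function(s) lapply(strsplit(s, "")[[1]], gramtriple:::re_lit)
ast_kind <- function(a) a$kind

test_that("the supported grammar parses with the right precedence", {
  a <- parse_regex("(GPR|CCD).*MOUSE.*")
  expect_equal(a$kind, "concat")
  expect_equal(a$children[[1]]$kind, "or")
  expect_equal(a$children[[2]]$kind, "star")
  expect_equal(a$children[[2]]$child$kind, "any")

  expect_equal(parse_regex("a")$kind, "lit")

  q3 <- parse_regex("[0-9]19857[0-9]")
  expect_equal(q3$kind, "concat")
  expect_equal(q3$children[[1]]$kind, "class")
  expect_setequal(q3$children[[1]]$chars, as.character(0:9))
  expect_equal(length(q3$children), 7L)  # class + 5 digits + class

  # precedence: star binds tighter than concat, concat tighter than '|'
  ab <- parse_regex("ab|c*")
  expect_equal(ab$kind, "or")
  expect_equal(ab$children[[2]]$kind, "star")
})

test_that("unsupported constructs are rejected explicitly", {
  expect_error(parse_regex("^abc"), "unsupported regex feature")
  expect_error(parse_regex("abc$"), "unsupported regex feature")
  expect_error(parse_regex("(a)\\1"), "unsupported regex feature")
  expect_error(parse_regex("(?=x)y"), "unsupported regex feature")
  expect_error(parse_regex("[^abc]"), "unsupported regex feature")
  expect_error(parse_regex("a{2,3}"), "unsupported regex feature")
  expect_error(parse_regex("a\\bc"), "unsupported regex feature")
  expect_error(parse_regex("(a"), "missing ')'")
  expect_error(parse_regex("a)"), "unexpected")
})

test_that("normalization rewrites to the OR/STAR core", {
  # a+ -> aa*
  ap <- normalize_regex(parse_regex("a+"))
  expect_equal(ap$kind, "concat")
  expect_equal(ap$children[[1]]$kind, "lit")
  expect_equal(ap$children[[2]]$kind, "star")
  expect_equal(regex_deparse(ap), "aa*")

  # character class -> alternation over members
  cl <- normalize_regex(parse_regex("[a-c]"))
  expect_equal(cl$kind, "or")
  expect_setequal(vapply(cl$children, `[[`, character(1), "ch"),
                  c("a", "b", "c"))

  # X? -> (X | eps)
  op <- normalize_regex(parse_regex("x?"))
  expect_equal(op$kind, "or")
  expect_equal(op$children[[2]]$kind, "eps")

  # the full worked pattern: CONCAT(OR(GPR,CCD), STAR(ANY), M,O,U,S,E, STAR(ANY))
  full <- normalize_regex(parse_regex("(GPR|CCD).*MOUSE.*"))
  expect_equal(full$kind, "concat")
  kinds <- vapply(full$children, ast_kind, character(1))
  expect_equal(kinds[1], "or")
  expect_equal(kinds[2], "star")
  expect_equal(tail(kinds, 1), "star")
  mid <- full$children[3:7]
  expect_equal(paste0(vapply(mid, `[[`, character(1), "ch"), collapse = ""),
               "MOUSE")
  # only the core node kinds remain
  check_core <- function(n) {
    expect_true(n[["kind"]] %in% c("lit", "any", "eps", "concat", "or",
                                   "star"))
    if (!is.null(n[["children"]])) lapply(n[["children"]], check_core)
    if (!is.null(n[["child"]])) check_core(n[["child"]])
    invisible(NULL)
  }
  check_core(full)
})

test_that("normalization preserves the matched language", {
  set.seed(601)
  strings <- part_strings(read_triple_db(
    text = generate_corpus(fixture_spec(seed = 31, n_triples = 120))), "o")
  n_checked <- 0L
  for (i in 1:120) {
    pat <- random_regex(strings)
    norm <- regex_deparse(normalize_regex(parse_regex(pat)))
    probe <- c(sample(strings, 10), "GPR64_MOUSE", "", "xyz")
    expect_equal(grepl(paste0("^(?:", norm, ")$"), probe, perl = TRUE),
                 grepl(paste0("^(?:", pat, ")$"), probe, perl = TRUE),
                 info = pat)
    n_checked <- n_checked + length(probe)
  }
  expect_gte(n_checked, 1000L)
})

test_that("parse-tree conversion reproduces the worked AND/OR tree", {
  tree <- to_parse_tree(normalize_regex(parse_regex("(GPR|CCD).*MOUSE.*")))
  expect_equal(tree$kind, "and")
  expect_equal(length(tree$children), 2L)
  expect_equal(tree$children[[1]]$kind, "or")
  expect_setequal(vapply(tree$children[[1]]$children, `[[`, character(1),
                         "gram"), c("GPR", "CCD"))
  expect_equal(tree$children[[2]]$gram, "MOUSE")
})

test_that("ALL-merging rules: OR absorbs ALL; star-only patterns give ALL root", {
  expect_equal(to_parse_tree(normalize_regex(parse_regex("GPR|x*")))$kind,
               "all")
  expect_equal(to_parse_tree(normalize_regex(parse_regex("x*")))$kind, "all")
  expect_equal(to_parse_tree(normalize_regex(parse_regex(".*")))$kind, "all")
  # a non-starred '.' splits a literal run into two gram leaves
  sp <- to_parse_tree(normalize_regex(parse_regex("AB.CD")))
  expect_equal(sp$kind, "and")
  expect_equal(vapply(sp$children, `[[`, character(1), "gram"),
               c("AB", "CD"))
  # X? merges away (eps alternative makes the OR unconstraining)
  opt <- to_parse_tree(normalize_regex(parse_regex("AB(CD)?")))
  expect_equal(opt$gram, "AB")
})

test_that("merging is a fixpoint", {
  set.seed(77)
  strings <- c("GPR64_MOUSE", "spliceosomal complex", "alpha beta")
  for (i in 1:50) {
    tree <- to_parse_tree(normalize_regex(parse_regex(random_regex(strings))))
    expect_identical(merge_parse_tree(tree), tree)
  }
})

test_that("index choice follows the filter variable's position", {
  pat <- list(s = list(type = "var", value = "protein"),
              p = list(type = "const", value = "mnemonic"),
              o = list(type = "var", value = "m"))
  expect_equal(choose_index_part(pat, "m"), "o")
  expect_equal(choose_index_part(pat, "protein"), "s")
  expect_error(choose_index_part(pat, "nope"), "does not occur")
  patp <- list(s = list(type = "var", value = "x"),
               p = list(type = "var", value = "pred"),
               o = list(type = "const", value = "y"))
  expect_equal(choose_index_part(patp, "pred"), "p")
  dup <- list(s = list(type = "var", value = "x"),
              p = list(type = "const", value = "p"),
              o = list(type = "var", value = "x"))
  expect_error(choose_index_part(dup, "x"), "more than one position")
})

# index with exactly the keys of the worked plan example
fig_index <- function(keys = c("GPR", "CCD", "MOU", "USE")) {
  gram_index(keys,
             lapply(seq_along(keys), function(i) {
               list(tids = 1L, offs = list(0L))
             }),
             part = "o", n_triples = 100L)
}

test_that("plan compilation covers the three unindexed-gram cases", {
  ix <- fig_index()
  # the worked example: MOUSE unindexed, MOU/USE indexed
  plan <- compile_regex_plan("(GPR|CCD).*MOUSE.*", ix)
  expect_equal(
    gramtriple:::serialize_plan_node(plan$root),
    "IDXAND(IDXOR(IDXSCAN(GPR),IDXSCAN(CCD)),IDXAND(IDXSCAN(MOU),IDXSCAN(USE)))")
  # the MOUSE decomposition carries the exact offset gap MOU(0) -> USE(2)
  sub <- plan$root$children[[2]]
  expect_equal(sub$constraint, "exact")
  expect_equal(sub$gaps, 2L)

  # case 1 only: all leaves indexed -> structure-preserving conversion
  p1 <- compile_regex_plan("(GPR|CCD).*USE.*", ix)
  expect_equal(gramtriple:::serialize_plan_node(p1$root),
               "IDXAND(IDXOR(IDXSCAN(GPR),IDXSCAN(CCD)),IDXSCAN(USE))")

  # case 3 under an OR: the branch with no indexed substring collapses the
  # whole OR to ALL; the enclosing AND drops it and only USE remains
  p3 <- compile_regex_plan("(GPR|ZZZZ).*USE.*", ix)
  expect_equal(gramtriple:::serialize_plan_node(p3$root), "IDXSCAN(USE)")

  # whole tree unconstrained -> FULLSCAN
  pf <- compile_regex_plan("(ZZ|QQ)", ix)
  expect_equal(pf$root$op, "fullscan")

  # ordered mode drops the exact gaps
  po <- compile_regex_plan(".*MOUSE.*", ix, positional = "ordered")
  expect_equal(po$root$constraint, "ordered")
  expect_null(po$root$gaps)
})

test_that("plan gram sets and cost inputs are the distinct plan grams", {
  ix <- fig_index()
  plan <- compile_regex_plan("(GPR|CCD).*MOUSE.*", ix)
  expect_setequal(plan_grams(plan), c("GPR", "CCD", "MOU", "USE"))
  expect_equal(plan_grams(compile_regex_plan("(ZZ|QQ)", ix)), character(0))
})

test_that("candidate plans are sound: no false negatives on random patterns", {
  db <- read_triple_db(
    text = generate_corpus(fixture_spec(seed = 21, n_triples = 800)))
  ix <- build_gram_indexes(db)
  strs <- part_strings(db, "o")
  set.seed(321)
  for (i in 1:120) {
    pat <- random_regex(strs)
    for (mode in c("exact", "ordered")) {
      plan <- compile_regex_plan(pat, ix$o, positional = mode)
      cand <- plan_tids(plan, db, ix$o)
      truth <- oracle_regex_scan(db, pat, "o", "anchored")
      expect_true(all(truth %in% cand),
                  info = paste(mode, pat))
    }
  }
})
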