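fig2_setup <- function() {
  db <- two_triple_db()
  ix <- build_gram_indexes(db, alpha = 5, beta = 5, c = 1)
  list(db = db, ix = ix)
}

test_that("cursors exhaust idempotently and IDXSCAN streams whole postings", {
  s <- fig2_setup()
  cur <- idxscan_cursor(s$ix$o, "MOUSE")
  a <- get_next(cur); b <- get_next(cur)
  expect_equal(a, list(tid = 1L, offs = 6L))
  expect_equal(b, list(tid = 2L, offs = 6L))
  expect_null(get_next(cur))
  expect_null(get_next(cur))   # idempotent end
  expect_null(get_next(cur))

  # absent gram: empty stream, also idempotent
  cur2 <- idxscan_cursor(s$ix$o, "absent")
  expect_null(get_next(cur2))
  expect_null(get_next(cur2))

  # stream length equals posting length for every key
  db <- read_triple_db(
    text = generate_corpus(fixture_spec(seed = 14, n_triples = 400)))
  ix <- build_gram_indexes(db)
  for (k in seq_along(ix$o$grams)) {
    n_stream <- length(collect_stream(idxscan_cursor(ix$o, ix$o$grams[k])))
    expect_equal(n_stream, length(ix$o$postings[[k]]$tids))
  }
})

mk_stream <- function(entries) {
  i <- 0L
  make_cursor(function() {
    if (i >= length(entries)) return(NULL)
    i <<- i + 1L
    entries[[i]]
  })
}

test_that("IDXAND intersects with positional constraints", {
  mou <- list(list(tid = 1L, offs = 6L), list(tid = 2L, offs = 6L))
  use <- list(list(tid = 1L, offs = 8L), list(tid = 2L, offs = 8L))
  # exact gap 2 (MOU then USE inside MOUSE)
  got <- collect_stream(idxand_cursor(list(mk_stream(mou), mk_stream(use)),
                                      constraint = "exact", gaps = 2L))
  expect_equal(vapply(got, `[[`, numeric(1), "tid"), c(1, 2))
  expect_equal(got[[1]]$offs, 6L)  # combined-match start

  # wrong gap: nothing
  none <- collect_stream(idxand_cursor(list(mk_stream(mou), mk_stream(use)),
                                       constraint = "exact", gaps = 5L))
  expect_equal(length(none), 0L)

  # disjoint tid sets: empty
  a <- list(list(tid = 1L, offs = 0L)); b <- list(list(tid = 2L, offs = 0L))
  expect_equal(length(collect_stream(
    idxand_cursor(list(mk_stream(a), mk_stream(b))))), 0L)

  # ordered: right offset must be strictly greater
  x <- list(list(tid = 5L, offs = 4L))
  y <- list(list(tid = 5L, offs = 4L))
  expect_equal(length(collect_stream(idxand_cursor(
    list(mk_stream(x), mk_stream(y)), constraint = "ordered"))), 0L)
  y2 <- list(list(tid = 5L, offs = c(2L, 9L)))
  got2 <- collect_stream(idxand_cursor(list(mk_stream(x), mk_stream(y2)),
                                       constraint = "ordered"))
  expect_equal(got2[[1]]$tid, 5L)

  # a child without offsets only contributes the tid intersection
  or_like <- list(list(tid = 5L, offs = NULL))
  got3 <- collect_stream(idxand_cursor(list(mk_stream(or_like), mk_stream(x)),
                                       constraint = "ordered"))
  expect_equal(length(got3), 1L)
})

test_that("IDXOR unions tid streams, sorted and duplicate-free", {
  a <- list(list(tid = 1L, offs = 0L), list(tid = 3L, offs = 0L))
  b <- list(list(tid = 2L, offs = 1L), list(tid = 3L, offs = 5L))
  got <- collect_stream(idxor_cursor(list(mk_stream(a), mk_stream(b))))
  expect_equal(vapply(got, `[[`, numeric(1), "tid"), c(1, 2, 3))
  # x union empty = x
  got2 <- collect_stream(idxor_cursor(list(mk_stream(a), mk_stream(list()))))
  expect_equal(vapply(got2, `[[`, numeric(1), "tid"), c(1, 3))

  # random posting sets against the set-union oracle
  set.seed(55)
  for (i in 1:25) {
    sets <- lapply(1:3, function(j) sort(sample.int(40, sample(0:12, 1))))
    streams <- lapply(sets, function(s) {
      mk_stream(lapply(s, function(t) list(tid = t, offs = NULL)))
    })
    got <- vapply(collect_stream(idxor_cursor(streams)), `[[`,
                  numeric(1), "tid")
    expect_equal(got, sort(Reduce(union, sets)))
  }
})

test_that("REGSCAN resolves candidates through the dictionary; FILTER verifies", {
  s <- fig2_setup()
  plan <- compile_regex_plan(".*MOUSE.*", s$ix$o)
  cand <- collect_stream(regscan_cursor(plan, s$db, s$ix$o))
  expect_equal(length(cand), 2L)
  expect_equal(s$db$strings[cand[[1]]$o], "GPR64_MOUSE")

  kept <- collect_stream(filter_verify_cursor(
    regscan_cursor(plan, s$db, s$ix$o), "(GPR|CCD).*MOUSE.*", "o", s$db,
    "anchored"))
  expect_equal(length(kept), 2L)
  none <- collect_stream(filter_verify_cursor(
    regscan_cursor(plan, s$db, s$ix$o), "(XX|YY).*MOUSE.*", "o", s$db,
    "anchored"))
  expect_equal(length(none), 0L)

  # empty sub-plan -> empty candidate stream
  empty_plan <- structure(list(root = NULL, part = "o", positional = "exact"),
                          class = "candidate_plan")
  expect_equal(length(collect_stream(regscan_cursor(empty_plan, s$db,
                                                    s$ix$o))), 0L)
})

test_that("verified results equal the full-scan oracle; candidates are supersets", {
  db <- read_triple_db(
    text = generate_corpus(fixture_spec(seed = 17, n_triples = 900)))
  ix <- build_gram_indexes(db)
  strs <- part_strings(db, "o")
  set.seed(171)
  for (i in 1:100) {
    pat <- random_regex(strs)
    plan <- compile_regex_plan(pat, ix$o)
    cand <- plan_tids(plan, db, ix$o)
    ver <- verified_tids(plan, db, ix$o, pat)
    truth <- oracle_regex_scan(db, pat, "o", "anchored")
    expect_setequal(ver, truth)
    expect_true(all(ver %in% cand))
    # verification is independent of the positional mode
    plano <- compile_regex_plan(pat, ix$o, positional = "ordered")
    expect_setequal(verified_tids(plano, db, ix$o, pat), truth)
  }
})

test_that("TSCAN binds variables and sorts by the first variable", {
  db <- two_triple_db()
  pat <- list(s = list(type = "var", value = "x"),
              p = list(type = "const", value = "mnemonic"),
              o = list(type = "var", value = "m"))
  rows <- collect_stream(tscan_cursor(db, pat))
  expect_equal(length(rows), 2L)
  expect_equal(sort(names(rows[[1]])), c("m", "x"))
  ids <- vapply(rows, `[[`, integer(1), "x")
  expect_equal(ids, sort(ids))

  # constant matching nothing
  pat2 <- modifyList(pat, list(p = list(type = "const", value = "nope")))
  expect_equal(length(collect_stream(tscan_cursor(db, pat2))), 0L)

  # all-variable pattern returns n rows
  pat3 <- list(s = list(type = "var", value = "a"),
               p = list(type = "var", value = "b"),
               o = list(type = "var", value = "c"))
  expect_equal(length(collect_stream(tscan_cursor(db, pat3))), db$n)
})

test_that("MGJN and HSJN agree with each other and a nested-loop oracle", {
  db <- read_triple_db(
    text = generate_corpus(fixture_spec(seed = 23, n_triples = 300)))
  p1 <- list(s = list(type = "var", value = "gp"),
             p = list(type = "const", value = "rdf:type"),
             o = list(type = "var", value = "type"))
  p2 <- list(s = list(type = "var", value = "gp"),
             p = list(type = "const", value = "mnemonic"),
             o = list(type = "var", value = "m"))
  l <- function() tscan_cursor(db, p1)
  r <- function() tscan_cursor(db, p2)
  mg <- collect_stream(mgjn_cursor(l(), r(), "gp"))
  hs <- collect_stream(hsjn_cursor(l(), r(), "gp"))
  expect_gt(length(mg), 0L)
  expect_equal(canon_rows(mg), canon_rows(hs))

  # nested-loop oracle
  lr <- collect_stream(l()); rr <- collect_stream(r())
  nl <- list()
  for (a in lr) for (b in rr) {
    if (a[["gp"]] == b[["gp"]]) {
      nl <- c(nl, list(c(a, b[setdiff(names(b), names(a))])))
    }
  }
  expect_equal(canon_rows(mg), canon_rows(nl))

  # disjoint key sets join to nothing
  fake <- mk_stream(list(stats::setNames(c(999999L), "gp")))
  expect_equal(length(collect_stream(hsjn_cursor(fake, r(), "gp"))), 0L)
})

test_that("MGJN rejects unsorted input instead of producing wrong answers", {
  rows_desc <- list(stats::setNames(5L, "x"), stats::setNames(1L, "x"))
  rows_ok <- list(stats::setNames(1L, "x"), stats::setNames(5L, "x"))
  cur <- mgjn_cursor(mk_stream(rows_desc), mk_stream(rows_ok), "x")
  expect_error(collect_stream(cur), "not sorted")
})
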