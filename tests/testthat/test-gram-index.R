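test_that("gram enumeration is the exact sliding window", {
  g <- enumerate_grams("MOUSE", 3, 3)
  expect_setequal(paste(g$gram, g$offset), c("MOU 0", "OUS 1", "USE 2"))

  expect_equal(nrow(enumerate_grams("AB", 3, 4)), 0L)

  # 11-character string, lengths 2..4: 10 + 9 + 8 windows
  g2 <- enumerate_grams("GPR64_MOUSE", 2, 4)
  expect_equal(nrow(g2), 27L)
  # every reported (gram, offset) is a real occurrence
  for (i in seq_len(nrow(g2))) {
    expect_equal(substr("GPR64_MOUSE", g2$offset[i] + 1,
                        g2$offset[i] + nchar(g2$gram[i])), g2$gram[i])
  }
})

test_that("selectivity counts containing triples over corpus size", {
  db <- two_triple_db()
  expect_equal(gram_selectivity(db, "MOUSE", "o"), 1.0)
  expect_equal(gram_selectivity(db, "GPR", "o"), 0.5)
  expect_equal(gram_selectivity(db, "ZZZ", "o"), 0.0)
  empty <- triple_db(data.frame(s = character(), p = character(),
                                o = character()))
  expect_error(gram_selectivity(empty, "A", "o"), "empty corpus")
})

test_that("redundant grams are removed: only minimal infrequent grams remain", {
  # the worked redundancy example: MOU infrequent makes 4_MOU, _MOU, MOUS,
  # MOUSE redundant
  survivors <- gramtriple:::minimal_grams(
    c("MOU", "4_MOU", "_MOU", "MOUS", "MOUSE"), alpha = 3L)
  expect_equal(survivors, "MOU")

  # an antichain of incomparable grams is untouched
  expect_setequal(gramtriple:::minimal_grams(c("XQZ", "QZW"), 3L),
                  c("XQZ", "QZW"))
})

test_that("selective grams equal the brute-force oracle on seeded corpora", {
  for (seed in c(2, 9)) {
    db <- read_triple_db(
      text = generate_corpus(fixture_spec(seed = seed, n_triples = 150)))
    for (part in c("s", "o")) {
      expect_equal(select_selective_grams(db, part, 2, 4, 0.1),
                   oracle_selective_grams(db, part, 2, 4, 0.1),
                   info = paste("seed", seed, "part", part))
    }
  }
})

test_that("index keys are an infrequent-gram antichain with sound postings", {
  db <- read_triple_db(
    text = generate_corpus(fixture_spec(seed = 4, n_triples = 500)))
  ix <- build_gram_indexes(db, alpha = 2, beta = 4, c = 0.1)
  for (part in c("s", "p", "o")) {
    idx <- ix[[part]]
    keys <- idx$grams
    lens <- nchar(keys)
    expect_true(all(lens >= 2 & lens <= 4))
    # threshold property
    for (g in keys) {
      expect_lte(gram_selectivity(db, g, part), 0.1)
    }
    # antichain: no key is a substring of another key
    for (g in keys) {
      others <- setdiff(keys, g)
      expect_false(any(vapply(others, function(h) {
        grepl(g, h, fixed = TRUE)
      }, logical(1))), info = paste("key", g, "part", part))
    }
    # posting soundness + completeness against the part strings
    strs <- part_strings(db, part)
    for (k in seq_along(keys)) {
      g <- keys[k]
      p <- idx$postings[[k]]
      for (j in seq_along(p$tids)) {
        s <- strs[p$tids[j]]
        for (f in p$offs[[j]]) {
          expect_equal(substr(s, f + 1, f + nchar(g)), g)
        }
        # completeness: every occurrence recorded
        occ <- enumerate_grams(s, nchar(g), nchar(g))
        expect_setequal(p$offs[[j]], occ$offset[occ$gram == g])
      }
      # completeness over triples
      expect_setequal(p$tids, which(grepl(g, strs, fixed = TRUE)))
    }
  }
})

test_that("completeness: every infrequent gram contains an index key", {
  db <- read_triple_db(
    text = generate_corpus(fixture_spec(seed = 12, n_triples = 300)))
  ix <- build_gram_indexes(db, c = 0.1)
  occ <- gramtriple:::gram_occurrences(part_strings(db, "o"), 2L, 4L)
  grams <- unique(occ$gram)
  sel <- vapply(grams, function(g) gram_selectivity(db, g, "o"), numeric(1))
  infreq <- grams[sel <= 0.1]
  keyset <- ix$o$grams
  covered <- vapply(infreq, function(g) {
    g %in% keyset || any(vapply(keyset, function(k) {
      grepl(k, g, fixed = TRUE)
    }, logical(1)))
  }, logical(1))
  expect_true(all(covered))
})

test_that("the worked posting example: MOUSE at 0-based offset 6 in both triples", {
  db <- two_triple_db()
  ix <- build_gram_indexes(db, alpha = 5, beta = 5, c = 1)
  p <- gram_lookup(ix$o, "MOUSE")
  expect_false(is.null(p))
  expect_equal(p$tids, c(1L, 2L))
  expect_equal(p$offs, list(6L, 6L))
})

test_that("an all-frequent corpus yields empty indexes; lookups distinguish absent", {
  db <- triple_db(data.frame(s = rep("aaa", 4), p = rep("bbb", 4),
                             o = rep("ccc", 4)))
  ix <- build_gram_indexes(db, c = 0.5)
  expect_equal(length(ix$o$grams), 0L)
  expect_equal(ix$o$height, 1L)
  expect_null(gram_lookup(ix$o, "aa"))

  db2 <- two_triple_db()
  ix2 <- build_gram_indexes(db2, alpha = 2, beta = 4, c = 0.6)
  for (g in ix2$o$grams) {
    expect_false(is.null(gram_lookup(ix2$o, g)))
  }
  expect_null(gram_lookup(ix2$o, "notakey"))
})

test_that("index persistence round-trips structurally", {
  db <- read_triple_db(
    text = generate_corpus(fixture_spec(seed = 8, n_triples = 500)))
  ix <- build_gram_indexes(db)
  path <- withr::local_tempfile(fileext = ".idx")
  save_indexes(ix, path)
  expect_identical(load_indexes(path), ix)

  bad <- withr::local_tempfile()
  saveRDS(list(tag = "gramtriple-db"), bad)   # wrong container type
  expect_error(load_indexes(bad), "not a gramtriple index")
  writeLines("trunc", bad)
  expect_error(load_indexes(bad), "cannot read")
})

test_that("paging simulation follows the documented formulas", {
  # 300 postings at 128 entries/page -> 3 pages
  post <- list(list(tids = seq_len(300L), offs = as.list(rep(0L, 300L))))
  ix <- gram_index("ab", post, part = "o", n_triples = 1000L)
  expect_equal(ix$num_pages, 3L)
  expect_equal(ix$part_pages, as.integer(ceiling(1000 / 128)))
  # height: 1 key -> 1 + ceil(log_256(1)) = 1; many keys -> grows
  expect_equal(ix$height, 1L)
  many <- gram_index(sprintf("g%03d", 1:300),
                     replicate(300, list(tids = 1L, offs = list(0L)),
                               simplify = FALSE),
                     part = "o", n_triples = 10L)
  expect_equal(many$height, 1L + as.integer(ceiling(log(300) / log(256))))
})
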