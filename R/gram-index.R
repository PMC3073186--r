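#' Enumerate all n-grams of a string with their start offsets
#'
#' All substrings of `s` with length between `alpha` and `beta`, each paired
#' with every 0-based start offset (in characters, not bytes) at which it
#' occurs. Strings shorter than `alpha` yield no grams.
#'
#' @param s a single string.
#' @param alpha,beta minimum and maximum gram length, `1 <= alpha <= beta`.
#' @return data.frame with columns `gram` (character) and `offset` (integer,
#'   0-based), ordered by gram length then offset.
#' @examples
#' enumerate_grams("MOUSE", 3, 3)  # MOU, OUS, USE
#' @export
enumerate_grams <- function(s, alpha, beta) {
  stopifnot(length(s) == 1L, alpha >= 1L, alpha <= beta)
  occ <- gram_occurrences(s, alpha, beta)
  data.frame(gram = occ$gram, offset = occ$offset, stringsAsFactors = FALSE)
}

# Vectorized sliding-window gram extraction over a vector of strings.
# Returns data.frame(idx, gram, offset) where idx indexes `strings` and
# offset is 0-based. Offsets are character positions (substring() is
# code-point based on UTF-8 input), which keeps them aligned with the
# regex engine used for verification.
gram_occurrences <- function(strings, alpha, beta) {
  strings <- enc2utf8(strings)
  lens <- nchar(strings, type = "chars")
  idx_all <- integer(0); gram_all <- character(0); off_all <- integer(0)
  for (L in alpha:beta) {
    k <- pmax(lens - L + 1L, 0L)
    if (sum(k) == 0L) next
    idx <- rep.int(seq_along(strings), k)
    start <- sequence(k)                  # 1-based start within each string
    gram <- substring(strings[idx], start, start + L - 1L)
    idx_all <- c(idx_all, idx)
    gram_all <- c(gram_all, gram)
    off_all <- c(off_all, start - 1L)
  }
  data.frame(idx = idx_all, gram = gram_all, offset = off_all,
             stringsAsFactors = FALSE)
}

#' Selectivity of a gram on one part of the corpus
#'
#' `Sel(g) = C(g) / N` where `N` is the number of triples and `C(g)` the
#' number of triples whose part string contains `g` as a substring. The
#' counting unit is the triple, matching the triple-ID-keyed posting lists.
#'
#' @param db a [triple_db()]; must be nonempty.
#' @param gram the gram string.
#' @param part `"s"`, `"p"` or `"o"`.
#' @return a fraction in `[0, 1]`.
#' @export
gram_selectivity <- function(db, gram, part = c("s", "p", "o")) {
  part <- match.arg(part)
  if (db$n == 0L) stop("selectivity is undefined on an empty corpus")
  mean(grepl(gram, part_strings(db, part), fixed = TRUE))
}

#' Select the selective grams of one corpus part
#'
#' A gram is *infrequent* when its selectivity is at most `c`; it is
#' *selective* when additionally no proper substring of it with length at
#' least `alpha` is itself infrequent (such longer grams are redundant:
#' any string containing them necessarily contains the shorter infrequent
#' gram). The selective grams are the minimal infrequent grams within the
#' length window -- the keys actually indexed.
#'
#' @inheritParams gram_selectivity
#' @param alpha,beta gram length window.
#' @param c selectivity threshold, `0 < c <= 1`.
#' @return character vector of selective grams, sorted.
#' @export
select_selective_grams <- function(db, part = c("s", "p", "o"),
                                   alpha = 2L, beta = 4L, c = 0.1) {
  part <- match.arg(part)
  stopifnot(c > 0, c <= 1, alpha >= 1L, alpha <= beta)
  occ <- gram_occurrences(part_strings(db, part), alpha, beta)
  if (nrow(occ) == 0L) return(character(0))
  pair <- !duplicated(paste(occ$gram, occ$idx, sep = "\r"))
  cnt <- table(occ$gram[pair])
  infreq <- names(cnt)[as.vector(cnt) / db$n <= c]
  c_sort(minimal_grams(infreq, alpha))
}

# Keep only grams with no proper substring of length >= alpha in the set.
minimal_grams <- function(grams, alpha) {
  if (length(grams) == 0L) return(grams)
  lens <- nchar(grams)
  keep <- rep(TRUE, length(grams))
  for (P in unique(lens[lens > alpha])) {
    g <- grams[lens == P]
    redundant <- rep(FALSE, length(g))
    for (L in alpha:(P - 1L)) {
      for (s in 1L:(P - L + 1L)) {
        redundant <- redundant | substring(g, s, s + L - 1L) %in% grams
      }
    }
    keep[lens == P] <- !redundant
  }
  grams[keep]
}

#' Construct a gram index from explicit contents
#'
#' Low-level constructor for one per-part inverted index: an ordered map from
#' gram to posting list, where a posting list is the tid-ascending vector of
#' triples containing the gram plus the sorted 0-based start offsets within
#' each part string. Page counts per gram and a tree height are simulated by
#' deterministic formulas so the I/O cost model has something to charge:
#' `numPages(g) = ceiling(#postings / entries_per_page)` and
#' `height = 1 + ceiling(log_fanout(max(#keys, 1)))`.
#'
#' Most callers want [build_gram_indexes()]; this constructor exists for
#' assembling small indexes by hand (tests, worked examples).
#'
#' @param grams character vector of key grams.
#' @param postings list parallel to `grams`; each element a list with
#'   integer vector `tids` and list `offs` of integer offset vectors.
#' @param part which triple part the index covers.
#' @param n_triples corpus size backing the index.
#' @param alpha,beta,sel_threshold build parameters recorded on the index.
#' @param entries_per_page,fanout paging-simulation parameters.
#' @return an object of class `gram_index`.
#' @export
gram_index <- function(grams, postings, part = c("s", "p", "o"),
                       n_triples = 0L, alpha = 2L, beta = 4L,
                       sel_threshold = 0.1,
                       entries_per_page = 128L, fanout = 256L) {
  part <- match.arg(part)
  stopifnot(length(grams) == length(postings))
  ord <- order(grams, method = "radix")
  grams <- grams[ord]
  postings <- postings[ord]
  num_pages <- vapply(postings, function(p) {
    as.integer(ceiling(length(p$tids) / entries_per_page))
  }, integer(1))
  height <- if (length(grams) == 0L) 1L else {
    1L + as.integer(ceiling(log(max(length(grams), 1L)) / log(fanout)))
  }
  structure(list(part = part, grams = grams, postings = postings,
                 num_pages = num_pages, height = height,
                 n_triples = as.integer(n_triples),
                 part_pages = as.integer(ceiling(n_triples / entries_per_page)),
                 alpha = as.integer(alpha), beta = as.integer(beta),
                 sel_threshold = sel_threshold,
                 entries_per_page = as.integer(entries_per_page),
                 fanout = as.integer(fanout)),
            class = "gram_index")
}

#' Build the three selective-gram inverted indexes
#'
#' For each of the subject, predicate and object parts: select the selective
#' grams (see [select_selective_grams()]) and record, for every selected
#' gram, its full posting list of `(tid, offsets)` occurrences.
#'
#' With triple-counted selectivity, predicate strings (drawn from a tiny
#' vocabulary) almost never produce infrequent grams, so the predicate index
#' is typically near-empty; that is expected.
#'
#' @inheritParams select_selective_grams
#' @inheritParams gram_index
#' @return an object of class `gram_index_set`: list with elements `s`, `p`,
#'   `o` (each a `gram_index`) and the build parameters.
#' @export
build_gram_indexes <- function(db, alpha = 2L, beta = 4L, c = 0.1,
                               entries_per_page = 128L, fanout = 256L) {
  stopifnot(inherits(db, "triple_db"))
  idx <- lapply(c(s = "s", p = "p", o = "o"), function(part) {
    build_part_index(db, part, alpha, beta, c, entries_per_page, fanout)
  })
  structure(c(idx, list(alpha = as.integer(alpha), beta = as.integer(beta),
                        sel_threshold = c,
                        entries_per_page = as.integer(entries_per_page),
                        fanout = as.integer(fanout))),
            class = "gram_index_set")
}

build_part_index <- function(db, part, alpha, beta, c,
                             entries_per_page, fanout) {
  strings <- part_strings(db, part)
  occ <- gram_occurrences(strings, alpha, beta)
  selected <- character(0)
  postings <- list()
  if (nrow(occ) > 0L && db$n > 0L) {
    pair <- !duplicated(paste(occ$gram, occ$idx, sep = "\r"))
    cnt <- table(occ$gram[pair])
    infreq <- names(cnt)[as.vector(cnt) / db$n <= c]
    selected <- c_sort(minimal_grams(infreq, alpha))
    keep <- occ$gram %in% selected
    occ <- occ[keep, , drop = FALSE]
    ord <- order(occ$gram, occ$idx, occ$offset, method = "radix")
    occ <- occ[ord, , drop = FALSE]
    # group offsets per (gram, tid), then (tid, offs) records per gram
    by_gram <- split(seq_len(nrow(occ)), factor(occ$gram, levels = selected))
    postings <- lapply(by_gram, function(rows) {
      tids <- occ$idx[rows]
      offs <- split(occ$offset[rows], tids)
      utids <- as.integer(names(offs))
      o <- order(utids)
      list(tids = utids[o], offs = unname(offs[o]))
    })
    names(postings) <- NULL
  }
  gram_index(selected, postings, part = part, n_triples = db$n,
             alpha = alpha, beta = beta, sel_threshold = c,
             entries_per_page = entries_per_page, fanout = fanout)
}

#' Posting-list lookup
#'
#' @param index a `gram_index`.
#' @param gram the gram to look up.
#' @return the posting list `list(tids=, offs=, num_pages=)` if `gram` is an
#'   index key, else `NULL` (absent is distinguishable from an empty list:
#'   keys never have empty postings).
#' @export
gram_lookup <- function(index, gram) {
  stopifnot(inherits(index, "gram_index"))
  i <- match(gram, index$grams)
  if (is.na(i)) return(NULL)
  c(index$postings[[i]], list(num_pages = index$num_pages[i]))
}

#' @export
print.gram_index <- function(x, ...) {
  cat(sprintf("<gram_index %s> %d keys, height %d, %d posting pages (corpus n=%d)\n",
              toupper(x$part), length(x$grams), x$height,
              sum(x$num_pages), x$n_triples))
  invisible(x)
}

#' @export
print.gram_index_set <- function(x, ...) {
  cat(sprintf("<gram_index_set> alpha=%d beta=%d c=%g\n",
              x$alpha, x$beta, x$sel_threshold))
  for (part in c("s", "p", "o")) print(x[[part]])
  invisible(x)
}

IDX_FORMAT_TAG <- "gramtriple-index"
IDX_FORMAT_VERSION <- 1L

#' Persist / load a gram index set
#'
#' Same versioned container convention as [save_database()]; a load of a
#' file with the wrong tag or version is an error.
#'
#' @param indexes a `gram_index_set`.
#' @param path file path.
#' @export
save_indexes <- function(indexes, path) {
  stopifnot(inherits(indexes, "gram_index_set"))
  saveRDS(list(tag = IDX_FORMAT_TAG, version = IDX_FORMAT_VERSION,
               indexes = indexes), path)
  invisible(path)
}

#' @rdname save_indexes
#' @export
load_indexes <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("cannot read index file '", path, "': ", conditionMessage(e))
  })
  if (!is.list(obj) || !identical(obj$tag, IDX_FORMAT_TAG)) {
    stop("not a gramtriple index file: ", path)
  }
  if (!identical(obj$version, IDX_FORMAT_VERSION)) {
    stop("index format version mismatch: found ", obj$version,
         ", expected ", IDX_FORMAT_VERSION)
  }
  obj$indexes
}
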