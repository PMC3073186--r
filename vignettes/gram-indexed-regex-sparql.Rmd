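---
title: "Candidate generation for regex-filtered SPARQL with selective n-gram indexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Candidate generation for regex-filtered SPARQL with selective n-gram indexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gramtriple)
```

## The problem

Bioinformatics knowledge bases — GeneOntology, UniProt, Bio2RDF — ship as
RDF: sets of (subject, predicate, object) triples queried with SPARQL.
Users rarely know the exact lexical value of a fact ("find proteins whose
mnemonic mentions MOUSE"), so regex `FILTER` constraints are common, and a
naive engine must scan and regex-test every triple for each one.

`gramtriple` implements the alternative this package is built around: an
inverted index over *selective n-grams* of the triple strings, a compiler
that turns a regex into a *candidate-generation plan* over that index, and
a candidate-then-verify executor. Candidate generation is deliberately
approximate but **sound**: it may return false positives, never false
negatives; an exact regex re-check (`FILTER`) removes the false positives,
so answers are exact while the expensive regex runs only on a (usually
small) candidate set.

## Index model

For a database $D = \{t_1,\dots,t_n\}$ with parts $t_i.s, t_i.p, t_i.o$,
three independent indexes $I_S, I_P, I_O$ are built, because a filter
constrains exactly one part of its triple pattern. For one part:

1. **Enumerate** every substring (gram) of length $\alpha \le \ell \le
   \beta$ of every part string.
2. **Threshold**: the selectivity of gram $g$ is $Sel(g) = C(g)/N$, with
   $N$ the number of triples and $C(g)$ the number of triples whose part
   string contains $g$. Grams with $Sel(g) \le c$ are *infrequent* — they
   prune well.
3. **Minimize**: if $g$ is infrequent, every gram containing $g$ is too,
   and indexing it adds nothing; such redundant grams are dropped. The
   surviving *selective grams* are the minimal infrequent grams: the index
   keys form an antichain under the substring relation, and every
   infrequent gram in the window contains some key.

Each key maps to a posting list of $(tid, \textit{offs})$ pairs — every
triple containing the gram, with all 0-based character offsets at which it
occurs. Offsets are what let an intersection respect *positions* (below).

Two properties are enforced by tests: *posting soundness/completeness*
(every recorded occurrence is real, every real occurrence is recorded),
and *equivalence with a brute-force oracle* that re-derives the selective
grams by exhaustive enumeration.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `alpha`, `beta` | 2, 4 | gram length window (characters) |
| `c` | 0.1 | selectivity threshold for "infrequent" |
| `entries_per_page` | 128 | posting entries per simulated page |
| `fanout` | 256 | simulated B+-tree fanout (sets `height`) |

`alpha = 2, beta = 4, c = 0.1` are the classic operating point for
selective-gram indexing of this kind of data: shorter grams are almost
never selective, longer ones inflate the index without adding pruning
power, and a 10% containment threshold is the conventional cut for
"infrequent". All are overridable in `build_gram_indexes()` and the CLI.

The package stores everything in memory; pages are *simulated* so that the
I/O cost model has a deterministic, testable input:
`numPages(g) = ceil(|postings(g)| / entries_per_page)` and
`height(I) = 1 + ceil(log_fanout(#keys))` (1 for an empty index). Only
ratios of costs matter for plan choice, so the simulation's absolute scale
is immaterial.

One modeling choice deserves a note: selectivity counts **triples**, not
distinct strings, because posting lists are keyed by triple ID. A
consequence is that predicate strings — drawn from a tiny vocabulary that
appears in nearly every triple — almost never yield selective grams, so
$I_P$ is typically near-empty. That is accepted, not worked around:
regexes over predicates simply fall back to scanning.

## From regex to candidate plan

Compilation has three stages, each preserving a superset guarantee.

**Normalization** rewrites the pattern so only concatenation, alternation
and Kleene star remain: `X+` becomes `XX*`, `X?` becomes `(X|ε)`, a
character class becomes the alternation over its members. `.` is kept as a
symbolic any-character node rather than being expanded into an alternation
over the whole alphabet — every `.` ends up unconstraining anyway, so this
is observationally equivalent and avoids alphabet-sized trees. All
rewrites preserve the matched language exactly (a property test matches
thousands of (pattern, string) pairs against the stock engine both ways).

**Parse-tree conversion** builds the constraint tree: literal runs become
GRAM leaves, concatenation becomes AND, alternation OR. Anything that
cannot force a gram to appear — a starred subtree, a bare `.`, an ε
alternative — becomes the ALL node ("any string"). Merging then runs to a
fixpoint: AND drops ALL children; OR with an ALL child *becomes* ALL
(if one branch is unconstrained, the disjunction is too). Literal-run
concatenation happens once, at conversion, where adjacency still means
contiguity; after an ALL between two runs is dropped they are ordered but
not contiguous, so the merge rules never re-join them.

**Plan emission** maps the tree onto the index: AND → IDXAND, OR → IDXOR,
GRAM g → one of three cases:

1. `g` is a key → `IDXSCAN(g)`;
2. `g` is not a key but substrings of it are → an IDXAND over IDXSCANs of
   a greedy interval cover of `g` (repeatedly pick, among indexed
   substrings starting at or before the first uncovered position, the one
   reaching furthest right). The classic example: with `MOU` and `USE`
   indexed but `MOUSE` not, `IDXSCAN("MOUSE")` becomes
   `IDXAND(IDXSCAN("MOU"), IDXSCAN("USE"))` with an exact offset gap of 2;
3. nothing usable → ALL, and the merge rules re-apply upward.

If the root itself collapses to ALL, the plan is a FULLSCAN of the part —
the pattern has no indexable content, and scan-plus-verify is all that can
be done.

### Positional constraints

IDXAND uses posting offsets. For a case-2 substring cover the relative
offsets are known exactly, so by default the intersection demands
`off(USE) = off(MOU) + 2` (mode `"exact"`). For grams met across a `.*`,
only order is known: left start strictly before right start (mode
`"ordered"`). `positional = "ordered"` applies the weaker rule everywhere;
both modes are sound, exact prunes more. IDXOR discards offsets — a union
has no single positional interpretation — and an IDXAND child without
offsets simply contributes its tid set. A property test confirms verified
results are identical under both modes.

## Execution and verification

Every operator implements the GetNext iterator contract: one result per
call, `NULL` at exhaustion, idempotently. IDXSCAN streams a posting list
in tid order; IDXAND/IDXOR are streaming merge-intersection/union; REGSCAN
resolves candidate tids through the string dictionary; FILTER re-tests the
original (un-normalized) pattern against the full part string with R's
PCRE engine — ground truth, independent of everything the planner did.
Multi-pattern queries use TSCAN (pattern scan producing variable-binding
rows, sorted by the first variable), merge join (MGJN, which *errors* on
unsorted input rather than silently mis-joining) and hash join (HSJN); the
two joins are tested to produce identical multisets.

**Regex semantics.** The default is anchored whole-string matching —
patterns in this tradition carry explicit `.*` wrappers when they mean
containment. SPARQL's `regex()` is instead a substring search;
`regex_semantics = "search"` gives that behavior by wrapping the pattern
in `.*(...).*` before planning and dropping the anchors at verification.
The divergence is deliberate and switchable.

Unicode is handled per code point throughout (gram offsets, `substring`,
PCRE in UTF-8 mode), and the fixture generator plants non-ASCII labels to
keep that path exercised.

## Cost model and plan choice

Evaluating a candidate plan reads, for each distinct gram in the plan's
gram set $G$, one root-to-leaf descent of the index plus the posting
pages:

$$Cost = OnePageAccessCost \times \Big(|G| \times Height(I) + \sum_{g \in G} NumPages(g)\Big)$$

A FULLSCAN costs the part's triple pages under the same paging rule. CPU
cost of verification is ignored (negligible next to I/O);
`OnePageAccessCost` defaults to 1 since only ratios matter. Height is
charged once per distinct gram — a case-2 split that adds grams adds
descents.

The optimizer enumerates, per pattern, TSCAN versus REGSCAN (REGSCAN wins
when its posting pages beat the part pages — rare patterns on large
corpora), then all bushy join orders with both join algorithms via dynamic
programming over connected pattern subsets, which reaches the same optimum
as exhaustive enumeration because costs combine bottom-up. The page-access
model above covers only candidate generation, so join costs use a minimal
convention of this package's own design: child costs plus one page-counted
pass per input, a sort pass for MGJN on unsorted input, cardinalities
estimated from posting/scan sizes and join output as the smaller input (no
value-frequency statistics). Ties break on a canonical plan serialization,
so plan choice is deterministic. Enumeration is capped at 8 patterns;
heuristic search for larger queries is out of scope.

## The synthetic corpus generator

Real GeneOntology dumps are large and external; the test bed instead
generates corpora with the string shapes that matter here:
GO-accession-like subjects (`go:0005739`), a small predicate vocabulary,
UniProt-style mnemonics (`GPR64_MOUSE`), phrase labels from a biological
word pool ("spliceosomal", "activity", ...), and ISBN-like digit strings.
Two knobs create the two regimes gram selection must handle: a planted
rare gram (default `XQZ` in 5% of mnemonics) that falls below the
threshold and gets indexed, and common suffixes (`_MOUSE`, `_HUMAN`,
`_YEAST`) that stay above it so redundancy removal has work to do.
Generation is seeded and byte-reproducible, and leaves the caller's RNG
state untouched.

What the generator does *not* emulate: the real ontology's graph
structure, its term-frequency distributions, string lengths beyond the
template ranges, or its sheer size. Passing tests therefore demonstrate
correctness of the machinery and the plausibility of plan choices at desk
scale — not wall-clock performance on the original data.

### Problem sizes used by the test suite

Property tests run on seeded corpora of 120–2,000 triples; the end-to-end
exactness sweep uses 20 corpora of 1,000–2,000 triples with 200 random
supported patterns each, comparing engine output against a full-scan regex
oracle. The random-pattern generator draws literals from the corpus (so a
useful share of patterns match) and quantifies only star-free bodies,
since nesting unbounded quantifiers invites catastrophic backtracking in
the verification engine rather than testing anything about candidate
generation.

## Numerical and degenerate-input choices

- Offsets are 0-based character positions; `MOUSE` in `GPR64_MOUSE` sits
  at offset 6.
- Strings compare case-sensitively; no case-folding anywhere.
- Minimality testing uses only substrings of length ≥ `alpha` (shorter
  ones are never index candidates).
- An empty corpus builds empty indexes (height 1); selectivity on an empty
  corpus is an error rather than 0/0.
- `lookup` distinguishes "absent key" (`NULL`) from an empty posting,
  which never occurs for real keys.
- Anchors `^`/`$`, backreferences, lookaround, negated classes and counted
  repetition are rejected with an explicit "unsupported regex feature"
  error — silently mishandling them would break the soundness guarantee.
- Duplicate triples keep distinct triple IDs; joins are bag-semantics; row
  output is sorted lexicographically (C collation) for reproducibility.

## Known limitations

- The page/height simulation stands in for a real paged B+-tree; absolute
  costs are not I/O measurements, only consistent relative estimates.
- Rebuild-only indexing: no incremental maintenance under updates.
- The SPARQL subset covers basic graph patterns plus regex FILTERs — no
  OPTIONAL/UNION/ORDER BY/LIMIT/DISTINCT, no property paths, no HTTP
  endpoint.
- Regular *path* expressions over graph edges are a different problem and
  out of scope.
- At a few thousand triples, TSCAN's handful of simulated pages often
  beats any multi-gram plan; REGSCAN's advantage appears exactly where it
  should — selective patterns, or larger corpora where part pages dwarf
  posting pages.
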