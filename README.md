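# gramtriple

Regular-expression `FILTER` support for SPARQL over RDF triple stores, the
candidate-then-verify way: index *selective n-grams* of the triple strings,
compile each regex into a plan over those grams that generates a sound
candidate superset, verify candidates with an exact regex check, and let a
page-access cost model decide when the index beats a scan.

Bioinformatics knowledge bases (GeneOntology, UniProt, Bio2RDF) are
published as RDF and queried with SPARQL, and because users rarely know the
exact lexical form of a fact, regex filters such as
`FILTER regex(?m, ".*MOUSE.*")` are everywhere. Evaluating them naively
means regex-testing every triple. `gramtriple` is for anyone who wants the
indexed alternative in R — as a library of composable pieces (triple store,
gram indexes, regex planner, iterator-based executor, optimizer) or as a
small command-line tool.

## The method in brief

For a database *D* = {t₁,…,tₙ} three inverted indexes *I_S*, *I_P*, *I_O*
are built, one per triple part. A gram *g* (substring of length α ≤ ℓ ≤ β)
is **infrequent** when its selectivity *Sel(g) = C(g)/N* ≤ *c*, where
*C(g)* counts triples whose part string contains *g*; the index keys are
the **selective grams** — infrequent grams containing no shorter infrequent
gram (minimal, so the keys form a substring antichain). Each key carries a
posting list of (tid, offsets) occurrences.

A regex filter compiles to a candidate plan: normalize to an OR/STAR core,
build the AND/OR parse tree in which starred subtrees become the
unconstraining ALL node, merge (AND drops ALL; OR with an ALL child *is*
ALL), then emit `IDXSCAN` for indexed grams, `IDXAND`/`IDXOR` for the
connectives — an unindexed gram is covered by indexed substrings with exact
offset gaps, or becomes ALL. Candidates are a superset of the true matches
by construction; the `FILTER` operator re-tests the original pattern, so
results are exact. Plans are costed as

    Cost = OnePageAccessCost × (|G| × Height(I) + Σ_{g∈G} NumPages(g))

and a bottom-up optimizer picks the cheapest execution plan (REGSCAN vs
scan per pattern; bushy join orders with merge/hash joins under the
GetNext iterator model).

## Worked example

```r
library(gramtriple)

db <- read_triple_db(text = c(
  '<Gpr64>  <mnemonic> "GPR64_MOUSE" .',
  '<Ccdc80> <mnemonic> "CCD80_MOUSE" .',
  '<Abc1>   <mnemonic> "ABC1_HUMAN" .'))
ix <- build_gram_indexes(db, alpha = 3, beta = 5, c = 0.7)
ix$o
#> <gram_index O> 22 keys, height 2, 22 posting pages (corpus n=3)

gram_lookup(ix$o, "GPR")     # posting: triple 1, 0-based offset 0
#> $tids
#> [1] 1
#> $offs
#> [[1]]
#> [1] 0
#> $num_pages
#> [1] 1

run_query(db, ix, 'SELECT * WHERE { ?prot <mnemonic> ?m
                     FILTER regex(?m, "(GPR|CCD).*MOUSE.*") . }')
#>     prot           m
#> 1 Ccdc80 CCD80_MOUSE
#> 2  Gpr64 GPR64_MOUSE
```

The 22 keys are the minimal infrequent grams of the three mnemonics (a
gram like `GPR` is kept; `GPR6`, which contains it, is redundant). The
query's two answer rows are exact: candidates came from the index, the
regex re-check removed any false positive.

The planner's output is inspectable. With keys `GPR`, `CCD`, `MOU`, `USE`
and `MOUSE` *not* indexed, the pattern above compiles to the intersection
of an alternation with a substring cover of `MOUSE` (`MOU` at offset 0,
`USE` exactly 2 later):

```r
compile_regex_plan("(GPR|CCD).*MOUSE.*", ix_manual)
#> <candidate_plan> part=O positional=exact
#>   IDXAND [ordered]
#>     IDXOR
#>       IDXSCAN("GPR")
#>       IDXSCAN("CCD")
#>     IDXAND [exact, gaps=2]
#>       IDXSCAN("MOU")
#>       IDXSCAN("USE")
```

A seeded generator of GeneOntology-like corpora
(`fixture_spec()` / `generate_corpus()`) and a CLI
(`inst/scripts/gramtriple.R`: `build-index`, `query`, `explain`, `stats`,
`make-fixture`) round out the package; `regex_semantics = "search"` gives
SPARQL's substring-matching `regex()` behavior instead of the default
anchored whole-string match.

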