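# semkos

Semi-automatic construction of hierarchical **knowledge organization
systems** (KOS) from full-text article collections, for literature miners
and bibliometricians who need a navigable taxonomy of a field's research
keywords and methods without the years of manual curation behind systems
like MeSH.

Manually curated vocabularies update slowly and cover few terms; flat
clusterings of word embeddings have no hierarchy and force one similarity
threshold on every semantic group. `semkos` implements the middle road: it
extracts terms from the corpus itself, embeds them, organizes them into a
binary average-linkage tree in which similarity thresholds vary naturally
with depth, and reduces the curator's job to spot-checking a few
representative leaves per branch.

## What the package does

1. **Term extraction** (`read_jats_articles`, `build_lexicon`) — author
   keywords come from the keyword sections of JATS/NXML files; research
   method names come from the subtitles of sections whose title contains
   *method* or *procedure* ("Materials and Methods", "Experimental
   procedures", "Methodology"). Surfaces are lowercased, ranked by
   frequency (`kwd1`, `kwd2`, …, `mtd1`, …), and surfaces appearing in
   both lists are kept only as methods.
2. **Longest-phrase-first recognition** (`recognize_terms`) — the corpus is
   scanned left to right; at each position the longest lexicon phrase wins
   and its words are consumed, so "short-term memory" is not counted inside
   "visual short-term memory". Infrequent terms are dropped by strict
   thresholds (keywords: > 5 keyword-section occurrences and > 10 corpus
   occurrences; methods: > 2 and > 10).
3. **Embedding** (`train_embeddings`) — joint term and document vectors
   (window 7, 300 dimensions, minimum count 10 by default), unit-normalized
   before clustering.
4. **Tree building and curation** (`agglomerate_average_linkage`,
   `sample_branch_for_review`, `annotate_cluster`, `regroup_level3`) —
   UPGMA over Euclidean distances on the unit sphere; leaves are labelled
   1..n and the k-th merge creates node n+k. Curators name monophyletic
   branches (several sibling branches may share one name), and level-2
   clusters are re-clustered into coarser level-3 groups.
5. **Keyword × method co-occurrence** (`correlation_matrix`,
   `rank_top_combinations`, `fit_power_law`) — for an article with citation
   weight W, keyword-cluster counts K_i and method-cluster counts M_j, the
   per-article correlation index is

   C_ij = W · K_i · M_j / Σ_{i,j} K_i · M_j

   so each article distributes exactly its weight W. Summing over articles
   gives the cluster × cluster matrix; binned cell values (10–400, step 10)
   are fitted with a count-weighted log–log regression to check the
   power-law shape of combination popularity.
6. **Article-group profiling** (`retrieve_articles`, `multiround_cluster`,
   `coverage_vector`) — groups retrieved by cluster membership are clustered
   with multi-round affinity propagation, and characterized by coverage
   vectors (the fraction of the group's articles containing at least one
   term of each cluster) and coverage differences against a reference
   group.
7. **Synthetic corpora** (`planted_spec`, `generate_corpus`) — JATS-like
   corpora with planted keyword groups, nested phrases, a boosted
   keyword-group × method-group affinity block, and power-law citations,
   with ground truth for scoring recovery (`score_recovery`).

## Worked example

On a small synthetic corpus (4 planted keyword groups, 3 method groups,
300 articles):

```r
library(semkos)
spec <- planted_spec(n_keyword_groups = 4L, terms_per_group = 4L,
                     n_method_groups = 3L, methods_per_group = 4L,
                     n_articles = 300L, seed = 42L)
gen <- generate_corpus(spec)
lex <- build_lexicon(gen$articles)
streams <- tokenize_corpus(gen$articles, lex)
flex <- filter_lexicon(set_corpus_counts(lex, streams))
streams <- tokenize_corpus(gen$articles, flex)
tab <- normalize_vectors(train_embeddings(streams,
        embedding_config(dimension = 32L, random_seed = 42L)))
kw <- intersect(flex$term_id[flex$kind == "keyword"], rownames(tab$term_vectors))
kwd_tree <- agglomerate_average_linkage(pairwise_distances(tab, kw))
mt <- intersect(flex$term_id[flex$kind == "method"], rownames(tab$term_vectors))
mtd_tree <- agglomerate_average_linkage(pairwise_distances(tab, mt))
kwd_kos <- regroup_level3(kos_from_cut(kwd_tree, 4, prefix = "kwd"), tab, k = 2)
mtd_kos <- kos_from_cut(mtd_tree, 3, prefix = "mtd")
cits <- setNames(vapply(gen$articles, function(a) a$citation_count, integer(1)),
                 names(streams))
m <- correlation_matrix(streams, kwd_kos, mtd_kos, cits)
rank_top_combinations(m, 3)
#>   keyword method    value
#> 1  kwd_25 mtd_22 144.1227
#> 2  kwd_28 mtd_22 140.5339
#> 3  kwd_28 mtd_23 123.8377
```

The three highest cells of the aggregated correlation matrix: e.g. articles
about keyword cluster `kwd_25` cited 144 weight-units worth of use of
method cluster `mtd_22` (the planted affinity block). The total matrix mass
(928 here) equals the summed citations of articles carrying both keyword
and method tokens. Profiling the articles that mention cluster `kwd_25`:

```r
grp <- retrieve_articles(kwd_kos, "kwd_25", streams)   # 190 articles
prof <- profile_article_group(grp, streams, kwd_kos, mtd_kos, cits, k = 3)
prof$methods
#>     name     value
#> 1 mtd_23 0.7473684
#> 2 mtd_22 0.5736842
#> 3 mtd_19 0.2000000
```

74.7% of the group's articles contain at least one term of method cluster
`mtd_23` (its coverage); `prof$top_cited` lists the group's most-cited
articles. For branch curation, `sample_branch_for_review(kwd_tree, node,
budget, seed)` returns a handful of representative leaves — one per major
subtree — instead of the whole branch.

A command-line front end is installed at `inst/cli/semkos`
(`semkos run --config config.json`, `semkos synth`, `semkos lexicon`, …),
and `run_pipeline()` executes all stages with content-hash caching so
re-annotation loops only recompute what changed.

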