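---
title: "Building a hierarchical literature KOS: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building a hierarchical literature KOS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`semkos` builds a hierarchical knowledge organization system (KOS) from a
full-text corpus in five steps: term extraction, phrase-first recognition,
embedding, average-linkage tree construction with manual branch review, and
downstream analyses (citation-weighted keyword × method co-occurrence and
article-group coverage profiling). This vignette documents the statistical
model behind each step, every tunable parameter, the numerical conventions,
and the design decisions taken where the problem was genuinely open.

## 1. Term extraction

Two term streams are harvested from JATS/NXML article records:

* **Keywords** — the raw entries of every `<kwd-group>`, concatenated in
  document order. Duplicates within an article are kept: source counts are
  occurrence counts, not article counts, so an author repeating a keyword
  weighs it up, which is the behaviour we want for frequency ranking.
* **Methods** — the titles of first-level subsections of every section
  whose (lowercased) title contains the substring `method` or `procedure`.
  This single rule covers "Methods", "Materials and Methods",
  "Experimental procedures" and "Methodology". Only first-level subtitles
  are taken: method names ("Statistical analysis",
  "Immunohistochemistry") overwhelmingly sit at that level, while deeper
  nesting is dominated by parameter subsections that are not method names.

Surfaces are normalized by lowercasing and whitespace collapsing — nothing
more. No stemming or synonym merging: the embedding step is what groups
morphological and synonymous variants, and premature normalization would
silently merge terms the curator may want to keep distinct.

A surface occurring in both lists is deleted from the keyword list and kept
as a method. The co-occurrence analysis below crosses keyword clusters with
method clusters; shared surfaces would otherwise put mass on the diagonal
by construction.

IDs are frequency ranks within kind (`kwd1` = most frequent keyword,
`mtd1` = most frequent method), with ties broken lexicographically so runs
are reproducible. IDs are assigned once, before filtering, and never
reassigned: a curator's notes keep meaning across threshold changes.

## 2. Phrase-first recognition and the frequency filters

`recognize_terms()` scans word boundaries left to right; at every
unconsumed position the *longest* lexicon phrase starting there is emitted
and its words consumed. A shorter phrase nested inside an emitted phrase is
therefore never counted — "short-term memory" inside "visual short-term
memory" yields one token, the longer phrase. The rationale is an embedding
artifact: if nested phrases were all emitted, "image analyses" and "gene
analyses" would share a co-occurring "analyses" context and acquire
spuriously similar vectors, so recognition must commit to the most specific
reading.

Conventions, all deliberate:

* Words are maximal runs of alphanumerics with *internal* hyphens kept
  ("short-term" is one word); all other punctuation splits.
* Matches never cross sentence boundaries (`.`, `?`, `!`, newline):
  multiword terms are intra-sentence objects.
* After a match, scanning resumes at the first word following it — no
  overlapping matches.
* Every word that is not part of a matched term is dropped from the token
  stream, stop words included. The streams passed to the embedding are
  therefore pure term sequences; what makes two terms similar is occurring
  in the same articles and sentences, not sharing function words.

Rare terms are then filtered with strict (`>`) thresholds: keywords need
more than 5 keyword-section occurrences and more than 10 corpus
occurrences; methods more than 2 and more than 10. A term seen a handful of
times cannot receive a trustworthy vector, and a noisy vector pollutes the
tree around it. Filtering never reassigns IDs, and raising a threshold can
only remove terms (a property the tests assert).

## 3. Embeddings

`train_embeddings()` consumes token streams and produces unit-comparable
term vectors plus one vector per document, behind a narrow interface with
two interchangeable backends:

* **`ppmi_svd`** (default) — positive pointwise mutual information over
  symmetric window co-occurrences, factored by truncated SVD
  (`U_k sqrt(S_k)`). It is exactly reproducible (no stochastic training;
  singular-vector signs are fixed deterministically), fast at desk scale,
  and count-based PPMI factorization is a standard, well-understood
  embedding construction. Document vectors are the mean of the document's
  term vectors.
* **`sgns`** — an Rcpp skip-gram trainer with negative sampling that also
  trains document vectors in the paragraph-vector (dbow) style: the
  document vector predicts each of its tokens. It honours the epoch count
  and the linear learning-rate schedule (rate `max(initial − k·decay,
  1e-4)` at epoch `k`), uses reduced-window sampling, and runs
  single-threaded from an internal seeded RNG so a fixed seed reproduces
  the table bit for bit.

Defaults: window 7, dimension 300, minimum count 10, 10 epochs, learning
rate 0.025 decaying by 0.002 per epoch — conventional settings for
literature-scale corpora. The test suite uses dimensions 16–50: with
planted vocabularies of ~100 terms, higher dimensions only add noise
directions. `ppmi_svd` is the default because term clustering needs
deterministic geometry more than it needs the (stochastic) predictive
objective; `sgns` is provided and contract-tested for users who want the
iterative trainer. Terms below `min_count` get no vector and simply do not
enter the tree.

Before clustering, term vectors are normalized to unit Euclidean norm
(`normalize_vectors()`; tolerance 1e-9, zero-norm vectors are an error
naming the term). Distances are then Euclidean on the unit sphere,
`d = sqrt(2 − 2cos)`, a monotone transform of cosine distance — rankings
agree with cosine while keeping metric machinery simple.

## 4. The merge tree and branch review

`agglomerate_average_linkage()` implements UPGMA with an explicit labelling
contract: leaves are 1..n (in input order), the k-th merge creates node
n+k, the root is 2n−1. At each step the two active clusters with minimal
*average* inter-cluster distance merge, at a height equal to that average.
Average linkage is the compromise choice: single linkage chains through
outliers, complete linkage is hostage to them.

Numerical conventions:

* Inter-cluster sums are maintained additively over original matrix
  entries, so heights equal what a naive all-pairs recomputation gives (the
  acceptance suite checks exact merge-order agreement against such an
  oracle over 200 random matrices, heights to 1e-9).
* Ties on the minimal average are broken by the smallest
  `(min label, max label)` pair, making the whole construction
  deterministic; the tie-break is part of the contract and tested with
  exactly tied inputs.
* Average linkage is reducible, so heights are non-decreasing along the
  merge order; `validate_merge_tree()` asserts this (slack 1e-12) together
  with the label bijection.

One known discrepancy is worth recording: under this labelling rule a tree
with n leaves has root 2n−1, and that is what the package produces; texts
sometimes quote the root of an n-leaf tree as 2n, which is inconsistent
with "n−1 merges starting at n+1" and is treated here as an off-by-one.

**Branch review.** The point of the binary tree is that a curator need not
read every term under a node: nearby leaves are near-synonyms, so checking
one leaf per major subtree suffices. `sample_branch_for_review()`
formalizes one defensible version of that heuristic: starting from the
node's children, it repeatedly expands the subtree whose top split is
highest (the coarsest unresolved split) until the budget is reached, then
draws one seeded leaf per subtree. Budgets at least the leaf count return
everything. The strategy is a design choice — the underlying workflow is a
human heuristic with no unique formalization.

**Annotation.** Level-2 annotations attach names to monophyletic branches;
several *sibling* branches may share one name (the paraphyletic-union
rule) when a semantic group happens to be split across adjacent branches.
Level-2 annotations must be disjoint on terms — overlaps error, listing the
conflicting terms — and every annotation event is appended to a log so a
curation session can be replayed. `kos_from_cut()` produces the automatic
starting template (a k-cut of the tree, placeholder names); curation is
renaming and adjusting it. `regroup_level3()` re-clusters the level-2
cluster representations (plain componentwise means of member unit vectors,
not re-normalized — cluster coherence should show as vector length) with
the same UPGMA machinery; the default group count, one level-3 group per
~13 level-2 clusters, matches the curation granularity the workflow
targets. `layout_landscape()` projects representations to 2-D (PCA by
default; the projector is pluggable) with dot areas proportional to summed
citations and colors keyed by level-3 parent.

## 5. Citation-weighted co-occurrence

For one article with citation weight W, keyword-cluster occurrence counts
K_1..K_m and method-cluster occurrence counts M_1..M_n (token occurrences,
not distinct terms), the correlation index between keyword cluster i and
method cluster j is

$$C_{ij} = \frac{W \, K_i M_j}{\sum_{i'=1}^{m}\sum_{j'=1}^{n} K_{i'} M_{j'}}$$

The denominator runs over *all* keyword × method pairs of the article — the
only normalization under which an article distributes exactly its weight W
(`sum(C) == W`, asserted to 1e-9 relative over 1,000 random articles).
Articles with no keyword tokens or no method tokens contribute a zero
matrix. Aggregation is the elementwise sum, so the matrix total equals the
summed citations of contributing articles, aggregation is linear over
article subsets, and doubling all W doubles every cell.

For display, the log matrix masks zero cells as missing rather than −Inf.
For the power-law diagnostic, cell values are binned over [10, 400] in 39
width-10 bins — half-open [lo, lo+10), except the top bin, closed at 400 so
"from 10 to 400" is inclusive at both ends. Values below 10 are discarded
(too numerous), above 400 as well (the long tail makes bin counts
unstable).

**Fitting.** The exponent is estimated by least squares on (log bin
center, log count) over positive-count bins, with each bin *weighted by its
count*. The weighting is the one deliberate departure from the most naive
fit: tail bins hold 0 or 1 observations, and under unweighted least squares
their log 1 = 0 values flatten the slope — simulation during development
(planted discrete power law, exponent 2, 5,000 draws, this binning) showed
unweighted fits biased low by ≈ 0.4 while count-weighted fits recover the
exponent well within ±0.3, which is what the acceptance suite now
verifies. Count weights are the usual Poisson-variance approximation for
binned log-log regression. Exact power-law bins recover the exponent to
1e-6 regardless.

## 6. Article groups, affinity propagation, coverage

`retrieve_articles()` selects the articles whose streams contain at least
one member term of a cluster. Groups are clustered on their document
vectors with affinity propagation, pinned to explicit settings so results
reproduce anywhere: similarity = negative squared Euclidean distance,
shared preference = the median of the full similarity matrix (the zero
diagonal included — the convention of the reference library
implementations, and the one under which the two-blob fixtures converge),
damping 0.5, at most 200 iterations, convergence when the exemplar set is
stable for 15. A tiny fixed-seed jitter (1e-9 of the similarity range)
breaks the message-passing degeneracies that symmetric inputs otherwise
cause to oscillate; identical inputs still give identical outputs.
Coincident points short-circuit to a single cluster. Non-convergence
returns the last iteration's labels with a warning and a flag rather than
failing.

`multiround_cluster()` applies the same algorithm round over round; round
r > 1 clusters the *exemplar vectors* of round r−1. Exemplars rather than
means: they are affinity propagation's native representatives and actual
data points. Cluster counts are weakly decreasing by construction, and a
round collapsing to one cluster stops the recursion early with a note.

Coverage is definitional: an article covers a term cluster if it contains
at least one member term; a group's coverage of the cluster is the fraction
of its articles that cover it (a group in which 6 of 10 articles carry a
cluster-A term has coverage 60% over A). Coverage differences (subgroup
minus reference) highlight what a subgroup over-represents.
`profile_article_group()` ranks the top-k clusters by coverage — or by
coverage difference when a reference is supplied — excluding the retrieval
cluster by default (it trivially covers the whole group), and lists the
group's most-cited articles. Term hits are counted over the full
concatenated text (title, keywords, section titles, subtitles, body), the
same streams every other stage uses.

## 7. The synthetic corpus generator

`generate_corpus()` emits genuine JATS-like XML (exercised through the real
parser, not injected behind it) with planted structure:

* `n_keyword_groups × terms_per_group` keyword surfaces (a mix of single
  words and two-word phrases) and `n_method_groups × methods_per_group`
  method names, plus a ubiquitous "Statistical analysis" subtitle;
* per article: a topic group, 3–6 sampled keywords, a methods section with
  2–4 subtitles (titled "Methods" / "Materials and Methods" /
  "Experimental procedures" / "Methodology" to exercise the title rule),
  and 8–12 body sentences of 8–20 words mixing topic terms, group-specific
  or shared context words, and fillers;
* `group_separation` ∈ [0,1]: the probability that a body term or context
  word is drawn from the article's own group. At the reference value 0.9
  same-group terms co-occur strongly; at 0 the corpus has no recoverable
  structure;
* an affinity block: articles of one keyword group choose one method group
  with `multiplier`-fold odds (default 10), planting a co-occurrence
  hotspot;
* nested phrase pairs (default: "visual short-term memory" ⊃ "short-term
  memory") planted into a group, with guaranteed body sentences containing
  the longer phrase embedded and the shorter phrase alone, so
  longest-first recognition is exercised end to end;
* citations from a truncated discrete power law via inverse CDF (support
  0–10,000, default exponent 2), reproducing the heavy-tailed weighting of
  real citation data.

Reference conditions (the generator defaults, used by the acceptance
suite): 10 keyword groups × 8 terms, 5 method groups × 6 methods, 2,000
articles, separation 0.9, multiplier 10, exponent 2. The generator is fully
deterministic per seed and restores the caller's RNG state.

What it does *not* emulate: linguistic realism (sentences are bags of
units), citation network dynamics, abbreviations and synonym variation,
OCR/markup noise, or section-structure diversity beyond the titles above.
Passing the planted-recovery tests therefore shows the pipeline recovers
co-occurrence structure when present; it does not certify performance on
the messier term distributions of real corpora.

## 8. Pipeline, sizes and determinism

`run_pipeline()` executes corpus → lexicon → tokenize (count, filter,
re-tokenize) → embed → cluster → KOS template → correlate → power law →
article profiling, writing each stage's artifacts under `out_dir/<stage>/`
keyed by a hash of the stage parameters and upstream artifact hashes;
unchanged stages are skipped on re-runs, which is what makes the manual
annotation loop cheap. No artifact contains a timestamp, so identical
config + seed give identical manifests — verified by running the full
pipeline twice in the acceptance suite.

Problem sizes in the tests are deliberate choices: unit fixtures use 30–300
articles and 16–32 dimensions (enough for planted structure at separation
0.9, small enough for quick iteration); the planted-recovery acceptance
check runs the 2,000-article reference conditions at dimension 50 across
100 seeds; oracle checks use up to n = 50 items, where the naive O(n³)
recomputation is still fast.

## 9. Known limitations

* A binary tree cannot express poly-hierarchy: a term belongs to exactly
  one level-2 cluster, while real vocabularies (MeSH) place terms under
  several parents. The paraphyletic-union rule softens, but does not
  remove, this constraint.
* Level-2/level-3 quality is bounded by embedding quality; rare terms
  surviving the filters can still sit in odd branches, which is exactly
  what the branch-review workflow exists to catch.
* The power-law fit is a descriptive regression, not a hypothesis test; no
  likelihood-ratio comparison against alternative tails is attempted.
* Affinity propagation at damping 0.5 can oscillate on highly symmetric
  similarity structures (the reference implementations behave identically);
  the non-convergence flag is surfaced rather than hidden, and raising the
  damping is the standard remedy.
* Citation counts are an input table, frozen at whatever snapshot produced
  them; the package takes no position on citation-fetch timing.
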