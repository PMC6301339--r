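---
title: "Methods: triage, concept extraction and evaluation in annotriage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: triage, concept extraction and evaluation in annotriage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annotriage)
```

## The problem

Manual biocuration of gene-centric annotations — which papers to read
(*triage*) and which ontology concepts to record from them (*concept
extraction*) — is the bottleneck of curated protein databases. annotriage
implements a desk-scale assisted-curation pipeline for a query of the form
*(gene, annotation axis)*, where the axis is either Gene Ontology biological
process (`BP`) or a disease terminology (`D`):

1. **vocabulary** — load an OBO ontology or a TSV terminology into a
   `lexicon` with a normalized surface-form index;
2. **corpus** — read MEDLINE-style abstracts (JSONL or PubMed XML),
   tokenize with exact offsets, split sentences, accumulate corpus
   statistics;
3. **NER** — dictionary matching of concept and gene surface forms;
4. **triage** — rank candidate abstracts by a weighted combination of
   scores;
5. **annotation** — propose curation triplets *(subject protein, relation,
   concept object, evidence code)*, filter a blacklist, optionally re-rank
   by TF-IDF importance, and apply accept/modify/reject review semantics;
6. **evaluation** — triage agreement, class-level concept precision/recall,
   inter-annotator agreement, per-term rejection tables, precision-at-rank
   and relative gain.

A synthetic-data module generates every input the pipeline consumes, so the
whole system is testable offline and end to end.

## Text normalization and matching

All matching operates on one normalization contract: NFKC compatibility
normalization, case folding, and tokenization into maximal alphanumeric
runs with punctuation (including hyphens and en-dashes) as separators.
Token offsets always point into the *original* text, so matched surfaces
can be highlighted verbatim. This single contract is what makes
`"T-cell activation"`, `"T cell activation"` and `"Peutz–Jeghers"` vs
`"Peutz-Jeghers"` interchangeable at lookup time.

The matcher enumerates every token window up to the longest indexed surface
form and resolves overlaps **longest span first, then leftmost**. The
rationale is curational: longer surface forms are usually the more specific
ontology class, and curation guidelines prefer the child term over the
parent (so `"regulation of cell cycle"` must beat the nested
`"cell cycle"`). Ambiguous surface forms (one string, several concept ids)
yield one mention per id, flagged `ambiguous`; the package surfaces
ambiguity rather than resolving it, because dictionary NER has no reliable
local signal to disambiguate with. There is no stemming by default:
over-matching of morphologically promiscuous labels ("formation",
"growth") is a known precision drain, and stemming would only widen it.

Blacklisted concepts **are** extracted; the blacklist is applied when
candidates are proposed. This ordering is deliberate: evaluation needs to
count how often curators reject a vague term before one decides to
suppress it.

## The triage model

For a query gene $g$ and axis lexicon $L$, candidates are the documents
that mention $g$ (by symbol or synonym), pass the date window and the
pmid/keyword exclusions, and are not in the curation history for the same
query key (gene accession + axis; exclusion keywords deliberately do not
change the key). Each candidate $d$ receives three components:

* **BM25** over the gene's surface forms plus any boost keywords:
  $\sum_t \mathrm{idf}(t)\,\frac{f(t,d)\,(k_1+1)}{f(t,d)+k_1(1-b+b\,|d|/\mathrm{avgdl})}$
  with the +1-smoothed Robertson idf
  $\mathrm{idf}(t)=\ln\!\big(1+\frac{N-\mathrm{df}(t)+0.5}{\mathrm{df}(t)+0.5}\big)$,
  which stays non-negative even on single-document corpora. Defaults
  $k_1 = 1.2$, $b = 0.75$ are the standard Okapi settings.
* **Concept range**: the number of distinct axis concepts in $d$ divided
  by the maximum over the candidate set — a document rich in on-axis
  concepts is more curatable.
* **Concept TF-IDF**:
  $\sum_c \mathrm{tf}(c,d)\,\ln(N/\mathrm{df}_{\mathrm{concept}}(c))$ over
  the concepts of $d$.

BM25 and TF-IDF are min-max normalized to $[0,1]$ across the candidate set
(a constant component maps to 0); the range score is already in $[0,1]$ by
construction and is used as-is. The final score is the weighted sum. The
production weighting this design descends from was never published, so the
default is the neutral $w = (1/3, 1/3, 1/3)$, overridable per axis in the
run config. Min-max was chosen over z-scoring because the components live
on incomparable scales and candidate sets are small, where standard
deviations are unstable.

Ties are broken by year descending, then pmid descending. Score ties are
not hypothetical — equal-scored abstracts otherwise surface in
non-deterministic order and silently inflate annotation workloads — so the
ranking is made total on purpose.

## Annotation proposal and re-ranking

Candidates are one per distinct non-gene concept of a document with at
least one gene mention, initially in text order (the *linear view*), with
axis-default relation (`BP`: "is involved in"; `D`: "is associated with")
and evidence code `ECO:0000305`, both editable. The *ranked view* orders
candidates by

$$\mathrm{rank\_score}(c) = \mathrm{tf}(c)\cdot
  \ln\frac{N_{bg}+1}{\mathrm{df}_{bg}(c)+1},$$

where $\mathrm{tf}(c)$ counts retrieved documents mentioning $c$
(document counting, not mention counting: an important concept recurs
*across* the retrieved abstracts) and the background frequencies stand in
for a large MEDLINE sample, flooring vague everyday concepts at zero idf.
The +1 smoothing keeps unseen concepts rankable. The ranker is a plain
function of the candidate table, so a learned re-ranker can replace it
without touching the rest of the module.

Review semantics mirror curation practice: editing the relation or the
evidence code does not change the action; an unchanged concept is an
*accept*; a *modify* must stay within the same ontology branch as the
proposal, operationalized as sharing at least one non-root `is_a` ancestor
(each concept counting as its own ancestor); a *reject* leaves the proposal
in place with status `rejected`. Review never changes the candidate-set
size.

## Evaluation metrics

Every reported percentage uses **round-half-up to integer percent** — the
one convention that reproduces the bundled study tables exactly (e.g.
$699/3175 \to 22$, $2061/3175 \to 65$, $162/242 \to 67$).

* `triage_agreement()` — both-accept / both-reject / split counts and
  percentages over a shared pmid set; agreement is the identical-decision
  rate. The bundled disease-axis table carries an internal labelling
  inconsistency (its printed percentages do not match its own counts);
  this package always computes from counts and leaves such discrepancies
  visible rather than patching them.
* `concept_precision()` — (accepted + modified) / total proposals.
  Modifications count as credit: the system surfaced a usable concept.
* `concept_recall()` — gold units are **semantic classes per abstract**
  (manual groupings of near-equivalent concepts, supplied as an input
  file, never computed from the ontology: concepts describing one
  experiment can sit in entirely different branches, so hierarchy distance
  is the wrong equivalence). Recall pools class occurrences over abstracts
  (micro-average), under `both`- or `either`-curator gold.
* `iaa_concepts()` — per abstract, $|A \cap B| / |A \cup B|$ on classes;
  reports the mean and the share of abstracts with at least one common
  class.
* `precision_at_rank()` — P0 is precision at the first rank; P@k keeps the
  fixed denominator $k$ even when fewer proposals exist (TREC convention).
* `relative_gain()` — signed integer percent change over a baseline.
* `term_rejection_table()` — per-concept review outcomes, sorted by
  rejections, thresholded at a minimum proposal count (default 30), with
  always-rejected concepts flagged as blacklist material.

## The synthetic study generator

`synth_config()` fixes the emulated study conditions; all generators are
byte-deterministic under the seed.

* **Ontologies** (`make_mini_ontology()`): a rooted `is_a` tree per axis
  (default 40 concepts) with multi-word labels, hyphen-variant and
  reversed-form synonyms, one deliberately ambiguous shared synonym, and a
  handful of single-word *vague* concepts ("signaling", "tumor", …)
  destined for the blacklist. The disease terminology includes an en-dash
  label with a plain-hyphen synonym.
* **Corpora** (`make_corpus()`): default 20 relevant + 80 decoy abstracts,
  the scale of one per-gene triage batch. Relevant documents embed the
  gene symbol and $1 + \mathrm{Pois}(2)$ planted concept surfaces (a
  synonym with probability 0.3); concept choice is Zipf over the
  vocabulary (exponent 1.1), matching the heavy reuse of a few concepts
  seen in real proposal streams. Decoys embed filler only or the gene
  alone, half each, so the triage test includes gene-mentioning
  distractors. Filler words are drawn from a fixed pool disjoint from all
  concept-label vocabulary, so decoy text never matches a surface form by
  accident.
* **Curators** (`simulate_curators()`): a shared latent accept decision
  (a truly relevant document enters it with probability 0.9) flipped
  independently per curator with probability $e = (1-\sqrt{2a-1})/2$, so
  expected agreement is exactly $a$ (default 0.8, the observed
  inter-curator regime); accepted documents' gold concepts are each
  reported with probability 0.8. The class map gives gold concepts their
  own classes, with 20% of adjacent pairs merged to exercise class-level
  equivalence.
* **Background frequencies** (`make_background_df()`): vague concepts get
  df equal to the background size (zero idf), specific concepts small df,
  so the re-ranker provably demotes vagueness.

What the generator does **not** emulate: natural-language discourse
(filler is a word salad — sufficient for a dictionary matcher, useless for
learned NER), abstract section structure, genuine synonym ambiguity rates,
or realistic score ties. Passing tests therefore certify the mechanics of
matching, ranking and scoring, not extraction quality on real prose.

## Problem sizes and numerical choices

The test and acceptance runs use: brute-force BM25 equivalence on all
random corpora up to 4 documents × 6 tokens (30 cases); matcher-oracle
equivalence on random texts up to 20 tokens with up to 10 lexicon entries
(30 cases); planted-relevance recovery on the default 20 + 80 corpus;
agreement recovery at 2 000 abstracts (binomial standard error ≈ 0.9
points, comfortably inside the ±3-point check); Zipf rank verification on
1 000 documents. These sizes keep the full suite under a minute while
leaving each statistical check several standard errors of headroom.

Degenerate inputs are defined, not special-cased: empty queries score 0
with a warning; a constant score component normalizes to 0; an empty
candidate set is an empty ranking, not an error; abstracts where neither
curator found a concept are excluded from IAA with a warning; a concept
missing from corpus statistics is a hard error (stale stats), while one
missing from *background* statistics gets df = 0 and a warning (unseen in
background is expected, unseen in your own corpus is a bug).

## Limitations

The scorers are in-memory and desk-scale by design — no inverted index, no
MEDLINE-scale engineering. Gene mentions are matched, not normalized:
an ambiguous symbol is reported as-is. Recall against real curator data
depends on per-abstract judgment files that must be supplied; the package
ships only printed aggregate counts and synthetic equivalents. Obsolete
ontology terms resolve in gold files but never match text. Only
title/abstract sectioning is implemented; finer abstract structure is a
human-guideline matter, not automated here.
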