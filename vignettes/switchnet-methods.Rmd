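---
title: "Methods: semantic networks of bilingual code-switching speech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semantic networks of bilingual code-switching speech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(switchnet)
```

## The scientific problem

Bilingual speakers alternate between their two languages in spontaneous
conversation (code-switching, CS). `switchnet` treats the bilingual lexicon
as a weighted semantic network and asks two questions about CS speech:

1. **Representation.** Do the two languages occupy largely separate
   communities of the semantic network built from CS speech?
2. **Accessibility.** Are the words a speaker switches *into* less densely
   embedded in their semantic neighbourhood — lower weighted clustering
   coefficient — and more frequent than the translation equivalents (TEs)
   they replace?

The package implements the full pipeline: corpus I/O and preprocessing,
sentence-level CS typing, skip-gram embeddings, cosine-weighted semantic
networks, Louvain community detection with weighted modularity, the
geometric-mean weighted clustering coefficient, and the statistical battery
(z-scoring, residualization, split-plot ANOVA, paired t, sign tests,
Pearson correlation, logistic regression with Cox–Snell R²). Because the
speech corpora this kind of analysis is usually run on are licensed, the
package ships a synthetic bilingual-corpus generator with planted ground
truth, so every stage is testable offline.

## Sentence typing

Utterances are classified with a conservative rule that only consults
tokens with *unambiguous* language identity:

* **intra-sentential CS** — the utterance contains unambiguous words of
  both languages;
* **inter-sentential CS** — otherwise, it contains unambiguous words in a
  language not present among the preceding utterance's unambiguous words
  (the first utterance can never be inter-sentential);
* **non-CS** — everything else.

Two boundary conventions are worth stating because they are easy to get
wrong. First, an utterance following an intra-sentential utterance can
never be inter-sentential: the predecessor already contains both
languages, so nothing is "new". Second, an utterance with no unambiguous
tokens is non-CS and passes an empty language set to its successor, which
therefore counts as inter-sentential if it has any unambiguous content.
Utterance order is corpus line order, regardless of speaker; transcripts
do not reliably mark turn boundaries, and the classification rule only
needs the immediately preceding sentence.

A **CS word** is a word whose language differs from that of the
immediately preceding word in the same utterance; both words must be
unambiguous. Ambiguous tokens never transmit language context: in the tag
sequence (B, ambiguous, A) there is no switch event.

## Networks and the clustering coefficient

Word vectors come from skip-gram training with negative sampling (the
word2vec objective) on the corpus token stream, or from pretrained vectors
in the common one-word-per-line text format. Defaults follow common
practice: dimensionality 300 and window 5 (the two values standardly
reported), five epochs, five negative samples, initial learning rate 0.025
with linear decay, no frequency subsampling, and `min_count = 1` so that
networks can cover every word type of the selected sentences. Training is
single-threaded with a dedicated PRNG, so a seed fully determines the
vectors. The trainer is implemented in C++ (via Rcpp); no R-native
word2vec implementation was available in the package's dependency set.

Edges connect word pairs with strictly positive cosine similarity, with
the cosine as weight. Negative cosines denote dissimilarity and are
non-edges; a cosine of exactly zero carries no similarity signal and is
excluded as well (the boundary case is stated explicitly because the
exclusion rule is usually phrased only for negative values). Pairwise
cosines are computed blockwise so memory scales with one block of the
similarity matrix, not its square.

The weighted clustering coefficient of node $u$ is the normalised sum of
geometric means of triangle edge weights:

$$C_u = \frac{2}{\deg(u)\,(\deg(u)-1)}
  \sum_{\{v,w\}} \left(\hat W_{uv}\,\hat W_{uw}\,\hat W_{vw}\right)^{1/3},
  \qquad \hat W = W / \max(w),$$

where the sum runs over unordered pairs of neighbours of $u$ and pairs
without a connecting edge contribute zero. Conventions: $\deg(u)$ counts
retained (positive) edges only; nodes of degree $<2$ have $C_u = 0$ (the
formula's divergence guard); normalisation by the network-wide maximum
weight makes $C_u$ invariant under uniform rescaling of all weights. With
all weights equal the measure reduces to the unweighted closed-triple
fraction. The implementation is validated against a brute-force triple
enumeration to $10^{-12}$ on random graphs.

## Communities and modularity

Weighted Newman–Girvan modularity

$$Q = \frac{1}{2m}\sum_{u,v}\left[W_{uv} -
  \frac{s_u s_v}{2m}\right]\delta(c_u, c_v)$$

is optimised with the Louvain algorithm, reimplemented here rather than
delegated so that (a) runs are deterministic given a seed, (b) the per-phase
modularity trace is exposed (it must be non-decreasing), and (c) the
reported $Q$ is recomputed from scratch from the final assignment. The
igraph implementations serve as independent cross-checks in the test
suite. Numerical choices: node visit order is a seeded shuffle drawn once
per phase; a move requires a gain above $10^{-12}$ (ties keep the current
community, which stabilises runs); phases stop when a full phase improves
$Q$ by less than $10^{-7}$; community labels are relabelled by size,
largest first, for stable reporting. All communities found are reported;
none are merged. On graphs small enough for exhaustive search the greedy
optimum matches the true optimum in well over 90% of seeded instances,
which is the documented expectation for a greedy optimiser.

For study-1-style reports, network nodes are unique word *forms* tagged
with their modal language tag across the corpus (ties resolve to
ambiguous, reported as "other"). Tagging forms rather than (form, tag)
occurrences avoids duplicate nodes that would share identical vectors and
trivially co-cluster.

## The paired CS/TE analysis

For each switch direction (e.g. A→B: CS word in A replacing a TE in B),
unique CS words are paired with single-word translation equivalents from a
static translation map; words with multiword translations are excluded, as
are pairs missing from the frequency norms or the vector vocabulary, with
every exclusion counted. One semantic network per language is built over
that language's retained CS words and TEs (pooling both directions
maximises network context). Then:

* clustering coefficients are z-scored within language (reference
  distribution: all nodes of that language's network), making the two
  languages' distributions comparable;
* frequencies are per-million norms, log10-transformed;
* each measure is residualized against the other by OLS, pooling the CS
  and TE values of both directions (a single pooled regression per
  bilingual group, matching the single correlation coefficient such
  analyses report); per-direction residualization is a trivial variant but
  is not the default.

The statistical battery: a split-plot ANOVA with switching (CS vs TE) as
the within-item factor and direction as the between-item factor (classical
split-plot decomposition; with group sizes $n_1, n_2$ the interaction has
$(1, n_1+n_2-2)$ df, and the interaction F equals the squared pooled
two-sample t on per-item differences — an identity the tests verify);
per-direction paired t tests with Cohen's $d$; and per-direction sign
tests. The sign test is the two-cell goodness-of-fit chi-square without
continuity correction, $\chi^2 = (a-b)^2/(a+b)$ on 1 df, where $a$ and $b$
count pairs with lower and higher CS values; this form exactly reproduces
all eight published statistics from their published counts, which is its
verification. Ties are excluded before the test. Sample standard
deviations (ddof 1) are used throughout, consistent with the df
conventions above. No multiple-comparison correction is applied, matching
the analysis plan this battery mirrors.

The cognateness analysis assigns every produced word to the CS class if it
was *ever* used as a CS word, pairs it with its TE, measures orthographic
similarity, and fits a logistic regression of class on similarity,
reporting the slope $B$, Wald $= (B/\mathrm{SE})^2$, and Cox–Snell
$R^2 = 1 - (L_0/L_1)^{2/n}$ (Nagelkerke's rescaling is also returned; the
Cox–Snell form is the primary output). The default similarity is
normalised Levenshtein, $1 - d/\max(|w_1|,|w_2|)$: the measure used in the
psycholinguistic databases this proxies is not publicly specified, so the
similarity function is a plug point and results from the default should be
read as coming from a stand-in measure. Perfect separation is flagged as
non-convergence rather than silently returning a divergent slope.

## The synthetic generator

`generate_corpus()` emulates the statistical structure the pipeline
assumes in real CS speech, with planted ground truth:

* **Concepts and topics.** `n_concepts` translation pairs get Zipfian
  frequencies (`zipf_exponent`, default 1 — the classical value for word
  frequency distributions) and are assigned round-robin by rank to
  `n_topics` topics, so every topic mixes frequent and rare words. Each
  topic has a dominant language (topics alternate), which is what induces
  language-dominant semantic neighbourhoods; utterances keep their topic
  with probability `p_topic_stay` (0.7 — conversations stay on topic).
* **Language chain.** The produced language is a persistent first-order
  chain across the conversation. From the topic-dominant language, the
  per-token switch probability is
  $\mathrm{logit}^{-1}\!\big(\mathrm{logit}(1-p_{stay}) + \beta_C z_C +
  \beta_F z_F\big)$, where $z_C$ is the *target form's* standardized
  contextual-concentration proxy and $z_F$ its standardized log frequency
  norm. From the non-dominant language, the return probability adds an
  attraction term on the logit scale (3 for switch-prone words, 7
  otherwise), so switch bursts are short and the chain freezes entirely
  when `p_stay = 1` (the attraction scales with the base mobility, so a
  frozen chain stays monolingual, in its initial language A).
* **A switch-prone lexicon.** Only a `switchable_fraction` (default 0.06)
  of concepts can be produced in their non-dominant language, reflecting
  the concentration of insertional CS on a restricted content-word
  lexicon (function words famously resist switching). This is also what
  keeps the language communities of the resulting semantic network highly
  pure: guest words are a small minority of any topic neighbourhood.
* **Planted clustering proxy.** Each *form* (concept × language) has a
  dispersion in `[0, dispersion_max]`; a `p_dispersed` share of tokens is
  drawn from a dispersion-weighted pool of the current language instead of
  the utterance topic. High-dispersion forms are scattered across
  unrelated contexts, acquire centroid-like vectors with diffuse
  neighbourhoods, and end up with *lower* clustering coefficients — the
  classic contextual-diversity effect. The proxy is planted per form, not
  per concept, deliberately: a concept-level proxy would be shared by a CS
  word and its TE and cancel from the paired comparison.
* **Frequency norms.** Per-language per-million tables perturb the shared
  Zipfian core with log-normal noise (sd 0.5), emulating cross-language
  norm differences; the tables are idealised subtitle-style norms, not
  realized corpus counts.
* **Presets.** `seame_like_config()` (script-separable languages, no
  ambiguous tokens, heavy switching) and `miami_like_config()` (both
  Latin-script, 5% ambiguous tokens, light switching) echo the contrast
  between heavily and lightly switching speech communities in order of
  magnitude only. Defaults produce ≈52k tokens (6,500 utterances, mean
  length 8), sized so the full pipeline runs in about a minute on one CPU.

What the generator does *not* model: syntax, morphology, matrix-language
constraints, speaker variation, or any naturalness of word forms (forms
are random Latin strings or Han-character compounds). Passing tests on
synthetic corpora therefore validate the *pipeline machinery and its
statistical behaviour*, not claims about real speech.

### What the planted-effect recovery does and does not show

With $\beta_C < 0$, switching preferentially targets high-dispersion
(low-clustering) forms, and the end-to-end pipeline recovers a negative
mean CS−TE difference in residualized standardized clustering. Two
mechanisms contribute to that sign: the planted dispersion selection, and
an emergent one — inserted guest words occur in fewer, poorer contexts, so
their vectors are less embedded and their clustering lower regardless of
the plant. Both push the same way (both are forms of the accessibility
asymmetry the analysis is designed to detect), but because of the second
mechanism the end-to-end sign alone does not isolate the plant. The test
that isolates it compares the planted dispersion of realized CS words
under $\beta_C = -2$ versus $\beta_C = +2$ on the gold record: the
contrast must flip with the sign of $\beta_C$, and does. The planted
frequency effect ($\beta_F$) is weak at this corpus scale — selection on
the frequency covariate is dominated by the shared Zipf core rather than
the cross-language noise component — so it is documented here but not
asserted as an end-to-end recovery.

## Numerical and validation choices

* Sizes used by the validation suite: clustering is checked against brute
  force on 50 random graphs of up to 30 nodes; Louvain against exhaustive
  partition search on 50 graphs of up to 8 nodes; the type-I error of the
  paired t over 2,000 null simulations of 25 pairs (expected rejection
  0.05 ± sampling noise); the end-to-end run uses the ≈52k-token preset
  with 50-dimensional vectors. These sizes were chosen to make the full
  suite run in a few minutes while keeping each check statistically
  meaningful.
* `zscore` and `residualize` reject constant input rather than returning
  NaNs; degenerate directions (fewer than 2 retained pairs) are dropped
  with a warning rather than failing the whole report.
* Utterance indices and community labels are 1-based and contiguous, the R
  convention.
* Preprocessing strips leading/trailing Unicode punctuation from forms
  (so "job?" and "job" are one type) and then re-applies the
  marker/communicator filters; how the original transcription pipelines
  tokenized attached punctuation is not documented, so this choice is
  stated rather than inherited.

## Known limitations

* The skip-gram trainer is plain word2vec; subword (character n-gram)
  vectors are intentionally out of scope — the pretrained-vector reader
  covers analyses that need them — so sublexical similarity effects between
  same-script languages are not reproduced when training in-package.
* Louvain is a greedy optimiser; on adversarial small graphs it can miss
  the modularity optimum (observed in well under 10% of random instances).
* The orthographic-similarity default is a stand-in (normalised
  Levenshtein), pluggable for any better-validated cognateness measure.
* Split-plot ANOVA uses the classical sequential decomposition; with
  unbalanced groups, other sums-of-squares conventions would give slightly
  different main-effect F values (the interaction, fitted last, is
  unaffected).
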