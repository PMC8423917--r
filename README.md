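# switchnet

Network-science tools for bilingual **code-switching (CS) speech** — the
alternation between two languages within a conversation or a single
sentence. `switchnet` is aimed at psycholinguists and cognitive network
scientists who want to treat the bilingual lexicon as a weighted semantic
network and ask (1) whether the two languages occupy separate network
*communities*, and (2) whether the words speakers switch *into* are less
densely embedded among their semantic neighbours — and more frequent — than
the translation equivalents (TEs) they replace.

## What it computes

Given a corpus of utterances whose tokens carry language tags (or whose
languages are separable by script, as with Mandarin vs. English), the
package:

* classifies every sentence as **non-CS**, **intra-sentential CS** (both
  languages inside the sentence) or **inter-sentential CS** (a monolingual
  sentence in a different language than its predecessor), using only
  unambiguously tagged words;
* trains skip-gram word vectors (word2vec-style negative sampling,
  seeded/deterministic, implemented in C++) or loads pretrained vectors,
  and builds a **weighted semantic network**: nodes are word types, edges
  connect pairs with positive cosine similarity, weighted by that cosine;
* detects language communities by **Louvain** optimisation of weighted
  modularity

  $$Q = \frac{1}{2m}\sum_{u,v}\Big[W_{uv} - \frac{s_u s_v}{2m}\Big]\,
  \delta(c_u, c_v),$$

  and reports each community's language composition;
* computes the **geometric-mean weighted clustering coefficient**

  $$C_u = \frac{2}{\deg(u)(\deg(u)-1)}\sum_{\{v,w\}}
  \big(\hat W_{uv}\hat W_{uw}\hat W_{vw}\big)^{1/3},
  \qquad \hat W = W/\max(w);$$

* pairs every unique **CS word** (a word in a different language than the
  word before it) with its single-word TE, z-scores clustering within
  language, log-transforms per-million frequency norms, residualizes each
  measure against the other, and runs the full battery: split-plot
  (mixed-design) ANOVA, per-direction paired *t* with Cohen's *d*, and the
  sign test $\chi^2 = (a-b)^2/(a+b)$;
* fits a logistic regression of "was this word ever switched?" on
  orthographic similarity to its TE (cognateness), with Wald statistic and
  Cox–Snell $R^2$;
* **generates synthetic bilingual corpora** with planted ground truth
  (Zipfian frequencies, language-dominant topics, a switch-prone lexicon,
  planted contextual-diversity and frequency effects on switching), so the
  entire pipeline can be exercised and validated without licensed corpora.

See `vignettes/switchnet-methods.Rmd` for the model, conventions, and the
design rationale behind the generator.

## Worked example

Generate a heavy-switching synthetic corpus (two script-separable
languages, ≈52k tokens), train 50-dimensional vectors, and run the two
studies:

```r
library(switchnet)
gen <- generate_corpus(seame_like_config(seed = 1))
gen$corpus
#> <cs_corpus> mandarin/english: 6500 utterances, 51901 tokens
#>   (mandarin: 26240, english: 25661, ambiguous: 0)

types <- classify_cs_types(gen$corpus)
count_cs_types(types, gen$corpus)[, 1:3]
#>            cs_type n_sentences pct_sentences
#> 1           non_cs        4886     75.169231
#> 2 intra_sentential        1058     16.276923
#> 3 inter_sentential         556      8.553846

emb <- train_sgns(gen$corpus, embedding_config(dim = 50, seed = 1))
s1 <- run_study1(gen$corpus, embeddings = emb, seed = 1)
s1
#> <study1_report> filter = all, 449 nodes, 2 communities, Q = 0.207
#>  community   n pct_english pct_mandarin
#>          1 226    5.309735    94.690265
#>          2 223   96.860987    3.139013

s2 <- run_study2(gen$corpus, gen$translations, gen$freq_a, gen$freq_b,
                 emb, emb)
s2
#> <study2_report>
#>   filter counts: events=1939, unique_pairs=225, with_frequency=225, with_vectors=42
#>   clustering ~ frequency pooled r = -0.082 (p = 0.459)
#>   mean CS-TE difference: Res C_Z = -0.3801, Res LogF = -0.0140
```

Reading the output: the semantic network of the mixed corpus splits into
two communities, each dominated (≈95%+) by one language — the two lexicons
are largely separate, with a small overlap of "guest" words. In the paired
analysis, code-switched words have *lower* residualized standardized
clustering coefficients than their translation equivalents (mean
difference −0.38): switching targets words that stick out of sparse
semantic neighbourhoods, the planted accessibility effect of this
generator configuration (`beta_C = -0.8`).

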