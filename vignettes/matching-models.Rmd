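---
title: "Matching consumer health questions to education materials: models and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matching consumer health questions to education materials: models and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edurec)
```

## The problem

Patients ask questions in online health forums in everyday language;
expert-vetted patient education materials answer many of those questions but
are written in clinical register. Pointing a question at the right material
is an information-retrieval task with a twist: the query corpus and the
document collection share topics but only partially share vocabulary, so
plain lexical matching underperforms. `edurec` implements and compares three
matching models over a question corpus and a material corpus:

* **VSM** — the term-matching baseline. Documents and queries are TF-IDF
  vectors; relevance is cosine similarity.
* **TMB** (topic modeling-based) — a latent Dirichlet allocation model is
  fitted to the materials; each question is decomposed into expected
  per-topic token counts and compared with each material's topic mixture.
* **SGB** (semantic group-based) — a concept lexicon maps token spans to
  clinical concepts carrying one of ten coarse semantic groups (anatomy,
  chemicals & drugs, devices, disorders, genes, living beings, objects,
  phenomena, physiology, procedures); each group is treated as a "topic" and
  questions and materials are compared by their idf-weighted group
  frequency vectors.

Because realistic corpora of this kind (hospital education databases, forum
scrapes, expert relevance judgments, licensed terminologies) are generally
private, every component here is validated against synthetic corpora with
known ground truth, generated by the package itself.

## The topic model

`fit_lda()` is a collapsed Gibbs sampler written from scratch (inner loops
in C++). With $K$ topics, vocabulary size $V$, symmetric priors $\alpha$
(document–topic) and $\beta$ (topic–word), a token $w$ in document $d$ is
reassigned each sweep with probability

$$P(z = t \mid \cdot) \propto (n_{dt} + \alpha)\,
  \frac{n_{tw} + \beta}{n_t + V\beta},$$

where all counts exclude the token being updated. Point estimates are read
off the final sweep:
$\hat\phi_{tw} = (n_{tw}+\beta)/(n_t+V\beta)$ and
$\hat\theta_{dt} = (n_{dt}+\alpha)/(n_d+K\alpha)$.
Sweeps visit documents in index order and tokens left to right, and all
randomness flows through R's RNG, so a seed makes a fit bit-reproducible.

Defaults are $\alpha = 50/K$, $\beta = 0.1$ and 1000 sweeps — the
long-standing collapsed-Gibbs conventions — with $K = 20$ a sensible
starting point for an education-material collection of a few hundred
documents. None of these are estimated from data; all are exposed as
arguments. Model selection for $K$ is out of scope.

Unseen questions never refit the model. `fold_in()` Gibbs-samples only the
query's token assignments while the trained topic–word counts stay frozen,
and returns $(n_{qt}+\alpha)/(n_q+K\alpha)$ averaged over the final quarter
of sweeps. Out-of-vocabulary tokens are dropped and counted; a fully
out-of-vocabulary query returns the uniform prior. Note that for a short
query the $\alpha$ term dominates the posterior: with the default
$\alpha = 50/K$ a 20-token query can never concentrate above
$(20+\alpha)/(20+K\alpha) \approx 0.5$, which is the intended smoothing
behaviour for mixture estimation. Diagnostics that need a sharp assignment
(for example the block-corpus checks below) therefore fit with a small
$\alpha$ such as 0.1.

## The three scorers

**VSM.** `build_vsm_index()` uses raw term counts and the smoothed idf
$\ln\big((1+N)/(1+df)\big)+1$, with document vectors L2-normalized — the
widely used TF-IDF dialect, fixed bit-exactly so that the test suite can
compare against an independent dense implementation at $10^{-9}$.

**TMB.** `query_topic_frequency()` computes, for each in-vocabulary query
token, the posterior topic probability under a uniform topic prior,
$P(t \mid w) = \phi_{tw}/\sum_{t'}\phi_{t'w}$, and sums over tokens. The
entry for topic $t$ is then the *expected number of query tokens
attributable to topic $t$*: a "topic frequency" that is naturally
non-integer and sums to the in-vocabulary query length. `score_tmb()` ranks
materials by cosine similarity between the normalized profile and each
material's $\hat\theta$ row. An alternative reading — scoring by the query's
likelihood under each document's topic mixture — is deliberately not the
default: mixture-vs-mixture cosine treats short and long queries uniformly
and matches how the profile is used in the network analysis.

**SGB.** `annotate()` is a deterministic dictionary mapper: a greedy
left-to-right longest-match scan (terms up to 5 tokens) with no overlap and
no disambiguation. It deliberately trades the recall of a full
concept-mapping engine for determinism and testability; fidelity to any
particular engine is a non-goal. `group_profile()` weights each annotation
by the idf of its concept over the material collection — raw counts would
let ubiquitous concepts dominate, and idf is the minimal standard
correction consistent with the non-integer group frequencies the model is
meant to produce. `score_sgb()` is cosine over the ten-dimensional group
vectors.

All three scorers break ties by ascending document id, so rankings are
total orders and repeated runs are identical.

## Evaluation protocol

Relevance is graded 0/1/2 (none / partial / most). `precision_at_k()`
implements

$$P(k) = \frac{\text{number of relevant documents in the top } k}{k},$$

with a partially relevant document counted as 0.5 and unjudged pairs as 0.
When a ranking is shorter than $k$, $k$ is capped at the list length rather
than erroring, so a fixed $k$ grid can be applied to a small collection.
Inter-annotator agreement uses weighted Cohen kappa,
$\kappa = 1 - \sum w_{ij}O_{ij} / \sum w_{ij}E_{ij}$, defaulting to linear
disagreement weights ($w_{ij}=|i-j|/2$ for three grades); the quadratic
variant is available and every `AgreementResult` records which was used.
Two identical constant gradings are defined as $\kappa = 1$. Gold standards
are built by `consensus()`: agreements stand, and every disagreement must be
explicitly adjudicated or construction fails loudly.

## What the synthetic generators emulate

`generate_paired_corpora()` produces the two-corpus structure the models
are designed for: $K$ shared latent topics; per topic, a block of material
terms and a block of question terms sharing a fraction $\rho$ of them
(the vocabulary-gap dial); question lengths truncated-normal with mean 110
(SD 36, floor 10) and material lengths mean 968 (SD 115, floor 100) —
the characteristic shape of a short-question / long-document pairing.
Document mixtures use Dirichlet(0.3) (documents are mostly about one or two
topics, as in real collections) and within-block word distributions use
Dirichlet(0.2) (heavy-tailed word usage, so individual documents express a
topic through different term subsets). These two concentrations and the
block size of 30 terms per topic per side were chosen once as realistic
text-like values and are exposed as arguments.

`generate_lexicon()` samples vocabulary terms (seeded random order) until
the expected fraction of tokens covered reaches per-corpus targets, by
default 93.31% for materials and 91.18% for questions — a small but, at
corpus scale, highly significant difference in concept coverage between
registers. Selection overshoots targets slightly (terms arrive whole, and
terms added for one corpus also cover tokens in the other); the achieved
coverages are recorded on the lexicon. Semantic groups are drawn from
per-corpus mixes so the two corpora have distinguishable group
distributions.

`generate_gold()` plants graded relevance through latent-topic overlap:
grade 2 when question and material share a dominant topic, grade 1 when the
material's dominant topic carries intermediate question weight (the
0.2–0.5 window is arbitrary but fixed and configurable), otherwise 0.

What these generators do *not* emulate: real word-frequency laws across
topics, multi-word clinical terminology (generated lexicon entries are
single tokens, though the mapper and its tests cover multi-token terms),
polysemy, misspellings, and any correlation between semantic groups and
latent topics. The last point matters for interpretation: in the synthetic
benchmark the SGB model's group labels are only corpus-level skewed, not
topic-linked, so SGB is structurally handicapped there relative to a real
terminology — its absolute precision on synthetic data says little about
its behaviour on real corpora, and the package's claims about SGB are
limited to contract-level properties (it is a proper cosine ranker that
recovers group-planted relevance).

## The vocabulary-gap experiment

The central scientific property the test suite replicates is that topic
matching mitigates a vocabulary gap. With $K = 5$ shared topics, overlap
$\rho = 0.3$, 200 questions and 40 materials, and the planted gold above,
the suite compares mean P@1 of TMB and VSM over 20 replicate seeds: TMB
must beat VSM by a one-sided sign test at the 5% level (evaluation uses
every generated question; at $\rho = 0$ VSM collapses to zero by
construction, at $\rho = 1$ the gap disappears — 0.3 probes the middle).
The mechanism is visible in the scorers themselves: VSM needs the exact
shared terms of a specific material to co-occur in the question, while TMB
only needs the question's shared tokens to identify the topic, after which
the material's full length-968 evidence determines its mixture.

## Numerical and degenerate-input choices

* Chi-square tests use the Pearson statistic with expected counts from the
  marginals, no continuity correction, and the exact upper-tail p-value;
  zero marginal rows or columns are hard errors.
* Sample standard deviations use the $n-1$ denominator throughout.
* `group_distribution()` of an empty annotation set returns all-`NA`
  proportions flagged with an `empty` attribute rather than dividing by
  zero.
* All-out-of-vocabulary queries: VSM and both profile scorers return
  all-zero scores in document-id order; `fold_in()` returns the uniform
  prior.
* Bipartite network edges require frequency **strictly** greater than the
  cutoff (default 1); equality is excluded, and the same rule at cutoff 0
  keeps zero-frequency pairs out.
* Ties anywhere (ranking scores, topic argmax, top-word weights) break
  deterministically: ascending id, lowest index, alphabetical.
* Topic matching in recovery tests aligns estimated to true topics by
  exhaustive permutation search for $K \le 8$ (greedy beyond), minimizing
  mean total-variation distance.

## Problem sizes used in the validation suite

Unit and property tests run on corpora of tens of documents. The deeper
checks use: topic recovery on $K=3$, $V=30$, $D=200$, mean length 50
(about 10,000 tokens, where matched total-variation distance below 0.15 and
dominant-topic accuracy above 0.9 are comfortably attainable by a correct
sampler in 300 sweeps); the vocabulary-gap experiment at the scale above;
and mapping-rate significance on paired corpora of roughly 50,000 tokens
per side, where a two-point coverage difference is detectable at
$p < 10^{-3}$ by construction. These sizes were chosen as the smallest at
which each scientific claim is stable across seeds.

## Known limitations

* The dictionary mapper has no word-sense disambiguation and no term
  variant generation; mapping rates on real text would differ from a full
  concept-mapping engine's.
* $\hat\phi$/$\hat\theta$ come from a single final Gibbs sample (fold-in
  averages, training does not); posterior averaging across sweeps would
  reduce variance at the cost of label-switching bookkeeping.
* The SGB caveat above: synthetic benchmarks under-sell SGB by design.
* Score fusion across models, query expansion and learning-to-rank are out
  of scope.
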