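---
title: "Redundancy-aware topic modeling of clustered clinical notes"
author: "rednotes package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Redundancy-aware topic modeling of clustered clinical notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rednotes)
```

## The problem

Clinical notes in a patient record are written incrementally: clinicians
routinely copy sections of an earlier note and paste them into a new one.
A corpus of such records therefore contains large amounts of verbatim
within-record duplication. Latent Dirichlet allocation (LDA) assumes every
token is an independent draw from its document's topic mixture; pasted text
violates that assumption twice over. First, the copied occurrences of a word
should share the topic of the original occurrence, but a standard sampler is
free to scatter them across topics. Second, every duplicate inflates the
word's count in whatever topic it lands in, so words that happen to sit in
frequently pasted passages acquire topic weight that reflects documentation
habits, not topical relevance.

This package implements four strategies for topic modeling such corpora,
all sharing one fitting interface, `redlda()`:

* **vanilla** — ordinary collapsed Gibbs LDA over all notes;
* **deletedoc** — reduce each record to its single source note, then vanilla
  LDA;
* **deleteword** — delete the copied tokens from non-source notes, then
  vanilla LDA;
* **redlda** — the redundancy-aware sampler described next, which discards
  nothing.

## The redundancy-aware model

Each record (cluster) designates one **source note** — here, the longest
note, ties to the earliest note id — and a preprocessing step flags which
tokens of the other notes were copied from it. During collapsed Gibbs
sampling, a non-copied token in document $d$ with word $w$ is resampled from
the standard conditional

$$p(z = k) \propto (n_{dk} + \alpha)\,\frac{n_{kw} + \beta}{n_k + V\beta},$$

where $n_{kw}$ and $n_k$ count **only non-copied tokens**. A copied token
whose word $w$ occurs in its record's source note instead draws its topic
from the source note's current assignments of that word,

$$p(z = k) \propto n_{src}(w, k) + \delta,$$

with $n_{src}(w,k)$ the number of occurrences of $w$ currently assigned
topic $k$ in the source note and $\delta \in (0,1)$ a smoothing constant. A
copied token whose word does not occur in the source note (a detector
artifact) falls back to the standard conditional over the
redundancy-excluded counts. Copied tokens never contribute to $n_{kw}$ or
$n_k$, so the topic-word distribution $\phi$ is estimated without duplicated
text; they do contribute to their own note's $n_{dk}$, because in the
generative story even a copied word's topic is a draw from the document's
mixture (constrained to topics the source gave that word). Records are swept
in corpus order with the source note first, so copied tokens always
condition on fresh source assignments; with no flagged tokens the sampler
reduces *bit-exactly* to vanilla LDA under the same seed, which the test
suite asserts.

Point estimates use the final state of a single chain:
$\phi_{kw} = (n_{kw}+\beta)/(n_k+V\beta)$ and
$\theta_{dk} = (n_{dk}+\alpha)/(N_d+K\alpha)$.

### Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `K` | 50 | topics |
| `alpha` | `50/K` | symmetric Dirichlet on document mixtures |
| `beta` | 0.01 | symmetric Dirichlet on topic-word distributions |
| `delta` | 0.5 | smoothing of the copied-word source conditional |
| `iterations` | 2000 | Gibbs sweeps (single chain, last sample) |

`alpha`, `beta` and `delta` follow common collapsed-Gibbs practice; `delta`
trades off how strongly a copied token is tied to its source occurrences
(small `delta` = tight coupling). Smaller experiments in this vignette and
in the tests use `K = 5`, `alpha = 1`, `beta = 0.1` and a few hundred
sweeps, which mix well at that scale.

## Copy detection

`annotate_redundancy()` reconstructs the per-token copy flags the sampler
needs. For each record it indexes all token k-grams of the source note
(default `k = 8`), fingerprints each other note by winnowing (keep the
minimum k-gram hash per sliding window of `window = 4`), verifies every
fingerprint match token-by-token, extends it to a maximal exact run, and
keeps runs of at least `min_span = 10` tokens. Overlaps are resolved
greedily: longer runs first, then leftmost in the copy, then leftmost in
the source. Any shared run of at least `k + window - 1` tokens is
guaranteed to be seeded by a fingerprint, so with the defaults only runs of
exactly 10 tokens can occasionally be missed; the tests compare the
detector against a brute-force maximal-common-substring oracle in the
regime `min_span >= k + window - 1` where agreement is exact. Alignment is
token-level throughout so the flags line up one-to-one with the sampler's
tokens.

The 15% "maximum redundancy" setting is applied when holding out
evaluation notes: `split_by_record()` holds out whole records and keeps,
per held-out record, the note with the smallest copied fraction, which must
be at most `max_test_redundancy = 0.15`. Since a source note always has
copied fraction 0, every record has an eligible note.

## The synthetic generator

`simulate_records()` generates clustered corpora from the model's own
story so everything is testable without clinical data. Topic-word rows are
drawn from Dirichlet(`beta`); each record's source note is plain LDA output
(its own mixture from Dirichlet(`alpha`), default 0.3, with `beta` 0.05);
each other note copies contiguous spans from random offsets of its source —
totalling a per-note fraction drawn from `copy_fraction` — and draws its
remaining tokens from its own mixture. Copied tokens retain the topic of
their source occurrence. The exact annotation and all latent variables are
returned as ground truth, independent of any detector.

Choices worth knowing:

* **Source length.** Sources are drawn from 150–250 tokens and other notes
  (100–200) are capped at their source's length, so the longest-note rule
  always identifies the generating source. With overlapping ranges the
  detector frequently picks a non-source note and token-level recall drops
  to ~70%; with the cap it is 100% for spans twice `min_span`.
* **Copied fraction vs measured similarity.** The default `copy_fraction`
  of 0.2–0.4 mirrors a clinical corpus in which roughly a third of a later
  note is pasted. Note that pairwise Smith–Waterman similarity (best single
  local alignment, normalised by the shorter note) *under-reports*
  multi-span copying: a mean copied fraction of 0.3 yields mean same-record
  similarity near 0.17, and reproducing the ~0.3 similarity profile reported
  for real EHR corpora requires `copy_fraction = c(0.4, 0.6)` with spans of
  30–60 tokens (measured 0.31 ± 0.05 across seeds). The calibrated profile
  is what the profile tests and the acceptance script use.
* **Mis-specification mode.** `retain_topics = FALSE` copies the words but
  not the topics, for robustness experiments.

What the generator does **not** emulate: sectioned note structure, topic
drift over a patient's history, template/boilerplate text shared *across*
records, skewed notes-per-patient distributions, and editing of pasted text.
Passing tests on this generator therefore validate the machinery — the
conditionals, count exclusions, detector and metrics — not the clinical
claim that redundancy-aware modeling wins on real notes.

## Evaluation protocol

* **Held-out log-likelihood** (`heldout_loglikelihood()`): per note,
  fold-in Gibbs with $\phi$ fixed (50 sweeps by default) yields a mixture
  $\theta$, then the note scores $\sum_i \log \sum_k \theta_k\phi_{kw_i}$.
  Fold-in is the cheapest estimator consistent with "produce topic
  assignments for held-out documents"; left-to-right style estimators are
  out of scope, so absolute values are comparable only within this package.
* **Topic coherence** (`topic_coherence()`): the co-document-frequency
  score $\sum_{m<l}\log\frac{D(v_l,v_m)+1}{D(v_m)}$ over each topic's top
  words (default 20), with zero-document words skipped and the next rank
  promoted; reference documents are the training notes. Always $\le 0$;
  closer to zero is better.
* **Topic alignment** (`align_topics()`): greedy matching of topic-word
  rows by ascending Jensen–Shannon divergence, accepting pairs up to
  `0.5 * log(2)`; used to pair topics across models for side-by-side
  inspection, and (with threshold `Inf`) to score recovery against the
  generating topics (`recovery_score()`).
* **`compare_methods()`** splits by record, fits every method `n_runs`
  times with one derived seed per repetition (shared across methods, so
  comparisons are paired and a duplicated method reproduces identical
  rows), and reports means and standard deviations.

Natural logarithms are used throughout. All randomness flows from explicit
integer seeds; fits are bit-reproducible across machines because the
sampler uses its own deterministic generator and inverse-CDF draws.

## What the simulations actually show

At the scale used by the tests and the acceptance script (K = 5, V = 200,
50 records of 4 notes, copied fraction 0.4–0.6, 3 repetitions, 500
sweeps), the four methods come out much closer than on real clinical data,
and the ordering among the top methods is within seed noise. Two structural
reasons, worth stating because they say something real about when
redundancy hurts:

1. Copied spans in the generator are contiguous blocks of *fair* topic
   draws. Duplicating a fair draw leaves vanilla LDA's topic-word estimate
   nearly unbiased — it only adds correlated noise. The damage described
   for real corpora comes from copying that is skewed and repeated across
   many notes (a handful of patients with dozens of near-identical notes,
   rare co-occurrences amplified corpus-wide), which a uniform
   4-notes-per-record design cannot produce. Pushing redundancy to
   extremes (10 notes per record, 70–90% copied) does hurt vanilla, but
   hurts the redundancy-aware sampler more, because of the next point.
2. Under span-copying with retained topics, a copied token's topic comes
   from the *source* note's mixture, not the copying note's. Counting
   copied tokens into the copying note's $n_{dk}$ — which the model does,
   following its generative story — then injects source-mixture mass into
   that note's topic distribution. On this generator the best-specified
   treatment of copied tokens is simply to drop them, which is why
   DeleteWord-LDA, which estimates $\phi$ from exactly the same non-copied
   tokens, recovers the generating topics marginally better (matched JSD
   ~0.008 vs ~0.012) and why the held-out gap between Red-LDA and vanilla
   (±0.005 per token) changes sign across seeds.

The corresponding method-ordering acceptance check is therefore expected
to fail in part on this generator, and is left failing rather than tuned
around: the honest summary is that the redundancy-aware sampler's
machinery is fully verified (exact reduction to vanilla LDA, conditional
and count-conservation oracles, detector fidelity), while the *ranking*
claims from the original clinical study depend on properties of real
patient records that this generator deliberately does not fake.

## Numerical and degenerate-input choices

* Probability vectors are normalised exactly once per draw; `phi`/`theta`
  rows sum to 1 within 1e-8 (asserted in tests).
* Tokens outside a model's vocabulary are skipped (and counted) during
  evaluation; an all-out-of-vocabulary note folds in to a uniform mixture
  with a warning.
* Notes left empty by DeleteWord are dropped with a warning naming them;
  zero-length documents are degenerate for LDA.
* Fingerprint hash collisions are harmless: every seed match is verified
  token-by-token before extension.
* Ties: source selection (longest note) breaks ties by earliest note id;
  overlap resolution prefers longer, then leftmost runs; the split's
  least-redundant-note rule breaks ties by earliest note id.

## A small worked example

```{r example, eval = FALSE}
sim <- simulate_records(n_records = 20, K = 3, V = 120, seed = 42)
ann <- annotate_redundancy(sim$corpus)
fit <- redlda(sim$corpus, K = 3, annotation = ann,
              alpha = 1, beta = 0.1, iterations = 300, seed = 42)
summary(fit)
terms(fit, 8)

sp <- split_by_record(sim$corpus, 5, seed = 42, annotation = ann)
heldout_loglikelihood(fit, sp$test)$per_token
recovery_score(fit, sim$truth)
```

## Known limitations

* Single chain, last-sample estimates; no convergence diagnostics.
* Copies are detected only against the record's designated source note,
  not between arbitrary note pairs, and only the longest-note source rule
  is implemented.
* Character-level (edit-distance) alignment is out of scope; a paste that
  was lightly edited inside a span shorter than `min_span` around each
  edit will be partially missed.
* Held-out likelihood uses fold-in, so values are not comparable to
  left-to-right or importance-sampling estimators.
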