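# rednotes — redundancy-aware topic modeling for clustered clinical notes

Clinical notes in a patient record are heavily copy-pasted: later notes
reproduce whole passages of earlier ones verbatim. For topic modeling this
duplication is poison — latent Dirichlet allocation (LDA) treats every
token as an independent draw from its document's topic mixture, so pasted
text both scatters identical copies of a word across topics and inflates
that word's weight in whatever topic it lands in, for reasons of
documentation habit rather than topical relevance.

`rednotes` models collections of *records* (clusters of notes, one cluster
per patient) and provides, behind a single fitting interface, four
strategies for dealing with within-record redundancy:

| method | what it does |
|---|---|
| `vanilla` | collapsed Gibbs LDA over all notes, redundancy ignored |
| `deletedoc` | keep only each record's source note, then vanilla LDA |
| `deleteword` | delete copied tokens from non-source notes, then vanilla LDA |
| `redlda` | redundancy-aware sampler; nothing is discarded |

The redundancy-aware sampler resamples an ordinary token from the usual
collapsed conditional over *redundancy-excluded* counts,

p(z=k) ∝ (n_dk + α) (n_kw + β) / (n_k + Vβ),

while a token flagged as copied draws its topic from its record's source
note: p(z=k) ∝ n_src(w,k) + δ, where n_src(w,k) counts occurrences of the
word w currently assigned topic k in the source note. Copied tokens are
excluded from the topic-word counts (so duplicated text cannot inflate φ)
but still occupy their own note's topic mixture. With no flagged tokens
the sampler reduces bit-exactly to vanilla LDA under the same seed.

Around the sampler the package provides:

* fingerprint-based copy detection (`annotate_redundancy()`): winnowed
  token k-gram seeding, exact extension to maximal shared runs, per-token
  flags aligned to the source note;
* Smith–Waterman similarity over token sequences and a corpus redundancy
  profile (`corpus_similarity_report()`);
* evaluation: held-out log-likelihood via fold-in Gibbs, co-document-
  frequency topic coherence, Jensen–Shannon topic alignment, and a
  multi-method comparison harness (`compare_methods()`);
* a synthetic generator of clustered corpora with exact ground truth
  (`simulate_records()`, `recovery_score()`) so everything is testable
  without access to clinical data;
* a command-line entry point (`inst/cli/rednotes.R`, or `rednotes_main()`
  from R) with `simulate / preprocess / transform / train / evaluate /
  compare` subcommands.

## A worked example

```r
library(rednotes)

sim <- simulate_records(n_records = 20, K = 3, V = 120, seed = 42)
ann <- annotate_redundancy(sim$corpus)
ann
#> Redundancy annotation: 20 records, 2782/12717 tokens copied (21.9%)

fit <- redlda(sim$corpus, K = 3, annotation = ann,
              alpha = 1, beta = 0.1, iterations = 300, seed = 42)
summary(fit, n_terms = 6)
#> Topic model (redlda): K = 3 topics, V = 120 terms, 80 notes, 300 sweeps, seed 42
#> Tokens: 12717 total, 9935 counted toward topic-word estimates
#> Top terms per topic:
#>   topic1: w0087 w0019 w0014 w0008 w0035 w0010
#>   topic2: w0101 w0005 w0049 w0054 w0116 w0112
#>   topic3: w0090 w0065 w0056 w0080 w0029 w0041

sp <- split_by_record(sim$corpus, 5, seed = 42, annotation = ann)
heldout_loglikelihood(fit, sp$test)$per_token
#> [1] -2.9352
recovery_score(fit, sim$truth)
#> [1] 0.0071
```

The annotation found 21.9% of tokens copied (the generator planted ~22%);
2,782 copied tokens were excluded from the topic-word estimates. The
fitted topics match the three generating topics with a mean matched
Jensen–Shannon divergence of 0.007 (0 = perfect recovery, log 2 ≈ 0.69 =
none), and held-out notes score −2.94 log-likelihood per token. Aligning
this model against a vanilla fit of the same corpus
(`align_topics(fit, van)`) pairs all three topics:

```
#> Topic alignment: 3 pairs (JSD <= 0.3466), 0 + 0 unmatched
```

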