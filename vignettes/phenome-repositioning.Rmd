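---
title: "Modeling the drug phenome for repositioning: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the drug phenome for repositioning: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model and its assumptions

phenorepo treats the drug phenome — a binary incidence matrix whose rows are
drugs and whose columns are phenotype terms, partitioned into side effects
and indications — as a corpus for latent Dirichlet allocation. Each drug is
a document; each 1-cell contributes exactly one token of the corresponding
phenotype. The generative story is the standard one: each drug draws a topic
mixture θ_d from a symmetric Dirichlet(α), each topic draws a phenotype
distribution φ_t from a symmetric Dirichlet(β), and each observed phenotype
token is produced by sampling a topic from θ_d and then a phenotype from
φ_t. Topics act as surrogates for unobserved modes of action that generate
therapeutic effects and adverse effects jointly.

The assumptions worth keeping in mind:

* **Multinomial allocation.** Phenotypes are assumed exchangeable draws from
  a drug-specific mixture of multinomials. Real phenomes have correlated
  terms (MedDRA near-synonyms, severity grades) that violate
  exchangeability; the model sees these only as co-occurrence.
* **Binary evidence.** Incidence is 0/1, so a phenotype contributes a single
  token regardless of frequency or severity. This matches the input data
  but discards dose/frequency information by construction.
* **Missingness is uninformative.** A 0-cell is "unobserved", not "known
  absent" — which is exactly what makes the unobserved indication cells
  scoreable, but also means the model cannot distinguish a never-tested
  link from a tested-and-absent one.

Repositioning scores come from the path probability
`p(ph|d) = Σ_t p(t|d) p(ph|t)`. For indication prediction the vector is
restricted to indication columns and renormalized per drug to give `p(i|d)`;
renormalization is a positive rescaling per row, so within-drug ranking is
unaffected.

## Inference: collapsed Gibbs sampling

The sampler integrates out θ and φ and samples token-level topic
assignments; θ and φ are reported as posterior means of the
Rao-Blackwellised per-state estimates `(n_dk + α)/(n_d + Kα)` and
`(n_kw + β)/(n_k + Vβ)`, averaged over post-burn-in states at a fixed lag.
Collapsed Gibbs was chosen over variational EM because it is simple to
audit and can be tested exactly: on corpora small enough to enumerate every
topic-assignment vector, the test suite compares sampler posterior means
against the exact enumeration posterior (agreement within 0.05 absolute at
20,000 retained samples; observed discrepancies are below 0.01). The
interface contract is on the estimated distributions, not the algorithm, so
a variational backend could be added behind `fit_lda()` without touching
downstream code.

All randomness flows through R's RNG: a fit is a deterministic function of
(corpus, config, seed), and the suite asserts bit-identical refits. Topic
labels are arbitrary; every cross-model comparison in the tests is made
after best-permutation topic matching.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `n_topics` K | — | number of latent mechanisms; choose with `select_topics()` |
| `alpha` | 50/K | document-mixture concentration; the conventional Gibbs-LDA default. For small, strongly clustered corpora a smaller value (0.1–0.5) lets θ concentrate; the block-fixture tests use 0.1 for this reason |
| `beta` | 0.01 | topic–phenotype concentration; small values give sparse, interpretable topics |
| `n_iterations` / `burn_in` / `sample_lag` | 2000 / 500 / 10 | sampler schedule; sized so the tiny-corpus enumeration checks pass with margin while full fixture fits stay under a second |
| `default_is` | 13 | IS fallback for drugs with no recorded indication — the average indication count of the SIDER release the method was developed on |
| `bin_width` | 0.005 | histogram bin width for recovery summaries, aligned to the chance threshold of the published data set |

The decision threshold `q = N_known/(|D|·|I|)` is computed from the matrix,
not tuned: it is the probability of hitting a known pair by uniform guessing.
`N_known` counts **all** known drug–indication 1-cells, including pairs
whose indication is held by a single drug (for the published counts,
11,183 maskable + 883 single-drug = 12,066); either convention rounds to the
same q = 0.005 at that scale. The comparison `p > q` is strict: boundary
cases are rejected as indistinguishable from chance.

## Decision criteria and the recovery experiment

A prediction is accepted only if it is above chance **and** ranked within
the drug's indication space (IS = its number of known indications). The IS
rule is a drug-specific degrees-of-freedom control: a drug with two known
indications must place a candidate in its top 2, while a polypharmacological
drug gets more room.

`run_recovery()` masks each eligible known pair one at a time (eligible =
the indication is held by ≥ 2 drugs; masking a singleton would delete the
indication from the vocabulary), re-estimates, and scores the masked cell.
Two re-estimation policies exist:

* `mode = "refit"` (default): a full refit per masked pair with a per-pair
  derived seed — faithful to running the model on the perturbed matrix, at
  ~1 fit per pair.
* `mode = "foldin"`: one fit on the unperturbed matrix; per pair, only the
  perturbed drug's topic assignments are re-sampled against fixed φ. Cheap
  enough for thousands of pairs, at the cost that φ has already seen the
  masked cell once among all tokens — an acceptable leak when |tokens| per
  cell is 1 in a large corpus, and the mode is recorded in the report.

IS is always computed from the unperturbed matrix (the masked link still
counts toward the drug's IS), mirroring how a 13-indication drug is judged
against its full indication range when one link is hidden. The success rate
`s = n_recovered / n_above_chance` is reported as `NA`, not 0, when nothing
clears chance. `summarize_recovery()` also stratifies s by an IS cutoff
(dropping drugs below the cutoff), which reproduces, on synthetic data, the
qualitative pattern that drugs with more known indications are easier to
recover.

## Choosing the number of topics

The published procedure selects K by minimizing an information-loss
objective defined in prior work that this package does not reproduce
verbatim; rather than guess an uncited formula, `select_topics()` minimizes
**held-out perplexity** by default and exposes a `plugin` criterion so any
scalar objective `f(model, test_corpus)` can be registered. The held-out
split is deterministic — every 10th token of each document, in canonical
token order — so selection is reproducible without a second RNG stream.
Scores are averaged over replicate fits with derived seeds; ties break
toward the smaller K (prefer the simpler model). On the three-block fixture
the criterion's minimum sits at the planted K
(`tests/testthat/test-model-selection.R`).

## The synthetic generator

`generate_lda_phenome()` emulates the assumed generative process itself
(Dirichlet φ and θ, topic-then-phenotype token draws, binarization), so
pipeline tests have access to ground truth: the true φ/θ, the raw counts,
and optionally a set of *planted* held-out links — known indication cells
with generative `p(i|d)` in the top quartile that are flipped to 0 in the
emitted matrix. Defaults (200 drugs, 60 side effects, 40 indications, 5
topics, α = β = 0.1, 50 tokens per drug) are sized so that parameter
recovery is informative at desk scale: the suite requires the fitted φ to
match the generative φ within 0.1 mean absolute error after permutation
matching.

`make_block_fixture()` is the hard-structure counterpart: block-diagonal
incidence (drugs of block *b* carry exactly block *b*'s phenotypes, a fixed
fraction labelled indications) with Bernoulli bit-flip noise applied **to
side-effect columns only**. Keeping indication columns noise-free is a
deliberate fixture property: every block indication keeps column sum =
drugs-per-block, so the eligible maskable-pair count has a closed form the
tests assert, and the masking harness never tests noise-created "known"
links that carry no generative signal.

What the synthetics do **not** emulate: SIDER's heavy-tailed term
frequencies and drug degree distribution, MedDRA's correlated vocabulary,
and label-extraction noise. Passing tests therefore demonstrate correctness
of the machinery and recoverability under the model's own assumptions — not
performance on real pharmacovigilance data.

## Numerical and degenerate-input choices

* **Deterministic ordering everywhere.** Columns: side effects first, then
  indications, lexicographic by term id; drugs: lexicographic. Ranking ties
  break by this column order, so ranks are a stable permutation of 1..|I|.
* **Fixed-order mixture sums.** `phenotype_probabilities()` accumulates over
  topics in ascending index order in compiled code rather than delegating to
  BLAS, whose summation order is implementation-defined; the suite checks
  exact equality against an independent plain-loop oracle and closeness to
  the BLAS product.
* **Zero-mass rows.** A drug whose indication-column mass is zero cannot be
  renormalized; it is flagged, excluded from ranking, and warned about.
* **Empty documents.** A drug with an all-zero row is allowed (with a
  warning); its θ falls back to the prior (uniform at symmetric α).
* **K > token count** is a warning, not an error: surplus topics simply stay
  near their prior.
* **Masking is side-effect free.** The input matrix is never mutated; the
  suite asserts bit-identical serialization before and after a recovery run.
* **Problem sizes in tests.** The enumeration checks run at ≤ 8 tokens and
  K = 2 (exact oracle space 2^8); parameter recovery at 200 drugs × 50
  tokens; leave-one-out refit experiments at 60 drugs × 90 phenotypes with
  50–60 masked pairs. These sizes make every statistical assertion decidable
  in seconds while leaving the assertions strict.

## Known limitations

* Suggestions depend on the recorded phenome: an indication absent from
  every drug's record can never be suggested.
* IS is a data artifact — a drug's *recorded* indication count — not a
  pharmacological quantity; for drugs with sparse records the criterion is
  conservative.
* Cross-drug comparison in `query_drugs()` uses the per-drug renormalized
  `p(i|d)` under a uniform drug prior; renormalization makes rows comparable
  only up to each drug's indication mass, a caveat recorded with the result.
* The fold-in recovery mode lets φ see the masked cell once; use the refit
  mode when fidelity matters more than runtime.
* No hyperparameter learning: α and β are fixed user choices.
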