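---
title: "Methods: benchmark machinery for tweet-level depression subtyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: benchmark machinery for tweet-level depression subtyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subtypebench)
```

## The task and the label space

The pipeline targets six-way, single-label classification of short
social-media posts into five depression-subtype classes plus a no-depression
class. Labels here are content-based annotations of individual posts —
linguistic proxies for subtype-related expression, not clinical diagnoses.
The label space is closed and carries a fixed option-letter order used by the
multiple-choice prompting protocol and as the canonical axis order
everywhere else:

```{r}
subtype_labels()
```

Two modelling tracks share the data model and the evaluation layer: few-shot
multiple-choice prompting of a causal language model (no weight updates), and
supervised LoRA fine-tuning of an encoder under a composite imbalance-aware
objective. Everything in this package is desk-scale: the encoder is a
deterministic fixture, the LLM is a pluggable scorer contract, and the data
are synthetic. What the package claims — and tests — is the correctness of
the *machinery*: losses, protocols, schedules, metrics. It makes no claim
about absolute scores on the real corpus, which require the original data
and large pretrained backbones.

## Corpus handling

Text normalization is deliberately minimal: Unicode NFC, collapsing runs of
whitespace, stripping ends. No lowercasing, no negation or sarcasm handling —
contextual models are expected to handle surface variation, and handcrafted
filters would confound model comparisons.

Deduplication removes exact duplicates of the *normalized* text, keeping the
first occurrence (stable and deterministic, at the price of order
dependence). Splitting is stratified per class: a seeded shuffle within each
class followed by contiguous slicing, with slice sizes from largest-remainder
rounding of the ratios, so every partition's per-class count is within one of
its expectation. Because splitting operates on the deduplicated corpus, the
partitions are disjoint by id *and* by text — no exact-duplicate tweet is
shared across train/validation/test, which would otherwise leak content.

The split ratio is not part of the benchmark definition; the default
0.8/0.1/0.1 is a common convention and is configurable. Nothing downstream
depends on it.

## The synthetic-data generator

The generator emulates the structural features of the benchmark corpus that
the pipeline logic actually depends on:

* **Class proportions.** Defaults are the corpus's reported percentages
  (postpartum 24.9, major 16.8, bipolar 16.3, psychotic 15.4, atypical 13.2,
  no-depression 13.2). They are printed to one decimal and sum to 99.8%, so
  the generator renormalizes rather than padding any class — preserving
  relative composition. Counts are apportioned by largest remainder with
  ties broken by canonical class order: exact, deterministic, and
  independent of the PRNG.
* **Confusability structure.** The three clinically confusable classes
  (major, atypical, bipolar) share a common token pool, sampled at rate
  `overlap`; with `overlap = 0` the six class vocabularies are pairwise
  disjoint. A trivial keyword-count classifier serves as the independent
  reference: it is perfect at `overlap = 0` with no noise, and its errors
  concentrate inside the confusable block as `overlap` grows — the
  structural analogue of the major/atypical-into-bipolar confusions the
  benchmark reports.
* **Tweet-like noise.** A fraction `noise_rate` of tokens come from a
  class-neutral pool, and `url_mention_rate` of texts receive a synthetic
  URL or @mention token, which is what exercises the exemplar-selection
  cleanliness filters.

Lexicons are seeded pseudo-words (consonant–vowel syllables), not real
clinical vocabulary: the pipeline tests structure, not semantics, and the
package ships no sensitive text. Defaults — `overlap = 0.5`,
`noise_rate = 0.2`, `url_mention_rate = 0.15`, lengths 5–40 tokens — are one
fixed choice of "moderately confusable, moderately noisy"; the token-length
range in particular is a free choice, since no length distribution is
reported for the original corpus. Text collisions are resolved by appending
a `dupN` token so generated corpora always satisfy the uniqueness
invariants.

What the generator does **not** emulate: real lexical semantics, figurative
language, emoji/hashtag pragmatics, label noise, or annotation bias. A
pipeline that recovers planted labels here demonstrates that its mechanics
are sound — not that any model distinguishes real subtype language.

## The composite training objective

For logits $z \in \mathbb{R}^6$, true class $y$, and training-split class
counts $n_c$:

* **Class-balanced weights.** $w_c \propto (1-\beta)/(1-\beta^{n_c})$ with
  $\beta = 0.999$, normalized by the across-class mean so the weights
  average exactly 1. $\beta^{n_c}$ is computed as $\exp(n_c \log \beta)$;
  with counts in the thousands the naive power underflows.
* **LDAM margins.** $m_c = C_0\, n_c^{-1/4}$ with $C_0 = 0.5$, subtracted
  from the true-class logit before the softmax. This is the printed form; it
  deliberately omits the max-margin normalization of the original LDAM
  formulation, and the package implements the printed form exactly.
* **Focal term.** $w_y (1-\tilde p_y)^\gamma(-\log \tilde p_y)$ with
  $\gamma = 2$ on the margin-shifted softmax $\tilde p$, computed with
  log-sum-exp stabilization. $\gamma = 0$ with unit weights recovers
  margin-shifted cross-entropy (property-tested against an independent CE
  oracle).
* **R-Drop.** Symmetric KL between the predictive distributions of two
  dropout-perturbed passes, $\tfrac12[\mathrm{KL}(p^{(1)}\|p^{(2)}) +
  \mathrm{KL}(p^{(2)}\|p^{(1)})]$, weight $\lambda_{rd} = 0.5$.
  Probabilities are clipped below at $10^{-12}$ before logs — near-one-hot
  softmax outputs are routine late in training.
* **Pairwise margin penalty.** On bipolar-labeled examples only,
  $\max(0, \delta - (z_{bip} - z_{no})) + \max(0, \delta - (z_{bip} -
  z_{aty}))$ with $\delta = 0.15$, weight $\lambda_{pair} = 0.15$.

The total per example is $\tfrac12(L^{(1)} + L^{(2)}) + \lambda_{rd}
L_{RDrop} + \lambda_{pair} L_{pair}$, reduced by the batch mean. Three
choices here were genuinely open and are the package's own:

* the pairwise penalty is averaged over both stochastic passes, for symmetry
  with the focal term's treatment;
* batch reduction is the mean, so the effective step size does not scale
  with batch size;
* class counts feeding weights and margins come from the training split
  only — using validation/test frequencies would leak.

Analytic gradients of the full objective with respect to both logit vectors
are implemented and checked against central finite differences at relative
error $10^{-4}$; they are what the fixture trainer consumes. Class imbalance
is handled entirely at the loss level — there is no oversampling or
undersampling anywhere in the pipeline.

## The few-shot prompting protocol

The prompt is a fixed, versioned template: one instruction line; six option
lines in the fixed letter order A–F; an `Examples:` block with one exemplar
line per class (`L. <text> -> L`); the target line `Tweet: <text>`; and
`Answer:`. The original protocol's prompt wording is not published, so a
concrete template is specified for determinism and testability; the wording
is overridable without touching the protocol logic.

**Exemplars** are chosen once per run from the training split with a fixed
seed: per class, candidates are "clean, short" tweets — operationalized as
no `http`/`www.` substring, no `@`, and at most 120 characters — and the
shortest candidate wins, ties resolved by seeded shuffle. If a class has no
clean candidate the rule falls back to its shortest tweet and records a
flag.

**Realizations.** "k independent prompt realizations" is operationalized as
seeded permutations of the exemplar-line order (realization 0 is the
identity), with instruction, options and target fixed. With a deterministic
scorer this is the one stated degree of freedom available without
temperature sampling; it is an interpretation, flagged as such. A scorer
that ignores exemplar order therefore produces identical scores across
realizations — that invariance is itself tested.

**Scoring.** The scorer contract takes prompt text plus candidate
continuation strings and returns one finite log-probability per candidate.
Each letter is scored as the max over its surface variants (`"A"`, `" A"`) —
tokenizers disagree about leading spaces — and the six letter scores are
log-sum-exp renormalized into a proper log-distribution. Renormalization
subtracts a constant, so argmax and ordering are unaffected; whether the
original protocol renormalized before voting is unstated, and the vote is
invariant to it either way.

**Voting.** Majority over the k argmax letters; ties broken by the larger
sum of the tied letter's log-probabilities across realizations, then by
letter order. The chain is total and deterministic; only the majority rule
is inherited, the rest is the package's tie policy. The mock scorer
(lexicon-hit counts times a `sharpness`, plus a small seeded perturbation
derived from the seed and the prompt text) stands in for a causal LLM and
lets the whole track be tested: on a disjoint-vocabulary corpus it recovers
planted labels perfectly.

## The fine-tuning recipe and the fixture encoder

The optimizer recipe is fixed: AdamW with decoupled weight decay 0.03,
learning rate 2e-4 shared by the LoRA parameters and the classifier head,
linear warm-up over the first 6% of planned steps then cosine decay to zero,
global gradient-norm clipping at 1.0, batch size 16, up to 10 epochs with
early stopping on validation macro-F1 (patience 2, improvement threshold
5e-4), inputs head-truncated to 160 tokens. Warm-up shape (linear) and the
restoration of the best epoch's weights at the end are standard-practice
choices the recipe leaves unstated. The validation pass during training is
a deterministic single forward pass (dropout off); MC-dropout averaging at
prediction time is available separately and unbiased (the dropout scaling
keeps the mean logit equal to the deterministic logit).

LoRA: rank 8, α = 16, adapter dropout 0.05. Target projections resolve per
encoder family — `query_proj`/`key_proj`/`value_proj`/`dense` for DeBERTa
variants, attention q/k/v plus the two feed-forward projections otherwise.
Adapters are `A` (small Gaussian init) and `B` (zero init), so training
starts from the frozen backbone's behaviour; trainable values number
`rank × (fan_in + fan_out)` per adapted projection plus the head, a small
fraction of the frozen base.

The **fixture encoder** makes the recipe executable in seconds: whitespace
tokens are hashed into a 1024-bucket bag-of-buckets vector (L2-normalized),
passed through a frozen random projection to a 192-dimensional hidden
representation (the "backbone"), with dropout 0.1 on that representation
supplying the stochasticity R-Drop and MC-dropout need, and a linear head on
top. The dimensions are chosen so that disjoint class vocabularies remain
linearly separable after hashing and projection: a few hundred lexicon
tokens in a 256-bucket space collide enough to destroy the planted margin,
while 1024 buckets and 192 hidden units preserve it comfortably (the same
features are separable for an independent multinomial-logit fit). On a
200-example disjoint-vocabulary corpus the full recipe reaches validation
macro-F1 ≥ 0.99 within the 10-epoch budget — the recovery property the test
suite asserts. Real pretrained backbones are out of scope; the recipe is
expressed against the encoder contract precisely so that they could be
plugged in without touching the trainer.

## Evaluation layer

Confusion matrices are 6×6 with rows = true, columns = predicted, canonical
order. Per-class precision/recall/F1 use the zero-denominator convention:
an undefined value is reported as 0 with an explicit flag, and flagged
classes still count in macro means — conservative, and documented because
published analyses rarely hit the case. Macro values are unweighted means;
accuracy is trace over total. Published error analyses print only selected
confusion cells, so the package has a partial-matrix constructor that stores
known cells and known row/column totals and refuses to invent the rest;
per-class metrics and misclassification rates are computable exactly for
the classes whose totals are printed.

Comparisons against printed percentages use round-half-up at one decimal on
the percent scale.

`compare_best()` selects each track's best row by a *primary* metric
(default macro-F1, ties to the first listed model) and then reports the
delta on the requested metric between those two rows. This mirrors how the
benchmark reports its headline gaps: the accuracy delta is quoted between
the same two models that win on macro-F1, not between the per-column maxima
(which would differ, since the few-shot accuracy column is topped by a model
that does not win macro-F1). The transcribed score table treats its
precision/recall columns as macro-averaged, consistent with the macro
framing of the primary metric; that reading is an interpretation and is
confined to the fixture data.

## Problem sizes, determinism, and numerical choices

Every stochastic step — generation, splitting, exemplar selection,
realization permutation, adapter init, batch order, dropout masks,
MC-dropout — draws from a locally seeded RNG that restores the caller's
state, so identical inputs and seeds give byte-identical outputs and the
global RNG is never disturbed.

The shipped tests and the acceptance script run the pipeline at sizes a
laptop CPU handles in seconds: corpora of 120–1200 examples for recovery
and confusability properties, 200 examples for the fine-tuning recovery, a
1000-draw Monte-Carlo check for MC-dropout, and 1000 random prediction sets
for metric-oracle equivalence. These sizes are the package's choice of
desk-scale; the machinery itself is size-agnostic.

Numerical conventions collected in one place: log-sum-exp everywhere a
softmax or normalization appears; KL clipping floor 1e-12; weight
computation via `exp(n log β)`; largest-remainder ties by canonical class
order; argmax ties to the first class in canonical order; duplicate texts
resolve to the first occurrence.

## Known limitations

* Synthetic corpora test mechanics, not language: passing recovery tests
  says nothing about performance on real social-media text.
* The prompting track's "independent realizations" are exemplar-order
  permutations; protocols that vary temperature or wording are admissible
  readings not covered here (the scorer contract accommodates them).
* The fixture encoder is linear in a hashed bag-of-words; it cannot express
  the contextual phenomena real encoders are fine-tuned for, and absolute
  scores from it are meaningless outside the synthetic setting.
* The transcribed benchmark table and partial confusion matrices carry only
  what was printed; cells never printed are `NA` by design and nothing
  interpolates them.
* Single-post classification only: no user-level aggregation, timestamps,
  or cross-lingual handling.
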