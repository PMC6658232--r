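---
title: "Transfer learning for clinical sequence labeling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transfer learning for clinical sequence labeling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crfbridge)
library(dplyr)
```

## The problem

Nursing handover notes — the free-form text produced when responsibility for
a patient passes between nurses — carry structured facts (patient name, ward,
appointments, medications, status) that clinical information systems want in
form fields. `crfbridge` treats this as token-level sequence labeling: every
word in a sentence receives either one of the form-heading classes or the
dominant "not applicable" (NA) class marking irrelevant content. The
practical obstacle is data: labeled handover corpora are tiny, while larger
labeled corpora exist in *related* domains (clinical discharge summaries,
newswire entity annotation) whose label sets overlap only loosely with the
handover headings. The package implements three cooperating pieces:

1. a linear-chain conditional random field (CRF) tagger trained with AdaGrad
   and early stopping;
2. a three-step transfer procedure that initializes a target-domain CRF from
   a frozen source-domain CRF through a learned label-correlation bridge;
3. skip-gram word embeddings with negative sampling, plus an incremental
   adapter that folds a small domain corpus into embeddings trained on a
   large general corpus.

Everything is exercised on synthetic corpora generated by the package
itself, so no restricted clinical data are needed to test or demonstrate any
stage.

## The tagging model

For a sentence $x = x_1 \dots x_L$ with labels $y_1 \dots y_L \in Y$, the
model is the standard log-linear linear chain

$$
p(y \mid x) \;=\; \frac{1}{Z(x)} \exp\!\Big(
  \sum_{l=1}^{L} W^f f(y_l, x) + W^g g(y_{l-1}, y_l) \Big),
$$

with emission weights $W^f$ ($|Y| \times F$ over the feature space), a
transition matrix $W^g$ ($|Y| \times |Y|$) scoring adjacent label pairs, and
the partition function $Z$ summing over all $|Y|^L$ paths. One modeling
choice deserves a note: a multiplicative form with *un-exponentiated*
potentials inside the product is sometimes written for this model, but that
form is not a normalized distribution; we implement the log-linear reading,
which is also the only one consistent with the model's own lower layer — the
per-position emission posterior
$\sigma(y^*, x_i, W^f) = \exp(W^f_{\cdot y^*} f)/\sum_y \exp(W^f_{\cdot y} f)$
is exactly a multinomial logistic regression.

Inference is exact: `forward_backward()` computes $\log Z$ and unary and
pairwise marginals in log space with max-subtraction, and `viterbi_decode()`
computes the argmax path, breaking ties toward the lower label index (the
schema fixes label order, so tie-breaking is deterministic and documented
rather than incidental). Both routines are verified in the test suite
against exhaustive path enumeration on chains with $L \le 6$, $|Y| \le 5$.

### Features

Sentences are featurized with the classic window templates: unigrams at
offsets $-1, 0, +1$ and the two adjacent bigrams $(w_{i-1} w_i)$,
$(w_i w_{i+1})$. Sentence boundaries use explicit `<BOS>`/`<EOS>` sentinel
tokens (a choice the templates force us to make; sentinels keep the feature
space uniform across positions). Sparse template features are binary.
Resource-backed annotators — ontology lookups, part-of-speech tags,
gazetteers — are deliberately *not* bundled: they are licensed or external
resources orthogonal to the learning machinery. They plug in as named hook
functions (`feature_templates(hooks = ...)`), each contributing one
annotation feature per token. An embedding model can be attached as a dense
per-position feature block (the token's input vector), with ids disjoint
from the sparse space.

The feature index grows only during training; at prediction time unseen
feature names are dropped, so the test-time feature space never exceeds the
training space.

### Training

`train_crf()` minimizes the L2-regularized negative conditional
log-likelihood with per-sentence AdaGrad updates: each coordinate moves by
$\text{step} \cdot g / \sqrt{G + \varepsilon}$ where $G$ accumulates squared
gradients. Defaults are step 0.1, $\varepsilon = 10^{-8}$,
$\lambda = 10^{-3}$; these are conventional values that converge stably on
the synthetic tasks and are all exposed in `train_config()`. Two numerical
choices matter for efficiency and are worth recording:

* Per-sentence updates touch only the coordinates active in that sentence
  (features present, plus all transitions). The L2 term, which touches
  every coordinate, is applied as a single dense gradient pass at the end
  of each epoch instead of per sentence. The reported loss always includes
  the full $(\lambda/2)\lVert W \rVert^2$ penalty.
* The per-epoch sentence shuffle comes from the seeded R generator, so a
  training run is a pure function of (data, config); tests rely on
  bit-identical re-runs.

When a development corpus is given, each epoch is scored by macro-averaged
F1 over the non-NA classes (the package's headline metric, see below) and
training keeps the weights of the best epoch, stopping after `patience`
epochs without improvement. The regularized objective is convex, so with
enough epochs any seed reaches the same optimum — the test suite checks
that two seeds agree to $10^{-3}$ in final loss — but early stopping is
retained deliberately: in transfer fine-tuning it is what prevents the
optimizer from walking away from the transferred initialization (see
below).

## The transfer bridge

The transfer procedure has three steps.

**Step 1 — source model.** Train a CRF on the large source-domain corpus
and freeze its emission weights $W^s$.

**Step 2 — label-correlation bridge.** For each target-domain token with
features $f(x_i)$, compute the source score vector $a_i = W^s f(x_i)$ and
train a multinomial logistic classifier $W^t$
($|Y_{tgt}| \times |Y_{src}|$) to predict the target label from $a_i$:
$p(y' \mid x) = \sigma(y', x_i;\, W^t W^s)$. $W^t$ is trained by per-token
AdaGrad from zero initialization; $W^s$ is never touched (asserted
bit-identical in tests).

A design point: the bridge consumes the *raw linear scores* $a_i$, not
softmax probabilities. Linearity is what makes step 3 exact — the stacked
predictor $\mathrm{softmax}(W^t (W^s f))$ and the composed single layer
$\mathrm{softmax}((W^t W^s) f)$ are identical by associativity, and the
package tests this equality at $10^{-12}$. With a softmax between the
layers the product initialization would only approximate the stacked
model.

**Step 3 — composed initialization and fine-tuning.** Initialize the
target CRF's emissions to $W^f = W^t W^s$, then (a) reset the row of the
target NA class to zero and (b) initialize transitions $W^g$ to zero, and
fine-tune on the target training data with AdaGrad and early stopping.

The NA reset exists because NA dominates the corpus (over half of all
tokens in the default generator, mirroring real handover text): left
alone, the transferred NA row biases every prediction toward the dominant
class. The reset is applied once, at initialization, to the composed
emission row; fine-tuning may move the row afterwards. (The reset could
equivalently be applied to the NA row of $W^t$ itself — both yield a zero
composed NA row at initialization; we chose the composed row as the more
direct statement of the intent.) Transitions start at zero because label
co-occurrence structure is domain-specific; there is no reason to expect
source-domain label bigram preferences to describe the target schema.

Fine-tuning uses early stopping *as a mechanism for knowledge retention*,
not merely for regularization: the objective is convex, so unlimited
fine-tuning on the 10-sentence target corpus would converge to the same
optimum as cold-start training and forget the initialization entirely.
Stopping on development macro-F1 keeps the model near the transferred
solution whenever the data are too sparse to justify moving away from it.

Source and target corpora must share one feature space. The package builds
a single `feature_index()` over the union of both corpora before source
training (the pipeline functions and the CLI `--union-features` flag do
this); this is the simplest choice that preserves exact composition.

## Embeddings and incremental adaptation

`train_skipgram()` implements the skip-gram objective with negative
sampling: for each (center, context) pair within a window of size $c$,
maximize

$$
\log \sigma(v'^{\top}_{w_O} v_{w_I}) +
\sum_{i=1}^{k} \log \sigma(-v'^{\top}_{w_i} v_{w_I}),
$$

with $k$ noise words drawn from a unigram-based distribution $U(w)$.
Defaults follow the settings commonly used for named-entity work:
$d = 200$, $c = 5$, $k = 10$, initial rate 0.05, 20 epochs. The noise
exponent defaults to 1 (raw unigram frequency), with the common smoothed
0.75 available in `skipgram_config()`; frequent-word subsampling is
available but off by default. Updates are applied sequentially in corpus
order with a seeded per-epoch shuffle — determinism was preferred over
multi-threaded asynchronous updates at the corpus sizes this package
targets. Rare words below `min_count` map to a trained `<unk>` entry whose
vector doubles as the unknown-word vector $v_0$.

`incremental_train()` adapts a base model (vocabulary $V_0$) to a new
domain corpus (vocabulary $V_1$) with two devices:

* **Averaged initialization.** A new word ($V_1 \setminus V_0$) starts at
  the per-dimension mean of the vectors of the words in the sentence where
  it first appears, $\frac{1}{S}\sum_i v_i$, with unknown neighbors
  contributing $v_0$ — new domain terms start from an averaged optimized
  point rather than from scratch.
* **Split learning rates.** New words train from
  $\alpha_{0_{new}} = 0.2$; words already in $V_0$ train from
  $\alpha_{0_{old}} = \alpha_{0_{new}} \cdot |V_1 \setminus V_0| / |V_0 \cup V_1|$,
  the share of new words in the joint vocabulary — the more new material
  there is, the more the old vectors are allowed to move to reconcile with
  it. Both rates decay linearly to zero over the run.

The published description of this schedule contains two different
right-hand sides for the same new-word case; the reading implemented here
(new words from 0.2, old words from the vocabulary-fraction rate, both
linear) is the one consistent with its accompanying prose, and we do not
claim it as the only possible interpretation. A practical corollary of the
design: words of $V_0$ absent from the new corpus are never sampled as
centers, contexts, or negatives (the noise table is built from the new
corpus), so their vectors are exactly untouched — an invariant the tests
assert.

The rate applied to an individual vector update is the rate of the word
*whose vector is being moved*: the center word's class governs its input
vector, each context/negative word's class governs its output vector.

## Evaluation

`score()` computes token-level precision, recall and F1 per class. The
headline number is **macro-averaged F1 excluding the NA class**, with NA F1
reported separately: NA is so frequent that including it (or
micro-averaging) rewards systems that do nothing but filter irrelevant
content. Schema classes with no gold and no predicted tokens contribute 0
to macro averages by default (`drop_absent = TRUE` drops them instead);
undefined precision or recall is scored 0. Micro averages pool counts over
all tokens and, for exhaustive single-label predictions, all equal token
accuracy.

`wilcoxon_signed_rank()` compares two systems' per-document scores. Zero
differences are dropped; for up to 12 remaining pairs the two-sided p-value
is computed by enumerating all $2^n$ sign assignments (exact even under
rank ties, which the classical exact distribution cannot handle), otherwise
by normal approximation with continuity and tie corrections. `Random`
(uniform label per token) and `Majority` (modal training label everywhere,
ties broken lexicographically) baselines calibrate task difficulty.

Scoring is token-level throughout; no span semantics are defined, so no
partial-span crediting arises.

## The synthetic task

`generate_tagged_corpora()` draws the five splits of a correlated
source/target task. The source domain carries coarse labels (PERSON, DATE,
ID, HOSPITAL, O); each target label refines one source label
(PERSON → Given_names, Last_name; DATE → Day, Time; ID → Current_room,
Current_bed; HOSPITAL → Hospital; O → NA). Sentences are sequences of
independent slots: NA with probability `na_fraction` (default 0.6 — NA is
deliberately dominant, as in real handover text), otherwise a uniform
entity label, with the token drawn from that label's lexicon. Each target
label owns a sub-lexicon of its source parent's lexicon, so by construction
the true source label reduces target-label uncertainty — exactly the
structure the bridge exploits. `noise_rate` (default 0.05) emits a token
from a wrong lexicon; `vocab_overlap` (default 0.8) controls how much
vocabulary the two domains share. Lexicons are synthetic stems
(`given_names_03`, `na_17`), not realistic names: the tests need
separability control, not realism.

What the generator does *not* emulate — and therefore what passing tests do
not show about real data: natural phraseology and grammar (slots are
independent, so transition structure is weak), speech-recognition errors,
label imbalance beyond the NA/entity split, multi-token entity spans with
internal structure, and the scale of real embedding corpora. Results on the
synthetic task demonstrate that the machinery is correct and that the
transfer mechanism helps when its structural assumption (correlated label
refinements) holds; they are not estimates of performance on clinical text.

`generate_text_corpus()` builds the embedding counterpart: sentences drawn
from one of ≥2 topic vocabularies mixed with shared function words, so
within-topic words co-occur and should embed closer than between-topic
words.

## Problem sizes and the package's own checks

The package's standing experiment (run by `scripts/acceptance.R` and
mirrored in the test suite) uses the low-resource study conditions: 500
source training sentences, 10 target training sentences, 50 development and
200 test sentences, NA fraction 0.6, 10 replicate seeds. Under these
conditions transfer initialization beats cold-start training by a wide
margin in median test macro-F1 (about 0.09 cold-start vs about 0.39 with
transfer under seed 1; the script recomputes these from scratch). With
abundant target data (hundreds of sentences) the two converge, as convexity
predicts — the tests assert agreement within 0.05 dev macro-F1.

Embedding checks use 200 two-topic sentences and 12-dimensional vectors;
CRF inference checks enumerate all paths on chains up to $L = 6$,
$|Y| = 5$; all gradients (CRF likelihood, skip-gram objective, bridge loss)
are verified against central finite differences at 50 random points each.
These sizes were chosen so the whole suite demonstrates every claim in
minutes on one core; nothing in the method depends on them.

## Known limitations

* Plain per-token labels only; BIO encoding is provided as a view
  (`as_bio_labels()`) but the models do not use span constraints.
* Transition features are label-pair indicators only — no feature-conjoined
  transitions, no higher-order chains.
* The bridge assumes the shared feature space described above; models
  trained with incompatible indices are rejected, not re-aligned.
* Skip-gram training is single-threaded by design (determinism over
  throughput); it is not meant for billion-word corpora.
* Hook features are the extension point for ontology/POS/gazetteer
  annotations; none are bundled.

## A minimal session

```{r example, eval = FALSE}
spec <- synthetic_spec(seed = 11)
corp <- generate_tagged_corpora(spec)

idx <- feature_index()
tpl <- feature_templates()
grow_feature_index(idx, corp$source_train, corp$target_train,
                   templates = tpl)

cfg <- train_config(max_epochs = 20, patience = 4, seed = 1)
src <- train_crf(corp$source_train, corp$source_dev, corp$source_schema,
                 tpl, cfg, index = idx, grow_index = FALSE)
fit <- transfer_train(src, corp$target_train, corp$target_dev,
                      corp$target_schema, cfg)

report <- score(corp$target_test, predict(fit, corp$target_test),
                corp$target_schema)
glance(report)
tidy(attr(fit, "bridge"))   # which source label backs each target label
autoplot(report)
```
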