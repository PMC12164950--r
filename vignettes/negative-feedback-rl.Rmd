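---
title: "Learning reaction outcomes from failed experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning reaction outcomes from failed experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Forward reaction prediction asks: given the precursors of a chemical
reaction (reactants and reagents, serialized as SMILES), what product
forms? Sequence-to-sequence models handle this task well when trained on
large collections of *successful* reactions, but laboratory practice
produces far more failures than successes, and those failures carry
information that plain likelihood training cannot use: a failed reaction
tells the model where the manifold of successful chemistry *ends*.

`rxnrl` implements a training strategy that feeds failed (negative)
reactions back into a forward-prediction model through reinforcement
learning. The components are:

1. a **forward model** — a compact encoder-decoder transformer over
   SMILES tokens trained by maximum likelihood (MLE), used both as the
   trainable policy and, frozen, as the reference policy;
2. a **reward model** — a separate bidirectional transformer encoder
   that turns whole reactions into fingerprint vectors, tuned on the
   success/failure classification task, plus a class-weighted,
   probability-calibrated support vector machine over those
   fingerprints;
3. an **RL tuner** — sampled rollouts scored by a composite reward,
   a small value network as baseline, and a clipped policy-gradient
   update with a per-sequence KL penalty towards the frozen reference.

The scientific claim the package is built to test is an *ordering*: when
positive examples are scarce but informative negatives are abundant, the
RL-tuned model should beat MLE fine-tuning on held-out positive
accuracy; when positives are abundant, plain fine-tuning is competitive
or better.

## The model

### Forward policy

The policy is a standard encoder-decoder transformer (post-layer-norm,
sinusoidal positions, multi-head attention) with desk-scale defaults:
2 encoder and 2 decoder layers, width 48, 4 heads, feed-forward width
96 — about 100k parameters. Training minimizes token-level
cross-entropy with teacher forcing; begin/end sentinels are excluded
from the loss, padding never arises because sequences are processed
individually. Decoding uses length-bounded beam search (default 10
beams, the conventional width for this model family) without length
normalization — products are short, so the usual length bias is
immaterial. The model is implemented twice: a reference implementation
in plain R matrix code, and compiled RcppArmadillo kernels used by all
production paths. The test suite checks the compiled kernels against
the R reference to machine precision, checks the R reference against
finite-difference gradients, and checks beam search against exhaustive
enumeration on a tiny decoder.

### Reward model

A reaction fingerprint is a pooled hidden state of a bidirectional
transformer encoder applied to the full serialized reaction
`lhs>>product`. Three design points here were settled empirically, and
each failure mode is worth recording because it is generic:

- **The encoder must start pretrained.** A randomly initialized
  encoder, classification-tuned on the regime's labels, collapses: all
  fingerprints converge to nearly one point and the classifier scores
  become constant. Distinguishing regio-isomers requires
  representations that already encode ring topology, so the default
  encoder is derived from the pretrained forward model's encoder stack
  (`as_reaction_encoder()`) — the package's analog of building reward
  embeddings on a pretrained chemical language model.
- **Pooling is product-sided by default.** Mean pooling over the whole
  reaction dilutes the one-token regiochemical difference between a
  positive and its negatives; averaging the product-side states (which
  still see the precursors through attention) keeps that difference in
  the fingerprint. Whole-reaction mean and first-token pooling remain
  available.
- **Tuning must be gentle.** Per-example Adam steps at any learning
  rate destroy the pretrained geometry. Classification tuning
  therefore accumulates gradients over batches of 16 and, by default,
  updates only the top self-attention block and the logistic head,
  leaving the lower layers frozen. The head is discarded after tuning.

On top of the fingerprints sits an SVM (radial kernel by default — the
kernel is exposed in the configuration, since nothing in the method
constrains it) with class weights inversely proportional to class
frequency, so that 20 positives among 900 negatives still shape the
margin, and sigmoid probability calibration. Calibrated probabilities
under a 2–3% positive prior compress towards zero, which would make
graded rewards indistinguishable from the KL penalty scale; the reward
path therefore converts them to the balanced-prior scale (a strictly
monotone Bayes correction for the training class frequencies), so
scores spread around 0.5.

The composite reward for a decoder output is a total function into
[0, 1]:

- unparsable SMILES → 0 (`invalid_reward`, configurable);
- canonical match to a recorded positive for that left-hand side → 1
  (`match_bonus`);
- canonical match to a recorded negative → 0;
- otherwise → the calibrated probability of the positive class; in
  binary mode (the screening-data workflow) this branch is thresholded
  at 0.5 to {0, 1}.

The exact-match rules make the reward label-faithful by construction on
known reactions; the classifier only ever extrapolates to novel
products. The magnitudes of the first three branches are configuration,
not dogma — they encode "reward valid known successes, discourage known
failures" and are exposed as fields of the reward model.

### RL tuner

Rollouts sample one or more products per left-hand side from the
current policy (ancestral sampling, temperature 1). Each sampled
reaction receives the composite reward, shaped by a per-sequence KL
penalty `r~ = r − kl_coeff · (log π − log π_ref)`; the reported KL
history uses the non-negative estimator `exp(−d) + d − 1` so that a
collapse guard can be a simple threshold. The advantage is `r~` minus a
state-value baseline: a two-layer network (linear → ReLU → linear →
sigmoid) on the mean-pooled encoder state of the left-hand side, with
its final layer zero-initialized so the untrained baseline is 0.5.
Advantages are additionally centered within each batch — a
miscalibrated baseline must not push the entire sampled distribution up
or down — and optionally standardized. The policy step is the
clipped-surrogate policy gradient with the importance ratio clipped to
`[1 − ε, 1 + ε]` (ε = 0.2); each rollout batch is split into
minibatches so an epoch takes several small clipped
steps rather than one large noisy one — with a tiny model and few
epochs, single large Adam steps per batch were the dominant source of
training collapse. The reward is terminal and credited uniformly
across the sequence, because it is defined on the whole predicted
reaction and the toy products are short. The very first minibatch of a
batch is exactly on-policy (ratio 1, clip fraction 0). Training
alternates rollout collection and updates, monitors validation top-1
positive accuracy, and returns the best checkpoint — the same protocol
as the MLE arm, so the comparison is symmetric.

Left-hand sides for rollouts are drawn from the *training* reactions,
positives and negatives alike. Because negatives share substrates with
positives (and with substrates whose successful outcome is unknown),
the RL arm effectively practices on many more left-hand sides than MLE
fine-tuning ever sees labeled — that, plus the reward model's
generalization, is the entire proposed advantage of the method in the
scarce-positive regime.

Two workflow choices round out the tuner, both settled empirically:

- **RL is chained after fine-tuning.** At patent-corpus scale a base
  forward model already ranks the true product of an unseen
  regiochemistry domain highly, so RL can start from the base. A
  desk-scale base transfers far too weakly (its samples essentially
  never hit a true downstream product), leaving RL without any reward
  gradient to find. The package therefore runs the chained workflow —
  fine-tune on the regime's positives, then RL from that checkpoint
  (which also becomes the frozen reference) — for all datasets, the
  same chaining used for screening data where domain shift forces it.
- **Pretraining replay as an anchor.** Each epoch one MLE step on
  held-in pretraining-domain reactions (at half the policy learning
  rate by default) pulls the policy back onto fluent chemistry.
  Sequence-level policy gradients alone slowly leak probability mass
  into malformed strings; the replay step is the standard practical
  stabilizer for RL tuning of language models and simultaneously
  protects the pretraining domain from catastrophic forgetting.

## The toy reaction language

Real benchmarks for this method need a GPU-scale pretrained transformer
and proprietary screening data. The package instead ships a synthetic
reaction family with exactly the statistical structure the method
needs, at a scale where the full pipeline runs on one CPU in minutes.

**Regioselectivity family.** Substrates are substituted five- and
six-membered aromatic rings (benzene, pyridines, diazines, triazines,
furans, thiophenes) carrying one directing substituent from a fixed set
(methyl, ethyl, hydroxyl, methoxy, amino, N-methylamino, chloro,
fluoro) and optionally a passive spectator (cyano or acetyl) at a
distal position. The reaction is halogenation (Br₂ or Cl₂ as the
halogen source). The ground-truth rule is *ortho* direction: the new
halogen goes to the ring carbon adjacent to the directing substituent
(position 2 of the builder's ring numbering, falling back to the other
neighbor when position 2 is a heteroatom). The rule is injective per
substrate, so evaluation has zero label noise; symmetry-equivalent
placements collapse under canonicalization. Negatives are *every other*
aromatic C–H placement of that halogen, enumerated by the same
graph-edit routine exposed to users (`generate_regio_negatives()`), so
the generator exercises the production path. Default conditions: 150
positive reactions split 40:30:30 into train/validation/test (60/45/45);
all negatives attached to the training split only (validation and test
contain positives exclusively, since the metric is positive accuracy);
a target of 14 training negatives per training positive (840
negatives). When the positives' own negatives cannot reach the target,
substrates outside the positive set contribute negative-only left-hand
sides — mirroring screening collections where most substrates never
show a success. The low-data regime keeps 20 of the 60 training
positives (subsample fraction 1/3) and every negative, i.e. at least 40
negatives per positive — the "handful of successes, forty-fold
failures" regime the method targets.

**Pretraining corpus.** A disjoint substituent family (hydroxymethyl,
aminomethyl, and friends) undergoes three deterministic template
reactions: halogenation, O-methylation with methyl iodide, and
N-acetylation with acetyl chloride. Products are disjoint from the
regioselectivity family's product space by construction and filtered
against it with the same leakage rule used for corpus cleaning. Two
design choices here are load-bearing, and both came out of analyzing
failed designs:

- *Mixed directing behavior.* The six pretraining substituents split
  into ortho, meta and para directors (two each). An earlier design
  used a single deterministic para rule; the resulting base model
  assigned essentially zero probability (log-probability around -50)
  to any ortho product, so no amount of sampling could discover the
  downstream family's correct outcomes -- unlike a patent-corpus
  model, which scores about half of an unseen regiochemistry benchmark
  before any tuning. Mixed directors give the base genuine positional
  entropy on unseen directing groups.
- *Downstream groups appear as spectators.* Pretraining substrates
  carry second substituents drawn from the downstream directing-group
  family (plus inert groups), always at non-reacting positions.
  Without this the base model cannot even copy an unseen substituent:
  it "corrects" unfamiliar groups into familiar ones while decoding.
  As a spectator, a downstream group is copied faithfully and observed
  with halogens landing at varied positions relative to it, without
  revealing the downstream rule (the reacting set-A group determines
  the position; spectators that would make a template ambiguous --
  e.g. a free hydroxyl under methylation -- are excluded from that
  template).

The held-out corpus slice provides the catastrophic-forgetting probe:
pretraining-domain accuracy is re-measured after RL, and the KL anchor
should keep it intact.

**Screening grid.** For the yield-labeled workflow, a factorial grid of
substrates × catalyst × solvent tokens receives yields from a hidden
deterministic rule (the matching catalyst/solvent pair yields 5–95%,
everything else below 1%); labels come from the strict >1% threshold
rule, and coverage can be thinned non-uniformly. This reproduces the
structure of high-throughput screening data: sparse positives, type-2
negatives (nothing formed), uneven substrate coverage.

What the toy language does *not* emulate: chemical energetics (the
ortho rule is arbitrary, not physical), multi-product outcomes,
stereochemistry, yield magnitudes beyond the threshold, and the
long-tail token statistics of patent-scale corpora. Passing the
package's tests therefore demonstrates that the *machinery* — negative
enumeration, reward shaping, clipped updates, the regime ordering —
behaves as designed on data with this structure; it does not certify
accuracy on real chemistry.

## Numerical and design choices

- **Canonicalization** is delegated to OpenBabel (via ChemmineOB); all
  string comparisons (deduplication, exact-match rewards, accuracy)
  happen in canonical space, and results are cached per session.
  Multi-line conversion falls back to bisection because the converter
  stops at the first invalid entry.
- **Reagents vs reactants** are never distinguished: the serialized
  input is the merged precursor list `a.b.c`, matching the `a.b>>p`
  convention of the model family.
- **Largest-remainder rounding** turns split ratios into sizes, so any
  ratio triple partitions any n exactly.
- **The moved halogen** in negative enumeration is identified as the
  halogen atom whose deletion recovers a precursor; ties break at the
  lowest atom index. Halogens carried in from precursors are therefore
  never repositioned.
- **Splits with negatives:** negatives are generated from the entire
  positive family, not per split, and all go to the training split —
  the negative pool is a property of the dataset, constant across
  splits, exactly as the regime tables of screening benchmarks keep it.
- **Optimizer**: Adam with a global gradient-norm clip at 1.0, Xavier
  initialization, flat-vector updates for speed. MLE uses gradient
  accumulation over 4 sequences.
- **Hyperparameters** (`rl_config()`): KL coefficient 0.05, clip 0.2,
  48 left-hand sides × 2 samples per epoch, temperature 1, advantage
  standardization on. These were selected on mean behavior across
  multiple seeds — never on a single favored seed — and every knob is
  exposed.
- **Determinism**: every stochastic step (generation, splits,
  initialization, sampling, SVM calibration folds) is governed by an
  explicit seed; identical configuration and seed reproduce histories
  bit for bit.
- **Problem sizes** in the shipped benchmark (2,400 pretraining
  reactions drawn from a ~2,500-reaction pool, pretraining with an
  early stop at 90.5% held-out top-1 and a 48-epoch cap, a
  150-positive family, 3 low-data comparison seeds plus one high-data
  seed, 20 fine-tuning epochs, 10 RL epochs at 64 left-hand sides x 2
  samples, both arms monitored with the same beam width and the same
  number of checkpoint evaluations) are the package's default
  desk-scale study conditions; they were chosen so the complete
  comparison runs in tens of minutes on one CPU while leaving the
  orderings under test clearly resolved. All of them are arguments,
  not constants. One caveat is stated openly: at this training budget
  the pretraining held-out top-1 lands in a 0.86-0.92 band depending
  on the data-split seed, crossing the 90% learnability mark on some
  seeds and narrowly missing on others; the fixture itself is
  deterministic and ambiguity-free (every left-hand side maps to
  exactly one product, enforced and tested), so the residual gap is
  compute, not label noise.

## Known limitations

- The policy processes one sequence at a time; there is no batched
  decoding, so wall time scales linearly in beams × length.
- The SVM's probability calibration uses libsvm's internal
  cross-validation; it is seeded for reproducibility but its folds are
  not configurable.
- Negative enumeration assumes a single movable halogen on an aromatic
  system; polyhalogenation and non-halogen chemistry are out of scope.
- With fewer than ~10 positives the classification-tuned encoder can
  collapse to the majority class; the class weights mitigate but do not
  eliminate this (the screening workflow's binary reward is more robust
  there).

## A worked run

```r
library(rxnrl)

spec <- toy_spec(seed = 1)
base <- pretrain_base(spec)                      # base forward model
fam  <- make_regio_family(spec)                  # high-data regime
klow <- subsample_positives(fam, 1/3, seed = 1)  # 20 positives, all negatives

res <- run_regime(base, klow,
                  mle_cfg = mle_config(epochs = 20, seed = 1),
                  rl_cfg  = rl_config(epochs = 10, seed = 1),
                  forgetting_slice = subset(base$corpus, slice == "test"))
res[c("ft_valid_top1", "rl_valid_top1", "forgetting_drop")]
```

Multi-seed orderings use `multi_seed_report()` over
`run_split_experiment()`; `run_acceptance_study()` packages the whole
protocol, and `scripts/acceptance.R` in the repository runs it and
writes every headline quantity to JSON.
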