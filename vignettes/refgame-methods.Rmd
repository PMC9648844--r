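---
title: "Methods: communication games between perceptually biased agents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: communication games between perceptually biased agents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, algorithms and numerical choices behind
`refgame`. The package simulates a Lewis-style reference game between two
neural agents in order to study how visual representation learning and
emergent communication shape each other, and provides the measurement tools
(representational similarity analysis, information-theoretic effectiveness
scores, evolutionary-stability analysis) to quantify that interaction.

## The stimulus world

Stimuli are images generated from six independent latent factors: floor color
(10 values), wall color (10 values), object color (4 values: red, yellow,
turquoise, purple), object scale (4 values), object shape (4 values: cube,
sphere, cylinder, ellipsoid) and object orientation (15 values). An *object
class* is defined by the triple (color, scale, shape), giving 4^3 = 64
classes, indexed color-major: `class = 16*color + 4*scale + shape` (0-based),
so each block of 16 consecutive classes shares a color. Floor, wall and
orientation are class-irrelevant nuisance factors: two instances of the same
object may differ in all three.

The renderer (`render_stimulus()`) is a deliberate 2-D proxy for the original
3-D scenes: a floor band, a wall, and a centered filled silhouette whose
outline encodes shape, area encodes scale, hue encodes object color, and
in-plane rotation encodes orientation. All analyses in the package depend
only on the latent-factor structure — which classes share which attribute
values, and which factors are class-irrelevant — not on photorealism. The
proxy preserves exactly that structure while letting the full pipeline run in
minutes. What it does *not* emulate: 3-D pose and lighting, occlusion
statistics, or the pixel statistics of rendered scenes. Passing tests
therefore demonstrate the mechanisms (bias induction, bias transfer into
language, and back) on images with the right generative structure, not that
effect sizes would be identical on the original data set. An optional loader
(`load_3dshapes()`) accepts the real HDF5 data for users who have it.

Images are `size x size x 3` arrays in [0, 1] (64 px by default; tests use
16 px). Splits are stratified per class at a 0.75/0.25 train/test ratio;
stratification is our choice (the ratio alone leaves it open) and makes
small-pool experiments well-behaved.

## Relational label smoothing

Perceptual biases are created during classifier pretraining by replacing the
one-hot target $y_0$ with

$$y = \sigma\, y_r + (1 - \sigma)\, y_0, \qquad \sigma \in [0, 1],$$

where the relational component $y_r$ spreads weight uniformly over the
*superclass* $C_i$ of classes sharing an attribute value with the true class
$i$: $y_r^{(j)} = (n-1)^{-1}$ for $j \in C_i,\ j \ne i$, and 0 otherwise,
with $n = |C_i| = 16$ for every single attribute. For several attributes,
$y_r$ is the (weighted) average of the per-attribute components,
$y_r = \tfrac1N \sum_a y_r^a$. The standard conditions are `default`
($\sigma = 0$), `color`/`scale`/`shape` ($\sigma = 0.6$) and `all`
($\sigma = 0.8$; the higher factor is tolerable because the weight spreads
over more classes). `calibrate_mixed_bias()` grid-searches $\sigma$ and the
two-attribute weighting for mixed conditions, maximizing the minimum RSA over
the enforced attributes subject to a cap on the unenforced attribute's RSA —
an explicit operationalization of "both biases strong and balanced, third
bias absent".

## Agents

Each agent couples a **vision module** — conv(32 ch, 3×3) → ReLU → 2×2
max-pool → conv(32 ch, 3×3) → ReLU → fc(16) → ReLU → fc(16) → ReLU → linear
softmax head over 64 classes — with a **language module** (symbol embedding +
single-layer GRU, both 128-dimensional). The 16-dim activations of the layer
before the softmax head are the agent's visual representation.

The sender initializes its GRU hidden state with an affine adapter of the
target's representation; the first input is a zero vector; at each of the
$L$ steps a symbol distribution is produced by a linear head, so the message
policy factorizes as $\pi_S(m \mid i) = \prod_t \pi_S(s_t \mid s_{<t}, i)$.
The receiver reads the message with its own embedding/GRU (no parameter
sharing — the agents are separate individuals) and scores each candidate
image by the dot product of its adapted representation with the final hidden
state; the selection policy is the softmax of those scores. During training
actions are sampled; at test time both agents use argmax.

All layers are implemented in base R with hand-derived backward passes
(im2col-free offset-GEMM convolution, BPTT through the GRU). Every gradient
path is verified against central finite differences in the test suite, and
the REINFORCE estimator is checked against the exact gradient of $-E[r]$ on
an enumerable toy policy.

## The reference game and its variants

A round: a target class is drawn uniformly; the sender sees one instance and
emits a message of length $L = 3$ over a vocabulary of size $|V| = 4$; the
receiver sees a *different* instance of the target plus $k = 2$ distractor
instances of other classes (mutually distinct classes — distinctness is our
choice, avoiding ambiguous credit when two candidates tie) in shuffled slots,
and must pick the target. Both agents receive reward 1 on success, else 0.
Chance level is $1/(k+1) = 1/3$.

In the irrelevant-attribute variants, a nonempty subset of
{color, scale, shape} is *relevant*: sender and receiver targets need only
agree on relevant attributes (the receiver target's irrelevant attributes are
redrawn freely), and every distractor must differ from the target in at least
one relevant attribute. With all three attributes relevant this reduces
exactly to "same object = same class".

## Training scenarios

Three scenarios control which modules learn:

* `fixed_vision_emergence` — both language modules train, both vision modules
  are frozen (used for the perception→language analyses and the tournament);
* `language_learning` — the entire sender is frozen, so its protocol defines
  a fixed language the receiver (language *and* vision) must learn;
* `full_emergence` — everything trains and the protocol emerges.

Policy gradients are plain REINFORCE: each agent minimizes
$-\tfrac1n\sum_b r_b \sum_t \log\pi(a_{t,b})$ minus an entropy bonus of 0.02
times the mean per-step policy entropy (per-step rather than per-message —
the finer-grained choice, applied uniformly). Optimization is Adam with
learning rate 0.0005 and batch size 128; 150 epochs when both agents train,
25 for language learning. No reward baseline is subtracted by default (basic
policy gradient); `scenario_config(baseline = TRUE)` enables a batch-mean
baseline, which we use in short small-batch runs where the variance reduction
matters. When a vision module is trainable, classification training continues
with the same smoothed targets as pretraining, one classification batch per
game batch drawn from the same train split (the interleaving granularity is
our choice), and the two losses are added unweighted;
`classification_loss = "off"` gives the no-classification control.

Pretraining uses SGD (learning rate 0.001, batch 128, 200 epochs at full
scale). `pretrain_hp(momentum =)` defaults to 0; small-budget runs use
momentum 0.9 with a larger step because a few hundred gradient steps must do
the work of ~10^5 plain-SGD steps. Two numerical details stabilize small
networks: input pixels are centered (−0.5), and the fully connected biases
start at 0.1 so the 16-unit representation layer does not start with dead
ReLU units (an all-zero representation would make cosine similarity
undefined). Weight matrices use uniform fan-based initialization. Divergence
(non-finite loss) aborts with a diagnostic rather than returning garbage.

## Evaluation

**Perceptual bias (RSA).** For each class, $N$ random instances (50 by
default) are embedded and the 64×64 representational similarity matrix (RSM)
of mean pairwise cosine similarities is built; diagonal cells average only
over pairs of *distinct* examples so that trivial self-similarity does not
inflate them. The RSA score is the Spearman correlation (average-rank ties)
between two RSMs over the upper off-diagonal triangle — the diagonal is
excluded because template diagonals are constant 1 and would only add tied
ranks. Templates come from attribute encodings: the overall template is the
cosine similarity of 3-hot (color, scale, shape) vectors — the fraction of
shared attributes — and each per-attribute template is the unit-block matrix
of classes sharing that attribute's value. Per-attribute RSA scores
attenuate each other: representations cannot match all three block
structures at once, which is precisely what makes the per-attribute profile
a *bias* measure. `rsa_alignment()` applies the same machinery between two
agents' representation spaces.

**Linguistic bias (information theory).** Messages are greedy-decoded per
test image (test-time argmax, matching the agents' evaluation regime).
With objects $O$, messages $M$ and selections $S$, plug-in (empirical)
entropies give the conditional entropies and mutual information; the
effectiveness score is

$$E(O, M) = 1 - \frac{H(O \mid M)}{H(O)} \in [0, 1],$$

computed overall, per attribute ($O_a$ = the attribute's values), and
averaged over attributes. The score is a ratio of entropies, hence
independent of the logarithm base (reported in bits). Degenerate inputs
($H(O) = 0$, constant RSMs) are flagged with warnings/NA rather than
silently coerced to 0. Estimators are plug-in by design; no small-sample
bias correction is applied. `info_diagram()` also reports the
sender/receiver symmetry diagnostics ($H(O\mid M)$ vs $H(S\mid M)$, both
mutual informations).

Uncertainty is quantified with seeded percentile bootstrap intervals (10 000
resamples by default); `mean_abs_diff()` compares per-condition mean scores.

## Evolutionary analysis

Bias types become strategies of a symmetric population game by
*symmetrizing* the role-asymmetric reference game: the payoff between types
$t$ and $t'$ is the mean of the run-mean rewards of a $t$-sender/$t'$-receiver
and a $t'$-sender/$t$-receiver. `run_tournament()` trains a fresh pair
(fixed visions, new language modules) for every ordered type pair and run.
Type $t$ is evolutionary stable iff for every mutant $t' \ne t$ either
$r(t,t) > r(t',t)$, or $r(t',t) = r(t,t)$ (within a tolerance of 1e-9 on
point estimates) and $r(t,t') > r(t',t')$. The strict conditions are
invariant under adding a constant to all payoffs, and the implementation is
tested for exact agreement with an exhaustive condition checker on random
matrices. A separate significance mode additionally requires the bootstrap
CI of each column-wise payoff difference to exclude zero; the CI-based rule
is an interpretive reconstruction of "pairwise comparisons between the CIs"
and is therefore kept behind a flag rather than folded into the default.

## Problem sizes used by the test suite

The full-scale protocol (96 000 images, 200 pretraining epochs, 150 game
epochs) produces rewards around 0.91–0.97 and sharp RSA contrasts, but is a
multi-day computation. The package's tests run the same code end-to-end at
desk scale, chosen once as the smallest sizes at which the qualitative
phenomena are stable across seeds:

* data: 8 instances per class (512 images), 16 px renders, 0.75/0.25 split;
* pretraining: SGD momentum 0.9, lr 0.1, batch 128, 60 epochs;
  RSA profiles from N = 8 examples per class;
* games: REINFORCE with batch 64, 6 batches/epoch, 15 epochs, batch-mean
  baseline, 400 greedy evaluation rounds;
* directional checks use 5 seeds with majority-vote pass rules.

At these sizes pretrained classifiers reach roughly 20–55% test accuracy
(far above the 1.6% chance level, far below the full-scale >97%), trained
pairs reach greedy test rewards around 0.7–0.84, single-attribute smoothing
reliably makes the enforced attribute's RSA rank first, color-biased pairs
ground their messages almost entirely in color, and the all-attribute bias
satisfies the point-estimate ESS conditions in desk tournaments over
{default, scale, all}.

## Known limitations

* The renderer is a structural proxy; absolute RSA/effectiveness magnitudes
  on real 3dshapes images will differ (the inherent color bias of RGB input,
  however, reproduces clearly even on the proxy).
* Plug-in entropy estimates are biased upward for undersampled joints; with
  64 objects and ≤64 messages and hundreds of evaluation rounds this is
  acceptable, but per-attribute scores from very few rounds should be read
  with care.
* Desk-scale accuracy is far from ceiling, so desk effectiveness scores mix
  representation noise with protocol structure; only directions/rankings,
  not magnitudes, are meaningful at that scale.
* Only pure-strategy, point-estimate ESS analysis is provided (plus the
  CI-significance flag); no replicator-dynamics integration and no
  mixed-strategy equilibria.
* Populations are single sender-receiver pairs; flexible-role agents and
  larger populations are out of scope.
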