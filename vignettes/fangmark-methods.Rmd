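---
title: "Methods: snakebite-mark classification, edge planning and feedback retraining"
author: "fangmark developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: snakebite-mark classification, edge planning and feedback retraining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

A bite from the Egyptian cobra (*Naja haje*) can be fatal within minutes, and
species identification is the first step of treatment: species-specific
antivenom avoids the risks of polyvalent administration. The bite *mark*
itself carries the signal — venomous snakes leave two deep fang punctures,
while many non-venomous species leave curved rows of small tooth marks. This
package implements a desk-scale version of a clinical pipeline built on that
signal: enhance poorly lit wound photographs, train a two-class convolutional
network (cobra vs other), evaluate it with the standard confusion-matrix
metrics, choose how many edge compute nodes to deploy per state with a
profit objective maximised by (quantum-behaved) particle swarm optimisation,
and simulate the cloud–edge loop in which misclassified, later-confirmed
cases are returned to the cloud for retraining.

Clinical bite-mark photographs cannot be redistributed (patient
confidentiality), so the package ships a seeded synthetic generator and every
empirical claim in the test suite is made on generated data. Nothing here
reproduces the original clinical accuracy; what the tests establish is that
each algorithmic component behaves as specified and that the pipeline as a
whole learns, evaluates, plans and retrains correctly on a dataset whose
ground truth is known by construction.

## The synthetic world

`generate_bite_image(label, config, seed)` draws a skin-toned background
(low-frequency sinusoid texture, amplitude 0.06), stamps soft elliptical
marks, applies a global brightness scale drawn from [0.3, 1.0] and additive
Gaussian noise with sigma drawn from [0, 0.05], and clips to [0, 1]. The
brightness and noise ranges emulate the poor acquisition conditions that
motivate the enhancement stage. Class geometry:

* **cobra** — exactly two elliptical punctures at a sampled inter-fang
  distance (40–70 px at the 256 px reference size);
* **other** — a curved double row of 6–9 small tooth marks per row along an
  arc.

Two calibration choices deserve explanation:

* **Mark scale.** Marks are large (puncture radius 20–30 px at 256 px,
  i.e. a wound close-up). The package's separability contract — a
  nearest-centroid classifier on raw 16×16 grayscale thumbnails must exceed
  0.7 accuracy — has to hold under a 3.3× multiplicative brightness jitter.
  A linear classifier on raw intensities can only ignore that jitter if the
  class-difference direction is orthogonal to the overall-brightness axis
  and the class signal dominates the sampling noise of per-class mean
  brightness; small marks cannot provide that. Clinical wound photographs
  are, in fact, framed on the wound.
* **Matched ink.** Each image's total mark darkness (integrated depth ×
  area, the integral of a Gaussian stamp being depth·π·r_x·r_y) is drawn
  from one distribution shared by both classes, and stamp depths are scaled
  to hit it. The classes therefore differ in spatial layout only — two
  central punctures versus a peripheral ring — and a classifier cannot cheat
  by thresholding overall darkness.

What the generator does *not* model: real skin texture, swelling, necrosis,
bleeding, occlusion, perspective, or more than two classes. A green test on
this world shows the harness can learn a clean geometric signal under
brightness/noise nuisance; it says nothing about clinical performance.

`generate_state_table(n_states, seed)` draws per-state epidemiology — total
bites `n` (Poisson, mean 400), deaths `d` (Binomial(n, 0.03)) and dangerous
or blinding cases `p` (Binomial(n − d, 0.08)) — guaranteeing `p + d ≤ n`.
The rates are of the order reported for snakebite morbidity/mortality; they
are inputs to the planner, not claims.

## Contrast enhancement

The enhancement is weighted two-exposure fusion

\[ R^c = \sum_{i=1}^{N} W_i \, P_i^c, \qquad P_i = g(P, k_i), \]

with `c` the colour channel, here with `N = 2`: the original (ratio 1) and
one synthetic exposure. The source method names this framework but not the
functional forms; the package uses the framework's standard camera-model
instantiation, with all constants config-exposed in `enhance_config()`:

* **Brightness transform function** `g(P, k) = exp(b(1 − k^a)) · P^(k^a)`
  with `a = −0.3293`, `b = 1.1258`. At `k = 1` it is the identity; black is
  a fixed point; it is monotone in intensity; output is clipped to [0, 1].
* **Weight map** `W = T^mu`, `T` the per-pixel channel maximum (an
  illumination estimate), `mu = 0.5`. Well-exposed pixels keep the original;
  dark pixels take the brightened exposure. Fusion weights are `(W, 1 − W)`,
  so they sum to one by construction.
* **Exposure ratio** `k` is chosen from a candidate grid by maximising the
  Shannon entropy (64-bin histogram) of the under-exposed pixels
  (`W < 0.5`) after transformation; ties and images with no under-exposed
  pixels resolve to the smallest ratio. The default grid
  `{1.5, 2, 3, 4, 6, 8, 12, 16, 24}` reaches high ratios deliberately: a
  severely under-exposed image is then lifted in a single pass, after which
  a second pass finds no under-exposed pixels, degenerates to `k = 1.5`, and
  changes the image by little — this is what makes `enhance()` saturate
  (the suite asserts < 0.05 mean absolute change on the second pass).

## Augmentation and resizing

The augmentation protocol is one 90° rotation variant plus one centre-zoom
variant with factor drawn uniformly from [0.5, 1.0] (factors below one crop
centrally and rescale), per image, seeded. "Flipping 90" in the protocol
table is read as a rotation — a mirror flip has no degree — with an optional
mirror flag for the other reading. Resizing to the canonical square (1000 px
in the study protocol; 64 px at desk scale) is bilinear, with an
integer-factor box prefilter when downscaling by more than 2× to avoid
aliasing; grayscale input is replicated to three channels.

## The classifier

The convolution layer computes
\(Y_i = f(B_i + \sum_j K_{ij} * Y_j)\)
with `*` valid cross-correlation at stride 1 (the source prints a `+` inside
the sum; its own prose describes wandering a filter over the image, so the
package implements convolution). Pooling maps an `(m1, m2, m3)` volume to
`(m1, ⌊(m2−F)/S⌋+1, ⌊(m3−F)/S⌋+1)` with max pooling; the floor and an
explicit `F ≤ dim` check handle non-divisible inputs. Both operations are
verified against brute-force quadruple-loop oracles in the suite.

No deep-learning runtime exists in the target environment, so the network is
implemented in vectorised base R: convolution as im2col + matrix multiply,
pooling by stride-shifted comparisons, and training by mini-batch softmax
cross-entropy with adaptive-moment updates. The protocol's "Epsilon 1e-10"
is used as the optimiser's numerical-stability constant — the one role such
a constant has in this optimiser family. Training defaults follow the tuned
protocol (epochs 100, learning rate 0.001, batch 64); tests and the
acceptance script use 10–15 epochs at desk scale, stated where used.

The `tiny` backbone (3×3 conv ×8, ReLU, 2×2 max-pool, 3×3 conv ×16, ReLU,
2×2 max-pool, fully connected to 2 softmax scores; input side 64) is
buildable offline and is what every test trains. The named transfer-learning
backbones (VGG16, VGG19, ResNet-101) are configuration options that require
a local weight file; without one they fail with a labelled "weights
unavailable" error rather than attempting a download. Splits are stratified
by class and seeded; epoch logs record train loss, train accuracy and
validation accuracy from a full evaluation pass at epoch end, which is why
predicting the training images afterwards reproduces the logged final
accuracy exactly.

## Evaluation

Cobra is the positive class throughout. From the 2×2 confusion matrix:
sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, accuracy
`(tp+tn)/total`. AUC uses the rank estimator — the probability that a random
positive outscores a random negative, ties counting one half — which equals
brute-force pair counting (asserted in the suite). Metrics are fractions
internally and percentages only at the reporting layer.

The published worked example (tp = 170, fn = 8, fp = 12, tn = 30 over 220
test bites) yields accuracy 90.9% and specificity 71.4%, which the
acceptance suite reproduces exactly. The same matrix gives sensitivity
170/178 ≈ 95.5%, while the source text states 96.7%; the package reports the
matrix-derived value and leaves the discrepancy documented rather than
reconciled.

## Edge-node planning

For a state with epidemiology `(n, d, p)` and a total budget of `K` nodes,
the profit of deploying `k` nodes is

\[ \mathrm{Profit}(k) = \frac{1}{k} - \left(\frac{k}{K} - \frac{p+d}{n}\right) - C(k). \]

The first term rewards delay reduction (hop delay is modelled as
`delay_constant / k`), the middle term penalises deviation of the state's
budget share from its danger ratio, and `C(k)` is the node cost (a per-node
price by default, or any function). The penalty is signed, exactly as
written: under-deploying below the danger ratio is *rewarded*. That is a
faithful property of the objective, documented, not corrected. The objective
also mixes units (inverse count, ratio, currency) with no stated
normalisation; it is implemented literally and any reweighting is left to
the caller via the cost function. The identity
`profit(k) + C(k) + gap(k) = 1/k` is asserted for all k.

Maximisation is over integer `k ∈ [1, K]`. PSO moves particles by
`v ← ωv + c1 φ1 (P − x) + c2 φ2 (Pg − x)`, `x ← x + v`; QPSO keeps no
velocities and samples around the local attractor
`PP = φP + (1 − φ)Pg` via `x ← PP ± α |m_best − x| ln(1/u)`, with `m_best`
the mean of personal bests, the sign decided by a fair coin, `u` drawn from
the open interval, and the contraction–expansion coefficient `α = 0.7`
(fixed, no annealing, per the tuned protocol). The source prints `P_i` in
one branch where the QPSO literature has the attractor; both branches use
the attractor here. Positions move continuously; the objective is always
evaluated at `round(x)` clamped to `[1, K]`, so the published update
equations are preserved while the result is the integer the design calls
for. An exhaustive scan (`method = "brute"`) is the oracle: on 20 random
problems with `K ≤ 50` the suite requires each swarm to hit the exact
optimum at least 18 times.

## The feedback-retraining loop

Each round, every edge classifies a stream of fresh synthetic cases; cases
whose confirmed true label disagrees with the prediction — only those, per
the source's rule, although correctly classified cases would also help — are
appended to the cloud dataset with their confirmed labels, and the model is
retrained with a warm start for a small number of epochs (default 5;
schedule unstated in the source, so config-exposed). Ground-truth
confirmation is modelled as arriving within the same round (a configurable
simplification of clinical confirmation; the mechanism is unstated in the
source but required for the loop to operate). The held-out test set and all
case streams use disjoint derived seed streams, so no feedback case can leak
into the test set.

The initial cloud training is deliberately short (2 epochs on 80 images at
desk scale) so the deployed model starts imperfect — the premise of the
whole loop is a ~91%-accurate deployed model. With a well-trained starting
model the synthetic world is easy enough that no misclassifications occur
and the loop has nothing to show. The simulator reports the trajectory only;
the source's claim that retraining reaches "the best level" has no stated
stopping criterion and none is invented.

## Pipeline and seeding

`run_pipeline()` executes synth → enhance → (augment) → train → evaluate →
plan-edges → simulate-loop from one validated YAML config; unknown keys are
rejected by name and any stage failure aborts naming the stage. One global
seed derives a per-stage seed by hashing the stage name, so stages can be
replayed in isolation and two runs with the same config agree exactly
(asserted). Reports print percentages with one decimal; all internal values
are fractions.

## Numerical and degenerate-input choices

* Images are H×W×3 arrays in [0, 1]; alpha channels are dropped, grayscale
  replicated.
* Exposure-set weights must sum to 1 within 1e-6 per pixel.
* Ties in the exposure-ratio search go to the smallest ratio; an image with
  no under-exposed pixels takes the smallest grid ratio.
* `u = 0` draws in QPSO are clamped to the machine epsilon (open interval).
* Contract violations raise classed conditions (`fangmark_*`), so tests
  distinguish contract errors from incidental ones.

## Known limitations

The synthetic world is linearly separable by design, so accuracy-style
results are ceilings, not estimates; the CNN is a small fixed architecture
with no pretrained weights; the planner is one-dimensional (node count, not
placement); the loop does not model confirmation failure, label noise or
network behaviour; and the published real-data headline metrics (e.g. AUC
97.4%) are out of reach by construction because the clinical dataset is
private.
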