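---
title: "Tuning transfer-learning classifiers with manta-ray foraging optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tuning transfer-learning classifiers with manta-ray foraging optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MRFOpt)
```

## The problem

Fine-tuning a pre-trained convolutional classifier on a medical imaging task
involves a dozen coupled choices — loss function, optimizer, batch size,
dropout, how much of the backbone to retrain, how images are scaled, and
whether (and how) to augment the training data. Grid search over this mixed
discrete/continuous space is infeasible when each point costs a training run.
`MRFOpt` treats the whole configuration as a single point in the unit
hypercube and searches it with manta-ray foraging optimization (MRFO), a
swarm metaheuristic with three complementary moves: *chain foraging* (members
file along behind a leader), *cyclone foraging* (spiralling around either the
incumbent best or a random reference point), and *somersault foraging*
(flipping around the best-known position).

## Encoding and decoding

A candidate solution is a vector $x \in [0,1]^{15}$. Element $j$ decodes
through the linear map

$$\mathrm{value} = \mathrm{lower} + x_j \,(\mathrm{upper} - \mathrm{lower}),$$

specialised by element kind. The default space (`defaultSearchSpace()`) is:
loss over six candidates, batch size $4..48$ in steps of 4, dropout
$[0, 0.6]$, learn ratio $1..100\%$, optimizer over eleven candidates, scaler
over four, an augmentation switch, and — active only when that switch is on —
rotation $0..45^\circ$, width/height shift, shear and zoom $[0, 0.25]$, two
flip switches and a brightness-multiplier range inside $[0.5, 2.0]$. With
augmentation on, all 15 elements are active; with it off, only the first 7
matter. The vector nevertheless always carries 15 elements so the swarm works
in a fixed dimension; resizing the population mid-run is not something the
update sweep defines.

Three decoding rules are under-determined by a range table alone, and we fix
them as follows, chosen for determinism, monotonicity in $x_j$ and full range
coverage:

* **stepped** ranges snap the linear value to the nearest grid point, ties
  toward the larger point;
* **categorical** sets partition $[0,1]$ into equal cells, with $x_j = 1$
  clamped into the last cell;
* **boolean** elements threshold at $0.5$, upper-inclusive.

The brightness element decodes to a centre $c$ and is emitted as the interval
$[c(1-w),\, c(1+w)]$ clipped to $[0.5, 2.0]$, with half-width fraction
$w = 0.05$ by default. Reported best-solution tables in the literature show
intervals of varying width with no generating rule, so the half-width is an
explicit, documented parameter rather than a reconstruction.

The learn ratio is interpreted as the percentage of *trailing* backbone
layers left trainable (the layers nearest the classification head), the rest
frozen; `freezeLayers(direction = "leading")` flips the interpretation, since
published tables label the same quantity both as a "learn ratio" and a
"freezing ratio". The lower bound of the ratio is 1%; a fully frozen backbone
is expressible only by editing the space (`writeSearchSpace()` /
`readSearchSpace()` round-trip a YAML mirror of the element table).

```{r}
x <- rep(0.5, 15); x[3] <- 0.85     # dropout element
decodeSolution(x)@dropout           # 0 + 0.85 * (0.6 - 0)
```

## The optimizer

Each iteration scores every member, then runs one update sweep
(`updatePopulation()`): members are sorted by score (descending, ties by
index), the incumbent best extracted, and each member updated in place by
cyclone foraging (with probability 0.5) or chain foraging — so each member
chases its already-updated predecessor — followed by a somersault sweep.
After each sweep every member is re-scored and the incumbent best is retained
greedily, so `bestScore` is non-decreasing at every evaluation point. One
iteration therefore costs about three evaluations per member;
`makeTransferFitness()` memoizes on the decoded configuration so identical
configurations are never retrained.

The cyclone move explores while $t/T_{\max}$ is small (reference point = a
fresh uniform random vector, drawn per member) and exploits later (reference
point = the incumbent best). The weight coefficients are the standard MRFO
forms $\alpha = 2 r \sqrt{|\ln r|}$ and
$\beta = 2 e^{r_1 (T_{\max} - t + 1)/T_{\max}} \sin(2\pi r_1)$, with
somersault factor $S = 2$; all three are configurable (`mrfoParams()`). The
somersault equation's two multipliers are treated as independent uniform
draws. Positions are clipped element-wise to the bounds after every move —
no boundary policy is otherwise defined, and decoding requires unit-interval
inputs.

**Randomness.** A run consumes a single seeded stream (`params$seed`) in a
fixed, documented draw order (branch, phase, reference vector if exploring,
then the per-equation draws; somersault draws $r_2, r_3$ per member). This
gives bit-identical histories for identical seeds with less machinery than
per-member substreams; the update operators additionally accept explicit
draws (`drawFun`) so tests can force entire sweeps and compare against
hand-traced expectations.

Defaults follow the published run configuration: population 10, 10
iterations, 5 epochs per evaluation, 85/15 double split, $128^2$ RGB inputs.

## Preprocessing

Images are resized to the network input size with separable bicubic
convolution (Keys kernel, $a = -0.5$, clamped borders) — implemented here
because the interpolation method is prescribed and the available image
libraries offer only bilinear resampling. Four per-image scalers are
available; statistics are per image, not per dataset, which is the only
reading that needs no global pass and keeps evaluation embarrassingly
parallel: divide by max, standardize to mean 0 / sd 1, min–max to $[0,1]$,
divide by max absolute value. Degenerate images (constant, or all-zero for
the ratio scalers) either signal an error or substitute a zero image,
per the caller's policy.

Class balancing up-samples every minority class to the majority count by
augmenting resampled originals with a fixed policy (rotation $30^\circ$,
20% shifts/shear/zoom, brightness $[0.8, 1.2]$, both flips); originals are
never removed. Balancing uses this fixed policy, not the solution-encoded
one, because it happens before the search chooses a policy. Balancing runs
before the split by default (matching the published dataset totals, e.g.
$\{2479, 5304\} \to 10608$); note this lets augmented near-duplicates cross
the split, so `runConfig(balance = FALSE)` plus manual balancing of the
training portion is the conservative alternative for real studies.

The split is two-stage at the same ratio (default 0.85): test share
$\mathrm{round}(0.15\,n)$ first, then validation share
$\mathrm{round}(0.15)$ of the remainder, both stratified by class with
largest-remainder apportionment and rounding half-up (only the ratio is
prescribed; the rounding is ours). For $n = 1000$: 722 train / 128
validation / 150 test.

## The fitness

The objective is the trained model's classification accuracy. By default the
score is computed on the **validation** split. Evaluating on the whole
dataset — as the source experiments describe — leaks training data into model
selection and inflates scores; that behaviour is available behind
`trainingRun(evalSplit = "whole")` but is deliberately not the default.

Backbones come from a provider registry. The shipped `"tiny"` provider is a
small trainable network written in base R: a fixed $8\times8$
average-pooling stem over the three channels (192 features) followed by two
dense tanh layers ($192 \to 32 \to 16$) with seeded Glorot-initialised
weights standing in for pre-trained parameters, then the configured dropout
and a softmax head sized to the class count. All six losses (cross-entropy,
categorical hinge, KL divergence, Poisson, squared hinge, hinge — hinge
variants on $\pm1$ targets with softmax outputs) and all eleven optimizers
(SGD, SGD-Nesterov, Adam, NAdam, AdaMax, AdaGrad, AdaDelta, RMSProp, centered
RMSProp, AMSGrad-Adam, FTRL) are implemented against a common minibatch
interface; gradients flow through the softmax Jacobian for the non-CE losses.
The default step size (0.05) is sized for this network. The eight published
large-backbone names are registered as stubs that fail fast, since running
them requires an external deep-learning runtime; any provider can be added
with `registerBackbone()`. A training collapse (non-finite weights) scores 0
with a diagnostic instead of aborting the search; a failed evaluation demotes
only that member.

`analyticFitness()` — $1/(1 + \lVert x - c\rVert^2)$, maximal at $c$ —
provides a desk-scale objective with a known optimum for verifying the
optimizer itself.

## What the synthetic data does and does not show

`generateImageDataset()` renders, per class, oriented sinusoidal stripes on a
class-specific base intensity plus Gaussian noise. It emulates the *shape* of
the real problem — class-conditional texture, optional imbalance,
folder-layout round trips — and is constructed to be learnable (a one-feature
threshold classifier reaches $\ge 0.95$ accuracy, which the tests verify
independently), so a passing end-to-end run demonstrates the plumbing:
decoding, training, scoring, greedy retention, reproducibility. It does not
mimic histopathology or ultrasound appearance statistics, and a high accuracy
here says nothing about accuracy on real medical images; reproducing the
published GPU-scale experiments requires the original Kaggle corpora and a
deep-learning backbone provider.

Problem sizes in the shipped tests are deliberately modest — $16^2$–$32^2$
images, tens of images per class, populations of 3–10, 1–2 iterations for
end-to-end runs and $10 \times 30$ for optimizer-recovery checks — chosen so
the whole suite runs in a couple of minutes on one CPU while still exercising
every code path. The optimizer-recovery surface (best point within
$L_\infty\ 0.05$ of the analytic optimum for $\ge 9/10$ seeds) uses dimension
2, matching the sphere-type benchmark the optimizer is specified against.

## Metrics

From hard counts TP/TN/FP/FN the suite computes accuracy, precision,
specificity, recall (= sensitivity), Dice $2TP/(2TP+FP+FN)$ and F1
$2PR/(P+R)$. Computed from the same hard counts these last two are
algebraically identical (property-tested); published tables that show them
apart were presumably computed from soft probabilities, which is not
reconstructable from counts. Multiclass counts are **micro-aggregated**
(one-vs-rest 2×2 tables summed over classes): this choice exactly reproduces
the published three-class sensitivity and specificity values from their
printed counts, which macro averaging does not. A zero denominator yields
`NA` ("undefined"), never a silent 0. Percent formatting rounds half-up to
two decimals at presentation time only.

```{r}
computeMetrics(confusionCounts(10363, 10363, 241, 241))[["accuracy"]] * 100
```

AUC, IoU, cosine similarity and the regression-error metrics are out of
scope: they require operand vectors (scores/probabilities) that confusion
counts do not carry.

## Known limitations

* The shipped backbone is a deliberately small dense network; it validates
  the optimization machinery, not state-of-the-art image classification.
* Balancing before splitting (the default, matching the published totals)
  lets augmented copies of one original land on both sides of the split.
* FTRL is implemented in its unregularised proximal form; with L1/L2 set to
  zero it reduces to per-coordinate adaptive gradient descent.
* The augmentation warp composes rotation, shear, zoom and shift into one
  bilinear resampling; extreme simultaneous draws can push content outside
  the frame (zero fill), as with any reflection-free affine augmenter.
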