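---
title: "Methods: GTO-driven hyperparameter search for image classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GTO-driven hyperparameter search for image classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Convolutional classifiers for brain MRI — e.g. staging Alzheimer's disease
from T2-weighted axial slices — are notoriously sensitive to training
hyperparameters: the loss function, batch size, dropout rate, how much of a
pretrained backbone to unfreeze, the weight optimizer, the pixel-scaling
convention, and the whole battery of data-augmentation settings. `gtotune`
treats this selection problem as black-box minimization over the unit
hypercube and solves it with the Artificial Gorilla Troops Optimizer (GTO),
a swarm metaheuristic in which candidate solutions are "gorillas" and the
incumbent best is the "silverback".

The package implements the full loop: data acquisition and cleaning,
preprocessing, the solution encoding and its decoding to a concrete
training configuration, the optimizer, a trainable classifier harness, and
a micro-averaged confusion-metrics suite. Everything runs at desk scale on
a single CPU using a built-in synthetic brain-image generator, so the whole
pipeline is testable without downloading any imaging data.

## Solution encoding and decoding

A candidate is a vector $x \in [0,1]^{16}$. Fifteen hyperparameters are
decoded in a fixed order; the brightness interval consumes two elements
(each mapped to $[0.5, 2.0]$, returned sorted), which is why the
dimensionality is 16 rather than 15.

For a list-like domain with $L$ entries, element $v$ decodes to the entry
with 1-based index

$$ \mathrm{idx} = \min(\max(\lceil v L \rceil, 1), L), $$

so e.g. $v = 0.75$ over the 12-value batch-size grid $\{4, 8, \dots, 48\}$
gives index 9, batch size 36. The clamp handles the boundary draws $v = 0$
and $v = 1$ exactly. Continuous domains decode by linear interpolation
$lo + v\,(hi - lo)$. The decoding is monotone in $v$ for ordered numeric
domains, and the midpoints $(i - 0.5)/L$ enumerate each list domain
bijectively — both properties are exercised in the test suite.

The default domains are: 6 loss functions (categorical crossentropy,
categorical hinge, KL divergence, Poisson, squared hinge, hinge); batch
size 4–48 in steps of 4; dropout $[0, 0.6]$; fine-tuning ratio 1–100 (the
percentage of backbone layers left trainable, counted from the output
end); 11 weight optimizers (Adam, NAdam, AdaGrad, AdaDelta, AdaMax,
RMSProp, SGD, FTRL, SGD-Nesterov, centered RMSProp, AMSGrad-Adam); 4
scaling techniques; an augmentation on/off flag; rotation 0–45° (step 1);
width/height shift, shear and zoom $[0, 0.25]$; two flip flags; and the
brightness interval. When the augmentation flag decodes to off, the
sub-parameters are still decoded but flagged inactive, so two solutions
differing only in augmentation fields compare cleanly.

## The optimizer

Positions are initialized uniformly in the box,
$X = \mathrm{rand}\,(UB - LB) + LB$. Each iteration $t$ of $T$ performs an
exploration step and an exploitation step, each followed by greedy
acceptance (a candidate replaces its member only on a strict fitness
improvement; the silverback is the running argmin, so the best-fitness
trace is non-increasing by construction).

Exploration proposes, per member, one of three moves chosen by a uniform
draw against the migration probability $p$:
migration to an unknown place ($GX = (UB-LB)\,r_1 + LB$), approaching
another gorilla ($GX = (r_2 - C)\,X_r + L\,H$ with $H = Z \circ X_i$,
$Z \sim U(-C, C)$ per dimension and $X_r$ a random member), or migration
to a known place
($GX = X_i - L\,(L\,(X_i - X_r) + r_3\,(X_i - X_r))$).

Exploitation compares the decaying coefficient
$C = (\cos(2 r_4) + 1)(1 - t/T)$ with a threshold $w$: while $C \ge w$
members follow the silverback,
$GX = L\,M\,(X_i - X_{sb}) + X_i$ with $g = 2^L$ and
$M = (|\overline{X}|^{\,g})^{1/g}$ elementwise; once $C < w$ the
competition move $GX = X_{sb} - (X_{sb} Q - X_i Q)\,A$ takes over, with
impact force $Q = 2 r_5 - 1$ and violence vector $A = \beta E$ ($E$
per-dimension standard normal with probability 1/2, otherwise a broadcast
scalar). $L = C\,l$ with $l \sim U(-1, 1)$. Defaults are $p = 0.03$,
$\beta = 3$, $w = 0.8$.

Three numerical choices were genuinely open and are resolved as follows.

* **Boundary handling.** Candidates are clipped to the box after every
  move. Clipping is the simplest contract that keeps the decoding total
  (every element stays in $[0,1]$) and it never destroys a greedy
  improvement, since acceptance is evaluated after clipping.
* **Evaluation cadence.** Fitness is evaluated, and greedy acceptance
  applied, after *both* the exploration and the exploitation step of each
  iteration — so one run performs $N(1 + 2T)$ evaluations.
* **Random stream.** A single generator per run, consumed in a documented
  fixed order: iteration-level coefficient draws ($r_4$, then $l$) first,
  then member-major per-member draws with the branch draw preceding the
  branch-specific draws. This makes seeded runs bit-reproducible and lets
  the test suite compare a full trajectory against an independent scalar
  transcription of the update equations on the same stream. Stochastic
  fitness functions must not disturb this stream; `preserve_rng()` runs
  them on their own seeded stream and restores the caller's state.

On the 16-dimensional sphere benchmark ($N = 30$, $T = 500$, bounds
$[-100, 100]$) the implementation drives the median final best fitness to
numerical zero over 20 seeds; the acceptance suite asserts the much weaker
$< 10^{-2}$.

## Preprocessing

* **SNR cleaning.** The per-image signal-to-noise ratio is
  $\mathrm{mean}(X)/\mathrm{sd}(X)$ — the conventional single-number
  imaging SNR; no formula is prescribed alongside the 1.15 threshold, so
  the package adopts this definition and validates it against the
  generator's ground truth. Images with SNR below the threshold (default
  1.15) are removed before resizing; a constant image has SNR $+\infty$
  and is always kept. Cleaning is idempotent and order-preserving.
* **Resizing.** Bicubic resampling (Keys kernel, $a = -0.5$, kernel
  weights renormalized at the clamped edges) to $128 \times 128 \times 3$;
  grayscale inputs are replicated across channels. Constants are preserved
  exactly.
* **Scaling.** Four techniques, applied per image: normalize ($X/\max X$),
  standardize ($(X - \mu)/\sigma$), min–max, and max-abs ($X/|\max X|$;
  identical to normalize for non-negative pixels — both are implemented
  literally). Degenerate denominators raise errors rather than emitting
  NaNs; the fitness harness converts such failures into an infinite
  fitness sentinel.
* **Splitting.** Stratified, seeded: per class, `round(n_c * 0.15)` images
  go to test (within one image of the 15% target), and 10% of the
  remaining training share goes to validation. The validation share is a
  package default — only the 85/15 train/test ratio is prescribed by the
  study conditions.
* **Augmentation and balancing.** The augmenter composes one
  center-anchored affine warp (rotation, shear, zoom, shifts; bilinear
  sampling), Bernoulli(1/2) flips where enabled, and a multiplicative
  brightness factor drawn from the configured interval, clipped to
  $[0,1]$. Zero-width ranges draw nothing and are exactly inert, so the
  all-zero configuration is pixel-identical. Balancing is implemented as
  oversampling: each epoch, minority classes are topped up to the majority
  count with augmented copies (originals appear exactly once, unmodified);
  no undersampling is performed.

## Fitness

The harness decodes a solution, scales all images with the decoded
technique, block-averages each image to an $8 \times 8$ feature grid, and
trains a small dense softmax network — 64 inputs, hidden layers of 32 and
16 units (the "backbone" that the fine-tuning ratio freezes or unfreezes,
at least one layer always trainable), inverted dropout, $K$-way softmax —
for the configured number of epochs with the decoded loss, optimizer and
batch size. All six losses are differentiated through the softmax
analytically, and all eleven optimizer update rules are implemented with
their standard formulations and a single shared learning rate of 0.01
(the rate is not part of the searched space, so one stable value serves
every rule).

The scalar fitness is $1 - \mathrm{accuracy}$ on the evaluation set. The
loss value cannot serve as the objective because the loss function itself
is searched, making raw loss values incomparable across solutions. By
default the evaluation set is the entire dataset, matching the stated
procedure of the original study; `eval_on = "test"` restricts it to the
held-out split, which is the leakage-free choice we recommend for real
use. Each evaluation runs on its own RNG stream seeded from the training
configuration, so fitness is a deterministic function of (solution, data,
seed) and repeated evaluations are identical.

The eight named pretrained CNN backbones (DenseNet201 through Xception)
are declared in the `backbone_spec()` surface for interface completeness
but require an external deep-learning runtime and weight files; the
package's own classifier is the `toy_cnn`, and it is what every test and
the end-to-end loop exercise.

## Metrics

Confusion counts are micro-aggregated: one-vs-rest TP/TN/FP/FN accumulated
over all $K$ classes, giving $TP + FN = n$ and accuracy equal to micro
recall. Rate metrics use the standard textbook definitions; zero
denominators yield `NA`, never a silent 0. F-beta defaults to $\beta = 2$
(exposed as a parameter). AUC is one-vs-rest, macro-averaged, by
trapezoidal ROC integration. Probability losses follow the usual
elementwise conventions (hinge family on $\{-1, 1\}$ targets; means over
samples, elementwise losses additionally over classes).

The package ships reference confusion counts for eight fine-tuned CNN
backbones on two Alzheimer's MRI datasets, together with the metric values
published alongside them. `reference_metric_report()` recomputes every
cell from the counts and flags disagreements. Recall, specificity, Youden
index, FNR and fallout reproduce the published values to printed precision
in every one of the 16 model columns; precision, FDR, MCC and NPV
reproduce only in some columns, because the published tables mix
count-derived values with streaming/thresholded metric variants for those
entries. The acceptance suite asserts exactly the always-consistent cells
plus the fully consistent best-model row, and requires the remaining
disagreements to be confined to those four metrics — they are reported,
not asserted.

## The synthetic generator

Each class $c \in \{0, \dots, K-1\}$ is rendered as an elliptical "brain"
on a 0.35-gray background: a bright cortical ring whose intensity falls
linearly from 0.85 to 0.60 across classes, an interior at 0.55, and a
central dark "ventricle" whose radius grows with $c$ — a geometric proxy
for progressive atrophy. Small seeded jitters of the center and axes give
within-class variability, additive Gaussian noise (default SD 0.05) gives
texture, and pixels are quantized to the 8-bit grid so a written PNG tree
round-trips bit-exactly. Defaults are $K = 4$ classes and 25 images per
class, mirroring a small four-grade staging dataset.

A configurable fraction of images (default 10%) is replaced by pure noise
drawn from a zero-inflated uniform mixture (0 with probability 0.6,
otherwise $U(0.5, 1)$), whose population moments give
$\mathrm{SNR} \approx 0.79$ — comfortably below the 1.15 cleaning
threshold with no tuning, even after 8-bit quantization, while the
rendered brains sit near SNR 2.5. The generator's manifest records the
ground truth, so tests can assert that cleaning removes *exactly* the
injected images.

The class signal is geometric and low-frequency by design, so the toy
network can learn it from pooled features on a CPU in seconds. That is
also the generator's main departure from real MRI: it has no acquisition
physics, no texture detail, no inter-scanner variation, and its classes
are far more separable than clinical stages. Passing the end-to-end tests
therefore demonstrates that the pipeline is wired correctly — decoding,
training, evaluation, and greedy improvement — not that any particular
accuracy would transfer to clinical data.

## Problem sizes and budgets

The test and acceptance runs use deliberately small instances: oracle
trajectory checks at $N = 3$, $D = 2$, 2 iterations; the sphere benchmark
at $N = 30$, $D = 16$, $T = 500$ over 20 seeds; and the end-to-end loop on
3 classes × 15 images (32 × 32 px) with population 4, 2 iterations and
1 epoch. These sizes keep the full suite in the low minutes on one CPU
while still exercising every code path; the defaults in `run_config()`
(population 10, 10 iterations, 5 epochs, 85/15 split, SNR 1.15) remain
the study-scale conditions.

## Known limitations

* No real pretrained backbones are shipped; the harness's classifier is a
  dense network on pooled features, adequate for optimizer and pipeline
  validation, not for state-of-the-art imaging accuracy.
* Default whole-dataset evaluation reproduces the original procedure but
  leaks training data into the fitness signal; prefer `eval_on = "test"`.
* The class-per-folder reader handles PNG trees; DICOM series must be
  converted to PNG upstream.
* The search space is fixed-structure: the only conditional behaviour is
  the augmentation on/off flag.
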