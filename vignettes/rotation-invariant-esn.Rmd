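---
title: "Rotation-invariant classification of single-cell patches with echo state networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rotation-invariant classification of single-cell patches with echo state networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the idea

Cells in tissue sections occur at arbitrary in-plane orientations, and
consecutive maturation stages of white blood cells (myelocyte,
metamyelocyte, band cell) differ only subtly in nuclear shape while varying
strongly within each stage. A conventional image classifier must either
learn orientation explicitly or be trained on rotated copies of every patch.

`rotesn` takes a different route: a *static* square patch is turned into a
*temporal* signal by presenting its successive in-plane rotations, one degree
per time step, to a fixed random recurrent network — an echo state network
(ESN). Only the pixels inside the incircle of the patch are forwarded, so
every rotation presents exactly the same set of pixel positions and no
information enters or leaves the receptive field as the patch turns. For a
$20\times 20$ patch with radius $r = 10$ this receptive field has $L = 332$
pixels (membership: the rounded distance from a pixel center, on the
half-integer grid, to the patch center is at most $r$; equivalently distance
$< r + 0.5$). Strict center-in-circle membership would give 316 pixels and
corner-touching membership 352; the rounded-distance rule is the convention
that yields 332.

## Model

The reservoir is a sparse random matrix $W \in \mathbb{R}^{N\times N}$
(30% nonzero entries, uniform on $[-1,1]$) rescaled so that its spectral
radius equals $\rho < 1$ — the echo-state property, which makes reservoir
activity forget its past at a rate controlled by $\rho$. Dense input weights
$W^{\mathrm{in}} \in \mathbb{R}^{N\times(1+L)}$ (uniform, column 1 = bias)
inject the rotated-patch pixels, shifted and scaled to $[-1,1]$ so the
$\tanh$ units are not confined to their linear range. The driven update is

$$x(t+1) = (1-\alpha)\,x(t) + \alpha \tanh\!\big(W^{\mathrm{in}}[1; u(t)] + W x(t)\big),$$

with leaking rate $\alpha$ smoothing the temporal features. In *generative
mode* the input is switched off and the update runs on the remaining
activity alone,

$$x(t+1) = (1-\alpha)\,x(t) + \alpha \tanh(W x(t)),$$

with neither input nor bias. Skipping $\Delta\varphi$ rotation angles after
each external input (external inputs at recorded steps
$t \bmod (\Delta\varphi+1) = 0$, rotation angle $\varphi_0 + t$) lets the
classifier run on a fraction of the image presentations: with
$\Delta\varphi = 5$ the first 13 recorded steps contain exactly three
external inputs, at 0°, 6° and 12°.

Per patch, exactly 360 reservoir states are recorded. Each recorded column
of the state matrix $X \in \mathbb{R}^{(1+L+N)\times\Psi}$ is
$[1; u(t); x(t)]$ (the input rows are zero on generative steps, so the
readout must rely on reservoir features there). One linear readout per class
is trained one-versus-all by ridge regression in feature space,

$$W^{\mathrm{out}}_c = Y^{\mathrm{target}}_c X^{\mathsf T}\,(X X^{\mathsf T} + \beta I)^{-1},
\qquad \beta = 10^{-2},$$

solved by a stable symmetric solve rather than explicit inversion. (The
transposed-Gram form $X^{\mathsf T}X$ sometimes written for this estimator is
dimensionally inconsistent with readouts living in the
$(1+L+N)$-dimensional feature space; the feature-space form above is the
canonical ESN ridge solution.) Targets are piece-wise constant: every
recorded column of an image, generative columns included, carries that
image's one-hot label. At inference a patch's stream is harvested from rest,
per-step outputs $y_c(t) = W^{\mathrm{out}}_c [1;u(t);x(t)]$ are averaged
over a trimmed window $\Omega$ dropping the first and last 5% of recorded
steps (readout activity there is dominated by onset/offset transients;
$\lfloor 0.05\cdot 360\rfloor = 18$ steps per side, $|\Omega| = 324$), and
the class with the maximal mean score wins, ties to the smallest class
index.

During training, the per-image streams are concatenated in shuffled order
with zero-input gaps of uniform random length in $[50, 100]$ steps between
images, so the readout cannot learn the class sequence and the reservoir
"forgets" between images. Gap steps drive the reservoir through the bias
column with $u = 0$ but are *not* recorded — unlike generative steps, which
are part of an image's 360 recorded states. The reservoir state is zero at
stream start and carries over through gaps (no hard reset).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| $N$ | task-dependent (100–4000) | reservoir units; more units, more feature capacity |
| $\rho$ | 0.6 / 0.8 / 0.95 for $\Delta\varphi$ = 0 / 5 / 10 | spectral radius; slower decay for longer generative periods |
| $\alpha$ | 0.85 | leaking rate; temporal smoothing of features |
| connectivity | 0.3 | fraction of nonzero recurrent weights |
| $\beta$ | $10^{-2}$ | ridge regularization |
| $\Delta\varphi$ | 0 | skipped rotation angles per external input |
| trim | 0.05 | inference-window trim per side |
| gap range | [50, 100] | zero-input steps between training images |

The $(\Delta\varphi, \rho, \alpha)$ pairings reflect that a longer
generative period needs slower activity decay: there must be activity left
when the next input arrives. With the leaky generative update the asymptotic
decay rate of $\|x\|$ is $1 - \alpha(1-\rho)$ per step — about 0.66 at
$\rho = 0.6$ but about 0.96 at $\rho = 0.95$, where a few hundred steps are
needed to reach numerical rest ($\|x\| < 10^{-6}$). The gap range $[50,100]$
comfortably resets the reservoir for small radii and approximately for
large ones.

## The random-forest baseline

The comparison classifier is a classification random forest on the raw
$20\times 20$ gray patch. Each internal node tests
$I(p_1) - I(p_2) \le \theta$ for a random pixel pair; 100 pairs × 20
thresholds = 2000 candidate tests per node (far more than the conventional
$\lfloor\sqrt{p}\rfloor = 20$ for $p = 400$ features), each scored by Gini
impurity decrease on a random subsample of at most 200 node samples, with
the winning split applied to the full node data (ties to the first-sampled
candidate; a best decrease of exactly zero makes the node a leaf, since such
a split cannot improve purity). Thresholds are drawn uniformly between the
minimum and maximum pair difference observed on the evaluation subsample, so
no candidate is trivially dead. Leaves arise at the depth limit or below 100
samples and store normalized class histograms; trees see all training data
(no bagging — decorrelation comes from the split search alone), and the
forest averages leaf histograms. Rotation invariance is bought
conventionally, by replicating every training patch at
$360/\max\{\Delta\varphi, 1\}$ rotation angles. (Note the deliberate
asymmetry: the ESN stream places external inputs every $\Delta\varphi + 1$
degrees following the worked 0°/6°/12° example, while the RF augmentation
count follows the $360/\max\{\Delta\varphi,1\}$ rule; the two conventions
are kept as stated rather than reconciled.)

## Metrics

Per class (one-vs-rest): precision, recall, specificity and F1; the overall
accuracy is the class-distribution-weighted mean recall
$\mathrm{ACC} = \sum_c \frac{n_c}{n}\mathrm{REC}_c$, which equals the
fraction of correctly classified samples. (Written with true-positive
*counts* instead of rates this formula would not be an accuracy; the
recall-rate reading is the dimensionally consistent one and is what the
package computes.) Ratios of the form 0/0 are reported as 0 with a warning.
Precision–recall curves use all distinct score thresholds and the step-wise
average-precision rule for the AUC.

## What the synthetic generator emulates — and what it does not

The original bone-marrow dataset (944 patches from two patients) is not
public. The generator emulates its statistical structure: centered,
hematoxylin-dark nuclei as noisy, possibly lobed ellipses at uniformly
random orientation with chromatin-like speckle, a lighter cytoplasm rim, a
bright textured background, a textured background *class* with off-center
clutter and no centered object, native $33\times 33$ patches resized to
$20\times 20$, and the reference class proportions 69 : 56 : 61 : 65 : 70
with a 66/34 train/test split and stratified cross-validation folds. A
separability knob $\delta$ moves consecutive class means apart in nucleus
radius, intensity, elongation and lobedness (round → indented →
band-shaped, mimicking the maturation progression); $\delta = 0$ makes all
foreground classes identically distributed.

What it does not emulate: stain-color variation (the pipeline is
gray-scale by design), scanner noise and focus artifacts, patient-level
batch structure, scale variation, and the long-tailed morphology of real
marrow. Passing tests on synthetic data therefore demonstrate the
*mechanics* of the method — rotation-invariant prediction, capacity and
skip-period trends — not clinical-grade performance on H&E histology.

## Numerical choices and degenerate inputs

* Incircle membership: distance $< r + 0.5$ on half-integer centers (no
  ties are possible: a tie would need an odd-integer sum of two odd squares
  equal to $(2r+1)^2$, which is impossible mod 8).
* Rotation: counterclockwise on display axes, bilinear, about the geometric
  patch center; samples outside the source grid are 0 — they lie outside
  the incircle and are never read by the receptive field. Quarter turns are
  exact index permutations. Resizing aligns pixel centers and replicates
  borders.
* Reservoir sampling: exactly `round(connectivity * N^2)` (at least 1)
  nonzero positions; a sample with numerically zero spectral radius is
  rejected and redrawn with a diagnostic. After rescaling, the spectral
  radius equals $\rho$ to machine precision of the eigensolver.
* Harvesting applies the exported update functions step by step, so
  harvesting a continuous stream is bit-identical to manual stepping (a
  batched BLAS formulation would differ in the last bits and was rejected
  for that reason).
* Ridge: `solve()` on the symmetric regularized Gram matrix; column
  (recorded-step) order cannot change the solution.
* Ties in the winner class and in split selection go to the smallest index
  / first-sampled candidate; the inference trim uses `floor` on both ends.
* "Circular distortion" for augmentation is a center-anchored swirl whose
  angular displacement decays linearly from ±35° at the center to zero at
  the incircle edge — the closest standard operator to a warp that twists
  the cell body while keeping the patch border fixed.
* Random starting angles for robustness evaluation are uniform integers in
  $[0, 359]$ and may fall inside a skipped-angle period.
* Cross-validation re-randomizes stratified folds per repeat and derives
  per-fold reservoir seeds from `(master seed, repeat, fold)`, so repeats
  are independent but every record is exactly reproducible. Folds stratify
  by class *and* source patch, so augmented variants of one source never
  straddle folds — a conservative policy against augmentation leakage.

## Problem sizes used by the test suite

The package's own evaluation runs at desk scale, chosen once as realistic
miniatures of the method's operating conditions:

* Rotation-robustness: three well-separated classes ($\delta = 1.5$),
  150 patches, 66/34 split, $N = 500$, $\Delta\varphi = 5$; the trained
  classifier must give the same label at starting angle 0 and at a random
  starting angle for at least 95% of test patches.
* Capacity/skip trends: the five-class default distribution at scale 0.2
  (64 patches) and moderate separability $\delta = 0.75$, three independent
  3-fold cross-validations; mean accuracy must be non-decreasing in
  $N \in \{100, 200, 500\}$ and non-increasing in
  $\Delta\varphi \in \{0, 5, 10\}$, each within one standard deviation.

## Known limitations

* Training forms the full recorded state matrix in memory; at $N = 500$ and
  a few hundred images this is a few hundred MB. Streaming accumulation of
  the Gram matrix would lift this ceiling.
* The reservoir loop is interpreted R; large sweeps ($N \gtrsim 2000$,
  thousands of patches) are supported but slow.
* The generative-mode decay bound above means very large spectral radii
  combined with long gaps leave residual activity between images; the
  zero-input gaps are long enough in practice but are not a hard reset.
* No output feedback, online training, nonlinear readouts or classifier
  ensembles; cell detection/localization in whole slides is out of scope —
  patches are assumed centered on a single cell.
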