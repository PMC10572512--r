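---
title: "Methods: enhancement, fusion and marine-predator feature selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enhancement, fusion and marine-predator feature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dermafuse)
```

This vignette explains the models and procedures the package implements,
the design decisions taken where the design was genuinely open, and what
the synthetic-data experiments do and do not demonstrate.

## 1. Contrast enhancement

### Luminance model

Every pixel's lightness is computed as the CIELAB transform
$L^\* = 116\,f(Y) - 16$, where $Y$ is the weighted channel sum with
Rec.709-type weights $\{0.212, 0.715, 0.072\}$ and
$f(Y) = Y^{1/3}$ for $Y > 0.008856$, else $7.787\,Y + 16/116$ — the
standard cube-root/linear piecewise function, with the knee and linear
constants of the CIELAB convention. The three weights are normalised to
sum to one, so the weighted sum is a relative luminance with white at
$Y = 1$: a pure-white image maps exactly to $L^\* = 100$ and black to 0.
This normalisation is what makes the transform agree with an independent
scalar CIELAB $L^\*$ reference to $10^{-6}$, which the test suite checks
on 1000 random RGB triples.

### Texture residual and activation

The luminance map is smoothed with a truncated discrete Gaussian kernel
(half-width $\lceil 3\sigma \rceil$, reflective borders — deterministic
and directly checkable against a naive $O(nk^2)$ convolution, which the
suite does). The texture residual is the relative difference

$$\rho = \frac{L}{\varphi} - L = \frac{L\,(1-\varphi)}{\varphi},$$

with the smoothed map $\varphi$ epsilon-floored at $10^{-6}$ before
division. The two algebraic forms are verified to agree to $10^{-10}$.

The activation rule flags lesion pixels where $\rho > \varphi$. Two scale
choices make this rule meaningful:

* **The map.** The inequality is evaluated on the *linear relative
  luminance* $Y \in [0,1]$, not on the compressed $L^\*$ scale. When
  $\varphi$ varies slowly, $\rho > \varphi$ reduces to
  $Y(1-Y) > Y^2$, i.e. $Y < 0.5$: a soft darkness detector. On the
  $L^\*/100$ scale the cube-root compression pushes even dark lesions
  above 0.5 and the mask would be empty; on the raw $[0,100]$ scale the
  residual is negative wherever $\varphi > 1$ and the rule can never fire
  at all.
* **The scale $\sigma$.** The spatial smoothing scale is the population
  standard deviation of the $[0,100]$ lightness values,
  $\sigma = \sqrt{\overline{L^2} - \bar L^2}$, read in pixel units
  (typically 5–25 px). This single statistic adapts the texture scale to
  the image's global contrast.

At these defaults the mask is a conservative, high-precision partial
cover of the lesion (mean intersection-over-union ≈ 0.2 against the
generator's ground truth over seeds 1–10, every seed > 0.05); it also
picks up hairs, which are genuinely dark. That is sufficient for its role
here — steering the tone mapping — and no morphological post-processing
is attempted.

### Tone mapping and Retinex

The masked lesion pixels' lightness is darkened by the exponent
$1/\gamma$ with $\gamma = 0.8$ (so $L \mapsto 100\,(L/100)^{1.25}$),
while skin pixels are untouched. Darkening, not brightening, is the
correct direction: the goal is to widen the gap between the darker lesion
and the brighter skin, and an exponent $>1$ on a $[0,1]$ scale lowers
values below 1.

Colour adjustment is single-scale Retinex in CIELAB: each of the L, a, b
channels is divided by its Gaussian-smoothed version (sign-preserving
epsilon guard at $10^{-6}$), min–max rescaled to the channel's original
range, and converted back to RGB with clipping to $[0,1]$. Two different
Gaussian scales therefore appear in the pipeline:

* the **texture scale** $\sigma$ above (5–25 px), used for the residual
  and activation;
* the **illumination scale** for the Retinex division, default
  $\min(H,W)/3$. The division removes structure *below* its scale, so the
  scale must exceed the lesion diameter: dividing at the texture scale
  would flatten the lesion itself and destroy exactly the contrast the
  stage is meant to create. $\min(H,W)/3$ is the usual single-scale
  Retinex choice.

With this composition the Michelson contrast between mean lesion and
mean skin lightness (measured on ground-truth regions) increased on 50
out of 50 seeded synthetic images in the packaged experiment, and the
coefficient of variation of the healthy-skin region decreases whenever a
multiplicative illumination gradient is present. On images with no
planted lesion the mean lightness moves by ≈ 1%, well within the ±10%
stability band the tests assert.

## 2. Serial–harmonic-mean fusion

The two feature sources (at pipeline scale, 1024- and 1920-column CNN
feature matrices; in the tests, generated matrices) are concatenated
column-wise. Each column is then scored by the **maximum absolute
Spearman rank correlation** against all columns of the *other* source.
The idealised quantity here is maximal correlation — the supremum of
correlation over all Borel transforms of the pair — which is not
computable directly; restricting the supremum to monotone transforms
yields exactly the rank correlation, is deterministic, and keeps the
"find the strongest cross-network association" intent. Constant columns
score 0 by convention. Scores are folded to $[0,1]$ by absolute value
because the harmonic mean below is undefined for non-positive entries;
zeros are floored at $10^{-6}$.

The retention threshold is the harmonic mean $H = k/\sum_i 1/f_i$ of the
scores. Since $H \le$ arithmetic mean (with equality only for constant
scores), thresholding at $H$ always retains at least as many columns as
the arithmetic-mean threshold — the threshold deliberately gives small
scores more influence so that moderately associated features survive.
Columns scoring $\ge H$ are kept; if the threshold would discard
everything, the single best column is kept and a warning raised.

A per-row (per-sample) reading of the cross-source correlation is
arithmetically impossible for sources of unequal width, so the
per-column reading is used. An optional `max_pairs` argument bounds the
$O(d_1 d_2 R)$ scoring cost by a seeded subsample of companion columns;
the default is exhaustive.

## 3. Marine Predator Algorithm with Rényi-entropy gating

### Encoding and fitness

The MPA is a continuous optimiser, so candidate solutions are positions
in $[0,1]^d$; a feature is selected when its coordinate $\ge 0.5$. The
wrapper fitness of a mask is the misclassification rate of a 5-nearest-
neighbour classifier under stratified 2-fold cross-validation on the
masked columns (empty masks are penalised with fitness 1). The fold
assignment is drawn once per run from the master seed, so fitness is a
deterministic function of the mask — without this, the elite's
"best-so-far" bookkeeping would compare errors measured on different
splits. Fitness values are memoised by mask. No cardinality penalty is
applied.

### Dynamics

With population $N = 20$ (a conventional size for this family of
optimisers), iterations $t_{\max} = 200$, step constant $F = 0.4$ and
FADs rate 0.4:

* **Phase 1** ($t < t_{\max}/3$): $V = R_B \otimes E - R_B \otimes P$,
  $P \leftarrow P + F\,R \otimes V$, with $R_B$ standard normal
  (Brownian) and $R$ uniform.
* **Phase 2** ($t_{\max}/3 \le t < 2t_{\max}/3$): the first half of the
  population takes the same step with Lévy draws $R_L$; the second half
  takes $V = R_B \otimes (R_B \otimes E - P)$,
  $P \leftarrow P + F\,\mathrm{AP}\,V$, where
  $\mathrm{AP} = (1 - t/t_{\max})^{2t/t_{\max}}$ decays from 1 to 0.
* **Phase 3** ($t \ge 2t_{\max}/3$): Lévy exploitation around the elite,
  $V = R_L \otimes (R_L \otimes E - P)$,
  $P \leftarrow E + F\,\mathrm{AP}\,V$.
* **FADs step**: with per-individual probability 0.4, a bounded random
  jump masked by a Bernoulli(0.4) binary vector and scaled by AP;
  otherwise a move along the difference of two *distinct* random
  individuals (the printed difference of an individual with itself would
  be identically zero). Positions are clipped to $[0,1]$ after every
  update.

Lévy steps use Mantegna's algorithm with stability index $\beta = 1.5$.
The elite matrix replicates the best position found so far (ties broken
by lowest index), so the best fitness is non-increasing by construction —
asserted over full 200-iteration runs, together with bound preservation
after every single update. Each phase rule and the FADs rule are also
checked, with pinned random draws, against a literal per-individual
transcription to $10^{-12}$. The original algorithm's marine-memory
refinement is not part of this variant.

### Entropy gate

Before fitness evaluation each iteration, every position is normalised
to a probability vector and its Rényi entropy
$\mathrm{Ent}_\alpha(p) = \log(\sum_i p_i^\alpha)/(1-\alpha)$ (natural
log, $\alpha = 2$) is divided by $\log d$ to give a spread measure in
$[0,1]$. Individuals at or above the population median are re-evaluated;
the rest keep their previous fitness for that iteration. The raw
formulation compares a position value with an entropy value, which are
incommensurate scales; the median gate keeps the stated intent — cull the
most concentrated candidates from the expensive fitness evaluation —
while being well-defined. All-zero rows count as uniform, and ties at
the median pass.

### What the selector can and cannot recover

On a small instance (8 features, 60 samples) the selector's final
fitness matches exhaustive enumeration of all 255 nonempty subsets
(same CV folds) within 0.02 on 10/10 seeds in the packaged experiment.
At larger scale (200 features, 20 informative, class separation 2 SD,
n = 300) the k-NN error of almost any mask containing a handful of
informative columns is exactly 0: the fitness landscape is flat at its
optimum, the elite freezes on the first zero-error candidate, and the
recall of planted informative columns stays near the 0.5 rate of the
uniform initialisation (≈ 0.5–0.6 observed). This is a property of an
error-only wrapper fitness on strongly separable data, not of the
optimiser: selected-subset accuracy still matches the all-features
baseline, but the selector exerts no pressure to include *all*
informative columns once a sufficient subset is found. A cardinality or
margin term in the fitness would change this behaviour; it is
deliberately not added, keeping the fitness the plain classifier error.

## 4. Evaluation

Splits are stratified per class (default 50:50, seeded). Reported
metrics are percentages: accuracy, macro-averaged recall, precision and
F1, and FNR defined as $100 -$ macro recall (the standard complement of
sensitivity; a definition via precision is sometimes seen in print but
is not a false-negative rate). Classifier names map to open equivalents:
quadratic/cubic SVM are polynomial-kernel SVMs of degree 2/3
(`e1071::svm`), `fine_tree` is an `rpart` tree with small minimum split,
`gaussian_nb` is `e1071::naiveBayes`, weighted/cubic k-NN are 10-NN with
inverse-distance weights and Minkowski $p=3$ respectively (implemented
in-package with BLAS distance matrices, since no installed package
offers both options), and narrow/medium/wide NN are single-hidden-layer
`nnet` networks of sizes 10/25/100. Exact parity with any proprietary
implementation of these names is a non-goal.

## 5. Synthetic data

`make_lesion_image()` draws a darker elliptical lesion (darkening factor
0.45) whose border radius is perturbed by three sinusoidal harmonics
(irregularity amplitude 0.15), on a skin-toned background (RGB
0.85/0.62/0.50) with a multiplicative corner-to-corner illumination ramp
(strength 0.25), three dark quadratic hair strokes and additive Gaussian
noise (SD 0.02) — one instance of each artifact class that makes real
dermoscopy hard, at magnitudes chosen to be visible but not dominant.
The exact pre-noise lesion region is returned as ground truth.
`make_feature_dataset()` plants class-informative Gaussian columns
(class means separated by `effect_size` within-class SDs, random class
ordering per column), cross-source duplicate pairs related by the
strictly monotone map $\sinh(x/2)$ (rank correlation exactly 1), and
independent noise columns. Both generators are bit-reproducible given
their seed.

What passing these tests shows: the formulas are implemented correctly,
the optimiser obeys its invariants, the fusion threshold behaves as the
algebra predicts, and the enhancement increases region contrast under
controlled illumination/noise/hair artifacts. What it does not show:
performance on real dermoscopic images — synthetic lesions lack pigment
networks, vascular patterns, colour variegation and camera artifacts,
and the handcrafted histogram/region-statistics features are far weaker
than CNN features, so absolute accuracies here say nothing about
benchmark accuracy on clinical datasets.

## 6. Numerical choices and problem sizes

Epsilon floors: $10^{-6}$ for all guarded divisions ($\varphi$, Retinex
denominators, fusion scores). Identity checks are asserted at
$10^{-10}$–$10^{-12}$; Monte-Carlo checks at CLT-scale bounds. The
packaged experiments use deliberately modest sizes — 50 images of
96×96 px for the contrast experiment, 60-sample/8-feature instances for
exhaustive enumeration (60 optimiser iterations suffice there; the
fitness is memoised over at most 255 masks), and one 300×200 run at the
full 200 iterations — sizes at which every experiment is exactly
reproducible and the whole suite runs in a few minutes on one CPU.
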