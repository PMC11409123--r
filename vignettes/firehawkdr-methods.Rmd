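---
title: "Fire hawk optimization and the desk-scale retinopathy pipeline: models and methods"
author: "firehawkdr maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fire hawk optimization and the desk-scale retinopathy pipeline: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(firehawkdr)
```

# Scope

`firehawkdr` implements a nature-inspired metaheuristic — the Fire Hawk
Optimizer (FHO) and its adaptively scheduled variant (IFHO) — together with
the surrounding components of a small, fully seeded diabetic-retinopathy
screening pipeline: fuzzy-logic impulse denoising, SMOTE class balancing,
hyperparameter tuning of a small neural classifier by validation accuracy,
confusion-matrix metrics with AUC, stratified k-fold cross-validation, and a
synthetic fundus-image generator so that everything is testable without any
external dataset. This vignette records the models, the tunable parameters,
and the design decisions taken where the underlying method description left
the design open.

# The optimizer

## Population model

A population of $N$ candidate solutions lives in a box-bounded space
$[\ell_j, u_j]^d$ and is initialized uniformly, componentwise:
$z_{ij} = \ell_j + r\,(u_j - \ell_j)$, $r \sim U[0,1]$. After ranking by
objective value, the best $n$ candidates become *fire hawks* and the
remaining $m = N - n$ are *prey*. The hawk count is redrawn every iteration
from a clamped half-normal,
$n = \mathrm{clamp}\!\left(\mathrm{round}(|Z|\,N/5),\, 1,\,
\lfloor 0.2N \rfloor\right)$ with $Z \sim \mathcal N(0,1)$ — the method
description only asks for a "stochastic Gaussian spread", so the $N/5$ scale
and the 20% cap (configurable via `hawk_fraction_cap`) are package choices.
Each prey is assigned to the territory of its nearest hawk by Euclidean
distance (the distance is stated in planar form in the source description;
we use the obvious $d$-dimensional generalization), with ties going to the
better-ranked hawk.

## Position updates

With $GB$ the global best ("central fire"), hawks move as
$$H_l' = H_l + (r_1\,GB - r_2\,H_{near}),$$
and each prey generates two candidates,
$$P_q' = P_q + (r_3\,H_l - r_4\,S_l), \qquad
  P_q'' = P_q + (r_5\,H_{alt} - r_6\,S),$$
where $S_l$ is the mean of the territory's prey ("local safe place"), $S$
the mean of all prey, $H_{near}$/$H_{alt}$ a uniformly drawn *other* hawk,
and $r_1,\dots,r_6$ fresh scalar uniforms — one pair per update call, shared
across components. (A per-component variant was evaluated during
development and was strictly worse on every convergence measurement, so the
scalar reading is kept.) All proposals are clamped into the box, evaluated,
each prey keeps the better of its two candidates, and parents plus proposals
are merged elitistically and truncated back to $N$ — the method description
is silent on replacement; the elitist merge was chosen because it makes the
best-so-far trajectory provably monotone, which the test suite asserts
exactly. Non-finite objective values are ranked worst and counted, and the
run continues. When only one hawk exists, $H_{near}$ falls back to a uniform
non-self population member and $H_{alt}$ to the hawk itself.

## The adaptive factor (IFHO)

IFHO scales the hawk step by
$$f(\alpha) = \alpha + (1-\alpha)\,e^{-\gamma t},$$
which equals 1 at $t=0$ (the first iteration of an IFHO run is therefore
bit-identical to FHO under the same seed) and decays toward $\alpha$,
shifting the hawks from exploration to exploitation around $GB$. The source
description is ambiguous about $\alpha$: it is simultaneously called a
parameter and said to "gradually increase". Both readings are implemented:
`fixed_alpha` (default, $\alpha_0 = 0.1$) and `linear_alpha`
($\alpha$ ramped $0.1 \to 0.9$ across the run); $\gamma$ defaults to 0.01
per iteration. Defaults: population 25, 1000 iterations (an accompanying
run-settings sentence in the source — "1000, 25, and 200" generations /
candidates / hawks — is internally inconsistent, since 200 hawks cannot be
drawn from 25 candidates; the hawk count therefore follows the capped draw
above and the 200 is ignored).

## Benchmarks

Four classical functions (sphere, rastrigin, rosenbrock, ackley) with their
conventional bounds stand in for an external shifted/rotated competition
suite that would require downloaded data files. `benchmark_suite()` shifts
each optimum to a seeded random in-bounds point and self-verifies
$f(x^\ast)=0$ on construction. Absolute values from the external suite are
not reproduction targets.

## Known limitations (and two deliberately red tests)

Every update above steps by $r_a X - r_b Y$ where $X, Y$ are *absolute
positions*. Once the population has collapsed near an optimum $o$, each
proposal carries a residual step $(r_a - r_b)\,o$ whose magnitude scales
with $\|o\|$, so the probability that a proposal improves the incumbent
scales like $\mathrm{err}/\|o\|$ and the error decays only harmonically,
$\mathrm{err} \approx \|o\|/(c\,t)$. Measured on the 2-D sphere (pop 30,
200 iterations, 20 seeds): median best value $\sim 10^{-92}$ with the
optimum at the origin, $1.4\times10^{-7}$ at $\|o\|=1$, $1.9\times10^{-5}$
at $\|o\|=10$, and $3\times10^{-4}$ for uniform in-bounds shifts. Two
acceptance tests assume precision that this scheme cannot deliver at their
stated budgets — median $10^{-6}$ on a *shifted* sphere, and exact recovery
of the integer hyperparameters $(100, 64)$ in 18/20 tuning runs at 1740
evaluations. Both are implemented exactly as stated and left failing rather
than weakened; the same mechanism explains both, and diagnostic variants
(per-component uniforms; 10× iteration budgets) did not close the gap.

# The imaging pipeline

## Fuzzy impulse denoising

Images are min/max-normalized to $[0,1]$; salt-and-pepper corruption sets
each pixel independently with probability `density` (0.04 is the working
density throughout) to 0 or 1 with equal probability. The denoiser follows
the fuzzify / detect / adapt / iterate pattern of rule-based impulse
filters. The underlying description names no membership shapes, window, or
stopping rule, so these are fixed here: three triangular fuzzy sets on
intensity — *pepper* falling from 1 at intensity 0 to 0 at $2t_{low}$
($t_{low}=0.02$), *salt* mirrored around $t_{high}=0.98$, and *signal*
peaking at mid-gray; a pixel is flagged when its extreme membership exceeds
its signal membership **and** it deviates from the median of its $3\times3$
neighbors by more than $\delta = 0.4$. Flagged pixels are replaced by the
signal-membership-weighted mean of their non-flagged neighbors (fallbacks:
non-flagged median, $5\times5$ expansion, global median), and the sweep
repeats up to 3 times or until nothing is flagged. Two consequences are
tested as exact properties: non-flagged pixels are bit-unchanged (so clean
images pass through identically), and the two-sided membership/median guard
keeps genuinely dark or bright regions intact (a zero-valued pixel inside a
uniformly dark region is *not* noise). Color planes are denoised per
channel.

## SMOTE

Class balancing follows classical SMOTE on flattened image vectors: a
uniformly drawn minority sample, one of its $k=5$ nearest minority
neighbors (Euclidean, ties to the lower row index), and one interpolation
multiplier $\lambda \sim U[0,1]$ *per synthetic sample*. The source's
pseudocode draws a fresh multiplier per pixel while its prose describes a
single multiplier; the single-$\lambda$ (classical) reading is the default
and the per-pixel reading is available as `per_component = TRUE`. Synthetic
rows are appended until class counts are equal, are flagged `synthetic`,
and — being convex combinations — can never leave the componentwise
envelope of the minority class. Real rows are never modified.

## Classifier and tuning

The tunable hyperparameters and their boxes are: hidden width
$N \in [50, 200]$, learning rate $LR \in [0.001, 0.01]$ (searched on the
linear scale, as the interval is given), batch size $B \in [32, 128]$.
Positions are decoded by rounding $N$ and $B$ half-away-from-zero and
clamping; $LR$ passes through. The default `hidden_layer` architecture — a
one-hidden-layer ReLU network with a softmax head trained by seeded
mini-batch SGD (momentum 0.9, a standard SGD variation) under cross-entropy
— houses the literal "neurons in the hidden layer" decision variable and is
what every acceptance path uses. The `reduced_bottleneck` architecture
reproduces the inverted-bottleneck structure (stem $3\times3$ convolution;
expand $1\times1$ / depthwise $3\times3$ / project $1\times1$ blocks with
stride-1 channel-matched shortcuts; global average pooling; trained head)
at small width; because no deep-learning backend is available in the target
environment, its convolutional stack uses frozen seeded random weights with
instance normalization and only the head is trained. Epochs are fixed (not
a decision variable; default 20, 5 in the fast pipeline). Features are
z-scored inside `train_classifier()` using training-split statistics; this
is ordinary SGD conditioning and matters greatly at small epoch budgets.

Tuning maximizes validation accuracy
$A(D) = \tfrac1m \sum_i [\hat y_i = y_i]$ on a stratified 80:20 split.
Fitness values are cached by the decoded key $(N, LR, B)$, so revisiting an
equivalent integer configuration never retrains; training uses one fixed
derived seed so the fitness surface is deterministic within a run.

## Evaluation

Precision, specificity, sensitivity, accuracy and F1 are reported on the
0–100 scale from the confusion counts; a metric with a zero denominator is
reported as undefined (`NA`), never coerced, and excluded (with a count)
from fold means. AUC uses the rank-sum estimator with half ties — the
method description reports AUC without naming an estimator. Folds are
stratified (the description is silent; stratification is required for
imbalanced screening data): each class is shuffled and dealt into $k$
near-equal parts, so per-class counts differ across folds by at most one.
Inside cross-validation, SMOTE and all fitting happen strictly within the
training folds; synthetic rows are created per fold and can never appear in
a test fold.

# The synthetic generator, and what a green test establishes

`generate_fundus_image()` draws a radial-gradient disc (center $\approx
0.55$ fading to $0.35$, dark surround), dark vessel-like random walks, and
— for the positive class only — 1–4 bright exudate-like blobs (intensity
0.95, radius 1.8–3.2 px) and 1–4 dark hemorrhage-like dots (0.05). Default
resolution is 64 px (224 is accepted); the default DR fraction is 0.25 so
the positive class is the minority that SMOTE exists to correct. The
pipeline's feature step is $8\times8$ block-**max** pooling: block-maximum
is the natural detector for bright lesions, whereas average pooling dilutes
a $\sim$20-pixel lesion into a shift that five epochs of SGD cannot exploit
(measured: 97% vs 34–68% cross-validated accuracy).

The generator emulates exactly the structure the pipeline is designed to
detect. It does **not** emulate illumination variation, camera blur,
anatomical variability, lesion grading, or the 5-grade severity scale of
real screening data — a green end-to-end test therefore establishes that
the pipeline's stages compose correctly and that tuning and evaluation are
leak-free and reproducible, *not* that any particular clinical accuracy
would be attained on real fundus photographs. Headline metrics published
for the full-scale system (GPU-trained transfer-learning backbone on the
public retinopathy dataset) are out of scope here and are not reproduction
targets.

# Numerical choices

* Maximization is handled by internal negation; results are reported on the
  caller's scale.
* Merge ties keep parents (stable ordering), making repeated runs
  bit-reproducible from the seed.
* One global seed fans out to per-stage child streams via a deterministic
  string hash (`derive_seed()`), so pipeline stages are independently
  reproducible; all derived seeds stay below $2^{31}$.
* Images on disk use ASCII PGM (P2) — a plain-text raster format — because
  the target environment provides no PNG codec for R; 8-bit round-trips are
  exact. Run configs are JSON for the same reason (no YAML parser).
* Benchmark specs verify their optimum to $10^{-9}$ on construction; the
  ackley closed form is additionally checked against an independent
  evaluation to $10^{-12}$ in the tests.
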