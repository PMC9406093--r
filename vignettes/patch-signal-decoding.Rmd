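---
title: "Models and methods behind patchkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind patchkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchkit)
```

patchkit models a thin multi-node resistive skin patch and implements its
full signal-analysis pipeline. This vignette explains the models, the
tunable parameters, the synthetic-data generator that defines the test
conditions, and the numerical and design choices made where the design was
genuinely open.

## Transduction model

Each node and a reference resistor form a voltage divider,
$V_{out} = V_{in} R_{ref} / (R_{patch} + R_{ref})$, followed by linear ADC
quantization against the $V_{in}$ reference. Full contact
($R_{patch} = 0$) returns $V_{in}$; no contact is an *open circuit*,
represented by the `Inf` sentinel rather than a large finite resistance so
that $V_{out} = 0$ exactly. `transduce()` is strictly decreasing in
$R_{patch}$; after quantization the composition is only weakly monotone
because of rounding plateaus.

The ADC reference scale of the hardware is not published; the default is
**10 bits** (full scale 1023), which comfortably contains the
100–250-count signals the calibration law implies, and `adc_bits` is
configurable. Likewise $V_{in}$ (3.3 V) and $R_{ref}$ (10 kΩ) are
conventional defaults — only their ratios to $R_{patch}$ matter
downstream. The node count is free (default 10 dynamic / 6 static)
because the sensor is size-cuttable.

## Curvature geometry

Static mode treats a skin protrusion as the osculating circle of the
surface profile: curvature is
$\kappa = |y''x' - x''y'| / (x'^2 + y'^2)^{3/2}$, the reciprocal of the
osculating radius. The $3/2$ exponent in the denominator is the only
choice for which a circle of radius $r$ returns $\kappa = 1/r$, and the
implementation is verified against that oracle with sampled circles at
three radii, under refinement and under random rigid motions.

Derivatives use 3-point central differences with non-uniform-spacing
formulas (exact for quadratics); endpoints are excluded (an index must be
at least two samples from either end) rather than falling back to
one-sided stencils of lower order. A zero tangent raises a singularity
error rather than returning an arbitrary value.

## Buckling of the wrinkling skin

Wrist wrinkles are rationalized by a Timoshenko beam on an elastic
foundation reduced to second order,
$(P - k_p\bar{EI} - k_w\kappa_s\bar{GA})\,\nu'' + k_w\kappa_s\bar{GA}\,\nu = 0$,
where $\kappa_s$ is the shear correction factor — deliberately named
`kappa_shear` in code to keep it distinct from geometric curvature. The
equation is implemented exactly in this grouped form without re-deriving
the underlying foundation model.

Boundary conditions are not prescribed by the source mechanics, so the
standard pinned–pinned benchmark is used: $\nu(0) = \nu(L) = 0$ gives
sinusoidal modes and the closed-form critical load
$P_n = k_p\bar{EI} + b + b\,(L/n\pi)^2$ with
$b = k_w\kappa_s\bar{GA}$. Two independent routes exist: the closed form
(`buckling_solution()`) and a finite-difference eigen-solve
(`buckling_critical_load_fd()`, 400 interior points with $h^2$ Richardson
extrapolation over a doubled grid), which agree to better than $10^{-6}$
relative for modes 1–3. When $b = 0$ the reduced equation admits no
sinusoidal bifurcation and an explicit no-buckling result is returned
instead of an exception. Residual checks evaluate the equation on the
returned profile with a fourth-order stencil.

## Calibration

Fabrication non-uniformity gives each node a fixed multiplicative gain
deviation. On a uniform-curvature surface the correction factor of node
$i$ is $\bar{S}/S_i$ (grand mean over node mean); applying the factors
equalizes all node means by construction. A zero node mean is a *dead
node* and raises an error naming it.

The ADC–curvature law is fitted by ordinary least squares of mean ADC on
curvature over reference cylinders; cylinder curvature uses the
**$\kappa = 2/\text{diameter}$** convention since cylinders are specified
by diameter. The default constants $C_1 = 82.6$, $C_2 = 6927.6$ are the
characterized device's; note that a nominal "7.16 counts per 0.001
mm⁻¹" sensitivity figure quoted for the same device disagrees slightly
with $C_2$ (which implies 6.93) — the constants are taken as
authoritative because they drive the published worked example. Signals
below $-C_1$ clip to zero curvature with a warning.

The baseline is the per-node mean over the initial idle window, default
**2 s** (60 frames at 30 Hz), taken half-open so the first post-idle
frame is excluded. Stage segmentation (attach/idle → curvature change →
detach) thresholds the baseline-relative mean signal at a configurable
onset level; detachment is recognized by every node losing ≥ 90% of its
level within one frame, the signature of peeling breaking all contacts
at once. Ambiguous traces stay in stage I.

## The synthetic-data generator

No raw recordings of the device are published, so the generator defines
the study conditions; it is first-class, tested code.

**Finger templates.** Per-finger 10-node profiles encode the anatomy:
negative cores at thumb → 9 (8 weakly), index → 8 (valleys 7–9),
middle → 6 (reaching 5 and 4), ring → 5 (flanked by 4 and 6), little →
two comparable peaks at 3 and 4; positive side lobes flank each core.
Template depths are phenomenological free parameters (`scale`, default
100 counts for a primary core). The positive-lobe gain default (1.563)
was calibrated once, numerically, so that the mean total negative
deformation of four-finger folds is 3.49× the single-finger mean with
near-linear growth over 1–4 folded fingers, and then frozen.

**Superposition and interference.** Natural multi-folds are the exact
linear sum of their fingers' templates. The anatomically awkward codes
(`01001`, `00101`, `01101`, `10101`, `11101` — little folded while ring
stays up) make the ring finger co-fold involuntarily: their maps add the
ring template plus an interference bump at node 5 (default 160 counts),
so they deviate from the linear sum by well over 125 counts. A closed
fist (`11111`) gets crowding relief (+70 at nodes 3 and 6), dropping its
total negative deformation below the four-finger level. These defaults
also guarantee, by construction, the decoder's disambiguation margins:
`11101` runs ≥ 107 deeper at node 5, `11110` ≥ 50 shallower at node 4,
and `11011` ≥ 70 shallower at node 5 than `11111`.

**Noise.** Frame noise is i.i.d. Gaussian, default $\sigma = 10$ counts
for gesture maps — a realistic frame noise for ~100–200-count
deformations — and $\sigma = 5$ for cylinder traces. The static 6-node
deviation vector has mean exactly 1 with node 5 reading 25% high and
node 2 low (factor 1.49 to restore), so calibration closes the loop on
the generator. All randomness flows through one integer seed per
generator call; trial sets derive one sub-seed per trial, and output
files record the seed in a header comment.

**Drift.** The post-attachment settling trace is
$y(t) = 0.7 + 0.3\,e^{-t/15\text{ s}}$ plus $\sigma = 0.02$ noise on a
normalized scale, sampled at 2 s intervals over 60 s — exactly 31
points, split chronologically 26 train / 5 test.

**What the generator does not emulate**: tendon/muscle mechanics (the
buckling model is a rationale, not the generator), inter-user variation
in fold depth and speed, temperature drift, electrode aging, and
non-Gaussian artifacts. Tests passing on this generator demonstrate
internal consistency of the pipeline under its stated conditions, not
performance on real skin.

## Core lines and vector quantization

A core line is a connected region — **4-connectivity** on the node × time
grid, the simplest definition consistent with contiguous dark bands — of
cells at or below the core threshold (−40 counts; the type requires
thresholds ≤ 0, and −∞ degenerates to one whole-grid line). Lines are
reported deepest first; equal depths break toward the lower node index
for stable ordering.

Map quantization is 1-D K-means on cell values; for a monotone colormap
this is equivalent to quantizing rendered colors. K = 6 (two-finger) and
K = 5 (three-finger) are the optimized palette sizes; for other fold
counts no optimum is published and the default stays K = 6, overridable.
Initial centroids are deterministic quantiles of the distinct values, so
results reproduce without restarts; Lloyd iterations then guarantee
local optimality (no single reassignment lowers the SSE). Passing fixed
`centroids` skips refitting, which makes quantization idempotent.
Upsampled (interpolated) maps are flagged and refused by the decoder.

## Decoding

Only the single-finger decision rule is fully pinned down by the
device's published procedure: the node of the maximum negative peak
decides the finger, with the little finger requiring *both* nodes 3 and
4 below threshold (it co-folds with the ring finger, so a single dip is
not accepted), and "none" when nothing crosses the threshold.

For multi-finger codes the published rules are the core line's position
and depth; patchkit realizes them as template matching: each of the 32
candidate codes is rendered by the same composite model the generator
uses, and the candidate minimizing the L2 distance to the map's node
profile over core cells (either profile ≤ threshold) wins. The node
profile is the per-node minimum over time after a 5-frame moving
average — smoothing keeps frame noise from biasing the minimum.
Distance ties break toward fewer folded fingers (the conservative
decision). When the winner is in the `{11110, 11101, 11011, 11111}`
quartet, the node-4/node-5 depth margins against the fist profile settle
the code. Confidence, `1 − best/second-best distance`, is a diagnostic
invented here and labelled as such.

## Evaluation

The confusion matrix has six prediction rows (five fingers + none) and
five actual columns; "none" predictions count as false negatives for the
actual class and never as false positives for a finger. Per-class
metrics follow the standard TP/FP/FN/TN definitions; F1 is 0 when
precision and recall are both 0. Full precision is kept internally;
display rounding is **half away from zero** at 3 decimals, matching
hand-computed tables (base `round()` rounds half to even).

## Drift prediction

The drift predictor is a multi-layer perceptron regressing the
normalized signal on min-max-scaled time: hidden widths 128-256-128-64-16,
sigmoid on the first hidden layer, ReLU elsewhere, linear output, trained
200 epochs by AdaGrad on the MAE loss with batch size 64 (full batch for
26 training samples). One published account of the architecture counts
four hidden layers while listing five unit widths; the five-width list
is implemented. Similarly, batch size 64 is the main-text optimum while
a figure caption favors 32; the default is 64 and the parameter is
exposed.

Unstated optimizer details were fixed as follows and are all exposed in
`mlp_spec()`:

* weight init: seeded uniform with fan-in scaling
  ($\pm\sqrt{6/\text{fan-in}}$), biases zero;
* AdaGrad accumulator initialized at 0.1 rather than 0, so the first
  update is not a full-step sign kick (with a zero accumulator the first
  AdaGrad step is exactly ±learning-rate for every weight);
* learning rate 0.02, chosen for training-set fit at the noise floor
  across traces;
* target min-max scaled over the training split;
* because MAE is non-smooth, the returned parameters are the averaged
  iterates over the trailing half of the epochs — the estimator that
  subgradient-method guarantees apply to — which damps the late-training
  oscillation of sign gradients.

The parametric baseline `fit_exponential_decay()` (nonlinear least
squares with a log-linear start, an `optim` fallback, and a
`scaleOffset` so the convergence test is valid on noise-free traces)
serves as the oracle the network is compared against on the 26/5 split.
The published test MAE of the physical device (0.0969) is on an
unpublished recording and is not a reproducible target; the
package-level check is the bound against the exponential oracle on the
synthetic trace.

## Problem sizes and tolerances

The test suite uses circles sampled at up to 20 001 points (curvature
error < 10⁻⁶), a 400/801-point Richardson pair for the buckling
eigen-solve (< 10⁻⁶ relative), 750 noisy single-finger trials (150 per
finger) for classification rates, 5 cylinders × 100 frames at σ = 5 for
calibration recovery (slope within 5%, R² ≥ 0.95), and 20 short seeded
runs for the optimizer sanity check. These sizes were chosen to keep the
full suite around ten seconds while leaving each tolerance comfortably
non-trivial.

## Known limitations

* Templates are phenomenological; the buckling model is not coupled to
  the generator.
* The decoder assumes one gesture epoch per map — no temporal
  segmentation of gesture streams.
* The 32-class decoder is validated by round-trip and noise-robustness
  properties; only single-finger classification has a published
  reference confusion table to reproduce.
* No temperature compensation or per-user personalization (skin modulus,
  fold speed), both named as future directions for the device itself.
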