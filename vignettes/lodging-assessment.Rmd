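---
title: "Assessing and predicting wheat lodging: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing and predicting wheat lodging: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lodgescore)
```

Lodging — the irreversible bending of stems or displacement of root
anchorage from the vertical — is one of the main yield-limiting events in
wheat. This package implements a complete desk-scale version of a field
lodging study: the manual scoring protocol, an image-based estimate of
lodged area, and a comparison of four regression models that predict the
lodging score from stem-architecture traits. This vignette explains the
models and the design decisions; the README shows the workflow.

## The field scoring protocol

Two quantities describe a lodged plot. The **crop angle of inclination**
(CAI, degrees) measures how far stems lean from the vertical: a plumb
bob gives the vertical height $h_v$ of a bent stem whose length along
its axis (slant height) is $h_{sl}$, and

$$\mathrm{CAI} = 90^\circ - \arcsin(h_v / h_{sl}),$$

so an upright stem scores 0° and a flat one 90°. The **lodged area**
(LA, percent) is assessed visually in four plot quadrants; each quadrant
contributes its lodged area as a percentage of the whole plot (at most
25), and the plot LA is their sum. Lodged plots carry 4–8 lodged
subplots whose angles are averaged — unweighted, because patch areas are
not recorded by the protocol — into the plot CAI. The normalized
**lodging score**

$$\mathrm{LS} = \frac{\mathrm{LA}}{100} \times \frac{\mathrm{CAI}}{90^\circ}
\in [0, 1]$$

merges both into one severity index, classed as H (healthy, LS exactly
0), Upright (0, 0.05], LL (0.05, 0.15], ML (0.15, 0.30], SL (0.30,
0.60] and VSL (0.60, 1.0].

Three conventions close gaps the protocol leaves open:

* The printed class bounds are two-decimal values whose literal reading
  leaves unassigned slivers such as (0.05, 0.06); the package uses
  contiguous right-closed intervals so classification is total and
  monotone on [0, 1].
* A healthy plot has no lodged subplots and hence no measurable angle;
  its CAI and LS are defined as 0.
* A vertical height marginally above the slant height (ratio within
  1e-9 of 1) is treated as measurement noise and clamped; anything
  larger is a recording error and rejected, because silently clamping a
  genuinely impossible pair would mask bad field data.

## Lodged area from canopy photographs

Canopy RGB images are converted to CIELAB (D65), where the $a^*$ axis
separates green (negative) from red (positive) and $b^*$ blue from
yellow. The cool halves of both opponent axes are clipped
($a' = \max(a, 0)$, $b' = \max(b, 0)$) and each pixel is labeled warm
("white") or cool ("black"); the lodged-area estimate is the warm pixel
percentage.

The default warm predicate is $a^* > 0$. A rule that also counts
positive $b^*$ as warm misclassifies healthy vegetation, because green
canopy typically has strongly positive $b^*$ (leaf green sits around
$a^* \approx -30$, $b^* \approx +30$); senescent straw and soil sit at
$a^* > 0$. The predicate is nevertheless configurable as an arbitrary
function of $(L, a, b)$, and a weighted warm-intensity rule
($w_a \max(a,0) + w_b \max(b,0) > \tau$) ships for scenes where
yellowing matters. Two further conventions: the warm *fraction* is
reported as the LA estimate (the raw black:white ratio is available in
verbose output), and an optional affine calibration against visual
quadrant assessments can be applied but is off by default — on the
synthetic imagery the uncalibrated estimator is already unbiased.

No color correction is applied anywhere in the pipeline. Conversion
accuracy is pinned by tests against published sRGB/D65 reference values
for the primaries (±1 unit per channel).

## The four predictors

Lodging score is predicted from four stem traits: plant height (PH,
cm), penultimate internode diameter (PeD, mm) and the two uppermost
internode lengths (IL1, IL2, cm). Data are split 75/25 by simple
seeded random sampling (not stratified by severity); all models share
one split.

**Stepwise MLR.** Forward selection: at each step the candidate with
the largest partial $R^2$ (increment in model $R^2$) enters if its
partial F-test has $p < 0.05$; there is no removal step. The trace
records partial $R^2$, cumulative $R^2$, and the entered variable's VIF
against the variables already in the model (1 for the first entry).
Ties — possible only on degenerate data — break by candidate column
order.

**Neural network.** A feed-forward net with three sigmoid hidden layers
of sizes 3, 9 and 8 and a linear output, trained with learning rate
0.2, momentum 0.1, and 2000 iterations. Those four parameter names
belong to the classic per-pattern backprop vocabulary, and the trainer
follows it: weights update after every training example, in row order,
for 2000 epochs. (A full-batch variant at the same learning rate was
evaluated first and discarded: averaging the gradient over the batch
shrinks the effective step so much that the net cannot even fit a
noiseless linear response within the fixed iteration budget, while the
per-pattern trainer reaches $R^2 > 0.999$ on the same check.) The inner
loop is compiled code; initialization is seeded uniform scaled by
fan-in, so fits are reproducible.

**SVR.** Epsilon-SVR with an RBF kernel, $\gamma = 0.004$, $C = 0.1$;
the tube width $\epsilon$ is not part of the study configuration and
defaults to 0.1 (exposed in `svr_config()`). A small $C$ with a wide
tube makes the fit deliberately stiff — which is exactly why SVR cannot
reach the exact-zero scores of resistant genotypes: any target within
$\epsilon$ of the regression surface exerts no pull, so the point mass
at 0 is approached no closer than the tube allows. In the degenerate
regime where *all* targets fall inside the tube the dual solution has no
support vectors and the model is the bare intercept; the predictor
handles this explicitly.

**Random forest.** 100 regression trees, 2 candidate features per
split, minimum leaf size 4, bootstrap resampling, seeded.

Inputs to the network and the SVR are min-max scaled to [0, 1] on the
training split only (the same affine map is applied at test time);
forest and linear regression use raw units, which they are invariant
to. The score target is already in [0, 1] and is never scaled.

## Evaluation metrics

`evaluate_predictions()` reports RMSE, nRMSE, MAE, RAE, RRSE, Pearson
CC, $R^2$, the ±25 %-band coverage, and $n$. Two definitional choices:

* **$R^2$** is the squared Pearson correlation between observed and
  predicted — the quantity a scatter plot's fitted line reports, and the
  definition under which $R^2 = \mathrm{CC}^2$ holds identically. The
  sums-of-squares definition $1 - \mathrm{SSE}/\mathrm{SST}$, which
  penalizes bias and can be negative, is available via `method = "ss"`.
  The distinction matters: a biased but well-correlated predictor (the
  network on some splits) scores high under the Pearson definition and
  poorly under the other.
* **nRMSE** can be normalized by the observed range (default) or the
  observed mean; both are always emitted, because published values
  rarely state which normalizer was used.

The ±25 % error band ($0.75\,O_i \le P_i \le 1.25\,O_i$) collapses to a
point at $O_i = 0$, so zero observations instead pass when
$|P_i| \le 0.01$ score units (configurable).

## The synthetic study

No field data ship with the package; a generator produces every input
the pipeline needs, calibrated to the study conditions.

**Trait tables.** A latent five-variate Gaussian is assembled from a
single "lodging propensity" factor: LS loads on the factor with loading
$b = 0.9$, and each trait with $r_i / b$, so every planted trait–LS
correlation $r_i$ (PH 0.78, IL1 0.70, IL2 0.63, PeD −0.48) is hit
exactly while trait–trait correlations $r_i r_j / b^2$ emerge as
realistic multicollinearity (study-scale VIFs around 1.3–1.8). The
factor structure is the minimal assumption that yields collinearity at
all; pairwise trait correlations are not part of the calibration
targets, and a nearest-positive-definite repair guards configs that push
the loading structure outside the PD cone. Marginals are scaled to the
published training-set means and SDs (PH 102.2/13.0 cm, PeD
4.02/0.59 mm, IL1 7.63/1.84 cm, IL2 13.06/2.14 cm, LS 0.288/0.263); the
published minima and maxima are carried as metadata but not enforced,
since a Gaussian marginal has no hard range. For $n$ above the trait
count the draw is recolored to *sample-exact* moments (empirical-mode
multivariate normal sampling), so planted values are reproduced in the
sample rather than only in expectation — recovery tests are then sharp
instead of hostage to $\approx 1.5\sigma$ sampling bounds.

**Zero inflation.** Lodging-resistant genotypes have LS exactly 0. The
generator models this by left-censoring the latent Gaussian score at 0
rather than by a separate Bernoulli mixture: censoring preserves the
latent correlation machinery and gives a closed-form zero fraction,
$\Phi(-0.288/0.263) \approx 13.7\%$, that tests can check exactly.
Scores above 1 (about 0.3 % of draws) are capped at 1, as the score
index is bounded by construction. Censoring attenuates the planted
correlations by a few hundredths, so calibration tests run in
no-censoring mode and censored-mode checks use wider (±0.05)
tolerances.

**Consistent plot protocol.** Each generated plot decomposes its LS
into an (LA, CAI) pair (a jittered square-root split, so neither factor
is systematically extreme), quadrant values that water-fill the LA under
the 25 % cap, and 4–8 subplot angles recentered to average exactly to
the plot CAI. Scoring the generated measurement files therefore
reproduces the generated scores to floating precision — an end-to-end
identity the tests assert.

**Canopy images.** A green-textured background receives elliptical
straw-colored patches until the truth mask covers the target fraction
within 0.5 percentage points (candidate ellipses that would overshoot
are rejected; a bounded retry count turns pathological configs into an
explicit placement error). Pixel colors are drawn from CIELAB boxes
(healthy $a^* \in [-40, -18]$, lodged $a^* \in [8, 25]$) chosen to be
separable by the default predicate, converted to sRGB, optionally
perturbed by Gaussian RGB noise, and quantized to 8 bits. Images are
written as lossless PNG so estimator tests are exact.

What the generator does **not** emulate: illumination gradients, shadow,
specular soil, mixed pixels at patch boundaries, perspective, and JPEG
artifacts — passing image tests show the estimator is correct *given*
separable warm/cool colors, not that the default predicate segments
arbitrary field photography. Likewise the trait generator has Gaussian
tails and a single-factor dependence; real accession panels have
population structure, season and block effects, and nonlinear
trait relationships. Model-comparison results on synthetic tables
reproduce qualitative orderings (the forest's training-fit advantage,
SVR's zero-score failure), not the study's printed metric values, which
belong to an undeposited dataset.

## Problem sizes and numerical choices

Default study size is 456 rows (228 accessions × 2 replications), split
342/114; calibration checks run at $n = 20{,}000$; canopy images are
120 × 160 px. These sizes keep every check fast on one CPU while
leaving sampling error far below the tolerances tested. Other numerical
conventions: angles stay in degrees at every interface (radians appear
only inside trig calls); severity boundaries are right-closed;
`findInterval` handles classification so boundary values cannot fall in
two classes; all randomness flows through explicit seed arguments and a
save/restore helper, so no call disturbs the caller's RNG stream.

## Known limitations

* The image module estimates the lodged-area *fraction* of a frame; it
  does not detect plot boundaries, correct geometry, or handle UAV
  orthomosaics.
* The stepwise trace reports VIF against already-entered variables,
  matching a forward trace's information set; full-model VIFs can be
  had by calling `vif()` on the final design.
* The network trainer is plain per-pattern backprop — adequate for the
  fixed 2000-epoch configuration it reproduces, not a general-purpose
  deep-learning tool.
* Severity classes, moments and correlations are wheat-study
  calibrations; other crops or protocols will need their own
  `trait_gen_config()`.
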