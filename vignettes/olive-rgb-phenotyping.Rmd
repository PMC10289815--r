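---
title: "Predicting olive fruit quality traits from RGB colorimetric indexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting olive fruit quality traits from RGB colorimetric indexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(OlivePhen)
```

## The problem and the model

Oil (% fresh weight) and total phenols (mg gallic-acid equivalents per g
dry weight) develop along characteristic seasonal trajectories in olive
fruit — a roughly sigmoidal oil rise and a parabolic phenol peak — while
the fruit's skin color moves through the green-to-purple transition of
veraison. `OlivePhen` models both traits as functions of the fruit's mean
R, G, B pixel values via 35 colorimetric indexes, and compares three input
encodings for a single-hidden-layer regression network trained by
resilient backpropagation (Rprop+): the raw standardized indexes (BPNN),
retained principal-component scores (PCA_BPNN), and the subset of indexes
with a nonzero sparse-PCA loading (SPCA_BPNN).

The central assumptions are (i) that the channel means over the segmented
fruit region carry enough information about ripening stage to proxy the
traits, (ii) that a network of modest capacity — hidden size
`round(N/3 + 2)` for `N` inputs, logistic hidden units, one linear output
— suffices for the smooth trait-versus-color relationship while limiting
overfitting, and (iii) that the comparison between encodings is only fair
when every variant sees exactly the same train/test partitions, which the
`SplitPlan` object enforces.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `variance_cutoff` (`fitPCA`) | 0.85 | fraction | conventional ~85 % cumulative-variance cutoff; the smallest k reaching it is kept, which is deterministic |
| `max_iter`, `ridge_penalty` (`fitSPCA`) | 200, 1e-6 | – | the sparse fits use a bounded alternation with a small quadratic penalty that regularizes the ridge step without influencing the solution materially |
| `tol` (`fitSPCA`) | 1e-6 | loading units | convergence on the maximum absolute change of the normalized loadings |
| GA controls (`gaConfig`) | pop 20, gen 50, tournament 3, crossover 0.8, mutation 0.1, elitism 1 | – | small-integer search space (k genes in 1..p); these settings converge well before the generation budget at k = 2 |
| `sparsity_weight` | 0.5 | – | see "GA fitness" below |
| Rprop+ controls (`networkSpec`) | eta 1.2/0.5, step 0.1 (1e-6..50) | – | the de-facto resilient-backprop defaults |
| `gradient_threshold`, `max_epochs` | 0.01, 10000 | SSE gradient / epochs | training stops when the largest partial derivative is below threshold; hitting the epoch budget flags (not fails) the run |
| `b_star_threshold` (`segmentFruit`) | -15 | CIELAB b* | the blue backdrop sits near b* = -57, fruit tissue above ~0; a fixed cut is reproducible, an Otsu option exists |
| `train_fraction`, `n_repeats` | 0.7, 5 | – | the repeated hold-out protocol; train size is floor(0.7 n) |
| `clip_z_margin` (`runScenario`) | 3 | z units | off-manifold guard, see "Numerical choices" |

## What the synthetic generator emulates — and what it does not

`trajectoryParams()` encodes one cultivar's season on the
days-after-pit-hardening (DAPH) axis:

* oil follows a logistic curve from `oil_base` = 5.5 %FW to `oil_max`
  (22 / 20 / 18 %FW for the late / middle / early preset), midpoint
  60 DAPH, rate 0.08 per day. A logistic was chosen over a straight line
  because it captures the plateau at both season ends while being nearly
  linear mid-season;
* phenols follow a downward parabola truncated at zero, peaking at
  41 / 30 / 28 mg GAE/g (the late-ripening preset carries the highest
  phenol load) at 45 DAPH with curvature 0.0028 mg/day^2;
* each channel mean follows a clamped parabola; R and G peak near 140 and
  130 around 40-45 DAPH and decline to dark-fruit values near 50 by season
  end, B stays the lowest channel throughout (peak 65, curvature 0.005).
  Ripening groups are encoded as -10/0/+10-day shifts of the channel peak
  times, so the early cultivar darkens first;
* noise is additive, Gaussian and independent: SD 2.5 pixel values per
  channel, 0.8 %FW for oil, 2.0 mg GAE/g for phenols. No per-sample
  variance estimates exist for the original study, so these are plausible
  magnitudes chosen once, not calibrated values.

The renderer draws each sample as jittered ellipses on a saturated blue
background (RGB 30, 60, 160 — chosen so the CIELAB b* of the backdrop is
strongly negative) with an optional white reference patch, and returns its
own ground truth (mask and per-fruit drawn colors), which the imaging
tests round-trip against.

Deliberately not emulated: illumination gradients, vignetting, JPEG
artifacts, fruit occlusion and per-fruit instance structure, petioles, and
the skin-versus-pulp color divergence of late veraison. Passing tests on
this generator therefore demonstrate that the pipeline recovers a smooth
trait-color relationship under realistic noise — not that a camera in a
real light box would achieve the same accuracy.

One emulation detail matters for modeling: with R and G peaks only ~10
pixel values apart, the G - R difference crosses zero during late
ripening, as it does at veraison. The hue index is an arctangent of a
ratio with G - R in the denominator, so it is bimodal across that
crossing; this is a property of the index family, not of the generator.

## Numerical choices

* **Formula dialects.** Several published index formulas contain obvious
  typesetting artifacts. The default `interpreted` dialect reads the
  constant `30.5` in the two hue formulas as \(3^{0.5}\) (the \(\sqrt 3\)
  of the standard hue definition) and `L` as \((R+G+B)/3\); the
  `as_printed` dialect evaluates every formula exactly as typeset
  (including a literal divide-by-30.5-then-multiply). Two terms with no
  recoverable intent — `BIM`'s `(R*2+G*2+B*2)` and `HUE2`'s `(R-G-R)` —
  are kept as printed under both dialects rather than guessed.
* **Degenerate denominators** (e.g. `HI` and `SHP` when G = B, the
  normalized channels at R+G+B = 0) yield an undefined flag (`NA`), never
  an error; imputation by the training-set column median happens only at
  modeling time so no test-set information leaks in.
* **Boundedness.** GLI, NGRDI and SCI are provably in [-1, 1]; VARI is
  not (its denominator G+R-B can be arbitrarily small), so the package
  does not claim that bound.
* **Off-manifold guard.** Standardized test features are clamped to the
  training split's observed range widened by `clip_z_margin` = 3 z units
  (training statistics only). Without it, a noisy test sample crossing
  the G = R hue singularity on a training split that never saw the far
  branch can standardize to |z| > 100 and saturate every network at once.
* **White balance** multiplies in real arithmetic, clips to [0, 255] and
  rounds half-up; rendered images are 8-bit, so round trips are exact to
  0.5 per channel.
* **PCA sign convention:** each loading column's largest-magnitude entry
  is positive, making decompositions comparable across runs. The retained
  k is the smallest k whose cumulative explained fraction is >= the
  cutoff (a deterministic reading of "close to 85 %").
* **GPI normalization scope and ties.** Indicators are min-max normalized
  over all model x iteration cells within one cultivar x trait scenario,
  and the reference is the median of those cells; this makes models
  comparable on one scale and gives higher GPI = better rank. An
  indicator constant across all cells is set to 0.5 uniformly (zero
  contribution) with a warning. Rank ties break by model registration
  order (BPNN, PCA_BPNN, SPCA_BPNN) — with continuous metrics a tie
  essentially never occurs, but the rule keeps ranking total.
* **RMSE** uses an \(n-1\) denominator and \(R^2\) is the squared Pearson
  correlation, matching the benchmark definitions this package mirrors;
  with a constant prediction vector \(R^2\) is reported as `NA` with a
  warning rather than silently zero.
* **Network output** is linear on min-max-scaled targets rather than
  logistic: a logistic output saturates exactly at the trait extremes
  where the oil curve plateaus, and a linear read-out with scaled targets
  avoids that while keeping the logistic hidden layer.
* **GA fitness.** The published description defers the fitness to its
  reference; the package uses
  `APEV / CPV_pca - sparsity_weight * sum(nnzl) / (k p)` — adjusted
  explained variance of the sparse fit relative to the retained-PCA
  cumulative variance, penalized by total cardinality. With weight 0.5
  the search keeps most variables and zeroes a handful, the qualitative
  outcome of the reference loading table, and the form is brute-force
  verifiable at small p (the test suite enumerates all chromosomes at
  p = 3). Whether the two components' NNZL should be optimized jointly or
  separately is left to the GA (the chromosome is the full length-k
  vector).
* **Seeds.** Every stochastic stage (generator, splits, GA, weight
  initialization) takes an explicit seed; derived seeds are mixed with a
  32-bit-safe linear scheme. Weight initialization is uniform(-0.5, 0.5),
  and because random initialization is an irreducible source of run-to-run
  variation, the seed is a mandatory, logged input of every report.

## Problem sizes

The default benchmark uses 3 cultivars x 17 sampling times x 3 replicates
= 153 samples (51 per cultivar, mirroring the observation counts of the
study design this package emulates), five hold-out iterations, and the
default GA and Rprop budgets; a full `runAll()` over 6 scenarios completes
in well under a minute on a single core. The test suite uses smaller
configurations (8-20 samples, reduced GA populations and epoch budgets)
wherever the property under test does not depend on scale.

## Known limitations

* The synthetic benchmark is a stand-in: accuracy numbers obtained on it
  characterize the pipeline, not any particular orchard's data.
* The hue-family indexes are discontinuous across the G = R crossing;
  with real late-season data the same guard (or dropping those indexes)
  may be needed.
* Only the white patch is used for color correction (per-channel gains),
  not a full color-checker correction matrix.
* `R^2` for a constant predictor is undefined; scenarios with saturated
  networks surface this as `NA` plus a warning rather than a value.
* The GA optimizes a surrogate fitness; nothing guarantees the selected
  NNZL matches the reference study's (unpublished) objective, only that
  the selection mechanism and its constraint handling behave as specified.
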