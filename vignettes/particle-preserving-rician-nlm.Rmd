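---
title: "Particle-preserving Rician non-local means: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Particle-preserving Rician non-local means: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnlmstar)
```

## The problem

Magnitude MR images carry Rician noise: each observed intensity is
`M = sqrt((A + n1)^2 + n2^2)` with `n1, n2` i.i.d. zero-mean Gaussians of
standard deviation `sigma`, so `E[M^2] = A^2 + 2 sigma^2` and low-signal
regions are biased upward. Non-local means (NLM) denoisers average pixels
whose *patches* look alike and handle this noise well once the bias is
subtracted, but they share a failure mode that matters clinically: tiny
high-contrast spots — a 1–3 pixel lesion in cartilage or bone — resemble no
other patch in their search window, receive a diluted self-weight, and get
averaged away ("particle blurring"). This package implements an NLM variant
whose weights combine patch similarity with raw pixel-intensity similarity
and whose self-weight is boosted exactly where the center pixel differs
sharply from even its best-matching neighbor, so isolated particles survive.

## The filter family

For a pixel `i` with search window `Win(i)` (radius `rads`, clipped at
image borders):

* **NLM** (`nlm_filter`): `xhat(i) = sum_j w(i,j) y(j)` with
  `w ∝ phi(i,j) = exp(-d2(i,j) / h^2)`, where `d2` is the kernel-weighted
  mean squared difference between the patches (radius `radp`) around `i`
  and `j`. The self-weight `phi(i,i)` is set to the maximum non-central
  `phi` so the center cannot dominate by construction.
* **RNLM** (`rnlm_filter`): the same weights applied to squared
  intensities with the Rician bias removed,
  `xhat(i) = sqrt(max(sum_j w(i,j) y(j)^2 - 2 sigma^2, 0))`.
* **RNLM\*** (`rnlm_star_filter`): non-central weights are
  `phi*(i,j) = phi(i,j) * rho(i,j)` with the pixel similarity
  `rho = 1 / (1 + (|y(i)-y(j)| / degc)^omega)`, and the self-weight is
  `phi*(i,k) * theta(i,k)` where `k` is the most similar non-central pixel
  and `theta = 1 + (2 radp + 1)^2 / (1 + (degc / |y(i)-y(k)|)^omega)`.
  `theta` rises from 1 (center looks like its best neighbor) towards
  `1 + (2 radp + 1)^2` (center looks like nothing nearby — a particle),
  re-concentrating weight on the center precisely where averaging would
  destroy information.

The squared-magnitude estimator is printed in some formulations without the
final square root; this package applies the square root by default so the
output is in intensity units, and exposes `sqrt_output = FALSE` for the
literal squared form. Ties in the argmax over `k` are broken by first
occurrence in raster order, making every output bit-deterministic.

## Parameters, units, defaults

All intensities live on a normalized `[0, 1]` scale; `h`, `degc` and the
noise intensities (`sigma`, `d`, `v`) are interpreted on that scale.

| parameter | meaning | default | notes |
|---|---|---|---|
| `h` | weight decay; larger smooths more | 0.8 | the random-search optimum on musculoskeletal MR series |
| `radp` | patch radius | 3 | 7×7 patches |
| `rads` | search-window radius | 10 | 21×21 window; separate from `radp` because patch and search radii play different roles |
| `degc` | intensity difference at which pixel similarity drops to 1/2 | 6.65 | see the scale note below |
| `omega` | slope of that transition | 4 | integer |
| `a` | spatial std of the Gaussian patch kernel | `Inf` | uniform kernel by default |

**A note on `degc`'s scale.** The reported optima for `degc` (about 6.5 on
average) exceed the entire normalized intensity range, which makes `rho`
and `theta` nearly inert: at such settings RNLM\* behaves like RNLM with a
marginal reweighting. The pixel-similarity machinery only engages when
`degc` is commensurate with real intensity differences — a few tenths on
the `[0, 1]` scale, below the contrast of the particles one wants to keep.
The package keeps the published value as the default and leaves `degc` a
free parameter; the property checks in the test suite exercise both
regimes deliberately.

**The particle/impulse trade-off.** The self-weight boost cannot
distinguish a diagnostically meaningful particle from a salt-and-pepper
impulse: both are single pixels unlike their surroundings. With `degc`
well below the impulse contrast (e.g. 0.2), RNLM\* faithfully preserves
particles under Rician noise *and* faithfully preserves impulses under
impulse noise, which hurts restoration quality there. At `degc ≈ 1` the
pixel-similarity term still suppresses impulse values from the weighted
average (they differ from the center by ~0.5–1.0) while the self-weight
boost stays bounded, and RNLM\* outperforms RNLM under salt-and-pepper
corruption. The sweep-based tests use that setting; the particle-
preservation tests use the aggressive one. This trade-off is inherent to
the method, not an implementation artifact.

## Noise generators and their laws

* `add_rician`: exact magnitude model; non-negative, unclipped. Checked
  against `E[M^2] = A^2 + 2 sigma^2` and the Rayleigh mean at `A = 0`.
* `add_salt_pepper`: each pixel independently replaced with probability
  `d`, half salt (1) and half pepper (0). The equal split is a declared
  choice; only the total density is fixed by the problem statement.
* `add_speckle`: `J = I + n I` with `n` zero-mean of variance `v`,
  uniform on `[-sqrt(3v), sqrt(3v)]` by default (the distribution family
  of the multiplier is conventionally left open; a Gaussian option is
  provided).
* `estimate_sigma_background`: `sigma = sqrt(mean(M^2) / 2)` over a
  signal-free mask, the inversion of the Rayleigh second moment. A
  printed form of this estimator without the square root is dimensionally
  inconsistent with its own definition of the background mean; the
  square-root form is implemented.

## Synthetic phantoms: what they emulate, what they do not

`make_phantom` builds layered, piecewise-smooth horizontal bands (distinct
mean levels in `[0.15, 0.45]`, a gentle ±0.04 within-band gradient, seeded
band order) with optional Gaussian edge blur, plus non-overlapping hard
disc particles of known contrast added before the blur, with a ground-truth
mask (`particle_mask`). This emulates the layered geometry of cartilage MR
slices and the tiny lesions whose preservation motivates the filter, at
known ground truth and at desk scale. It does **not** emulate MR physics:
no coil sensitivity or bias fields, no partial-volume mixing, no spatially
correlated noise, no anatomical curvature. Passing the property suite
therefore demonstrates the *mechanisms* (bias correction, particle
preservation, monotonic degradation, segmentation benefit) on controlled
inputs — not clinical performance on real series. A single-band spec
degenerates to a constant background by design, so the flat-phantom edge
case is exact.

## Metrics

MSE, SNR (filtered-signal power over residual power — deliberately
role-asymmetric), PSNR, the universal quality index Q (correlation ×
luminance × contrast factors; the contrast factor uses the sum of
variances in its denominator, since a difference there would unbound an
index defined on `[-1, 1]`), SSIM (`l^alpha c^beta s^gamma` with
`C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`, `C3 = C2/2`, `L = 1`; global
statistics by default with an 8×8 sliding-window option), Pearson
correlation, and intensity-difference statistics (per-pixel
`|native - filtered| × 100`, summarized by median, histogram-mode over 256
bins, and sample variance). Degenerate inputs return documented sentinels
(`Inf` for log-ratios of identical images, `NA` for zero-variance
correlation factors) so batch sweeps never abort. Sample (n−1) moments are
used throughout, which also makes the global SSIM agree with the standard
reference implementation configured with a full-image window.

## Random-search optimization

`optimize_filter_params` draws `n` parameter combinations uniformly
(`h`, `degc` continuous; `radp`, `omega` discrete), scores each by the
mean MSE of RNLM\* output against the noise-free references over a set of
images and Rician levels (reference setting
`sigma ∈ {0.05, 0.1, 0.15, 0.2, 0.3}`), and returns the minimizer with its
full trial table. Corruption seeds depend only on (seed, image, level),
never on the trial, so every combination is scored against identical
corruptions — without this the trial MSEs would not be comparable — and
draws are made trial-by-trial from one stream, so a larger run extends a
smaller one (`best_mse` is non-increasing in `n` at fixed seed). The
`degc` sampling interval `[0.5, 10]` covers the reported optima.

## Fuzzy soft-thresholding segmentation

`fuzzy_soft_threshold` is fuzzy c-means run on the intensity distribution:
distinct pixel values weighted by their counts (the exact limit of a
histogram-domain formulation, with no binning error), quantile
initialization at `(j + 0.5)/C`, fuzzifier `m = 2`, convergence when the
largest centroid shift is below `1e-6` (cap 300 iterations), zero-distance
values assigned crisp membership, classes relabeled by ascending centroid.
It is deterministic and invariant to pixel permutation. Segmentations are
compared after rendering each label by its centroid intensity, so SSIM and
SNR operate on intensity-commensurate images rather than label integers.

One published qualitative claim does **not** reproduce on these phantoms:
that a 3-region segmentation retains agreement with the noise-free
reference better than an 8-region one under impulse noise. On
piecewise-smooth phantoms the centroid-rendered comparison consistently
favors 8 regions (by ~0.03 SSIM): with many classes a noise-induced label
flip lands in an intensity-adjacent class (a small rendering error), while
with 3 classes flips are rarer but large. The corresponding assertion is
kept in the acceptance suite as stated and fails; the companion claim —
that RNLM\* pre-filtering improves segmentation agreement at all — holds in
10/10 seeds for both class counts.

## Numerical choices and edge cases

* Mirror (symmetric, edge-duplicating) padding for patch extraction and
  the local baseline filters; search windows are clipped at borders and
  weights renormalized.
* If every non-central weight underflows to zero (tiny `h` on a unique
  patch), the center keeps its own value rather than dividing by zero.
* `|y(i) - y(k)| = 0` in `theta` takes the analytic limit `theta = 1`.
* Patch distances are kernel-normalized (weights sum to 1), so `h` has the
  same meaning for every `radp`.
* The stride-2 patch dialect (offsets `{-2 radp, …, -2, 0, 2, …, 2 radp}`)
  is available alongside the default contiguous neighborhood.
* Noise outputs are not clipped (metrics accept values above 1); writing
  to image files clips to `[0, 1]` with a warning.

## Problem sizes

The shipped tests and the reproduction script run on 16×16 images for
oracle equivalence (against a quadruple-loop reference), 12×12 for weight
normalization, 24×24–32×32 phantoms for sweeps and segmentation (search
radius 3–5), 64×64 for bias correction, and 10^5-pixel constants for the
distributional laws — sizes at which every mechanism is measurable and the
whole suite runs in minutes on one core. The filters themselves are
compiled (Rcpp) and handle full-size images; runtime grows as
`(2 rads + 1)^2 (2 radp + 1)^2` per pixel.

## Known limitations

2-D single-coil magnitude images only (no non-central chi multi-coil
model, no 3-D volumes); no spatially correlated noise; the segmentation
stands in for a soft-thresholding formulation whose original internals are
not fully specified in the source literature — it is a declared,
deterministic fuzzy-c-means design; and parameter optima transfer across
intensity scales only if `h` and `degc` are rescaled with them.
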