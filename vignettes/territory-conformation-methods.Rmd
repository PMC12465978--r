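---
title: "Methods: territory conformation and locus dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: territory conformation and locus dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(territoryshape)
```

This vignette is the package's own account of what it computes, the
assumptions behind each stage, the parameters that matter, and the design
choices that were genuinely open.

## Shape: the gyration tensor and the aspect ratio K

A chromosome territory is represented by its backbone, an ordered 2D
curve of N points in physical micrometres. The gyration tensor
$Q_{\alpha\beta} = \frac{1}{N}\sum_i (r_{i,\alpha}-r_{c,\alpha})
(r_{i,\beta}-r_{c,\beta})$ is the unweighted second central moment of the
points; its eigenvalues $\lambda_1 \le \lambda_2$ (µm²) are the squared
extents along the principal axes.

We define the aspect ratio as $K = \lambda_{\max}/\lambda_{\min}$, so
that $K \ge 1$ always, $K = 1$ is a perfectly round shape, and larger K
is more extended. (The opposite ratio convention, $\lambda_1/\lambda_2$
with $\lambda_1 \le \lambda_2$, would confine K to (0, 1]; the two carry
the same information, and the convention here keeps "more extended" and
"larger K" aligned.) Three consequences of the definition drive
implementation decisions:

* **Degenerate input.** Collinear points have $\lambda_{\min} = 0$ and
  K is infinite. This is not an error: `gyration_tensor()` flags it
  (`infinite_K`), `aspect_ratio()` returns `Inf` with a warning, and
  mixture fits refuse infinite values so callers must exclude them (the
  pipeline counts them in its report). Hard classification of an
  infinite K, where requested, is "extended" — the only direction that
  makes sense for a maximally elongated object.
* **Invariance.** K is invariant under rotation, translation, reflection
  and uniform scaling. The test suite asserts this property over random
  similarity transforms at a relative tolerance of 1e-9, and checks Q
  against a brute-force double-sum oracle at the same tolerance.
* **Point weighting.** Points are unweighted, and curves are used as
  given. Spline or skeleton point density can in principle bias Q, so an
  optional equal-arc-length resampling flag exists
  (`shape_from_curve(..., resample_arclength = TRUE)`); it is off by
  default because the reference procedure computes the tensor directly
  from the traced curve points.

## The bimodal mixture model of K

Across a population of cells the K distribution is bimodal: a low
"collapsed" mode and a high "extended" mode. `fit_bimodal()` models the
finite K values as $w_e N(\mu_e, \sigma_e^2) + (1-w_e) N(\mu_c,
\sigma_c^2)$ and relabels so $\mu_c < \mu_e$.

Two fitting routes are deliberately provided:

* `method = "em"` (default): expectation-maximization on the raw values.
  EM is started from 10 quantile-spread initializations (component means
  at the (0.10, 0.90), (0.13, 0.87), ... quantile pairs), and the best
  log-likelihood is kept; per-restart convergence is $|\Delta\ell| <$
  1e-8 within 500 iterations, component SDs are floored at $10^{-4}$
  sample SDs to prevent variance collapse onto a single point, and the
  log-likelihood is asserted non-decreasing at every step. EM avoids any
  binning choice.
* `method = "histogram_ls"`: least-squares fit of a two-Gaussian sum to
  the histogram density with Freedman–Diaconis bin width, the route most
  spreadsheet/plotting packages take. It is retained for comparability —
  the two methods agree on component means to within 0.1 on simulated
  data — but is bin-width sensitive, which is why EM is the default.

**Percentages are mixture weights, not counts.** The extended/collapsed
percentages reported by `conformation_percentages()` are $100 w_e$ and
$100(1-w_e)$ — the areas of the fitted components. Hard per-territory
labels (posterior of the extended component ≥ 0.5, ties to extended by
convention) are available separately via `classify_territory()` and are
what the pipeline feeds to Fisher's exact test; with well-separated modes
the two notions differ by at most a few percent.

**Overlap guard.** When $|\mu_e - \mu_c| < (\sigma_c + \sigma_e)/2$ the
two components are not separable modes, the fit is flagged and
percentages are refused rather than reported meaninglessly.

Condition comparisons use the two-sided Fisher's exact test on the 2×2
extended/collapsed count table (`stats::fisher.test`; an exhaustive
hypergeometric enumeration over every table with margins up to 12 serves
as the oracle in the test suite). Multiple-condition runs report pairwise
tests without multiplicity correction, matching common practice for
small numbers of planned contrasts; `p.adjust` can be applied downstream
where many contrasts are run.

## Dynamics: MSD, power law, R_g, D_eff

Trajectories are uniform-interval position series; whole-cell motion is
removed first, by referencing each frame to the nuclear centroid:
$p'(t_k) = p(t_k) - c(t_k) + c(t_0)$. The correction is exact when the
centroid series is exact, is idempotent, and leaves a drift-free
trajectory unchanged.

The MSD estimator is the overlapping time average
$\mathrm{MSD}(k\Delta t) = \frac{1}{n-k+1}\sum_{m=0}^{n-k}
|p(m\Delta t + k\Delta t) - p(m\Delta t)|^2$, with exactly $n-k+1$ pairs
at lag k. The non-overlapping (stride-k) estimator is a different, noisier
statistic and is explicitly not used (a test asserts they differ).

Fits, and their numerical conventions:

* **Power law** $\mathrm{MSD} = 4 D_{app} \Delta t^{\alpha}$: ordinary
  least squares of log MSD on log lag. The fit range is the first 25% of
  lags by default (`fit_fraction = 0.25`): time-averaged MSD values at
  long lags are computed from very few pairs and are strongly
  correlated, so including them degrades the fit. α is the slope and
  $D_{app} = e^{\mathrm{intercept}}/4$.
* **R_g**: the trajectory gyration radius is
  $\sqrt{\frac{1}{n+1}\sum_k |p(t_k)-p_c|^2}$, the root-mean-square
  distance from the trajectory centroid — a length, in µm, with the
  radical over the whole mean.
* **D_eff**: a through-origin least-squares fit of
  $\mathrm{MSD} = 4 D_{e\!f\!f}\,\Delta t$ over lags $\le 3\Delta t$.
  The zero intercept is physical (MSD(0) = 0); a free intercept would
  absorb localization noise but also leak signal into it at only three
  points.

Group contrasts (R_g, D_eff) use Welch's unequal-variance t-test with
Satterthwaite degrees of freedom. Two equal constant groups give p = 1 by
convention (a vacuous comparison); a single zero-variance group is an
error rather than a fake p-value. Trajectories shorter than 4 frames are
skipped by the pipeline — below that no power-law fit is defined — and
frames are never interpolated: a tracking gap should split a trajectory
upstream rather than fabricate positions.

## The synthetic-data generators

The generators exist so that every downstream stage has ground truth.
What they emulate, and what they deliberately do not:

* **Territory curves** are discrete worm-like chains: fixed step length
  (default 0.05 µm, 200 points — a ~10 µm contour at the scale of a
  labelled territory backbone) and i.i.d. Gaussian turning angles with
  variance $1/(1+\mathrm{persistence})$. One stiffness knob spans
  crumpled (persistence 0) to nearly straight (persistence → ∞ gives an
  exactly collinear chain, exercising the infinite-K path). The mode
  presets are persistence 0 ("collapsed") and 50 ("extended"). The K
  distributions of the two presets *overlap substantially* — as real
  conformation ensembles do — so the preset label is not recoverable
  from K with high accuracy even in principle; see the end-to-end
  section below for what is therefore tested.
* **K samples** are drawn from the two-component Gaussian mixture
  directly, with defaults anchored to a reference osteoblast-like
  condition (collapsed mean 1.82, extended mean 3.58, extended weight
  0.81); the matching osteosarcoma-like setting is means 1.65/2.93 with
  weight 0.31. Component SDs (0.3 collapsed, 0.6 extended) are a
  modelling choice — not measured values — and must be treated as free
  parameters. Draws below 1 are redrawn within their component rather
  than clipped: K ≥ 1 by definition, and clipping would pile probability
  mass at the boundary and distort the collapsed mode.
* **Trajectories** are exact 2D fractional Brownian motion with Hurst
  exponent $H = \alpha/2$, synthesized by Cholesky factorisation of the
  exact position covariance $C_{ij} = D(t_i^\alpha + t_j^\alpha -
  |t_i-t_j|^\alpha)$ per coordinate, so the ensemble MSD is exactly
  $4D(k\Delta t)^\alpha$ at every lag. Exactness at the typical tracking
  length (100 frames at 0.2 s) is worth the $O(n^3)$ factorisation,
  which is negligible at that size; the factor is shared across an
  ensemble generated in one call. Injected drift is a constant per-frame
  vector, and the emitted nuclear-centroid series *equals* the cumulative
  drift, so drift correction inverts it exactly — a deliberate
  testability contract. Optional reflecting circular confinement is
  applied increment-wise; reflection breaks exact fBM covariance and is
  for qualitative confined-motion scenarios only. Not modelled: exposure
  -time motion blur, localization noise, photobleaching.
* **Image stacks** render each backbone point as a 3D Gaussian spot
  (error-function integrals over voxels, so each spot deposits its
  expected photon budget exactly), on 10 slices at 0.25 µm with the
  curve in the mid-plane, plus uniform background and Poisson shot
  noise. Defaults: 0.1 µm pixels, PSF σ 0.12 µm lateral / 0.3 µm axial,
  500 photons per point over a background of 10 counts — a bright,
  well-sampled widefield acquisition. No camera gain model, no
  deconvolution (segmentation operates on raw projections).

Every generator is a pure function of its parameters including the seed.

## Imaging: projection, segmentation, backbone extraction

The image chain mirrors a manual territory-tracing workflow with
automated, parameterised stages:

1. **Maximum-intensity projection** over z.
2. **Segmentation**: Otsu threshold, then a radius-1 opening applied *by
   reconstruction* — components that survive the opening are kept whole,
   components the opening erases are dropped. A plain opening would also
   erode a genuinely thin (1–2 px) diagonal backbone to nothing, which
   the reconstruction variant avoids while still removing specks.
   Because Otsu always produces a threshold, a contrast guard
   (`contrast_min = 2`: mean above-threshold intensity must be at least
   twice the mean below) declares featureless or signal-free images
   empty instead of segmenting their own shot noise. The largest
   remaining component with at least `min_area_px` pixels (default 20 px
   ≈ the PSF footprint at 0.1 µm sampling) is the territory; an empty
   result is a flagged mask, not an error.
3. **Backbone extraction**: the mask is skeletonized (Zhang–Suen
   thinning) and the longest geodesic path through the 8-connected
   skeleton graph is taken via a double breadth-first sweep (exact on
   tree skeletons, the standard approximation when loops are present),
   then converted to µm and smoothed with a 5-point centred moving
   average — wide enough to suppress pixel-lattice zigzag, narrow enough
   not to shorten the curve materially.

**The blob regime.** A skeleton midline only represents shape when the
object is much longer than wide. For a compact blob the medial axis
degenerates toward a point — a short, straight fragment whose K is
spuriously enormous (a perfectly round disk would come out "infinitely
extended"). `extract_curve()` therefore switches representation when the
midline is shorter than `blob_aspect` (default 12) times the local tube
width (twice the mean distance-to-background along the path): it returns
an ordered serpentine sweep through all mask pixel centres, a curve whose
gyration tensor equals that of the mask region, so a round blob correctly
yields K ≈ 1. The cutoff was calibrated on simulated territories with
known K: values between ~8 and ~15 behave equivalently, below ~6 blob
masks are mis-measured by their midlines, and a thin 100×4 px rectangle
(aspect ≈ 25) must remain in the midline regime.

## What the end-to-end tests do and do not show

On 200 rendered territories (100 per mode preset) at default SNR, the
full chain — render, project, segment, extract, K — attains a median
per-territory relative K error under 15%, and the extended/collapsed call
obtained from the recovered K agrees with the call obtained from the
ground-truth curve's K for over 90% of territories (same fitted
classifier applied to both). Two honest caveats:

* Agreement is measured against the *classification of the true curve's
  K*, not against the generator's mode preset: the presets' K
  distributions overlap by construction, so preset recovery has a low
  ceiling (~75% for an ideal classifier on true K) and would measure the
  generator, not the imaging chain.
* Sub-resolution structure is unrecoverable by any method: a 10 µm
  contour crumpled into a ~1 µm blob leaves no backbone ordering in the
  image. In the blob regime the recovered K is the region's K — the
  right quantity at the resolution the optics provide, but not the
  chain's K at polymer scale. Passing tests show the chain is faithful
  at and above the diffraction scale; they cannot certify polymer-scale
  shape in collapsed territories, and neither could the microscope.

These checks run on synthetic renders; real acquisitions add
deconvolution artefacts, nonuniform background, neighbouring territories
and human inclusion criteria ("well-separated territories only") that the
generator does not emulate.

## Spike-in normalization

`compute_scale_factors()` is deliberately minimal arithmetic: f = m/s per
sample (m the minimum mouse-aligned count, s the sample's own), expected
target reads = round(f × human reads). The smallest-depth sample always
has f = 1; factors are invariant under a common multiplier on all mouse
counts. Zero mouse reads in any sample is a normalization error (the
spike-in failed) rather than a silent f = 0. Actual BAM subsampling, and
everything upstream of the count table (alignment, deduplication, peak
calling), is out of scope — published tools do those steps.

## Problem sizes and reproducibility

The test and validation suites use: 10⁵ draws for mixture moment checks,
10⁴ draws for large-sample mixture recovery (component means within
±0.05, weight within ±0.03), 20 replicate fits at n = 104 territories
(median weight error ≤ 0.08 — the honest uncertainty of a weight
estimated from ~100 cells), 2000 trajectories per anomalous-diffusion
setting (mean α within ±0.1 and D within 15% for α ∈ {0.5, 1.0, 1.5}),
500-trajectory ensembles for drift-restoration checks (within 3 SE), and
200 rendered territories for the imaging round-trip. All randomness is
seeded; rerunning any pipeline with the same config and seed produces
byte-identical tables.

## Known limitations

* 2D only: shape is quantified on maximum-intensity projections; a 3D
  gyration tensor is out of scope.
* The imaging stage assumes one territory per field (largest component);
  multi-territory nuclei need upstream cropping.
* The EM fit assumes exactly two Gaussian components; strongly skewed or
  three-mode samples will still be forced into two.
* The drift model is the nuclear-centroid reference itself: rotational
  nuclear motion is not corrected.
* Reflecting confinement in the trajectory generator is approximate, as
  noted above.
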