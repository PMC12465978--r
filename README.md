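# territoryshape

Quantifying mesoscale chromosome-territory conformation and genomic-locus
dynamics from live-cell fluorescence imaging.

Interphase chromosome territories occupy micrometre-scale nuclear volumes
whose shape carries biological information: in some cell states a labelled
territory is drawn out into an extended, elongated conformation, in others
it collapses into a compact globule, and a population of cells typically
shows a *bimodal* mixture of the two. This package implements the analysis
chain used to quantify that behaviour from live-cell images of
repeat-tagged territories (e.g. CRISPR-based locus labelling), together
with the single-particle-tracking statistics used to characterise the
mobility of individual genomic loci, and the spike-in normalization
arithmetic for matched ChIP-seq experiments. A synthetic-data layer
generates territory curves, aspect-ratio samples, fractional-Brownian
trajectories and noisy image stacks with known ground truth, so every
stage of the chain is testable without any microscope data.

## The statistics at the core

**Territory shape.** A territory backbone is an ordered 2D curve of N
points r_i (µm). Its gyration tensor is the second central moment matrix

    Q_ab = (1/N) * sum_i (r_i,a − r_c,a)(r_i,b − r_c,b),

with r_c the centroid. The eigenvalues λ1 ≤ λ2 of Q are the squared
principal extents, and the **aspect ratio K = λ2/λ1** is the shape
statistic: K = 1 is perfectly round, larger K is more extended. Over a
population, K is bimodal and is modelled as a two-component Gaussian
mixture w_e·N(µ_e, σ_e²) + (1−w_e)·N(µ_c, σ_c²); the extended/collapsed
percentages are the fitted weights, per-territory labels come from the
posterior, and conditions are compared with Fisher's exact test on the
classified counts.

**Locus dynamics.** A tracked locus gives positions p(t_k) at uniform
interval Δt, drift-corrected against the nuclear centroid c(t_k) by
p′ = p − c + c(t_0). The time-averaged mean squared displacement over
overlapping windows,

    MSD(kΔt) = (1/(n−k+1)) * sum_{m=0}^{n−k} |p(mΔt+kΔt) − p(mΔt)|²,

is fitted with the anomalous-diffusion power law MSD = 4·D_app·Δt^α
(log-log least squares over the first quarter of lags), and two further
summaries are reported: the trajectory gyration radius
R_g = sqrt(mean |p(t_k) − p_c|²) (the radius of the explored area) and the
short-lag effective diffusion constant D_eff from a through-origin fit of
MSD = 4·D_eff·Δt over lags ≤ 3Δt. Groups are compared with Welch's
t-test.

**Spike-in normalization.** For ChIP-seq with mouse spike-in chromatin,
each sample's scale factor is f = m/s (m = minimum mouse-aligned read
count across samples, s = the sample's own), giving the subsampling
fraction and expected human read target per sample.

## Worked example

```r
library(territoryshape)

## shape of a synthetic extended territory backbone
curve <- generate_territory_curve(mode = "extended", seed = 7)
shape_from_curve(curve)
#> Gyration tensor of 200 points
#>   eigenvalues: 0.6334, 4.422 um^2
#>   aspect ratio K: 6.981

## a study-sized sample of aspect ratios, fitted with the bimodal model
k <- generate_k_sample(104, w_extended = 0.81, seed = 42)
fit <- fit_bimodal(k, seed = 1)
fit
#> Bimodal Gaussian fit of K (em, n = 104)
#>   collapsed: mean 1.848, sd 0.242 (weight 21.8%)
#>   extended:  mean 3.520, sd 0.569 (weight 78.2%)
#>   assignment threshold: K = 2.312
conformation_percentages(fit)
#>  pct_extended pct_collapsed
#>      78.19309      21.80691

## compare two conditions on classified counts (Fisher's exact test)
ob <- conformation_counts(classify_territory(k, fit))
os <- conformation_counts(classify_territory(
  generate_k_sample(100, w_extended = 0.31, seed = 43), fit))
compare_conditions(ob, os)[c("odds_ratio", "p_two_sided")]
#> $odds_ratio
#> [1] 5.388459
#> $p_two_sided
#> [1] 2.115288e-08

## dynamics: drift-corrected MSD, power law, R_g, D_eff
traj <- generate_trajectory(D_true = 0.01, alpha_true = 0.7,
                            drift_per_frame = c(0.02, 0), seed = 5)
round(trajectory_stats(traj), 4)
#>   n_frames    R_g  D_eff  D_app  alpha r_squared
#> 1      100 0.1782 0.0124 0.0093 0.5869    0.9818
```

The fitted weight (78% extended) recovers the generating 81% to within
the sampling error expected at n = 104 territories; the trajectory fit
recovers the generating subdiffusive exponent (0.59 fitted vs 0.7 true at
single-trajectory noise) after the injected drift has been removed
exactly by the nuclear-centroid correction.

Image stacks go through the same chain:
`generate_image_stack()` → `max_intensity_project()` →
`segment_territory()` → `extract_curve()` → `shape_from_curve()`, or in
one step through `run_conformation_pipeline()`. A thin CLI wrapper for
batch runs is in `inst/scripts/territoryshape`
(`simulate | conformation | dynamics | spikein` with YAML configs).

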