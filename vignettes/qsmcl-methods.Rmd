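---
title: "Models and methods behind qsmcl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind qsmcl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`qsmcl` quantifies absolute molecular quantities from DNA-PAINT
single-molecule localization data. This vignette documents the models the
package implements, the parameters that matter and why their defaults are
what they are, what the synthetic-data generator does and does not emulate,
and the numerical and design choices a maintainer should know about.

## The measurement model

DNA-PAINT reads out molecule positions through transient hybridization of
dye-labeled imager strands to docking strands on the target. A single
docking site produces an alternating dark/bright renewal process; over an
acquisition of `n_frames` frames every bright frame yields one localization
scattered around the true site position with isotropic Gaussian error of SD
σ (the localization precision). Three corrections separate what is imaged
from what is there:

* **Labeling efficiency (LE)** — the probability that a target molecule
  carries a functional docking strand. Published tag values used as
  defaults: HaloTag 0.30, SNAP-tag 0.20.
* **Detection efficiency (DE)** — the fraction of labeled molecules the
  automated cluster pipeline returns as clouds; measured in simulation by
  matching cluster centroids to ground-truth molecules, and in the
  experimental workflow by comparison with manual selection (50–60%
  regime).
* **Localization precision (σ)** — estimated from the data itself by the
  NeNA approach: displacements between nearest-neighbour localizations in
  consecutive frames stem mostly from repeated visits to one site and are
  Rayleigh-distributed with scale σ√2. The package fits a truncated
  Rayleigh by maximum likelihood on displacements below `max_radius`
  (default 100 nm; the cap suppresses cross-site pairs).

## Cluster detection and temporal filters

Localization clouds are found by DBSCAN with ε in nm and `min_pts`
localizations inside the ε-disk (the point itself counts). Defaults follow
the workflow's logic rather than fixed magic numbers:

* ε = the dataset's NeNA precision. Rationale: the ε-neighbourhood should
  capture the repeated-visit scatter of one site, whose scale *is* the
  localization precision.
* `min_pts = max(10, 0.3 × expected localizations per site)`, where the
  expectation `ξ · T · (mean bright time / exposure)` follows from the
  imager binding frequency. The 0.3 factor keeps genuine clouds (Poisson
  fluctuations and density fall-off at the cloud rim) while rejecting
  sparse background.

Both values are recorded per run in the pipeline manifest.

Two temporal filters then remove imager artefacts:

* **Mean-frame filter.** Genuine clouds are revisited throughout the
  acquisition, so their mean frame concentrates near `n_frames/2`;
  contaminations that appear or bleach early/late sit in the tails. The
  population of cluster mean-frames is summarized robustly (median and
  1.4826 × MAD by default; plain mean/SD optionally) and clusters outside
  centre ± 1 × spread are dropped. Two consequences are intentional:
  (i) the cut-off is a property of the *detected population* — the fit is
  stored on the filtered set and reused if the filter is re-applied, which
  makes the filter idempotent; (ii) a ± 1σ cut removes roughly a third of
  genuine clouds. That loss is part of the measured DE and is corrected
  by the DE term in every downstream quantity, which is why the pipeline's
  closed-loop density recovery works despite it.
* **Std-frame filter.** A cloud produced by one long sticking event of L
  frames has frame-SD ≈ L/√12, far below the ≈ 0.289 × `n_frames` of a
  uniformly revisited site. Clusters with frame-SD < 0.2 × `n_frames` are
  dropped; 0.2 sits safely below the uniform expectation and far above any
  plausible sticking artefact.

## qPAINT counting

Dark times of a single binding site are exponential with rate ξ (the
influx rate); n independent sites in one cloud superpose to rate nξ. With
ξ calibrated on reference clouds known to hold one site, a cloud's site
number is estimated as n̂ = τ_d,cal / τ̄_d. The default dark-time estimator
is the arithmetic mean of uncensored gaps; a censoring-aware exponential
MLE (`method = "mle"`) including the leading/trailing gaps is provided.
Counting consumes either simulator traces or detected clusters: cluster
frames are gathered pick-style from all localizations within 3 × ε of the
centroid — using only the DBSCAN member localizations would split binding
events wherever a tail localization was classed as noise and inflate the
count (during development this was a ~1.6× inflation on single-site
clouds).

Frame quantization drops binding events that cover less than half of any
frame (configurable `frame_overlap`), so the *absolute* calibrated influx
rate refers to detectable events and sits below the generative ξ at short
bright times. The counting estimator is a ratio of dark times measured
under identical conditions, so this detectability factor cancels; the
package's counting tests confirm linearity for 1, 2, 3 and 5 sites.

## Spatial statistics

Nearest-neighbour distances are computed exactly with a compiled kd-tree,
within a species (self-excluded) or across species. For a homogeneous
Poisson process of intensity ρ the order-k NND density is

$$P_k(r) = \frac{2(\pi\rho)^k}{(k-1)!}\, r^{2k-1} e^{-\pi\rho r^2},$$

with mean first-NND 0.5/√ρ. The default fit is maximum likelihood on raw
distances, which has the closed form ρ̂ = nk/(π Σ rᵢ²) with exact gamma
confidence intervals; a least-squares fit to the log-binned histogram is
available for figure parity with legacy fitting software. Goodness of fit
is reported as the KS p-value of the fitted-model probability transform.
Distances are reported without edge correction, matching experimental
practice; simulation benchmarks can enable toroidal wrap (`torus_period`)
to separate estimator properties from edge bias — the package's 2%-level
density-recovery tests do so deliberately.

## Colocalization calibration and inversion

The observed fraction of species-B molecules within 25 nm of a species-A
molecule mixes true complexes with density-driven chance proximity: against
a CSR reference of intensity ρ the chance fraction is 1 − exp(−πρr²).
The calibration curve simulates two species at the measured densities,
places a fraction c of B molecules 12–16 nm from a distinct A partner
(uniform distance and angle — the neutral reading of the tandem-tag
control's measured range), thins both species by their LEs, and records
the observed colocalization per c. Defaults: c on a 0–1 grid in 0.1 steps,
20 replicates, 10 × 10 µm region — sized so the Monte-Carlo SE of each
curve point is well below one percentage point. Inversion uses monotone
(isotonic-then-linear) interpolation of the replicate means, with an
uncertainty interval from where the observation crosses the curve ± SD
band; observations outside the curve are clipped and flagged. An optional
DE thinning of both species is off by default, since the complex-formation
recipe corrects by LE only; the flag exists because schematic descriptions
of the workflow include DE.

## Ternary tuples and the bootstrapped 2D KS test

For three species, each anchor molecule contributes a tuple of its
nearest-neighbour distances to the two partner species. Tuple clouds are
compared with the Fasano–Franceschini two-sample statistic: D is the
maximum, over all data points of both samples and the four quadrant
orientations, of the difference in empirical quadrant fractions (boundary
points count toward the quadrant closed on both axes). The bootstrap draws
`subsample` tuples per set without replacement (duplicate points would
distort quadrant counts), `runs` times; the null distribution is built by
within-set self-splits, and p is the fraction of null D draws at least as
large as the mean cross-set D.

This p-value construction is a declared methodological choice, and it is
*not* uniform under the null: comparing a mean against a matched
distribution concentrates the null p near 0.5 (measured in the test suite:
mean null p ≈ 0.46, zero rejections at the 0.05 level over 200 null
replicates). It is therefore conservative — same-source comparisons give
high p, genuinely different tuple clouds give p ≈ 0 — which mirrors how
the procedure is used: as a strong contrast between intrinsic and
cross-population comparisons, not as a calibrated frequentist test.

## The synthetic-data generator

The generator emulates: homogeneous Poisson molecule fields (50–1000
molecules/µm²), two-species populations with a tunable complexed fraction
at 12–16 nm pair distance, striped micropatterns, DNA-origami grids (20 nm
spacing; 1 or 3 concatenated binding sequences per site, scaling the event
rate 3×), exponential dark/bright kinetics quantized to frames, Gaussian
localization noise, and geometric photon counts. Kinetics defaults — mean
bright time 0.5 s, mean dark time 50 s (ξ = 0.02 s⁻¹ per sequence) at
100 ms exposure — are a plausible DNA-PAINT calibration regime chosen
once; they are not fitted to any dataset and all are overridable.

It does **not** emulate: drift and its correction, fiducials, raw camera
frames and PSF fitting, background localizations from non-specific imager
binding, multiple docking strands per antibody, photophysics beyond
first-order kinetics, or 3D. Passing tests therefore validate the
estimators under the stated model — unbiasedness, linearity, resolution,
closed-loop recovery — not robustness to every experimental nuisance.

## Numerical choices and degenerate inputs

* Localization tables are nm-denominated everywhere; pixels exist only at
  the I/O boundary (130 nm default pixel size). Frames are 0-based.
* DBSCAN input is sorted by (frame, x, y) so border-point assignment (first
  core cluster to reach them) is order-independent; `min_pts` counts the
  point itself.
* Events whose quantized frame ranges touch are merged; an event must
  cover ≥ 50% of a frame's exposure to light it (configurable).
* Greedy DE matching processes candidate pairs by increasing distance with
  ties broken by lower index; on sparse instances it coincides with the
  optimal assignment (checked against a maximum-bipartite-matching oracle).
* Degenerate inputs fail loudly: empty reference sets, all-equal distance
  vectors, zero-area masks, calibrations without usable dark times, and
  fewer than two clusters in the mean-frame filter (pass-through with a
  warning) are all explicit error or warning paths.
* One master seed expands into independent per-stage streams via a stable
  string hash, so adding a pipeline stage never perturbs another stage's
  draws.

## Problem sizes used in validation

The shipped checks run at desk scale, chosen to keep Monte-Carlo error
well inside each tolerance: density recovery at 10⁴ molecules per field;
resolution benchmarking with 50 pairs per separation at 80,000 frames;
counting studies with 200 reference sites and 60 clouds at 160,000 frames;
calibration curves with 20 replicates per grid point on 100 µm² regions;
bootstrap comparisons with subsamples of 500 tuples and 300 runs. The
command-line and pipeline layers are exercised on smaller fields since
they only orchestrate the same functions.

## Known limitations

* The colocalization calibration assumes the measured densities and the
  published LEs are correct; LE itself is not estimated from data.
* qPAINT counting saturates when many sites share one cloud (simultaneous
  binding events merge); linearity is validated up to 5 sites.
* The 2D-KS bootstrap p-value is conservative by construction (see above).
* Without deposited experimental data, experimental headline values
  (e.g. measured cell NNDs or observed colocalization percentages) can
  only be mirrored qualitatively by synthetic analogues.
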