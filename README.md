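# qsmcl — quantitative single-molecule colocalization analysis

Single-molecule localization microscopy (SMLM) can resolve individual
proteins, but only a fraction of the target molecules is ever seen: labeling
efficiencies (LE) of common protein tags are 20–30% and automated cluster
detection recovers only 50–60% of the labeled molecules (DE). Absolute
quantities — how many molecules per µm², what fraction of two species is in
a complex, whether three species co-assemble — cannot be read off such data
directly. `qsmcl` implements a quantitative single-molecule colocalization
workflow for DNA-PAINT data that corrects for both efficiencies by combining
automated cluster detection, kinetic molecular counting, spatial statistics,
and efficiency-aware simulation, so that absolute molecular quantities can
be inferred. Its intended users are microscopists and image analysts working
with DNA-PAINT / qPAINT localization tables (e.g. from focal-adhesion
biology, where the talin–kindlin–integrin machinery was first quantified
this way).

Because public localization data for this workflow are scarce, the package
ships a first-class synthetic-data module (molecule fields, DNA-origami
site layouts, frame-quantized imager binding kinetics, Gaussian
localization noise) that serves both as the validation harness and as the
simulation engine the quantification itself requires.

## What it computes

* **Cluster detection** — DBSCAN over localization coordinates with
  radius ε set to the estimated localization precision (NeNA estimator:
  nearest-neighbour displacements between consecutive frames are Rayleigh
  with scale σ√2) and `min_pts` tied to the imager binding frequency,
  followed by two temporal filters: clouds whose *mean frame* falls outside
  the population centre ± 1 spread, and clouds whose *frame SD* is below
  0.2 × n_frames (a uniform visit history gives n_frames/√12 ≈ 0.289 ×
  n_frames; a sticking event of length L gives only L/√12), are removed.
* **qPAINT counting** — dark times between binding events are exponential
  with rate ξ per binding site; with ξ calibrated on single-site reference
  clouds, a cloud's site number is n̂ = τ_d,cal / τ̄_d = 1/(ξ · τ̄_d).
* **Spatial statistics** — exact k-nearest-neighbour distances (kd-tree)
  within and across species; homogeneous-Poisson fits of the order-k NND
  law P_k(r) = 2(πρ)^k r^(2k−1) e^(−πρr²)/(k−1)! (k = 1: the familiar
  P(r) = 2πrρ e^(−πρr²)), with the closed-form MLE ρ̂ = nk/(π Σ r²);
  molecular densities per region-of-interest polygon.
* **Colocalization quantification** — the fraction of molecules of one
  species within 25 nm of the other, compared against simulation-based
  calibration curves (complexed fraction c → expected observed fraction
  under the given LEs) and inverted to the true complexed fraction; the
  absolute density extrapolation ρ_abs = ρ_measured/(LE · DE).
* **Ternary statistics** — per-anchor nearest-neighbour tuple clouds
  (e.g. integrin-to-kindlin vs integrin-to-talin distances), compared via a
  two-sample 2D Kolmogorov–Smirnov statistic (Fasano–Franceschini quadrant
  scan) with a subsample bootstrap.

## Worked example: absolute density from a simulated acquisition

```r
library(qsmcl)

cfg    <- kinetics_config(n_frames = 80000, sigma = 7)   # 100 ms exposure
roi    <- rect_mask(1500, 1500)                          # 2.25 um^2
field  <- apply_labeling(gen_random_field(600, roi, seed = 11), le = 0.30)
lp     <- labeled_points(field)
layout <- site_layout(lp$x, lp$y)
locs   <- render_localizations(simulate_kinetics(layout, cfg, seed = 12),
                               layout, cfg, seed = 13)

eps <- nena_precision(locs)
cs  <- detect_clusters(locs, cluster_params(eps, default_min_pts(cfg),
                                            cfg$n_frames))
de  <- detection_efficiency(cs, field, match_radius = 20)
extrapolate_density(density_in_mask(cs, roi), le = 0.30, de = de$de)
```

Output of this exact script:

```
molecules: 1328   labeled: 399   localizations: 312116
NeNA precision: 7.9 nm
clusters: 235   DE: 0.589
cluster density: 104.4 /um^2
absolute density: 591.1 /um^2
```

A field simulated at 600 molecules/µm² is observed at only ~104
clusters/µm² after 30% labeling and 59% detection; dividing the measured
density by LE × DE recovers 591 molecules/µm² — the closed loop that
justifies the same correction on experimental data. The measured DE of
0.59 emerges from the pipeline itself (mostly the ±1σ mean-frame filter),
matching the 50–60% regime reported for this analysis style.

The same functions drive the other analyses; see the methods vignette
(`vignettes/qsmcl-methods.Rmd`) for the models, parameter choices, and
validation scope, and `inst/scripts/qsmcl.R` for a thin command-line front
end over `run_pipeline()`.

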