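---
title: "Trajectory analysis for sub-millisecond MINFLUX tracking: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectory analysis for sub-millisecond MINFLUX tracking: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

MINFLUX single-molecule tracking localises individual membrane molecules
with a precision of about 7 nm at sub-millisecond rates, but the sampling
intervals are irregular (mean near 492 µs, heavy-tailed up to several
milliseconds) because localisation only completes when enough photons have
been collected. `minfluxsmt` implements a complete trajectory-analysis
pipeline for such data: immobile-track exclusion, two-species ratiometric
assignment, binned time-averaged MSD kinetics, transient-confinement
detection, turning-angle statistics, two-channel overlap quantification with
a Monte-Carlo significance test, and free/confined/hop diffusion model
selection. A synthetic-track generator with the same statistical structure
makes every stage testable without instrument data.

This vignette explains the models, the tunable parameters, the numerical
choices, and the points where the design was genuinely open.

## The synthetic-track generator

`simulate_dataset()` draws per-track localisations under one of five motion
models, then adds independent Gaussian localisation noise per axis
(`sigma_loc`, default 7 nm) and timestamps. Defaults are chosen to emulate
the acquisition statistics the pipeline assumes:

* **Sampling intervals.** Lognormal with mean 492 µs and SD/mean ≈ 780/492,
  clipped at 100 µs. The lognormal shape is our choice — the heavy-tailed
  "mean ± SD" statistic alone does not pin a distribution; the clip encodes
  the minimal photon-collection time.
* **Motion.** `brownian` uses Gaussian increments of variance `2 D dt` per
  axis (default D = 1e5 nm²/s, a typical membrane-molecule scale);
  `confined` adds reflective walls of a square of side `L` (reflection by
  folding, exact for instantaneous reflection); `hop` uses a square lattice
  of side-`L` compartments in which a boundary-crossing attempt succeeds
  with probability `p_hop`; `immobile` is pure localisation noise;
  `superdiffusive_drift` adds a constant drift velocity.
* **Hop defaults.** `L = 150` nm and `p_hop = 0.045` were calibrated once so
  that the effective compartmentalisation strength `S = D_mu / D_M`
  (long-lag ensemble-MSD slope against the short-term coefficient) is close
  to 3, a mid-range value for compartmentalised membrane diffusion. Measured
  values at the calibration: S ≈ 3.7 at `p_hop = 0.04` and ≈ 2.8 at 0.05.
* **Channel counts.** Per-localisation intensity is negative-binomial
  (overdispersed photon counting); a clipped-Gaussian per-localisation
  detector channel ratio (DCR = red/(red+blue)) splits it between the two
  spectral channels. Species A (cholesterol-like probe) has mean DCR 0.30,
  species B (toxin-like) 0.65, well separated around the 0.40/0.55
  assignment thresholds. During a simulated co-diffusion window the counts
  of a second emitter of the other species are added, which moves the DCR
  into the intermediate corridor and roughly doubles the intensity — the
  signature the detector looks for.
* **Two-state tracks.** `simulate_two_state_dataset()` alternates free
  episodes with residence in a reflective 50-nm trap on a known schedule
  (defaults 600 confined / 300 free localisations, i.e. ≈0.3 s and ≈0.15 s).
  The residence times place the trap visits inside the operating regime of
  the recurrence criterion at its default visit threshold; much shorter
  visits are genuinely invisible to that criterion.

What the generator does **not** emulate: motion blur (positions are
instantaneous; the blur factor R is nevertheless applied in fits, as the
analysis of real data would), bleaching/blinking photophysics, 3D motion,
and any instrument-specific beam geometry. Passing tests therefore
demonstrate correctness of the analysis on idealised tracks with the right
first- and second-order statistics, not robustness to every artefact of real
recordings.

## Immobile-track exclusion

A track's radius of gyration `Rg` (root-mean-square deviation from the
centroid) is compared with its mean step length: an immobile emitter's `Rg`
stays at the noise scale while its step length is set by noise too, so the
ratio is O(1); a mobile track accumulates displacement and the ratio grows.
When no threshold is supplied, `classify_mobility()` locates the immobile
mode of the (bimodal) ratio distribution by a two-means split of the log
ratios and sets the threshold at that mode's upper 95% band,
`mean + 1.96 SD` over the lower cluster. In a dataset with a substantial
immobile subpopulation (about half of the tracks, as in the recordings this
emulates) this places the cut just above the immobile mode, well inside the
gap between the modes; at the 100 + 100 benchmark the per-class error is
below 5%. A plain CI-of-the-mean rule over the whole mixture was considered
and rejected: its threshold scales with the mixture composition and clips
the lower tail of the mobile mode. If the distribution shows no separated
immobile mode, a warning is issued and the CI-of-the-mean fallback is used —
for such datasets an explicit threshold should be supplied, which mirrors
the practice of excluding immobile-free datasets from threshold
selection.

## Binned TA-MSD and the anomalous-diffusion fit

Displacement pairs are binned by time separation (`delta0 = 84` µs offset,
`dt_bin = 132` µs width), the bin's nominal lag being `m dt_bin`. Because
the intervals are irregular, the mean pair separation inside a bin
(`tau_mean`) can deviate from the nominal lag at small `m`; the curves carry
it, and the model-selection fits evaluate models there.

The per-track fit is
`msd(m) = Γ (m Δt)^(β−1) · 2 n_d Δt m (1 − 2R/m) + 2 n_d σ²` with `R = 1/6.2`
(motion blur under homogeneous illumination), `n_d = 2`, and
`K_β = 2 n_d Γ`. Numerical choices:

* bounded Levenberg–Marquardt (β ∈ [0.1, 2], Γ ∈ (0, 1e9], σ ∈ [0, 100] nm),
  one data-driven start (log–log slope) plus nine random restarts;
* weights from the inverse-variance model
  `Var(msd_m) ≈ μ_m² (2/n_pairs + m Δt / T)`. The first term is ordinary
  pair-count noise; the second captures the *correlated* fluctuations of a
  single-track MSD, whose relative variance grows like lag/duration. Two
  iteratively reweighted passes evaluate the weights at the current model
  curve. Pure pair-count weighting leaves β dominated by the long-lag
  excursions (β SD ≈ 0.2 on 2000-step Brownian tracks, against ≈ 0.06 with
  the variance model); the pair counts still enter the weights.
* fits with residual SD above 1000 nm², or on curves with at most half of
  the available bins populated, are flagged invalid;
* regimes: subdiffusive β ≤ 0.9, Brownian 0.9 < β ≤ 1.1, superdiffusive
  β > 1.1. (The alternative closure β < 0.9 / 0.9 ≤ β appears in some
  descriptions; the difference has measure zero and we use the former.)

Benchmarks in the test suite use 2000-localisation Brownian tracks (about
1 s, matching long co-tracking recordings) fitted up to 50 ms; confinement
sojourns are fitted up to 25 ms.

## Recurrence-based confinement detection

For every consecutive localisation pair a circle is drawn at the midpoint
with diameter equal to the step length; the number of track localisations
falling inside is the circle's visit count. If it exceeds `v_th = 33` both
endpoints are marked confined (the historical preset 11 over-calls
confinement at these sampling rates and is kept only as an option). A
radius floor of 7 nm (the localisation precision) prevents zero-area circles
under noise; visits are counted over the whole track, past and future —
the simplest reading of "revisiting an area". The raw state sequence is
smoothed by majority vote in non-overlapping 3-step windows (a trailing
partial window takes its own majority; a tie inherits the previous window's
state). Maximal runs become sojourns; a sojourn's interval extends to the
start of the next sojourn so confined and free residence times partition
the track duration exactly, making `r + free fraction = 1` an identity.
Confined sojourns get a convex-hull area and a second-moment ellipse
(semi-axes at 2 SD; no specific ellipse algorithm is canonical here, and the
covariance ellipse is the standard moment-based choice).

## Turning angles

The angle between successive displacement vectors at integer step lags
(step lags, not time lags, because of the irregular intervals), histogrammed
in 10° bins over [0°, 180°]. Zero-length displacement vectors are skipped
(the angle is undefined) and counted. For stratified densities, angles are
computed within sojourns only, so that no vector straddles a confined/free
boundary, and raw angles are pooled across tracks per stratum before
normalisation. Brownian increments give a uniform density; confinement
gives a density rising towards 180° whose slope relaxes as the step lag
grows, provided the lag-Δ displacement stays below the domain size — with
~100 nm domains and ~10 nm steps the relaxation is visible by Δ = 8,
while in very small domains (≈50 nm) the angle distribution is already
saturated at Δ = 1 and stays anticorrelated at all lags.

## Two-species overlap and the IoU significance test

Confined-region overlap is counted via convex-hull intersection (an exact
separating-axis test for the convex hulls; verified against a brute-force
edge/containment oracle), reported as the coefficient `C` in both
directions. Free-walk proximity uses a fixed-radius neighbour query
(`r = 10` nm, the localisation precision) on a uniform-grid spatial index
that agrees exactly with the all-pairs computation.

Significance of co-confinement uses the grid IoU: the ROI is divided into
7 × 7 nm cells (half-open, anchored at the bounding-box minimum corner),
occupancy is marked per species from confined localisations, and
IoU = |A∧B| / |A∨B|. The null model re-places circular confinement zones of
the same radii uniformly in the ROI (total zone area ≈ 10% of the ROI,
independently per species) and runs surrogate walks through them; the
observed IoU is compared against the `⌈(1−α)(n_sims+1)⌉`-th order statistic
of the simulated IoUs — the exchangeability-exact Monte-Carlo critical
value, which keeps the type-I error at α even for modest `n_sims`. With
`n_sims = 100` and α = 0.05 the measured null rejection rate is
0.035–0.05 across calibration runs.

## Free / confined / hop model selection

Mobile tracks are truncated to 500-localisation segments (a final partial
segment of at least 250 is kept — the truncation convention needs a rule
for remainders and half a segment is the natural cut). Per segment the
initial 20% of the TA-MSD bins (counted in bins, not lag time) is resampled
at ≈15 log-spaced lags and fitted to three corrected models:

* free: `2 n_d D Δt (n − 2R) + 2 n_d σ²`
* hop: `2 n_d Δt {D_M + ((D_µ−D_M)/D_µ)(L²/(6 n_d n Δt))[1 − e^{−12 D_µ n Δt/L²}]}(n − 2R) + 2 n_d σ²`
* confined: `(L²/3)[1 − e^{−12 D_µ n Δt/L²}](n − 2R) + 2 n_d σ²`

and the lowest BIC (`n ln(SSR/2) + k ln n`, k = 2/3/4) wins. Three design
points deserve explanation:

1. **Whitened selection.** The residuals of a single-segment MSD curve are
   strongly and smoothly correlated; fitted naively, the flexible models
   absorb those excursions and Brownian segments are misclassified about
   half of the time. Selection therefore whitens the residuals with the
   covariance model
   `C_ij = msd_i msd_j ((4/3) min(τ_i, τ_j)/T + (2/n_pairs_i) δ_ij)`
   (a random-walk-in-lag structure for the correlated part plus independent
   pair-count noise) and computes the BIC on the whitened residuals. On
   synthetic ground truth this lifts correct-classification of free
   segments to ≈ 75–80% while retaining sensitivity to confinement and
   hopping.
2. **The confined model as printed is convex before saturation** (the
   `(n − 2R)` factor multiplies the saturating term directly, so the model
   equals the hop model at `D_M = 0` only up to a factor of n). It is
   implemented exactly as specified, but two consequences follow: genuinely
   confined segments are usually captured by the hop model with `D_M`
   collapsing to zero, and the confinement size is better read from the
   uncorrected plateau form `(L²/3)(1 − e^{−t/τ})` (plateau = L²/3,
   `τ = L²/(12 D_µ)`), which `fit_and_select()` fits separately and reports
   as `l_conf`.
3. **Unresolved D_M relabel.** A hop selection with fitted
   `D_M < 1e4 nm²/s` (an order of magnitude below membrane-scale diffusion;
   configurable) is reported as confined: within a ≈50 ms fit window an
   inter-compartment coefficient that small cannot be distinguished from
   zero, which is precisely the situation the confined model exists for.
   Conversely `S = D_µ/D_M` is only reported when hop is retained. Reported
   parameter values come from ordinary unweighted fits (amplitudes such as
   `L_hop` are pinned by the plateau-scale points, which the whitening
   deliberately discounts), while the class decision uses the whitened
   fits; the two roles need different estimators.

The hop fit enforces `D_µ > D_M` by construction (`D_M = f·D_µ`,
`f ∈ (0, 1]`); the stricter `D_µ > 5 D_M` variant is available via
`constraint = "s_gt_5"` but not default, since S slightly above 1 is
physically meaningful.

At the benchmark conditions (500-localisation segments, irregular sampling)
the measured rates are ≈ 75% correct on free cohorts, ≈ 55–60% "confined or
hop-with-unresolved-D_M" on confined cohorts (L = 130 nm, τ_eq ≈ 35 ms —
close to the resolvable limit of a 0.25 s segment), and a plurality of hop
with S ≈ 3 recovered on hop cohorts. These are intrinsic limits of
per-segment MSD model selection at this data volume, not implementation
artefacts: the confined-versus-hop distinction requires lags several times
the equilibration time.

## Reporting policy and statistical tests

All reported means and SEMs are computed across ROIs, never across tracks
(`run_pipeline()`'s summary); per-track tables are exported alongside.
Two conditions are compared metric-by-metric with the two-sample
Kolmogorov–Smirnov test on ROI-level values; three or more with the
Kruskal–Wallis test (`compare_conditions()`).

## Problem sizes used by the test suite

The suite's simulation scales were chosen to make the statistical criteria
sharp at desk scale: 200 tracks × 2000 localisations for the Brownian
calibration; 100 + 100 tracks for the immobility benchmark; 15 two-state
tracks × 1800 localisations for confinement; 10⁶ angles for the uniformity
test; 500 repetitions × 100 null simulations for the IoU calibration; and
200 segments per cohort (15 restarts per model fit) for model selection.
The acceptance script reruns the same computations at moderately reduced
sizes and reports the resulting quantities.

## Known limitations

* The generator omits motion blur and photophysics (see above).
* The automatic mobility threshold assumes a visible immobile
  subpopulation.
* Confinement detection requires trap residencies long enough to exceed the
  visit threshold; brief visits (≲ 0.1 s at these rates) go undetected.
* Per-segment model selection near the equilibration-time limit is
  intrinsically uncertain; ensemble curves (`ensemble_model_curves()`)
  should accompany per-segment class fractions.
* ROI polygons are treated as simple polygons in the plane; localisations
  are not re-projected or filtered against membrane topology.
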