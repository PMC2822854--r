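---
title: "Methods: speed-mixture behavioural classification and rotation-null habitat association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: speed-mixture behavioural classification and rotation-null habitat association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shelfbreak)
```

`shelfbreak` analyses GPS tracks of pelagic seabirds that mix two
sampling regimes: continuous 5-second fixes (short, detailed) and a
burst of fixes at every two-hour wake-up (long, sparse). This vignette
is the package's account of its methods: the models, every tunable that
matters, the numerical conventions, and the limits of what the synthetic
generators can demonstrate.

## Ingest and filtering

Fixes carry a timestamp (UTC), WGS84 lon/lat, an optional satellite
count and an optional quality flag. `filter_fixes()` keeps a fix when it
used at least `min_sats = 4` satellites *or* carries a `FIX3D` flag —
four satellites are what a receiver needs to resolve altitude, the
higher-accuracy "3D" class — because device logs may carry either field.
Fixes with neither field are dropped and counted. Speeds of exactly
0 m s⁻¹, a receiver null-velocity artefact, are excluded later, at the
modelling stage (`fit_mixture_em()`), not at ingest: the artefact lives
in the speed series, and log(0) is undefined under the log-space model.

All geometry is spherical, radius 6,371,008.8 m (haversine distances,
great-circle bearings and destinations, via `geosphere` with zero
flattening). The spherical error is far below GPS noise at foraging-trip
scales and keeps every number reproducible. Trip area is the convex hull
of the fixes after a Lambert azimuthal equal-area projection centred on
the colony, so hull area is projection-exact.

Rasters (bathymetry, or any co-registered field such as chlorophyll-a
concentration) are regular lon/lat grids of elevation with an NA mask,
read and written as plain-text ESRI ASCII grids. Sampling is
nearest-cell; a point exactly on a cell boundary belongs to the cell
with the smaller index (floor convention), asserted in the tests because
rotated tracks regularly produce boundary-adjacent coordinates.

## The speed mixture

Let $v_i$ be over-ground speeds between consecutive fixes no more than
`max_dt = 30` s apart (pairs spanning duty-cycle gaps are skipped). The
model is a $K$-component Gaussian mixture on $x_i = \log v_i$:

$$p(x) = \sum_{k=1}^{K} w_k\, \mathcal{N}(x;\, \mu_k, \sigma_k^2),$$

fitted by EM. Modelling in log space avoids placing probability on
negative speeds and makes the two modes near-symmetric. Conventions:

* **Initialisation** is a deterministic K-quantile split of the sorted
  log speeds (group means/variances/proportions). The default fit is
  therefore fully reproducible without a seed; a seed only perturbs the
  optional random restarts (`n_restarts`), which the well-separated
  two-mode problem does not need.
* **Convergence**: relative log-likelihood change below `tol = 1e-8`, or
  500 iterations. The E step runs in log space (log-sum-exp); variances
  are floored at `1e-8` of the total variance to keep the likelihood
  bounded. The log-likelihood trace is stored, and the test suite
  asserts it never decreases — the EM guarantee — on every fit it runs.
* **Degenerate inputs** error: fewer than $2K$ positive speeds, all
  speeds equal, $K < 1$, negative speeds.
* **Reporting**: components are ordered by mean; with $K = 2$ the lower
  mean is `SLOW` (drift) and the higher `FAST` (flight).
  `natural_scale_summary()` maps $(\mu_k, \sigma_k^2)$ to natural-scale
  moments via the exact log-normal identities (mean
  $e^{\mu + \sigma^2/2}$, variance $(e^{\sigma^2}-1)e^{2\mu+\sigma^2}$),
  and `lognormal_params()` is the exact inverse. Published mode
  means/variances on the m s⁻¹ scale are interpreted as these log-normal
  moments — the self-consistent, invertible reading when the fit itself
  is in log space.

**Classification** assigns a speed to the component maximising
$w_k\,\mathcal{N}(\log v; \mu_k, \sigma_k^2)$. An exact posterior tie
goes to the slower component: misclassifying rest as flight inflates
apparent foraging range, the worse error for a conservation snapshot.
Burst clusters (`segment_clusters()`, split at inter-fix gaps strictly
greater than `gap_s = 600` s — unambiguous against the 7,200-s cycle)
are classified by their **median** within-burst speed; the median is
robust to single-fix jitter, and per-fix posterior pooling would give
the handful of burst fixes spuriously confident products. Clusters with
fewer than two fixes have no speed, are flagged, and never enter
proportions.

The transfer design — fit on the near-complete high-resolution tracks,
classify the sparse bursts — mediates behaviour-dependent acquisition
bias. The suite checks this directly: over 100 simulated replicates in
which sitting fixes survive at 0.9 and flight fixes at 0.5, the
transferred model's mode-mean errors are smaller on average than those
of a mixture refitted on the biased sparse speeds.

## Rotation null and repeated KS testing

For habitat association the null asks what depths a trip *could* have
covered. `rotate_track()` maps each fix to the same great-circle
distance from the origin with its initial bearing shifted by the
rotation angle — an isometry about the origin, so the track's internal
structure (inter-fix distances, timing, labels) is untouched. The
**origin is the track's first fix**: deployments begin at the burrow, so
the first fix is the colony; it is configurable for tracks cut mid-trip.
The default null uses angles $k \times 22.5°$, $k = 1..15$ — fifteen
equally spaced rotations through 360°, the sixteenth being the identity.
Depths are sampled under every rotated fix; positions over land
(elevation ≥ 0 in the bathymetry itself, no separate coastline dataset)
and over nodata are excluded, and rotated positions leaving the raster
extent are dropped with a count. High-resolution tracks are first
reduced by `merge_windows()` (one mean location per 120-s half-open
window, stamped at the window centre) to limit pseudo-replication of
5-second fixes.

`ks_two_sample()` computes the exact two-sample $D$ — the supremum ECDF
gap, by a sweep over pooled breakpoints, correct under ties (routine for
raster-sampled depths) — and an asymptotic p-value from the Kolmogorov
distribution at effective size $n_1 n_2/(n_1+n_2)$, using the
theta-function form of the CDF for small arguments and the alternating
series otherwise. `stats::ks.test(exact = FALSE)` and a brute-force
sweep serve as independent oracles in the tests.

`repeated_subsample_test()` draws, per run, a without-replacement
subsample of the null pool equal in size to the observed sample and
applies the KS test; 1000 runs by default. Because no single aggregation
rule is canonical, it reports the full per-run table, the proportion of
runs significant at `alpha = 0.05`, and median $D$ and $p$, and declares
overall significance when the proportion reaches 0.95 (configurable).
Per-track tests are reported without multiple-testing correction across
tracks; users comparing many individuals should adjust.

One calibration subtlety is worth stating plainly. For a *fixed*
observed sample drawn from the null pool, the proportion of significant
runs is itself a highly dispersed random variable — most draws give a
proportion near zero, occasional draws give large ones — because the
runs share the one observed sample. The package's calibration test
therefore evaluates the unconditional size: each of 1000 runs draws a
fresh observed sample from the pool, and the pooled rejection rate is
required to sit near the nominal 5% (the asymptotic p-values are
slightly conservative at these sample sizes, so "near" spans roughly
3–8%). Shifting the observed sample by ten standard deviations drives
every run significant, the power end of the same check.

`depth_band_occupancy()` reports the fraction of samples in the
600–1000 m band (depth $= -$elevation; both edges inclusive), the
operational definition of the shelf-break, overall or split by
behaviour label.

## Entropy (tortuosity) profile

The unpredictability score is this package's own self-contained
operator: at each fix, the (turn angle, speed) pairs of interior fixes
within ±300 s (window 600 s) are binned on a fixed 8 × 4 grid — turn
bins uniform over (−180°, 180°], speed bins at the track's own speed
quartiles, making the operator scale-free across individuals — and the
profile value is the Shannon entropy (bits) of the normalised joint
histogram: 0 for steady straight flight, up to $\log_2 32 = 5$ bits for
movement spread over every bin. Turn angles are signed changes in
great-circle bearing, wrapped to (−180°, 180°], positive clockwise.
Windows with fewer than 5 pairs are flagged undefined; quartile breaks
that collide within numerical jitter collapse (a constant-speed track
uses a single speed bin). `categorize_entropy()` bands the profile into
within-track quantile categories for display; all-equal entropies fall
in category 1. It is a *reimplementation of the analysis role* — a local
unpredictability score along the track — not a replication of any
specific published estimator, and no figure-level numeric agreement is
claimed. The operator is rotation-invariant (asserted in tests) and, on
simulated tracks alternating straight legs with tortuous bouts, scores
the bouts higher in at least 19 of 20 seeded replicates.

## Synthetic data: what it emulates, and what it does not

`simulate_two_state_track()` is a discrete-time two-state Markov switch
(drift/flight). Per 5-s step: a speed from the state's log-normal
(natural-scale moments: drift 0.83 m s⁻¹, variance 0.13; flight
10.20 m s⁻¹, variance 27.0 — the fitted high-resolution values, used as
generator settings), a heading increment $\mathcal{N}(0, sd)$ with
sd 5° in flight (near-straight commuting) and 60° in drift (diffuse
wander), and a great-circle advance. Switch probabilities default to
0.005 per step — mean bouts of ~17 min, long enough that bursts usually
sample a single behaviour — chosen once as a realistic bout scale; no
published bout statistics constrain it. Tracks start in flight (birds
leave the colony on the wing). `apply_duty_cycle()` reproduces the two
field regimes; the burst length defaults to 60 s (the two-hour cadence
is fixed by the schedule, the burst length is not, so it is a
parameter). `apply_acquisition_bias()` thins fixes per true state.
`make_shelf_bathymetry()` builds land, a shallow shelf, a monotone ramp
containing every depth in 600–1000 m, and an abyssal plain, with ±10 m
seeded cell roughness outside the band so sampled depths are effectively
continuous. `simulate_speed_mixture()` draws i.i.d. speeds from the
two-mode log-normal; its default **equal weights** are a choice — no
mixing proportions are published for the high-resolution fit — and the
mode-recovery results are insensitive to moderately unequal weights.

Not emulated: wind (the flight mode's large variance is carried entirely
by its speed distribution, with no into-/down-wind structure), currents,
central-place trip shape (no drift homeward pull), positional GPS error
(positions are exact; speeds inherit no jitter), tides, and any
behaviour–habitat coupling in the *track generator* itself (tests that
need sitting-over-the-band structure place locations explicitly).
Passing tests therefore demonstrate that the estimators recover the
structure this generator creates — mode separation at 0.83 vs
10.2 m s⁻¹ makes the Bayes error of classification negligible — not that
real tracks satisfy the model.

## Problem sizes and reproducibility

The shipped tests run, per check: 100 replicates of 5,000-speed mixture
fits; 1000-run repeated KS calibrations on rotation-null pools of a few
thousand depths (observed size 400); 50 end-to-end habitat replicates of
300 locations each; 20 entropy replicates of 2-hour tracks; and 12–48 h
simulated tracks at 5-s resolution — sizes at which the whole suite
completes in about a minute while keeping Monte-Carlo error well inside
the asserted margins. Every stochastic step takes an explicit integer
seed, and all generators are bit-reproducible under a fixed seed.

Known limitations: no hidden-Markov temporal dependence in
classification (each speed classified independently); no model-selection
machinery beyond per-K log-likelihood (K = 2 is an empirical choice for
this system); asymptotic (not exact) KS p-values; no ellipsoidal
geometry; GeoTIFF rasters must be converted to ESRI ASCII externally;
and the null subsamples are drawn without replacement (the natural
reading of drawing "equally sized random distributions" from a finite
pool).
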