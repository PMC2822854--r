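# shelfbreak

Behavioural classification and shelf-break habitat association for
GPS-tracked pelagic seabirds.

## The problem

Miniature GPS loggers deployed on a foraging seabird return two kinds of
track: short stretches of continuous 5-second fixes, and long duty-cycled
records where the receiver wakes for a brief burst of fixes every two
hours to save power. From these, three questions recur in movement
ecology:

1. **What was the bird doing?** Over-ground speed separates two modes of
   at-sea behaviour — slow drift while sitting on the water (~0.8 m s⁻¹,
   moving with the current) and fast flight (~10 m s⁻¹, with large
   variance from wind). `shelfbreak` models the speed distribution as a
   K-component Gaussian mixture on log speed,

   p(log v) = Σₖ wₖ 𝒩(log v; μₖ, σₖ²),

   fitted by expectation-maximisation on the near-complete
   high-resolution tracks, and classifies each speed (or each two-hour
   burst cluster, via its median within-burst speed) to the component
   under which it is most probable. Fitting on the complete track and
   *transferring* the model to the sparse bursts matters: fix-acquisition
   success can depend on behaviour, and a model refitted on the sparse
   data would inherit that bias. Fitted modes are reported on the natural
   scale through the log-normal moment map (mean = exp(μ + σ²/2)).

2. **Was the bird selecting particular seafloor depths?** For each track
   a randomisation null asks which depths the bird *could* have used:
   the track is rigidly rotated about its origin (the colony) through
   fifteen 22.5° angles — preserving its internal geometry while sweeping
   it over the surrounding bathymetry — and seafloor depth is sampled
   under every rotated fix, excluding positions over land. The observed
   depth distribution is then compared with equal-size random subsamples
   of this null pool by two-sample Kolmogorov–Smirnov tests, repeated
   1000 times; the proportion of significant runs, and median D and p,
   summarise the association. Occupancy of the 600–1000 m band
   operationalises use of the shelf-break. High-resolution tracks are
   first thinned to one merged location per two-minute window to limit
   pseudo-replication.

3. **Where was movement unpredictable?** A sliding-window Shannon
   entropy of the joint (turn angle × speed) histogram profiles local
   path tortuosity along high-resolution tracks: straight commuting legs
   score near 0 bits, area-restricted search spreads over many bins and
   scores high.

Because tracking data of threatened species are rarely released, the
package ships generators for everything it analyses: two-state
Markov-switching tracks with log-normal speeds, duty-cycle subsampling,
state-dependent fix loss, and shelf-break bathymetry grids — so the full
pipeline is testable end-to-end.

## Worked example

```r
library(shelfbreak)

# 1. fit the movement model on a high-resolution track
hires  <- simulate_two_state_track(sim_config(duration_s = 12 * 3600), seed = 42)
speeds <- compute_speeds(hires, max_dt = 30)
fit    <- fit_mixture_em(speeds$speed, K = 2)
fit
#> <sb_mixture> K = 2, n_obs = 8640
#>   [1] w = 0.440  log: mu = -0.275, s2 = 0.181  natural: mean = 0.832 m/s, var = 0.137
#>   [2] w = 0.560  log: mu = 2.205, s2 = 0.228  natural: mean = 10.169 m/s, var = 26.519
#>   EM: 10 iterations, loglik -11291.3751
```

The two components recover the generator's drift (0.83 m s⁻¹) and flight
(10.20 m s⁻¹) modes. Transfer the model to a two-hourly duty-cycled
track and classify each burst as sitting or flying:

```r
lowres   <- apply_duty_cycle(simulate_two_state_track(
              sim_config(duration_s = 47 * 3600), seed = 43), "BURST_2H")
clusters <- classify_cluster(fit, segment_clusters(lowres, gap_s = 600))
round(classification_proportions(clusters$label, fit), 3)
#>  SLOW  FAST
#> 0.458 0.542
```

Test whether the depths under a track differ from the depths it could
have reached, against a synthetic shelf-break bathymetry:

```r
bathy  <- make_shelf_bathymetry(bathy_config())
trk    <- simulate_two_state_track(sim_config(duration_s = 6 * 3600),
                                   seed = 44, start = c(175.3, -36.2))
merged <- merge_windows(trk, window_s = 120)   # 2-min anti-pseudo-replication
obs    <- depth_under_track(merged, bathy)
pool   <- build_rotation_null(merged, bathy)
repeated_subsample_test(obs$depth, pool$depth, n_runs = 1000, seed = 45)
#> Repeated subsample KS (1000 runs, n = 181, alpha = 0.05):
#>   significant runs: 100.0%  median D = 0.2652  median p = 5.926e-06
#>   overall: significant
depth_band_occupancy(obs)          #> 0
depth_band_occupancy(pool$depth)   #> 0.146
```

Every subsample comparison rejects: this bird's observed depths (an
abyssal-side excursion, 0% of locations over the 600–1000 m shelf-break
band) are unambiguously different from the depth distribution available
within rotation reach of its colony (14.6% over the band). See
`vignettes/shelfbreak-methods.Rmd` for the model, the null construction,
parameter choices, and what the synthetic generators do and do not
emulate.

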