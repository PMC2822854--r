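# Synthetic two-state tracks and shelf-break bathymetry.
#
# The generators reproduce the statistical structure the analysis relies
# on: two movement modes with log-normal speeds (slow surface drift around
# 0.83 m/s, fast flight around 10.2 m/s with large variance), Markov
# switching between them, heading persistence that is tight in flight and
# loose while drifting, the two field sampling regimes (continuous
# 5-second fixes; a 60-second burst every two hours), behaviour-dependent
# fix loss, and a bathymetry grid with land, a shallow shelf, a monotone
# 600-1000 m shelf-break band and an abyssal plain.

#' Two-state movement simulation settings
#'
#' Defaults are the fitted high-resolution movement modes: drift mean
#' 0.83 m s^-1 (variance 0.13), flight mean 10.20 m s^-1 (variance 27.0).
#' Switch probabilities are per time step; the default 0.005 per 5-s step
#' gives mean bout lengths of ~17 minutes in each state, bouts long
#' enough to look like real sitting spells and commuting legs. Heading
#' noise is a per-step Gaussian increment: nearly straight in flight
#' (sd 5 deg), diffuse while drifting (sd 60 deg).
#'
#' @param slow_mean,slow_var Natural-scale mean (m s^-1) and variance of
#'   the drift mode.
#' @param fast_mean,fast_var Natural-scale mean and variance of the flight
#'   mode.
#' @param p_slow_to_fast,p_fast_to_slow Per-step switch probabilities.
#' @param fix_interval_s Simulation time step, seconds (default 5).
#' @param duration_s Track duration, seconds (default 24 h).
#' @param heading_sd_slow,heading_sd_fast Heading-increment standard
#'   deviations, degrees.
#' @return List of class `"sb_sim_cfg"`.
#' @export
sim_config <- function(slow_mean = 0.83, slow_var = 0.13,
                       fast_mean = 10.20, fast_var = 27.0,
                       p_slow_to_fast = 0.005, p_fast_to_slow = 0.005,
                       fix_interval_s = 5, duration_s = 86400,
                       heading_sd_slow = 60, heading_sd_fast = 5) {
  stopifnot(slow_mean > 0, fast_mean > 0, slow_var >= 0, fast_var >= 0,
            p_slow_to_fast >= 0, p_slow_to_fast <= 1,
            p_fast_to_slow >= 0, p_fast_to_slow <= 1,
            fix_interval_s > 0, duration_s >= fix_interval_s)
  structure(as.list(environment()), class = "sb_sim_cfg")
}

#' Simulate a two-state movement track
#'
#' Discrete-time Markov switching between drift (`"SLOW"`) and flight
#' (`"FAST"`). Each step draws a speed from the state's log-normal
#' distribution (natural-scale moments from the config, mapped through
#' [lognormal_params()]), updates the heading by a state-dependent
#' Gaussian increment, and advances the position along a great circle.
#' The true state is stored with every fix, and fixes carry full GPS
#' quality (`n_sats = 8`, `FIX3D`) so the generator's output passes the
#' accuracy filter untouched.
#'
#' @param cfg A [sim_config()].
#' @param start `c(lon, lat)` of the first fix (the colony).
#' @param seed Integer seed; same seed, same track.
#' @param t0 Timestamp of the first fix.
#' @param id Track id.
#' @return An [track()] with regime `"OTHER"` (the raw simulation grid;
#'   see [apply_duty_cycle()]) and a `state` column of true modes.
#' @export
simulate_two_state_track <- function(cfg = sim_config(),
                                     start = c(175.0, -36.2),
                                     seed = NULL,
                                     t0 = as.POSIXct("2006-02-24 00:00:00",
                                                     tz = "UTC"),
                                     id = "sim") {
  stopifnot(inherits(cfg, "sb_sim_cfg"))
  if (!is.null(seed)) set.seed(seed)
  n <- floor(cfg$duration_s / cfg$fix_interval_s) + 1
  p_slow <- lognormal_params(cfg$slow_mean, cfg$slow_var)
  p_fast <- lognormal_params(cfg$fast_mean, cfg$fast_var)
  # state sequence: 1 = SLOW, 2 = FAST; start in flight (birds leave the
  # colony on the wing)
  state <- integer(n)
  state[1] <- 2L
  u <- runif(n - 1)
  for (i in 2:n) {
    p_sw <- if (state[i - 1] == 1L) cfg$p_slow_to_fast else cfg$p_fast_to_slow
    state[i] <- if (u[i - 1] < p_sw) 3L - state[i - 1] else state[i - 1]
  }
  mu <- ifelse(state == 1L, p_slow$mu, p_fast$mu)
  sig <- ifelse(state == 1L, sqrt(p_slow$sigma2), sqrt(p_fast$sigma2))
  speed <- rlnorm(n, mu, sig)
  hsd <- ifelse(state == 1L, cfg$heading_sd_slow, cfg$heading_sd_fast)
  heading <- .wrap180(cumsum(c(runif(1, -180, 180), rnorm(n - 1, 0, hsd[-1]))))
  lon <- numeric(n); lat <- numeric(n)
  lon[1] <- start[1]; lat[1] <- start[2]
  step_d <- speed * cfg$fix_interval_s
  for (i in 2:n) {
    p <- .dest_point(lon[i - 1], lat[i - 1], heading[i], step_d[i])
    lon[i] <- p[1, 1]; lat[i] <- p[1, 2]
  }
  fixes <- data.frame(
    time = t0 + (seq_len(n) - 1) * cfg$fix_interval_s,
    lon = lon, lat = lat, n_sats = 8L, quality = "FIX3D",
    state = c("SLOW", "FAST")[state], stringsAsFactors = FALSE
  )
  track(fixes, id = id, regime = "OTHER")
}

#' Subsample a simulated track to a field duty cycle
#'
#' `"CONTINUOUS_5S"` resamples to 5-second spacing (the high-resolution
#' regime); `"BURST_2H"` keeps `burst_len_s` of consecutive fixes at the
#' start of every two-hour cycle (the low-power regime; the burst length
#' is configurable — 60 s by default — since only the two-hour cadence is
#' fixed by the schedule). Output fixes are always a subset of input
#' fixes.
#'
#' @param track An [track()] at <= 5 s resolution.
#' @param mode `"CONTINUOUS_5S"` or `"BURST_2H"`.
#' @param burst_len_s Burst length for `"BURST_2H"`, seconds.
#' @param cycle_s Duty-cycle period, seconds (default 7200).
#' @return The subsampled track, regime tag updated.
#' @export
apply_duty_cycle <- function(track, mode = c("CONTINUOUS_5S", "BURST_2H"),
                             burst_len_s = 60, cycle_s = 7200) {
  stopifnot(inherits(track, "sb_track"))
  mode <- match.arg(mode)
  f <- track$fixes
  tt <- as.numeric(f$time)
  if (nrow(f) >= 2 && median(diff(tt)) > 5 + 1e-9) {
    stop("duty cycling needs a track simulated at <= 5 s resolution")
  }
  rel <- tt - tt[1]
  keep <- switch(mode,
    CONTINUOUS_5S = {
      # keep the first fix of each 5-s slot
      slot <- floor(rel / 5)
      !duplicated(slot)
    },
    BURST_2H = (rel %% cycle_s) < burst_len_s
  )
  out <- track
  out$fixes <- f[keep, , drop = FALSE]
  rownames(out$fixes) <- NULL
  out$regime <- mode
  out
}

#' State-dependent fix loss
#'
#' Retains each fix independently with the probability assigned to its
#' true behavioural state, emulating acquisition success that differs
#' between behaviours (e.g. fixes easier to obtain while the bird sits on
#' the surface than in flight).
#'
#' @param track An [track()] with a `state` column.
#' @param p_fix Named vector of retention probabilities per state, e.g.
#'   `c(SLOW = 0.9, FAST = 0.5)`.
#' @param seed Integer seed.
#' @return The thinned track.
#' @export
apply_acquisition_bias <- function(track, p_fix, seed = NULL) {
  stopifnot(inherits(track, "sb_track"))
  f <- track$fixes
  if (is.null(f$state)) stop("track has no true-state labels")
  if (!all(unique(f$state) %in% names(p_fix))) {
    stop("p_fix must name every state present in the track")
  }
  stopifnot(all(p_fix >= 0), all(p_fix <= 1))
  if (!is.null(seed)) set.seed(seed)
  keep <- runif(nrow(f)) < p_fix[f$state]
  out <- track
  out$fixes <- f[keep, , drop = FALSE]
  rownames(out$fixes) <- NULL
  out
}

#' Draw speeds from a two-mode log-normal mixture
#'
#' The speed-only counterpart of [simulate_two_state_track()]: i.i.d.
#' draws from a mixture of two log-normals with the given natural-scale
#' moments, e.g. to exercise the mixture fit at a chosen sample size.
#'
#' @param n Sample size.
#' @param means,variances Length-2 natural-scale means (m s^-1) and
#'   variances of the slow and fast modes.
#' @param weights Length-2 mixing proportions, summing to 1.
#' @param seed Integer seed.
#' @return List: `speed` (length n), `component` (1 = slow, 2 = fast).
#' @export
simulate_speed_mixture <- function(n, means = c(0.83, 10.20),
                                   variances = c(0.13, 27.0),
                                   weights = c(0.5, 0.5), seed = NULL) {
  stopifnot(length(means) == 2, length(variances) == 2,
            abs(sum(weights) - 1) < 1e-8)
  if (!is.null(seed)) set.seed(seed)
  pars <- lognormal_params(means, variances)
  comp <- 1L + (runif(n) >= weights[1])
  speed <- rlnorm(n, pars$mu[comp], sqrt(pars$sigma2[comp]))
  list(speed = speed, component = comp)
}

#' Shelf-break bathymetry settings
#'
#' The default grid spans roughly a 2 x 2 degree coastal region: land in
#' the west, a shallow shelf, then a monotone shelf-break ramp covering
#' every depth in the 600-1000 m band, then an abyssal plain. Depth
#' increases with longitude (distance from the coast), the canonical
#' cross-shelf profile.
#'
#' @param lon_min,lon_max,lat_min,lat_max Grid extent, degrees.
#' @param res_deg Cell size, degrees.
#' @param coast_lon Longitude of the coastline; cells west of it are land.
#' @param shelf_width_deg Width of the shallow shelf, degrees.
#' @param band_width_deg Width of the 600-1000 m shelf-break ramp,
#'   degrees.
#' @param land_elev Land elevation, m (> 0).
#' @param shelf_depth Shelf depth, m (< 600).
#' @param band Shelf-break depth range, m (default `c(600, 1000)`).
#' @param abyss_depth Abyssal-plain depth, m (> `band[2]`).
#' @param noise_sd Cell-level depth roughness (m) added outside the band,
#'   so sampled depths are effectively continuous; 0 disables.
#' @param seed Integer seed for the roughness field.
#' @return List of class `"sb_bathy_cfg"`.
#' @export
bathy_config <- function(lon_min = 174, lon_max = 176,
                         lat_min = -37.2, lat_max = -35.2,
                         res_deg = 0.01, coast_lon = 174.4,
                         shelf_width_deg = 0.5, band_width_deg = 0.3,
                         land_elev = 100, shelf_depth = 150,
                         band = c(600, 1000), abyss_depth = 3000,
                         noise_sd = 10, seed = 1) {
  stopifnot(lon_max > lon_min, lat_max > lat_min, res_deg > 0,
            shelf_depth < band[1], band[1] <= band[2],
            band[2] < abyss_depth, land_elev > 0)
  structure(as.list(environment()), class = "sb_bathy_cfg")
}

#' Generate shelf-break bathymetry
#'
#' Builds an elevation grid (negative below sea level) from a
#' [bathy_config()]: land west of the coastline, a shallow shelf sloping
#' gently from 0 at the coast to the shelf depth, a monotone shelf-break
#' ramp containing every depth in the band, and an abyssal plain. A small
#' seeded cell-level roughness is added outside the band so depth values
#' are continuous; the band ramp itself is left exact so the band's depth
#' range is guaranteed. Deterministic given the config's seed.
#'
#' @param cfg A [bathy_config()].
#' @return A [raster_grid()] of elevations.
#' @export
make_shelf_bathymetry <- function(cfg = bathy_config()) {
  stopifnot(inherits(cfg, "sb_bathy_cfg"))
  nc <- round((cfg$lon_max - cfg$lon_min) / cfg$res_deg)
  nr <- round((cfg$lat_max - cfg$lat_min) / cfg$res_deg)
  lon_c <- cfg$lon_min + (seq_len(nc) - 0.5) * cfg$res_deg
  shelf_end <- cfg$coast_lon + cfg$shelf_width_deg
  band_end <- shelf_end + cfg$band_width_deg
  elev_profile <- vapply(lon_c, function(x) {
    if (x <= cfg$coast_lon) {
      cfg$land_elev
    } else if (x <= shelf_end) {
      # gentle shelf: 0 at the coast down to shelf_depth, then a short
      # drop to the top of the band is handled by the ramp below
      -cfg$shelf_depth * (x - cfg$coast_lon) / cfg$shelf_width_deg
    } else if (x <= band_end) {
      # monotone shelf-break ramp spanning the full 600-1000 m band
      -(cfg$band[1] + (cfg$band[2] - cfg$band[1]) *
          (x - shelf_end) / cfg$band_width_deg)
    } else {
      -cfg$abyss_depth
    }
  }, numeric(1))
  m <- matrix(rep(elev_profile, each = nr), nrow = nr, ncol = nc)
  if (cfg$noise_sd > 0) {
    set.seed(cfg$seed)
    noise <- matrix(rnorm(nr * nc, 0, cfg$noise_sd), nr, nc)
    in_band <- matrix(rep(lon_c > shelf_end & lon_c <= band_end,
                          each = nr), nr, nc)
    on_land <- m >= 0
    # keep the band exact and the land/sea boundary intact
    noise[in_band | on_land] <- 0
    sea <- !on_land
    m[sea] <- pmin(m[sea] + noise[sea], -1)
  }
  raster_grid(m, xll = cfg$lon_min, yll = cfg$lat_min,
              dx = cfg$res_deg, dy = cfg$res_deg)
}
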