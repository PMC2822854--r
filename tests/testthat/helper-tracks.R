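# Shared fixture builders; everything is generated in code.

t_utc <- function(s) as.POSIXct("2006-02-24 00:00:00", tz = "UTC") + s

# Track from second offsets and coordinates.
make_track <- function(sec, lon, lat, n_sats = NA_integer_,
                       quality = "UNKNOWN", id = "t", regime = "OTHER",
                       ...) {
  track(data.frame(time = t_utc(sec), lon = lon, lat = lat,
                   n_sats = n_sats, quality = quality, ...,
                   stringsAsFactors = FALSE),
        id = id, regime = regime)
}

# Track of n fixes advancing east along the equator with fixed step (m)
# and spacing (s).
make_equator_track <- function(n, step_m = 50, dt_s = 5, lat = 0,
                               lon0 = 0, ...) {
  steps <- rep_len(step_m, n - 1)
  lon <- lon0 + cumsum(c(0, steps)) / (EARTH_RADIUS_M * pi / 180) /
    cospi(lat / 180)
  make_track((seq_len(n) - 1) * dt_s, lon, rep(lat, n), ...)
}

# Uniform-value ocean raster centred on (lon0, lat0).
make_flat_ocean <- function(value = -500, lon0 = 175, lat0 = -36,
                            half_deg = 2, res = 0.05) {
  n <- round(2 * half_deg / res)
  raster_grid(matrix(value, n, n), xll = lon0 - half_deg,
              yll = lat0 - half_deg, dx = res)
}

# The movement model at the study's fitted high-resolution values.
paper_model <- function() {
  p <- lognormal_params(c(0.83, 10.20), c(0.13, 27.0))
  speed_mixture(c(0.5, 0.5), p$mu, p$sigma2)
}
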