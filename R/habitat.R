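# Rotation-based habitat randomisation null and repeated KS testing.
#
# The null asks: given the internal geometry of a foraging trip, what
# seafloor depths *could* the bird have sat over? Rigidly rotating the
# track about its origin (the colony, where deployments begin) through
# fifteen 22.5-degree angles sweeps the trip over every bearing while
# preserving all distances along the track. Depths sampled under the
# rotated replicates, with on-land positions excluded, form the null pool
# against which the observed depth distribution is tested.

#' Rotation-null configuration
#'
#' Angles are `k * angle_step` for `k = 1..n_angles`; the default — fifteen
#' 22.5-degree steps — covers the full circle, the sixteenth step being the
#' identity.
#'
#' @param n_angles Number of rotated replicates (default 15).
#' @param angle_step Step between successive rotations, degrees
#'   (default 22.5).
#' @param origin Optional `c(lon, lat)` rotation origin; defaults to the
#'   track's first fix.
#' @return List of class `"sb_rotation_cfg"`.
#' @export
rotation_null_config <- function(n_angles = 15, angle_step = 22.5,
                                 origin = NULL) {
  stopifnot(n_angles >= 1, angle_step > 0)
  structure(list(n_angles = n_angles, angle_step = angle_step,
                 origin = origin),
            class = "sb_rotation_cfg")
}

#' Rigidly rotate a track about an origin
#'
#' Each fix keeps its great-circle distance from the origin while its
#' initial bearing from the origin is increased by `angle` (degrees,
#' clockwise from north). Timestamps and all non-positional columns are
#' unchanged, so the track's internal structure — inter-fix distances and
#' timing — is preserved.
#'
#' @param track An [track()] object.
#' @param angle Rotation angle, degrees clockwise.
#' @param origin `c(lon, lat)`; defaults to the first fix.
#' @return The rotated track.
#' @export
rotate_track <- function(track, angle, origin = NULL) {
  stopifnot(inherits(track, "sb_track"))
  f <- track$fixes
  if (nrow(f) == 0) return(track)
  if (is.null(origin)) origin <- c(f$lon[1], f$lat[1])
  pts <- cbind(f$lon, f$lat)
  org <- matrix(origin, nrow = nrow(pts), ncol = 2, byrow = TRUE)
  d <- great_circle_distance(org, pts)
  b <- initial_bearing(org, pts)
  at_origin <- d < 1e-9
  b[at_origin] <- 0
  new_pts <- destination_point(org, b + angle, d)
  out <- track
  out$fixes$lon <- new_pts[, 1]
  out$fixes$lat <- new_pts[, 2]
  out
}

#' Seafloor depths under a track
#'
#' Samples the bathymetry under each fix and reports positive-down depth
#' (`-elevation`). On-land fixes (elevation >= 0) and fixes over nodata
#' cells are dropped by default.
#'
#' @param track An [track()] object.
#' @param grid Bathymetry [raster_grid()] (elevation, negative at sea).
#' @param drop_land Drop samples with elevation >= 0 (default TRUE).
#' @param outside Passed to [sample_raster_at()]: `"error"` or `"na"`.
#' @return Data frame: `lon`, `lat`, `depth` (m, positive down), `label`
#'   (carried from a `label` or `state` fix column when present).
#' @export
depth_under_track <- function(track, grid, drop_land = TRUE,
                              outside = "error") {
  stopifnot(inherits(track, "sb_track"))
  f <- track$fixes
  elev <- sample_raster_at(grid, cbind(f$lon, f$lat), outside = outside)
  lab <- if (!is.null(f$label)) f$label else
         if (!is.null(f$state)) f$state else NA_character_
  out <- data.frame(lon = f$lon, lat = f$lat, depth = -elev, label = lab,
                    stringsAsFactors = FALSE)
  keep <- !is.na(elev)
  if (drop_land) keep <- keep & elev < 0
  out[keep, , drop = FALSE]
}

#' Build the rotation-based depth null
#'
#' For each rotation angle `k * angle_step` the track is rotated about its
#' origin, the bathymetry is sampled under the rotated fixes, and on-land
#' (elevation >= 0) and nodata samples are discarded. Behaviour labels are
#' carried over from the unrotated fixes. Rotated positions falling outside
#' the raster extent are dropped and counted.
#'
#' @param track An [track()] object (labels in a `label` or `state` column
#'   are propagated).
#' @param grid Bathymetry [raster_grid()].
#' @param cfg A [rotation_null_config()].
#' @return Data frame of pooled null samples: `lon`, `lat`, `depth`,
#'   `label`, `angle`, `source = "ROTATED"`. Attributes `n_land_dropped`
#'   and `n_outside_dropped` count exclusions.
#' @export
build_rotation_null <- function(track, grid, cfg = rotation_null_config()) {
  stopifnot(inherits(track, "sb_track"), inherits(grid, "sb_raster"))
  if (nrow(track$fixes) == 0) stop("track has no fixes")
  angles <- seq_len(cfg$n_angles) * cfg$angle_step
  origin <- cfg$origin
  if (is.null(origin)) origin <- c(track$fixes$lon[1], track$fixes$lat[1])
  n_land <- 0L
  n_outside <- 0L
  pools <- lapply(angles, function(a) {
    rot <- rotate_track(track, a, origin = origin)
    f <- rot$fixes
    elev <- sample_raster_at(grid, cbind(f$lon, f$lat), outside = "na")
    # distinguish outside-extent (no cell) from nodata/land
    ux <- (f$lon - grid$xll) / grid$dx
    uy <- (f$lat - grid$yll) / grid$dy
    inside <- ux >= 0 & ux <= grid$ncol & uy >= 0 & uy <= grid$nrow
    n_outside <<- n_outside + sum(!inside)
    n_land <<- n_land + sum(!is.na(elev) & elev >= 0)
    keep <- inside & !is.na(elev) & elev < 0
    lab <- if (!is.null(track$fixes$label)) track$fixes$label else
           if (!is.null(track$fixes$state)) track$fixes$state else
           NA_character_
    lab <- rep(lab, length.out = nrow(f))
    nk <- sum(keep)
    data.frame(lon = f$lon[keep], lat = f$lat[keep],
               depth = -elev[keep], label = lab[keep],
               angle = rep(a, nk), source = rep("ROTATED", nk),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pools)
  rownames(out) <- NULL
  attr(out, "n_land_dropped") <- n_land
  attr(out, "n_outside_dropped") <- n_outside
  out
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum gap between the two empirical cumulative distribution
#' functions, evaluated by a sweep over the pooled breakpoints (ties are
#' handled exactly). The p-value uses the asymptotic Kolmogorov
#' distribution at effective sample size `n1 * n2 / (n1 + n2)`.
#'
#' @param a,b Numeric samples, each non-empty.
#' @return List of class `"sb_ks"`: `D`, `p`, `n1`, `n2`.
#' @export
ks_two_sample <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  n1 <- length(a)
  n2 <- length(b)
  if (n1 < 1 || n2 < 1) stop("both samples must be non-empty")
  w <- sort(unique(c(a, b)))
  Fa <- cumsum(tabulate(findInterval(a, w), length(w))) / n1
  Fb <- cumsum(tabulate(findInterval(b, w), length(w))) / n2
  D <- max(abs(Fa - Fb))
  neff <- n1 * n2 / (n1 + n2)
  p <- 1 - .kolmogorov_cdf(sqrt(neff) * D)
  structure(list(D = D, p = p, n1 = n1, n2 = n2), class = "sb_ks")
}

#' @export
print.sb_ks <- function(x, ...) {
  cat(sprintf("Two-sample KS: D = %.4f, p = %.4g (n1 = %d, n2 = %d)\n",
              x$D, x$p, x$n1, x$n2))
  invisible(x)
}

# CDF of the Kolmogorov distribution, K(t) = P(sup|B(s)| <= t).
# Series form for t >= 1, theta-function form for small t (fast
# convergence in each regime).
.kolmogorov_cdf <- function(t) {
  if (t <= 0) return(0)
  if (t < 1) {
    k <- 1:20
    s <- sum(exp(-(2 * k - 1)^2 * pi^2 / (8 * t^2)))
    sqrt(2 * pi) / t * s
  } else {
    k <- 1:100
    1 - 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  }
}

#' Repeated equal-size subsample KS test
#'
#' Each run draws, without replacement, a subsample of the null pool the
#' same size as the observed sample and applies [ks_two_sample()] against
#' the observed depths. Reported are the per-run results, the proportion
#' of runs significant at `alpha`, and median D and p. The procedure is
#' declared significant overall when the proportion of significant runs
#' reaches `prop_threshold` (default 0.95).
#'
#' @param observed Observed depths (m).
#' @param null_pool Null depths; at least as many as `observed`.
#' @param n_runs Number of subsample comparisons (default 1000).
#' @param alpha Per-run significance level (default 0.05).
#' @param seed Integer seed; same seed, same result.
#' @param prop_threshold Proportion of significant runs declaring overall
#'   significance.
#' @return List of class `"sb_repeated_ks"`: `runs` (data frame of `D`,
#'   `p`), `prop_significant`, `median_D`, `median_p`, `significant`,
#'   `n_obs`, `n_runs`, `alpha`.
#' @export
repeated_subsample_test <- function(observed, null_pool, n_runs = 1000,
                                    alpha = 0.05, seed = NULL,
                                    prop_threshold = 0.95) {
  observed <- observed[!is.na(observed)]
  null_pool <- null_pool[!is.na(null_pool)]
  n <- length(observed)
  if (length(null_pool) < n) {
    stop("null pool (", length(null_pool),
         ") smaller than observed sample (", n, ")")
  }
  if (!is.null(seed)) set.seed(seed)
  runs <- vapply(seq_len(n_runs), function(r) {
    sub <- null_pool[sample.int(length(null_pool), n)]
    ks <- ks_two_sample(observed, sub)
    c(ks$D, ks$p)
  }, numeric(2))
  runs <- data.frame(D = runs[1, ], p = runs[2, ])
  prop <- mean(runs$p < alpha)
  structure(
    list(runs = runs, prop_significant = prop,
         median_D = median(runs$D), median_p = median(runs$p),
         significant = prop >= prop_threshold,
         n_obs = n, n_runs = n_runs, alpha = alpha),
    class = "sb_repeated_ks"
  )
}

#' @export
print.sb_repeated_ks <- function(x, ...) {
  cat(sprintf(
    "Repeated subsample KS (%d runs, n = %d, alpha = %.3g):\n",
    x$n_runs, x$n_obs, x$alpha))
  cat(sprintf("  significant runs: %.1f%%  median D = %.4f  median p = %.4g\n",
              100 * x$prop_significant, x$median_D, x$median_p))
  cat(sprintf("  overall: %s\n",
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Occupancy of a depth band
#'
#' Fraction of depth samples inside `[band[1], band[2]]` metres, both
#' edges inclusive. The 600-1000 m band operationalises the shelf-break,
#' the steep transition from continental shelf to the deep ocean floor.
#'
#' @param depth Depths (m, positive down), or a data frame with `depth`
#'   (and optionally `label`) columns.
#' @param band Two-element numeric, default `c(600, 1000)`.
#' @param by_label With a data-frame input, also return per-label
#'   fractions.
#' @return Single fraction, or (with `by_label = TRUE`) a named list
#'   `overall` plus one fraction per label. Empty input gives `NA` with a
#'   warning.
#' @export
depth_band_occupancy <- function(depth, band = c(600, 1000),
                                 by_label = FALSE) {
  stopifnot(length(band) == 2, band[1] <= band[2])
  df <- NULL
  if (is.data.frame(depth)) {
    df <- depth
    depth <- df$depth
  }
  depth <- depth[!is.na(depth)]
  inband <- function(d) {
    if (length(d) == 0) {
      warning("no depth samples; occupancy undefined")
      return(NA_real_)
    }
    mean(d >= band[1] & d <= band[2])
  }
  if (!by_label || is.null(df) || is.null(df$label)) return(inband(depth))
  labs <- unique(df$label[!is.na(df$label)])
  out <- list(overall = inband(depth))
  for (l in labs) {
    out[[l]] <- inband(df$depth[!is.na(df$label) & df$label == l &
                                  !is.na(df$depth)])
  }
  out
}
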