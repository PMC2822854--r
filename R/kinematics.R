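# Speeds, burst clusters, window merging and per-trip summaries.

#' Over-ground speeds between consecutive fixes
#'
#' One speed sample per consecutive fix pair whose time separation is at
#' most `max_dt`; pairs spanning longer gaps (e.g. between two-hourly
#' bursts) are skipped so that inter-burst "speeds" never contaminate the
#' within-burst series.
#'
#' @param track An [track()] object with at least 2 fixes.
#' @param max_dt Maximum inter-fix interval (seconds) for a valid sample.
#' @return Data frame with one row per sample: `mid_time`, `speed`
#'   (m s^-1), `dt` (s), and the fix indices `i0`, `i1` of the segment
#'   endpoints.
#' @export
compute_speeds <- function(track, max_dt = 30) {
  stopifnot(inherits(track, "sb_track"))
  f <- track$fixes
  if (nrow(f) < 2) stop("need at least 2 fixes to compute speeds")
  tt <- as.numeric(f$time)
  dt <- diff(tt)
  if (any(dt <= 0)) stop("fixes must be strictly increasing in time")
  d <- great_circle_distance(cbind(f$lon[-nrow(f)], f$lat[-nrow(f)]),
                             cbind(f$lon[-1], f$lat[-1]))
  keep <- dt <= max_dt
  data.frame(
    mid_time = f$time[-nrow(f)][keep] + dt[keep] / 2,
    speed = (d / dt)[keep],
    dt = dt[keep],
    i0 = which(keep),
    i1 = which(keep) + 1L
  )
}

#' Segment a duty-cycled track into fix clusters (bursts)
#'
#' Splits the fix sequence wherever the inter-fix gap strictly exceeds
#' `gap_s`; each resulting cluster is one wake-up burst of the two-hour
#' duty cycle. The cluster's representative speed is the median of its
#' within-cluster consecutive-pair speeds — robust to single-fix jitter.
#' Clusters with fewer than 2 fixes have no defined speed and are flagged.
#'
#' @param track An [track()] object.
#' @param gap_s Gap (seconds) above which a new cluster starts; the default
#'   600 s separates two-hourly bursts unambiguously. A gap exactly equal
#'   to `gap_s` does not split.
#' @return Data frame, one row per cluster: `cluster`, `t_start`, `t_end`,
#'   `lon`, `lat` (fix centroid), `speed` (median within-cluster speed,
#'   `NA` when undefined), `n_fixes`, `flagged`.
#' @export
segment_clusters <- function(track, gap_s = 600) {
  stopifnot(inherits(track, "sb_track"))
  f <- track$fixes
  if (nrow(f) == 0) {
    return(data.frame(cluster = integer(), t_start = as.POSIXct(character()),
                      t_end = as.POSIXct(character()), lon = numeric(),
                      lat = numeric(), speed = numeric(),
                      n_fixes = integer(), flagged = logical()))
  }
  tt <- as.numeric(f$time)
  cl <- cumsum(c(1, as.integer(diff(tt) > gap_s)))
  idx <- split(seq_len(nrow(f)), cl)
  rows <- lapply(seq_along(idx), function(k) {
    ii <- idx[[k]]
    sp <- NA_real_
    if (length(ii) >= 2) {
      d <- great_circle_distance(
        cbind(f$lon[ii[-length(ii)]], f$lat[ii[-length(ii)]]),
        cbind(f$lon[ii[-1]], f$lat[ii[-1]])
      )
      sp <- median(d / diff(tt[ii]))
    }
    data.frame(
      cluster = k, t_start = f$time[ii[1]], t_end = f$time[ii[length(ii)]],
      lon = mean(f$lon[ii]), lat = mean(f$lat[ii]),
      speed = sp, n_fixes = length(ii), flagged = length(ii) < 2
    )
  })
  out <- do.call(rbind, rows)
  if (!is.null(f$state)) {
    # majority true state per cluster, for simulation studies
    out$state <- vapply(idx, function(ii) {
      names(which.max(table(f$state[ii])))
    }, character(1))
  }
  rownames(out) <- NULL
  out
}

#' Merge fixes into fixed-width time windows
#'
#' Partitions the time axis into consecutive half-open windows
#' `[k*window_s, (k+1)*window_s)` anchored at the first fix. Every
#' non-empty window collapses to a single location at the arithmetic mean
#' lon/lat of its fixes, timestamped at the window centre; empty windows
#' produce nothing. Thins pseudo-replicated 5-second fixes to (by default)
#' one location per two minutes before depth comparisons. Windows spanning
#' the antimeridian are shifted to a continuous longitude branch before
#' averaging.
#'
#' @param track An [track()] object.
#' @param window_s Window width, seconds (default 120 = two minutes).
#' @return A new [track()]; merged fixes carry `n_sats = NA`,
#'   `quality = "UNKNOWN"` and an `n_merged` count.
#' @export
merge_windows <- function(track, window_s = 120) {
  stopifnot(inherits(track, "sb_track"))
  f <- track$fixes
  if (nrow(f) == 0) return(track)
  tt <- as.numeric(f$time)
  k <- floor((tt - tt[1]) / window_s)
  idx <- split(seq_len(nrow(f)), k)
  t0 <- tt[1]
  rows <- lapply(idx, function(ii) {
    lon <- f$lon[ii]
    if (max(lon) - min(lon) > 180) lon <- ifelse(lon < 0, lon + 360, lon)
    mlon <- mean(lon)
    if (mlon > 180) mlon <- mlon - 360
    kk <- floor((tt[ii[1]] - t0) / window_s)
    data.frame(
      time = as.POSIXct(t0 + (kk + 0.5) * window_s, tz = "UTC",
                        origin = "1970-01-01"),
      lon = mlon, lat = mean(f$lat[ii]), n_sats = NA_integer_,
      quality = "UNKNOWN", n_merged = length(ii)
    )
  })
  fixes <- do.call(rbind, rows)
  track(fixes, id = track$id, regime = track$regime)
}

#' Per-trip summary: path length, furthest point, hull area
#'
#' `length_km` is the summed great-circle distance along consecutive fixes;
#' `furthest_km` the maximum great-circle distance from the colony;
#' `area_km2` the area of the planar convex hull of the fixes after a
#' Lambert azimuthal equal-area projection centred on the colony (so hull
#' area is distortion-free at trip scales). Degenerate tracks (single fix,
#' or collinear fixes) have zero length and/or area.
#'
#' @param track An [track()] object with at least 1 fix.
#' @param colony Numeric `c(lon, lat)` of the colony (trip origin).
#' @return Data frame with one row: `length_km`, `furthest_km`, `area_km2`,
#'   `n_fixes`.
#' @export
summarize_track <- function(track, colony) {
  stopifnot(inherits(track, "sb_track"))
  f <- track$fixes
  if (nrow(f) < 1) stop("need at least 1 fix")
  pts <- cbind(f$lon, f$lat)
  len_m <- if (nrow(f) >= 2) {
    sum(great_circle_distance(pts[-nrow(pts), , drop = FALSE],
                              pts[-1, , drop = FALSE]))
  } else 0
  furthest_m <- max(great_circle_distance(
    matrix(colony, nrow = nrow(pts), ncol = 2, byrow = TRUE), pts))
  xy <- .laea_project(pts, colony)
  area_m2 <- .hull_area(xy)
  data.frame(length_km = len_m / 1000, furthest_km = furthest_m / 1000,
             area_km2 = area_m2 / 1e6, n_fixes = nrow(f))
}

# Lambert azimuthal equal-area projection about `centre` on the sphere:
# rho = 2 R sin(c/2), plane coords by initial bearing from the centre.
.laea_project <- function(pts, centre) {
  ctr <- matrix(centre, nrow = nrow(pts), ncol = 2, byrow = TRUE)
  d <- great_circle_distance(ctr, pts)
  b <- initial_bearing(ctr, pts) * pi / 180
  rho <- 2 * EARTH_RADIUS_M * sin(d / (2 * EARTH_RADIUS_M))
  b[is.na(b)] <- 0  # coincident with centre: rho = 0, bearing irrelevant
  cbind(x = rho * sin(b), y = rho * cos(b))
}

# Convex hull area (shoelace); 0 for fewer than 3 distinct vertices.
.hull_area <- function(xy) {
  xy <- unique(xy)
  if (nrow(xy) < 3) return(0)
  h <- grDevices::chull(xy)
  if (length(h) < 3) return(0)
  v <- xy[h, , drop = FALSE]
  n <- nrow(v)
  j <- c(2:n, 1)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}
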