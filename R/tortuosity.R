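# Path-unpredictability (entropy) profile along high-resolution tracks.
#
# At each location the local movement is summarised by the joint
# distribution of (turn angle, speed) pairs within a sliding time window;
# the Shannon entropy of that 2-D histogram scores how unpredictable —
# tortuous — the movement is there. Straight commuting flight occupies one
# heading/speed bin (entropy near 0); area-restricted search spreads over
# many bins (high entropy). This windowed-histogram operator is this
# package's own self-contained formulation of a spatio-temporal
# unpredictability score; it is a reimplementation of the analysis role,
# not a replication of any particular published estimator.

#' Signed turn angles along a track
#'
#' For each interior fix, the change in great-circle initial bearing
#' between the incoming and outgoing segments, wrapped to (-180, 180]
#' degrees. Bearings are clockwise from north, so right turns are
#' positive and left turns negative. Turns at zero-length segments
#' (repeated positions) are `NA`.
#'
#' @param track An [track()] object with at least 3 fixes.
#' @return Numeric vector of length `n_fixes - 2`, one angle per interior
#'   fix.
#' @export
turn_angles <- function(track) {
  stopifnot(inherits(track, "sb_track"))
  f <- track$fixes
  n <- nrow(f)
  if (n < 3) stop("need at least 3 fixes for turn angles")
  p <- cbind(f$lon, f$lat)
  b <- initial_bearing(p[-n, , drop = FALSE], p[-1, , drop = FALSE])
  .wrap180(diff(b))
}

#' Sliding-window entropy profile
#'
#' For every fix, collects the (turn angle, speed) pairs of interior fixes
#' within `window_s / 2` seconds either side, bins them on a fixed
#' `angle_bins x speed_bins` grid — angle bins uniform over (-180, 180],
#' speed bins at the track's own speed quartiles so the operator is
#' scale-free across individuals — and scores the Shannon entropy (bits)
#' of the normalised histogram. Windows holding fewer than `min_pairs`
#' pairs are flagged undefined (`NA`).
#'
#' Intended for high-resolution tracks (median fix interval of a few
#' seconds); a warning is given when the median interval exceeds 30 s.
#'
#' @param track An [track()] object with at least 3 fixes.
#' @param window_s Window width, seconds (default 600).
#' @param angle_bins,speed_bins Histogram resolution (default 8 x 4).
#' @param min_pairs Minimum pairs for a defined value (default 5).
#' @return Data frame of class `"sb_entropy"`: per fix `time`, `lon`,
#'   `lat`, `entropy` (bits; `NA` when undefined), `n_pairs`, `defined`.
#' @export
sliding_entropy <- function(track, window_s = 600, angle_bins = 8,
                            speed_bins = 4, min_pairs = 5) {
  stopifnot(inherits(track, "sb_track"))
  f <- track$fixes
  n <- nrow(f)
  if (n < 3) stop("need at least 3 fixes")
  tt <- as.numeric(f$time)
  if (median(diff(tt)) > 30) {
    warning("median fix interval exceeds 30 s; the entropy profile is ",
            "designed for high-resolution tracks")
  }
  turns <- turn_angles(track)
  # pair the turn at interior fix i with the speed of the outgoing segment
  seg_d <- great_circle_distance(cbind(f$lon[-n], f$lat[-n]),
                                 cbind(f$lon[-1], f$lat[-1]))
  seg_v <- seg_d / diff(tt)
  pair_t <- tt[2:(n - 1)]
  pair_turn <- turns
  pair_speed <- seg_v[2:(n - 1)]
  ok <- !is.na(pair_turn) & !is.na(pair_speed)
  pair_t <- pair_t[ok]; pair_turn <- pair_turn[ok]; pair_speed <- pair_speed[ok]
  qb <- quantile(pair_speed, probs = seq(0, 1, 0.25), names = FALSE)
  # collapse quartile breaks that differ only by numerical jitter; a track
  # at constant speed then uses a single speed bin
  tol <- 1e-9 * max(abs(qb), 1)
  speed_breaks <- qb[c(TRUE, diff(qb) > tol)]
  if (length(speed_breaks) < 2) {
    speed_breaks <- c(speed_breaks - tol, speed_breaks + tol)
  }
  half <- window_s / 2
  lo <- findInterval(tt - half, pair_t, left.open = TRUE) + 1
  hi <- findInterval(tt + half, pair_t)
  ent <- rep(NA_real_, n)
  npair <- pmax(hi - lo + 1, 0)
  for (i in seq_len(n)) {
    if (npair[i] >= min_pairs) {
      jj <- lo[i]:hi[i]
      ent[i] <- joint_entropy(pair_turn[jj], pair_speed[jj],
                              angle_bins = angle_bins,
                              speed_breaks = speed_breaks)
    }
  }
  out <- data.frame(time = f$time, lon = f$lon, lat = f$lat,
                    entropy = ent, n_pairs = npair, defined = !is.na(ent))
  attr(out, "window_s") <- window_s
  attr(out, "n_bins") <- angle_bins * speed_bins
  class(out) <- c("sb_entropy", class(out))
  out
}

#' Shannon entropy of a turn-angle/speed histogram
#'
#' Bins turns uniformly over (-180, 180] into `angle_bins` cells and
#' speeds by `speed_breaks` (outermost values clamped into the end bins),
#' then returns the Shannon entropy, in bits, of the normalised joint
#' histogram: 0 when all pairs share one bin, `log2(n_bins)` when spread
#' uniformly over all bins.
#'
#' @param turn Signed turn angles, degrees in (-180, 180].
#' @param speed Speeds, m s^-1, same length.
#' @param angle_bins Number of uniform angle bins.
#' @param speed_breaks Increasing break points for the speed bins
#'   (`length(speed_breaks) - 1` bins).
#' @return Entropy in bits.
#' @export
joint_entropy <- function(turn, speed, angle_bins = 8, speed_breaks) {
  stopifnot(length(turn) == length(speed), length(turn) > 0,
            length(speed_breaks) >= 2)
  a_idx <- ceiling((turn + 180) / (360 / angle_bins))
  a_idx[a_idx < 1] <- 1
  a_idx[a_idx > angle_bins] <- angle_bins
  s_idx <- findInterval(speed, speed_breaks, rightmost.closed = TRUE,
                        all.inside = TRUE)
  n_sbins <- length(speed_breaks) - 1
  counts <- tabulate((s_idx - 1) * angle_bins + a_idx,
                     nbins = angle_bins * n_sbins)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

#' Categorise an entropy profile for display
#'
#' Maps each defined entropy value to a quantile category within its own
#' track's entropy distribution (category 1 = most predictable movement,
#' `n_categories` = most unpredictable), the banding used to colour
#' entropy along a plotted track. The mapping is monotone: a higher
#' entropy never receives a lower category. When all entropies are equal
#' every value falls in category 1.
#'
#' @param profile Output of [sliding_entropy()].
#' @param n_categories Number of quantile bands (default 5).
#' @return `profile` with an integer `category` column (`NA` where entropy
#'   is undefined).
#' @export
categorize_entropy <- function(profile, n_categories = 5) {
  stopifnot(is.data.frame(profile), "entropy" %in% names(profile))
  e <- profile$entropy
  def <- !is.na(e)
  if (sum(def) < n_categories) {
    stop("need at least ", n_categories, " defined entropy values")
  }
  br <- unique(quantile(e[def], probs = seq(0, 1, length.out =
                                              n_categories + 1),
                        names = FALSE))
  cat_idx <- rep(NA_integer_, length(e))
  if (length(br) < 2) {
    cat_idx[def] <- 1L   # all entropies identical
  } else {
    cat_idx[def] <- as.integer(cut(e[def], breaks = br,
                                   include.lowest = TRUE, labels = FALSE))
  }
  profile$category <- cat_idx
  profile
}
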