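# GPS track container and ingest/filtering.
#
# A Track is an S3 list: id (deployment identifier), regime (sampling
# schedule tag), and fixes — a data.frame with columns
#   time    POSIXct, UTC
#   lon     decimal degrees WGS84, [-180, 180]
#   lat     decimal degrees WGS84, [-90, 90]
#   n_sats  integer satellite count (NA allowed)
#   quality "FIX3D", "FIX2D" or "UNKNOWN"
# plus any extra columns (e.g. `state` from the simulator). Fixes are
# strictly increasing in time with no duplicate timestamps.

TRACK_REGIMES <- c("CONTINUOUS_5S", "BURST_2H", "OTHER")
FIX_QUALITIES <- c("FIX3D", "FIX2D", "UNKNOWN")

#' Construct a GPS track
#'
#' @param fixes Data frame with columns `time` (POSIXct or ISO-8601
#'   character, UTC), `lon`, `lat`; optionally `n_sats`, `quality`, and any
#'   extra columns which are carried along untouched.
#' @param id Deployment identifier.
#' @param regime Sampling-regime tag: `"CONTINUOUS_5S"` (continuous 5-second
#'   fixes), `"BURST_2H"` (a short burst of fixes every two hours), or
#'   `"OTHER"`.
#' @return An object of class `"sb_track"`.
#' @export
track <- function(fixes, id = "track", regime = "OTHER") {
  regime <- match.arg(regime, TRACK_REGIMES)
  stopifnot(is.data.frame(fixes))
  need <- c("time", "lon", "lat")
  missing_cols <- setdiff(need, names(fixes))
  if (length(missing_cols) > 0) {
    stop("fixes is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  fixes <- as.data.frame(fixes, stringsAsFactors = FALSE)
  if (!inherits(fixes$time, "POSIXct")) {
    fixes$time <- .parse_time(fixes$time)
  }
  attr(fixes$time, "tzone") <- "UTC"
  if (is.null(fixes$n_sats)) fixes$n_sats <- NA_integer_
  fixes$n_sats <- as.integer(fixes$n_sats)
  if (is.null(fixes$quality)) fixes$quality <- "UNKNOWN"
  fixes$quality <- as.character(fixes$quality)
  if (anyNA(fixes$time)) stop("unparsable or missing timestamp in fixes")
  bad <- !is.na(fixes$quality) & !(fixes$quality %in% FIX_QUALITIES)
  if (any(bad)) {
    stop("unknown fix quality value(s): ",
         paste(unique(fixes$quality[bad]), collapse = ", "))
  }
  if (any(fixes$lon < -180 | fixes$lon > 180, na.rm = TRUE) ||
      any(fixes$lat < -90 | fixes$lat > 90, na.rm = TRUE)) {
    stop("lon/lat outside valid WGS84 ranges")
  }
  if (any(!is.na(fixes$n_sats) & fixes$n_sats < 0)) {
    stop("negative satellite count")
  }
  if (nrow(fixes) > 1) {
    dt <- diff(as.numeric(fixes$time))
    if (any(dt < 0)) stop("fixes must be ordered by time")
    if (any(dt == 0)) stop("duplicate timestamps in fixes")
  }
  rownames(fixes) <- NULL
  structure(list(id = id, fixes = fixes, regime = regime),
            class = "sb_track")
}

# ISO-8601 parser that yields NA (rather than an error) on bad entries, so
# callers can point at the offending row.
.parse_time <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  x <- as.character(x)
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01",
                    tz = "UTC")
  for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                "%Y-%m-%dT%H:%M", "%Y-%m-%d")) {
    idx <- which(is.na(out))
    if (length(idx) == 0) break
    out[idx] <- as.POSIXct(strptime(x[idx], fmt, tz = "UTC"))
  }
  out
}

#' @export
print.sb_track <- function(x, ...) {
  n <- nrow(x$fixes)
  cat(sprintf("<sb_track '%s'> %d fixes, regime %s\n", x$id, n, x$regime))
  if (n > 0) {
    cat(sprintf("  time: %s .. %s\n",
                format(x$fixes$time[1], "%Y-%m-%dT%H:%M:%S"),
                format(x$fixes$time[n], "%Y-%m-%dT%H:%M:%S")))
    cat(sprintf("  lon: [%.4f, %.4f]  lat: [%.4f, %.4f]\n",
                min(x$fixes$lon), max(x$fixes$lon),
                min(x$fixes$lat), max(x$fixes$lat)))
  }
  invisible(x)
}

#' Number of fixes in a track
#' @param track An [track()] object.
#' @return Integer fix count.
#' @export
n_fixes <- function(track) {
  stopifnot(inherits(track, "sb_track"))
  nrow(track$fixes)
}

#' Read a GPS track from CSV or GPX
#'
#' CSV files need named columns `time`, `lon`, `lat`; `id`, `n_sats` and
#' `quality` are optional. Times are ISO-8601, UTC. GPX 1.1 track points
#' (`<trkpt lat= lon=>` with a `<time>` child; `<sat>` read when present)
#' are supported via the `gpx` format. Rows are sorted by time; rows sharing
#' a timestamp are collapsed to the first occurrence with a warning.
#'
#' @param path File path.
#' @param format `"csv"` or `"gpx"`.
#' @param id Deployment identifier; defaults to the file's `id` column (CSV,
#'   first value) or the file name.
#' @param regime Sampling-regime tag, see [track()].
#' @return An [track()] object.
#' @export
read_track <- function(path, format = c("csv", "gpx"), id = NULL,
                       regime = "OTHER") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  fixes <- switch(format,
    csv = .read_track_csv(path),
    gpx = .read_track_gpx(path)
  )
  if (nrow(fixes) == 0) stop("no fixes found in ", path)
  if (is.null(id)) {
    id <- if (!is.null(fixes$id) && !all(is.na(fixes$id))) {
      as.character(fixes$id[1])
    } else {
      sub("\\.[^.]+$", "", basename(path))
    }
  }
  fixes$id <- NULL
  ord <- order(fixes$time)
  fixes <- fixes[ord, , drop = FALSE]
  dup <- duplicated(fixes$time)
  if (any(dup)) {
    warning(sum(dup), " duplicate-timestamp row(s) collapsed to the first ",
            "occurrence in ", path)
    fixes <- fixes[!dup, , drop = FALSE]
  }
  track(fixes, id = id, regime = regime)
}

.read_track_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty file: ", path)
  need <- c("time", "lon", "lat")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("CSV ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  tm <- .parse_time(df$time)
  lon <- suppressWarnings(as.numeric(df$lon))
  lat <- suppressWarnings(as.numeric(df$lat))
  bad <- which(is.na(tm) | is.na(lon) | is.na(lat))
  if (length(bad) > 0) {
    stop("unparsable row ", bad[1], " in ", path,
         " (time/lon/lat could not be read)")
  }
  out <- data.frame(time = tm, lon = lon, lat = lat,
                    stringsAsFactors = FALSE)
  out$n_sats <- if (!is.null(df$n_sats)) {
    suppressWarnings(as.integer(df$n_sats))
  } else NA_integer_
  out$quality <- if (!is.null(df$quality)) {
    q <- as.character(df$quality)
    q[is.na(q) | q == ""] <- "UNKNOWN"
    q
  } else "UNKNOWN"
  if (!is.null(df$id)) out$id <- df$id
  out
}

.read_track_gpx <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns(doc)
  # strip the default namespace headache: match on local names
  pts <- xml2::xml_find_all(doc, ".//*[local-name() = 'trkpt']")
  if (length(pts) == 0) stop("no <trkpt> elements in ", path)
  lat <- as.numeric(xml2::xml_attr(pts, "lat"))
  lon <- as.numeric(xml2::xml_attr(pts, "lon"))
  tm_txt <- xml2::xml_text(
    xml2::xml_find_first(pts, "./*[local-name() = 'time']")
  )
  sat_txt <- xml2::xml_text(
    xml2::xml_find_first(pts, "./*[local-name() = 'sat']")
  )
  tm <- as.POSIXct(tm_txt, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS"))
  bad <- which(is.na(tm) | is.na(lon) | is.na(lat))
  if (length(bad) > 0) stop("unparsable track point ", bad[1], " in ", path)
  data.frame(time = tm, lon = lon, lat = lat,
             n_sats = suppressWarnings(as.integer(sat_txt)),
             quality = "UNKNOWN", stringsAsFactors = FALSE)
}

#' Write a track to CSV
#'
#' Writes columns `id,time,lon,lat,n_sats,quality` with ISO-8601 UTC times
#' and full-precision coordinates, so [read_track()] round-trips the fields
#' bit-identically.
#'
#' @param track An [track()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  stopifnot(inherits(track, "sb_track"))
  f <- track$fixes
  out <- data.frame(
    id = rep(track$id, nrow(f)),
    time = format(f$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    lon = sprintf("%.17g", f$lon),
    lat = sprintf("%.17g", f$lat),
    n_sats = f$n_sats,
    quality = f$quality,
    stringsAsFactors = FALSE
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Drop low-accuracy fixes
#'
#' Retains fixes obtained from at least `min_sats` satellites or carrying a
#' 3D quality flag ("3D fixes and higher" — a position solved with >= 4
#' satellites resolves altitude and is the higher accuracy class). Fixes
#' with neither an adequate satellite count nor a 3D flag are dropped;
#' fixes with no satellite count at all and `UNKNOWN` quality are dropped
#' and counted separately.
#'
#' @param track An [track()] object.
#' @param min_sats Minimum satellite count to retain a fix (default 4).
#' @return The filtered track. A `filter_report` attribute carries the
#'   counts: `n_in`, `n_kept`, `n_low_sats` (dropped on count),
#'   `n_unknown` (dropped for having neither field).
#' @export
filter_fixes <- function(track, min_sats = 4) {
  stopifnot(inherits(track, "sb_track"))
  f <- track$fixes
  has_sats <- !is.na(f$n_sats)
  keep <- (has_sats & f$n_sats >= min_sats) | f$quality == "FIX3D"
  unknown <- !has_sats & f$quality == "UNKNOWN"
  out <- track
  out$fixes <- f[keep, , drop = FALSE]
  rownames(out$fixes) <- NULL
  attr(out, "filter_report") <- list(
    n_in = nrow(f),
    n_kept = sum(keep),
    n_low_sats = sum(!keep & !unknown),
    n_unknown = sum(unknown)
  )
  out
}

#' Deployment log of the 2006 Great Barrier Island tracking study
#'
#' Reads the transcribed deployment/recovery log shipped with the package:
#' one row per tracker deployment with ring number, burrow, deployment and
#' recovery dates, deployment duration (days), bird mass at deployment and
#' recovery (g), and whether the tracker was recovered with usable data.
#'
#' @param path CSV path; defaults to the bundled log.
#' @return Data frame, one row per deployment.
#' @export
read_deployments <- function(path = system.file("extdata",
                                                "deployments_gbi_2006.csv",
                                                package = "shelfbreak")) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$data_recovered <- as.logical(df$data_recovered)
  df
}

#' Deployments recovered with data
#'
#' Applies the "recovered with data" rule to a deployment log: a deployment
#' is successful when the tracker was physically recovered and its memory
#' held fixes (lost trackers and data-less recoveries are excluded).
#'
#' @param deployments Data frame from [read_deployments()].
#' @return The successful subset, same columns.
#' @export
successful_deployments <- function(deployments) {
  stopifnot(is.data.frame(deployments),
            "data_recovered" %in% names(deployments))
  out <- deployments[deployments$data_recovered %in% TRUE, , drop = FALSE]
  rownames(out) <- NULL
  out
}
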