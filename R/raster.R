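# Regular lon/lat elevation grids (bathymetry, or any co-registered
# environmental field such as chlorophyll-a) with a nodata mask.
#
# Values are metres of elevation: negative below sea level, so seafloor
# depth = -elevation. Internally the value matrix is stored south-up:
# values[row, col] covers
#   lon in [xll + (col-1)*dx, xll + col*dx]
#   lat in [yll + (row-1)*dy, yll + row*dy]
# with nodata cells as NA. ESRI ASCII grids (north-up on disk) are flipped
# on read/write. No geospatial raster reader ships with the package's
# dependency set, so the plain-text ESRI ASCII grid is the interchange
# format; grids in projected coordinates must be converted to geographic
# lon/lat before use.

#' Construct a regular lon/lat raster grid
#'
#' @param values Numeric matrix, south-up (`values[1, ]` is the southernmost
#'   row, columns run west to east). `NA` marks nodata.
#' @param xll,yll Longitude/latitude of the grid's south-west corner
#'   (corner of cell (1,1)), decimal degrees.
#' @param dx,dy Cell size in degrees of longitude/latitude; both > 0.
#' @return An object of class `"sb_raster"`.
#' @export
raster_grid <- function(values, xll, yll, dx, dy = dx) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (!(dx > 0 && dy > 0)) stop("cell sizes must be > 0")
  if (any(is.infinite(values))) stop("raster values must be finite or NA")
  structure(
    list(values = values, xll = xll, yll = yll, dx = dx, dy = dy,
         nrow = nrow(values), ncol = ncol(values)),
    class = "sb_raster"
  )
}

#' @export
print.sb_raster <- function(x, ...) {
  cat(sprintf("<sb_raster> %d x %d cells, %.6g x %.6g deg\n",
              x$nrow, x$ncol, x$dx, x$dy))
  cat(sprintf("  extent: lon [%.6g, %.6g]  lat [%.6g, %.6g]\n",
              x$xll, x$xll + x$ncol * x$dx,
              x$yll, x$yll + x$nrow * x$dy))
  v <- x$values[!is.na(x$values)]
  cat(sprintf("  values: [%.6g, %.6g], %d nodata cells\n",
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA,
              sum(is.na(x$values))))
  invisible(x)
}

#' Read an ESRI ASCII elevation grid
#'
#' Single-band regular grid in geographic (lon/lat) coordinates. Supports
#' `xllcorner`/`yllcorner` or `xllcenter`/`yllcenter` headers and an
#' optional `NODATA_value`. Multi-band or skewed/projected rasters cannot
#' be represented in this format; convert such inputs to a geographic
#' single-band ESRI ASCII grid first.
#'
#' @param path File path.
#' @return A [raster_grid()].
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^[A-Za-z]", trimws(lines[i]))) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2) stop("malformed header line in ", path, ": ",
                                 lines[i])
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows")
  if (!all(need %in% names(hdr))) {
    stop("not an ESRI ASCII grid (missing ncols/nrows header): ", path)
  }
  nc <- as.integer(hdr$ncols)
  nr <- as.integer(hdr$nrows)
  if (!is.null(hdr$cellsize)) {
    dx <- dy <- hdr$cellsize
  } else if (!is.null(hdr$dx) && !is.null(hdr$dy)) {
    dx <- hdr$dx; dy <- hdr$dy
  } else {
    stop("missing cellsize (or dx/dy) header in ", path)
  }
  if (!is.null(hdr$xllcorner)) {
    xll <- hdr$xllcorner
  } else if (!is.null(hdr$xllcenter)) {
    xll <- hdr$xllcenter - dx / 2
  } else stop("missing xllcorner/xllcenter header in ", path)
  if (!is.null(hdr$yllcorner)) {
    yll <- hdr$yllcorner
  } else if (!is.null(hdr$yllcenter)) {
    yll <- hdr$yllcenter - dy / 2
  } else stop("missing yllcorner/yllcenter header in ", path)
  nodata <- hdr$nodata_value
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nr * nc) {
    stop("expected ", nr * nc, " cell values, found ", length(vals),
         " in ", path)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(nodata)) m[m == nodata] <- NA
  # disk order is north-up; store south-up
  m <- m[nr:1, , drop = FALSE]
  raster_grid(m, xll = xll, yll = yll, dx = dx, dy = dy)
}

#' Write a raster grid as ESRI ASCII
#'
#' @param grid A [raster_grid()]. Cells must be square in degrees
#'   (`dx == dy`), the only geometry the format can encode.
#' @param path Output path.
#' @param nodata Sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path, nodata = -9999) {
  stopifnot(inherits(grid, "sb_raster"))
  if (abs(grid$dx - grid$dy) > 1e-12) {
    stop("ESRI ASCII requires square cells (dx == dy)")
  }
  m <- grid$values[grid$nrow:1, , drop = FALSE]  # north-up on disk
  m[is.na(m)] <- nodata
  hdr <- c(
    sprintf("ncols %d", grid$ncol),
    sprintf("nrows %d", grid$nrow),
    sprintf("xllcorner %.12g", grid$xll),
    sprintf("yllcorner %.12g", grid$yll),
    sprintf("cellsize %.12g", grid$dx),
    sprintf("NODATA_value %g", nodata)
  )
  body <- apply(m, 1, function(r) paste(sprintf("%.10g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Sample a raster at point locations
#'
#' Nearest-cell lookup: each point takes the value of the cell containing
#' it. A point lying exactly on a cell boundary belongs to the cell with
#' the smaller index (the cell to its west/south). Masked (nodata) cells
#' yield `NA`.
#'
#' @param grid A [raster_grid()].
#' @param points Two-column matrix or data frame of `lon`, `lat`.
#' @param outside `"error"` (default) stops naming the first offending
#'   point; `"na"` returns `NA` for points outside the grid extent.
#' @return Numeric vector of cell values (`NA` for nodata, and for outside
#'   points when `outside = "na"`).
#' @export
sample_raster_at <- function(grid, points, outside = c("error", "na")) {
  stopifnot(inherits(grid, "sb_raster"))
  outside <- match.arg(outside)
  points <- as.matrix(as.data.frame(points)[, 1:2])
  ux <- (points[, 1] - grid$xll) / grid$dx
  uy <- (points[, 2] - grid$yll) / grid$dy
  col <- .boundary_floor_index(ux, grid$ncol)
  row <- .boundary_floor_index(uy, grid$nrow)
  out_of_extent <- is.na(col) | is.na(row)
  if (any(out_of_extent)) {
    if (outside == "error") {
      k <- which(out_of_extent)[1]
      stop(sprintf("point (%.6g, %.6g) is outside the raster extent",
                   points[k, 1], points[k, 2]))
    }
  }
  vals <- rep(NA_real_, nrow(points))
  ok <- !out_of_extent
  vals[ok] <- grid$values[cbind(row[ok], col[ok])]
  vals
}

# Map fractional cell coordinate u (0 at the low edge) to a 1-based cell
# index under the boundary-to-smaller-index convention; NA outside [0, n].
.boundary_floor_index <- function(u, n) {
  idx <- floor(u) + 1
  on_boundary <- u == floor(u) & u > 0
  idx[on_boundary] <- u[on_boundary]
  idx[u < 0 | u > n] <- NA
  as.integer(idx)
}
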