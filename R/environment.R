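#' Construct a grid specification
#'
#' @param latMin,latMax,lonMin,lonMax extent in decimal degrees.
#' @param resolution cell size in arc-minutes (default 6, roughly 10 km).
#' @return a [GridSpec-class].
#' @examples
#' gridSpec(24, 30, -82, -76)          # 60 x 60 cells at 6 arc-min
#' @export
gridSpec <- function(latMin, latMax, lonMin, lonMax, resolution = 6) {
  nr <- as.integer(round((latMax - latMin) * 60 / resolution))
  nc <- as.integer(round((lonMax - lonMin) * 60 / resolution))
  new("GridSpec", latMin = latMin, latMax = latMax, lonMin = lonMin,
      lonMax = lonMax, resolution = resolution, nRows = nr, nCols = nc)
}

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d x %d cells at %g arc-min, lat %g..%g, lon %g..%g\n",
              object@nRows, object@nCols, object@resolution,
              object@latMin, object@latMax, object@lonMin, object@lonMax))
  invisible(object)
})

#' Cell-centre coordinates
#'
#' @param grid a [GridSpec-class].
#' @param rows,cols cell indices (vectors recycled together); row 1 is the
#'   northernmost row.
#' @return data frame with `lat` and `lon` of the cell centres.
#' @export
cellCenters <- function(grid, rows, cols) {
  step <- grid@resolution / 60
  data.frame(lat = grid@latMax - (rows - 0.5) * step,
             lon = grid@lonMin + (cols - 0.5) * step)
}

#' Nearest cell for a coordinate
#'
#' @param grid a [GridSpec-class].
#' @param lat,lon decimal degrees.
#' @return list with `row` and `col`, or an error if outside the grid.
#' @export
cellAt <- function(grid, lat, lon) {
  step <- grid@resolution / 60
  row <- ceiling((grid@latMax - lat) / step)
  col <- ceiling((lon - grid@lonMin) / step)
  if (any(row < 1 | row > grid@nRows | col < 1 | col > grid@nCols))
    stop(sprintf("coordinate (%g, %g) lies outside the grid", lat, lon))
  list(row = as.integer(row), col = as.integer(col))
}

#' Assemble an environment stack
#'
#' Low-level constructor used by the readers and the synthetic generator.
#' Cells that are NA in any layer (or have non-positive depth) are forced
#' to land, so every marine cell carries complete data.
#'
#' @param grid a [GridSpec-class].
#' @param currentSpeed,currentDirection,sst,chlorophyll `nRows x nCols x 12`
#'   arrays.
#' @param depth `nRows x nCols` matrix (m, positive down).
#' @param landMask logical matrix, TRUE on land; missing-data cells are
#'   added to it.
#' @return an [EnvironmentStack-class].
#' @export
environmentStack <- function(grid, currentSpeed, currentDirection, sst,
                             chlorophyll, depth, landMask) {
  land <- landMask | is.na(depth) | depth <= 0
  for (a in list(currentSpeed, currentDirection, sst, chlorophyll)) {
    land <- land | apply(is.na(a), c(1, 2), any)
  }
  # normalise directions into [0, 360)
  currentDirection <- currentDirection %% 360
  obj <- new("EnvironmentStack", grid = grid,
             currentSpeed = currentSpeed, currentDirection = currentDirection,
             sst = sst, chlorophyll = chlorophyll, depth = depth,
             landMask = land)
  validObject(obj)
  obj
}

setMethod("show", "EnvironmentStack", function(object) {
  g <- object@grid
  cat(sprintf("EnvironmentStack: %d x %d cells x 12 months (%g arc-min)\n",
              g@nRows, g@nCols, g@resolution))
  cat(sprintf("  extent lat %g..%g, lon %g..%g; %d marine cells (%.1f%%)\n",
              g@latMin, g@latMax, g@lonMin, g@lonMax,
              sum(!object@landMask), 100 * mean(!object@landMask)))
  cat(sprintf("  current speed max %.3g m/s; SST %.1f..%.1f C; depth max %.0f m\n",
              max(object@currentSpeed[!is.na(object@currentSpeed)]),
              min(object@sst, na.rm = TRUE), max(object@sst, na.rm = TRUE),
              max(object@depth[!object@landMask], na.rm = TRUE)))
  invisible(object)
})

#' @describeIn environmentStack grid accessor.
#' @param x an [EnvironmentStack-class].
#' @export
envGrid <- function(x) x@grid

#' @describeIn environmentStack land-mask accessor.
#' @export
landMask <- function(x) x@landMask

#' Habitat suitability of one cell in one month
#'
#' Tests the cell's sea-surface temperature, chlorophyll and depth against
#' the configured habitable ranges.  The default scheme is binary: the
#' per-parameter score is 1 inside the range and 0 outside.  With
#' `config@suitabilityMode == "graded"` the score falls off linearly from
#' 1 at the range midpoint to 0 at (and beyond) the range edges; the
#' boolean verdicts remain binary in both modes and are what settlement
#' requires.
#'
#' @param stack an [EnvironmentStack-class].
#' @param cell `c(row, col)` of a marine cell.
#' @param month calendar month 1..12.
#' @param config a [ModelConfig-class].
#' @return list with booleans `sstOk`, `ccOk`, `depthOk` and numeric
#'   `scores` (named sst/cc/depth, each in `[0, 1]`).
#' @export
cellSuitability <- function(stack, cell, month, config) {
  stopifnot(length(cell) == 2, month >= 1, month <= 12)
  r <- cell[1]; c <- cell[2]
  if (stack@landMask[r, c]) stop("cell is land; suitability is undefined")
  vals <- c(sst = stack@sst[r, c, month],
            cc = stack@chlorophyll[r, c, month],
            depth = stack@depth[r, c])
  rng <- rbind(sst = config@sstRange, cc = config@ccRange, depth = config@depthRange)
  ok <- vals >= rng[, 1] & vals <= rng[, 2]
  if (config@suitabilityMode == "binary") {
    scores <- as.numeric(ok)
  } else {
    mid <- (rng[, 1] + rng[, 2]) / 2
    half <- (rng[, 2] - rng[, 1]) / 2
    scores <- pmax(0, 1 - abs(vals - mid) / ifelse(half > 0, half, 1))
    scores[!ok] <- 0
  }
  names(scores) <- names(vals)
  list(sstOk = unname(ok["sst"]), ccOk = unname(ok["cc"]),
       depthOk = unname(ok["depth"]), scores = scores)
}
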