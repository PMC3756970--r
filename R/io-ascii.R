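#' Read an ESRI ASCII grid
#'
#' Plain-text raster format: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `nodata_value`) followed by rows
#' north to south.  NODATA cells become NA.
#'
#' @param path file path.
#' @return list with `values` (matrix, row 1 = northernmost) and `grid`
#'   (the implied [GridSpec-class], cellsize interpreted as degrees).
#' @export
readAsciiGrid <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  lines <- readLines(path, n = 6L)
  hdr <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2) stop("malformed ASCII grid header in ", path)
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  if (!all(need %in% names(hdr)))
    stop("ASCII grid header of ", path, " is missing: ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  vals <- scan(path, skip = 6, quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop("ASCII grid ", path, " holds ", length(vals), " values; expected ", nr * nc)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA
  grid <- gridSpec(latMin = hdr$yllcorner,
                   latMax = hdr$yllcorner + nr * hdr$cellsize,
                   lonMin = hdr$xllcorner,
                   lonMax = hdr$xllcorner + nc * hdr$cellsize,
                   resolution = hdr$cellsize * 60)
  list(values = m, grid = grid)
}

#' Write an ESRI ASCII grid
#'
#' @param values matrix (row 1 = northernmost row).
#' @param grid the [GridSpec-class] supplying georeferencing.
#' @param path output path.
#' @param nodata value written for NA cells.
#' @return `path`, invisibly.
#' @export
writeAsciiGrid <- function(values, grid, path, nodata = -9999) {
  stopifnot(identical(dim(values), c(grid@nRows, grid@nCols)))
  step <- grid@resolution / 60
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", grid@nCols),
    sprintf("nrows %d", grid@nRows),
    sprintf("xllcorner %.10g", grid@lonMin),
    sprintf("yllcorner %.10g", grid@latMin),
    sprintf("cellsize %.10g", step),
    sprintf("nodata_value %.10g", nodata)
  ), con)
  vals <- values
  vals[is.na(vals)] <- nodata
  write.table(format(vals, trim = TRUE, scientific = FALSE, digits = 10),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a full environment from raster files
#'
#' Expects 12 monthly rasters for each dynamic layer plus a static depth
#' raster, all co-registered on the same lattice.  Current input may be
#' speed/direction or east/north (u/v) components; components are
#' converted to speed and degrees-from-north via the vector mean
#' convention.  Cells that are NODATA in any layer, or whose depth is not
#' positive (at or above sea level), are marked land.
#'
#' @param paths named list of file-path vectors:
#'   either `currentSpeed` + `currentDirection` (12 paths each) or
#'   `currentU` + `currentV` (12 each), plus `sst` (12), `chlorophyll`
#'   (12), `depth` (1) and optionally `landMask` (1; nonzero = land).
#' @param grid optional [GridSpec-class]; defaults to the grid implied by
#'   the first raster.  All rasters must match it exactly (no resampling).
#' @return an [EnvironmentStack-class].
#' @export
readEnvironment <- function(paths, grid = NULL) {
  getLayer <- function(name, n) {
    p <- paths[[name]]
    if (is.null(p)) stop("missing raster path set '", name, "'")
    if (length(p) != n)
      stop(sprintf("layer '%s' needs %d raster(s); got %d%s", name, n, length(p),
                   if (n == 12 && length(p) < 12)
                     sprintf(" (month %d onward missing)", length(p) + 1) else ""))
    p
  }
  hasUV <- !is.null(paths$currentU) && !is.null(paths$currentV)
  first <- if (hasUV) getLayer("currentU", 12)[1] else getLayer("currentSpeed", 12)[1]
  ref <- readAsciiGrid(first)
  if (is.null(grid)) grid <- ref$grid
  readMonthly <- function(name) {
    p <- getLayer(name, 12)
    arr <- array(NA_real_, dim = c(grid@nRows, grid@nCols, 12))
    for (m in seq_len(12)) {
      if (is.na(p[m]) || !file.exists(p[m]))
        stop(sprintf("layer '%s' month %d: raster missing (%s)", name, m, p[m]))
      g <- readAsciiGrid(p[m])
      if (!identical(dim(g$values), c(grid@nRows, grid@nCols)))
        stop(sprintf("layer '%s' month %d: dimensions %d x %d disagree with grid %d x %d",
                     name, m, nrow(g$values), ncol(g$values), grid@nRows, grid@nCols))
      arr[, , m] <- g$values
    }
    arr
  }
  if (hasUV) {
    u <- readMonthly("currentU"); v <- readMonthly("currentV")
    speed <- sqrt(u^2 + v^2)
    dir <- (atan2(u, v) * 180 / pi) %% 360
    dir[speed == 0] <- 0
  } else {
    speed <- readMonthly("currentSpeed")
    dir <- readMonthly("currentDirection")
  }
  sst <- readMonthly("sst")
  chl <- readMonthly("chlorophyll")
  dp <- readAsciiGrid(getLayer("depth", 1))
  if (!identical(dim(dp$values), c(grid@nRows, grid@nCols)))
    stop("depth raster dimensions disagree with grid")
  land <- matrix(FALSE, grid@nRows, grid@nCols)
  if (!is.null(paths$landMask)) {
    lm <- readAsciiGrid(paths$landMask[1])
    if (!identical(dim(lm$values), c(grid@nRows, grid@nCols)))
      stop("landMask raster dimensions disagree with grid")
    land <- !is.na(lm$values) & lm$values != 0
  }
  environmentStack(grid, speed, dir, sst, chl, dp$values, land)
}

#' Write every layer of an environment stack as ASCII grids
#'
#' Writes `current_speed_MM.asc`, `current_direction_MM.asc`, `sst_MM.asc`,
#' `chlorophyll_MM.asc` (MM = 01..12), `depth.asc` and `land_mask.asc`
#' into `dir`, in the layout [readEnvironmentDir()] expects.
#'
#' @param stack an [EnvironmentStack-class].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
writeEnvironmentDir <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- stack@grid
  for (m in seq_len(12)) {
    writeAsciiGrid(stack@currentSpeed[, , m], g,
                   file.path(dir, sprintf("current_speed_%02d.asc", m)))
    writeAsciiGrid(stack@currentDirection[, , m], g,
                   file.path(dir, sprintf("current_direction_%02d.asc", m)))
    writeAsciiGrid(stack@sst[, , m], g, file.path(dir, sprintf("sst_%02d.asc", m)))
    writeAsciiGrid(stack@chlorophyll[, , m], g,
                   file.path(dir, sprintf("chlorophyll_%02d.asc", m)))
  }
  writeAsciiGrid(stack@depth, g, file.path(dir, "depth.asc"))
  writeAsciiGrid(matrix(as.numeric(stack@landMask), g@nRows, g@nCols), g,
                 file.path(dir, "land_mask.asc"))
  invisible(dir)
}

#' Read an environment directory written by [writeEnvironmentDir()]
#'
#' @param dir directory holding the standard layer filenames.
#' @return an [EnvironmentStack-class].
#' @export
readEnvironmentDir <- function(dir) {
  mm <- sprintf("%02d", seq_len(12))
  readEnvironment(list(
    currentSpeed = file.path(dir, paste0("current_speed_", mm, ".asc")),
    currentDirection = file.path(dir, paste0("current_direction_", mm, ".asc")),
    sst = file.path(dir, paste0("sst_", mm, ".asc")),
    chlorophyll = file.path(dir, paste0("chlorophyll_", mm, ".asc")),
    depth = file.path(dir, "depth.asc"),
    landMask = file.path(dir, "land_mask.asc")
  ))
}
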