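#' Parameters of the synthetic environment generator
#'
#' Defaults describe a stylised subtropical western-boundary setting on a
#' 6 x 6 degree domain: land along the western edge, a shallow shelf
#' (< 40 m) within `shelfWidthCells` of the coast, a fast coast-parallel
#' jet that separates from the coast and veers offshore at
#' `separationLat`, a calm "retention" zone of weak meandering flow
#' inshore and north of the separation point, a meridional SST gradient
#' with a seasonal cycle that takes winter temperatures below the 16
#' degree C tolerance north of `coldLat`, and chlorophyll decaying from
#' coastal to oligotrophic offshore values (below the 0.10 ug/L tolerance
#' far offshore).
#'
#' @param peakSpeed jet core speed, m/s; the grid-wide maximum over all
#'   cells and months equals this exactly.
#' @param jetOffsetCells distance (cells) from the coastline to the jet
#'   axis south of the separation latitude.
#' @param jetWidthCells Gaussian cross-jet width (cells, one sd).
#' @param separationLat latitude at which the jet axis leaves the coast.
#' @param separationAngle degrees east of north the axis takes north of
#'   the separation latitude.  Kept above 45 degrees so the departing jet
#'   outruns kernels (which move at most one cell diagonally per hop) and
#'   genuinely strands them in the calm water inshore of the separation.
#' @param shelfWidthCells shelf width in cells; shelf depth stays < 40 m.
#' @param shelfDepthMin,shelfSlope,offshoreSlope,maxDepth bathymetry
#'   profile (m, m/cell, m/cell, m).
#' @param sstBase SST (C) at the southern edge in the seasonal mean.
#' @param sstGradient cooling per degree of latitude northward (C/deg).
#' @param sstSeasonalAmp,sstPeakMonth seasonal amplitude (C) and warmest
#'   calendar month.
#' @param coldLat latitude north of which winter SST is below 16 C.
#' @param winterMonths calendar months over which the cold constraint is
#'   enforced.
#' @param chlOffshore,chlCoastAmp,chlEfoldDeg chlorophyll profile: offshore
#'   floor, coastal amplitude (both ug/L) and e-folding scale (degrees).
#' @param backgroundSpeed,retentionSpeed weak flow outside the jet and in
#'   the retention zone (m/s).
#' @param speedSeasonalAmp relative seasonal modulation of current speed.
#' @param sstNoise,speedNoise,chlNoise bounded uniform noise amplitudes
#'   (additive C, relative, relative).
#' @return named list of generator parameters.
#' @export
synthParams <- function(peakSpeed = 2.0,
                        jetOffsetCells = 4,
                        jetWidthCells = 2.5,
                        separationLat = 27.5,
                        separationAngle = 60,
                        shelfWidthCells = 8,
                        shelfDepthMin = 3,
                        shelfSlope = 4.5,
                        offshoreSlope = 120,
                        maxDepth = 1000,
                        sstBase = 26,
                        sstGradient = 2.0,
                        sstSeasonalAmp = 4,
                        sstPeakMonth = 8,
                        coldLat = 28,
                        winterMonths = c(1, 2, 3),
                        chlOffshore = 0.07,
                        chlCoastAmp = 4,
                        chlEfoldDeg = 0.6,
                        backgroundSpeed = 0.05,
                        retentionSpeed = 0.03,
                        speedSeasonalAmp = 0.15,
                        sstNoise = 0.4,
                        speedNoise = 0.1,
                        chlNoise = 0.2) {
  as.list(environment())
}

#' Generate a synthetic monthly environment
#'
#' Builds a fully synthetic [EnvironmentStack-class] with the physical
#' structure described in [synthParams()].  The output is bit-identical
#' for a given seed and parameter set (the caller's RNG stream is left
#' untouched).  Construction guarantees, for any seed: the global maximum
#' current speed equals `peakSpeed`; shelf cells within `shelfWidthCells`
#' of the coast are shallower than 40 m; SST is below 16 C in
#' `winterMonths` north of `coldLat`; and a weak-flow retention zone lies
#' inshore of the jet north of `separationLat`.
#'
#' @param grid a [GridSpec-class]; default is the 60 x 60 cell, 6 arc-min
#'   study domain (24..30 N, -82..-76 W).
#' @param params list from [synthParams()].
#' @param seed integer seed.
#' @return an [EnvironmentStack-class].
#' @examples
#' env <- generateSyntheticEnvironment(seed = 1)
#' max(env@currentSpeed)    # == peakSpeed
#' @export
generateSyntheticEnvironment <- function(grid = gridSpec(24, 30, -82, -76, 6),
                                         params = synthParams(),
                                         seed = 1) {
  p <- params
  nr <- grid@nRows; nc <- grid@nCols
  cellsPerDeg <- 60 / grid@resolution
  lat <- cellCenters(grid, seq_len(nr), 1L)$lat         # by row
  # preserve the caller's RNG stream
  hadSeed <- exists(".Random.seed", envir = globalenv())
  if (hadSeed) oldSeed <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hadSeed) assign(".Random.seed", oldSeed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)

  # coastline: land strip on the west with a gentle alongshore undulation
  landWidth <- 2 + round(sin((lat - grid@latMin) * 2 * pi / 7))
  landWidth <- pmax(1, pmin(landWidth, nc - 2))
  colIdx <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  distCoast <- colIdx - landWidth                       # recycled by row
  land <- distCoast <= 0

  # bathymetry: linear shelf then a steep slope
  depth <- ifelse(distCoast <= p$shelfWidthCells,
                  p$shelfDepthMin + p$shelfSlope * (distCoast - 1),
                  pmin(p$maxDepth,
                       40 + p$offshoreSlope * (distCoast - p$shelfWidthCells)))
  depth[land] <- NA

  # jet axis column per row; veers offshore north of the separation latitude
  axisCol <- landWidth + p$jetOffsetCells +
    pmax(0, lat - p$separationLat) * cellsPerDeg * tan(p$separationAngle * pi / 180)
  if (any(axisCol > nc))
    stop("jet axis leaves the grid; shrink separationAngle or enlarge the domain")
  jetDir <- ifelse(lat >= p$separationLat, p$separationAngle %% 360, 0)

  crossDist <- sweep(colIdx, 1, axisCol, "-")
  jetProfile <- p$peakSpeed * exp(-crossDist^2 / (2 * p$jetWidthCells^2))
  retention <- sweep(colIdx, 1, axisCol - 2 * p$jetWidthCells, "<") &
    matrix(lat >= p$separationLat, nr, nc) & !land
  bg <- matrix(p$backgroundSpeed, nr, nc)
  bg[retention] <- p$retentionSpeed
  meanderDir <- matrix(runif(nr * nc, 0, 360), nr, nc)

  speed <- array(0, c(nr, nc, 12))
  dirA <- array(0, c(nr, nc, 12))
  sstA <- array(0, c(nr, nc, 12))
  chlA <- array(0, c(nr, nc, 12))
  sstLat <- p$sstBase - p$sstGradient * (lat - grid@latMin)
  chlProf <- p$chlOffshore +
    p$chlCoastAmp * exp(-(distCoast / cellsPerDeg) / p$chlEfoldDeg)
  for (m in seq_len(12)) {
    season <- 1 + p$speedSeasonalAmp * cos(2 * pi * (m - p$sstPeakMonth - 1) / 12)
    jm <- jetProfile * season * matrix(runif(nr * nc, 1 - p$speedNoise, 1 + p$speedNoise), nr, nc)
    useJet <- jm >= bg
    speed[, , m] <- ifelse(useJet, jm, bg)
    dirA[, , m] <- ifelse(useJet, matrix(jetDir, nr, nc), meanderDir)
    sstA[, , m] <- matrix(sstLat, nr, nc) +
      p$sstSeasonalAmp * cos(2 * pi * (m - p$sstPeakMonth) / 12) +
      matrix(runif(nr * nc, -p$sstNoise, p$sstNoise), nr, nc)
    chlA[, , m] <- chlProf * matrix(runif(nr * nc, 1 - p$chlNoise, 1 + p$chlNoise), nr, nc)
  }
  # hard construction guarantees independent of noise and parameter choice
  speed <- speed * (p$peakSpeed / max(speed))
  northWinter <- array(FALSE, c(nr, nc, 12))
  for (m in p$winterMonths) northWinter[, , m] <- matrix(lat > p$coldLat, nr, nc)
  sstA[northWinter] <- pmin(sstA[northWinter], 15.5)

  environmentStack(grid, speed, dirA, sstA, chlA, depth, land)
}
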