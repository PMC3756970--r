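# Programmatic fixtures: small uniform stacks with fully controllable
# layers, built in code so every test constructs exactly the physics it
# asserts about.

# A homogeneous stack: constant current, SST, chlorophyll and depth
# everywhere, optional land cells.  Defaults are habitable under the
# default configuration.
makeUniformStack <- function(nRows = 10, nCols = 10, latMax = 1, lonMin = 0,
                             resolution = 6, speed = 0.5, direction = 0,
                             sst = 28, cc = 0.5, depth = 20, landCells = NULL) {
  step <- resolution / 60
  grid <- gridSpec(latMax - nRows * step, latMax, lonMin, lonMin + nCols * step,
                   resolution)
  mk <- function(v) array(v, dim = c(nRows, nCols, 12))
  land <- matrix(FALSE, nRows, nCols)
  if (!is.null(landCells)) land[landCells] <- TRUE
  environmentStack(grid, mk(speed), mk(direction), mk(sst), mk(cc),
                   matrix(depth, nRows, nCols), land)
}

# A result object with a prescribed establishment raster (for sequence and
# mapping tests that do not need a full simulation).
makeEstablishmentResult <- function(stack, cells, cycles) {
  est <- matrix(NA_real_, stack@grid@nRows, stack@grid@nCols)
  for (i in seq_along(cycles)) est[cells[[i]][1], cells[[i]][2]] <- cycles[i]
  new("SimulationResult", grid = stack@grid,
      events = invasionCA:::.emptyEvents(),
      settledCount = matrix(0L, stack@grid@nRows, stack@grid@nCols),
      establishmentCycle = est,
      cycleSummary = data.frame(),
      months = if (length(cycles)) max(cycles) else 0, seed = NA_real_,
      config = NULL)
}

# Shared synthetic study environment (built once per test run).
studyEnv <- local({
  env <- NULL
  function() {
    if (is.null(env)) env <<- generateSyntheticEnvironment(seed = 1)
    env
  }
})

# Desk-scale configuration used for spread-rich engine tests: larval
# mortality lowered so invasions reliably cross the small synthetic
# domain, founder persistent at the origin.
deskConfig <- function(...) {
  simConfig(propaguleMortality = 0.075, founderImmortal = TRUE, ...)
}

# Origin inside the retention zone of the default synthetic environment.
retentionOrigin <- c(27.8, -81.5)
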