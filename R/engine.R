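METERS_PER_DEGREE <- 111200  # at the equator; scaled by cos(latitude)

# Per-run precomputed lattice tables: 0-based neighbour index matrix
# (ncells x 8, -1 for land/out-of-grid), static-parameter scores and
# habitability per cell and month, monthly fields as ncells x 12 matrices,
# grid-wide monthly maximum speed, and per-cell width in metres.
.buildContext <- function(stack, config) {
  g <- stack@grid
  nr <- g@nRows; nc <- g@nCols; ncells <- nr * nc
  marine <- !as.vector(stack@landMask)
  dr <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  dc <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  rows <- rep(seq_len(nr), nc)
  cols <- rep(seq_len(nc), each = nr)
  nbIdx <- matrix(-1L, ncells, 8)
  for (k in seq_len(8)) {
    r2 <- rows + dr[k]; c2 <- cols + dc[k]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    idx <- (c2[ok] - 1L) * nr + r2[ok]
    okMarine <- marine[idx]
    tgt <- which(ok)[okMarine]
    nbIdx[tgt, k] <- idx[okMarine] - 1L
  }
  layerScore <- function(vals, rng, mode) {
    ok <- vals >= rng[1] & vals <= rng[2]
    if (mode == "binary") return(as.numeric(ok))
    mid <- mean(rng); half <- diff(rng) / 2
    s <- pmax(0, 1 - abs(vals - mid) / ifelse(half > 0, half, 1))
    s[!ok] <- 0
    s
  }
  speedMat <- stack@currentSpeed; dim(speedMat) <- c(ncells, 12)
  dirMat <- stack@currentDirection; dim(dirMat) <- c(ncells, 12)
  sstMat <- stack@sst; dim(sstMat) <- c(ncells, 12)
  chlMat <- stack@chlorophyll; dim(chlMat) <- c(ncells, 12)
  depthVec <- as.vector(stack@depth)
  staticScore <- matrix(0, ncells, 12)
  okAll <- matrix(FALSE, ncells, 12)
  mode <- config@suitabilityMode
  depthS <- layerScore(depthVec, config@depthRange, mode)
  depthOk <- !is.na(depthVec) & depthVec >= config@depthRange[1] & depthVec <= config@depthRange[2]
  for (m in seq_len(12)) {
    sS <- layerScore(sstMat[, m], config@sstRange, mode)
    cS <- layerScore(chlMat[, m], config@ccRange, mode)
    staticScore[, m] <- config@sstWeight * sS + config@ccWeight * cS +
      config@depthWeight * depthS
    okAll[, m] <- marine & depthOk &
      sstMat[, m] >= config@sstRange[1] & sstMat[, m] <= config@sstRange[2] &
      chlMat[, m] >= config@ccRange[1] & chlMat[, m] <= config@ccRange[2]
  }
  staticScore[!marine | is.na(staticScore)] <- 0
  okAll[is.na(okAll)] <- FALSE
  maxSpeed <- vapply(seq_len(12), function(m) {
    s <- speedMat[marine, m]
    if (length(s)) max(s, na.rm = TRUE) else 0
  }, numeric(1))
  speedMat[is.na(speedMat)] <- 0
  dirMat[is.na(dirMat)] <- 0
  latRow <- cellCenters(g, seq_len(nr), 1L)$lat
  cellWidth <- rep(g@resolution / 60 * METERS_PER_DEGREE * cos(latRow * pi / 180), nc)
  list(nbIdx = nbIdx, staticScore = staticScore, okAll = okAll,
       speedMat = speedMat, dirMat = dirMat, maxSpeed = maxSpeed,
       cellWidth = cellWidth, marine = marine, nRows = nr, nCols = nc,
       hazards = perCycleHazards(config))
}

.cellIndex <- function(nr, row, col) (col - 1L) * nr + row

#' Movement probabilities over the 8 neighbours of a cell
#'
#' Each marine neighbour is scored
#' `w_OC * a + w_SST * s_SST + w_CC * s_CC + w_OD * s_OD`, where the
#' advection term `a = max(0, cos(angle between the cell's current
#' direction and the bearing to the neighbour)) * speed / max monthly
#' speed` uses the departing cell's current, and the `s` terms are the
#' neighbour's suitability scores.  Scores are normalised to
#' probabilities; if every score is zero (e.g. stagnant water among
#' unsuitable neighbours) the choice is uniform over marine neighbours.
#' In slow water the static parameters therefore dominate the choice; in
#' fast water the current direction does.
#'
#' @param stack an [EnvironmentStack-class].
#' @param cell `c(row, col)` of a marine cell with at least one marine
#'   neighbour.
#' @param month calendar month 1..12.
#' @param config a [ModelConfig-class].
#' @param context optional precomputed context (internal reuse).
#' @return named probability vector over N, NE, E, SE, S, SW, W, NW (land
#'   neighbours get probability 0); sums to 1.
#' @export
neighborScores <- function(stack, cell, month, config, context = NULL) {
  if (is.null(context)) context <- .buildContext(stack, config)
  nr <- context$nRows
  if (stack@landMask[cell[1], cell[2]]) stop("cell is land")
  idx0 <- .cellIndex(nr, cell[1], cell[2]) - 1L
  p <- cpp_neighbor_probs(idx0, as.integer(month), context$nbIdx,
                          context$staticScore, context$speedMat,
                          context$dirMat, context$maxSpeed,
                          config@currentWeight)
  if (all(is.na(p))) stop("cell is isolated: all 8 neighbours are land")
  names(p) <- c("N", "NE", "E", "SE", "S", "SW", "W", "NW")
  p
}

#' Transit of one kernel from spawning to settlement point
#'
#' Repeatedly samples a neighbour from [neighborScores()] and accumulates
#' the per-cell dwell time (destination cell width in metres at its
#' latitude, divided by its current speed floored at
#' `config@speedFloor`) until the running sum reaches the larval duration;
#' the cell occupied when the threshold is crossed is the settlement
#' point.  Monthly fields advance at each 30-day mark of the running sum.
#' A kernel whose cell has no marine neighbour dies in transit.
#'
#' @param stack an [EnvironmentStack-class].
#' @param origin `c(row, col)` of the spawning cell (marine).
#' @param spawnCalendarMonth calendar month in which the spawn occurred.
#' @param config a [ModelConfig-class].
#' @param context optional precomputed context.
#' @return list with `cell` (`c(row, col)` or NULL if dead), `elapsedDays`,
#'   `hops`, `endMonth` (calendar month when transit ended) and `dead`.
#' @export
traceTransit <- function(stack, origin, spawnCalendarMonth, config, context = NULL) {
  if (is.null(context)) context <- .buildContext(stack, config)
  nr <- context$nRows
  if (stack@landMask[origin[1], origin[2]]) stop("origin is land")
  res <- cpp_trace_transit(.cellIndex(nr, origin[1], origin[2]) - 1L,
                           as.integer(spawnCalendarMonth),
                           config@propaguleDuration,
                           context$nbIdx, context$staticScore,
                           context$speedMat, context$dirMat,
                           context$maxSpeed, context$cellWidth,
                           config@speedFloor, config@currentWeight)
  dead <- res[5] == 1
  cell <- if (dead) NULL else {
    idx <- as.integer(res[1]) + 1L
    c(row = ((idx - 1L) %% nr) + 1L, col = ((idx - 1L) %/% nr) + 1L)
  }
  list(cell = cell, elapsedDays = res[2], hops = as.integer(res[3]),
       endMonth = as.integer(res[4]), dead = dead)
}

#' Settlement attempt at the end of transit
#'
#' One Bernoulli draw with success probability `exp(-Z_p * D)` decides
#' transport survival; a surviving kernel settles if and only if the cell
#' is marine and its SST, chlorophyll and depth all fall inside the
#' habitable ranges in the settlement month, otherwise it dies.
#'
#' @param finalCell `c(row, col)` where transit ended.
#' @param calendarMonth month in which transit ended.
#' @param stack an [EnvironmentStack-class].
#' @param config a [ModelConfig-class].
#' @param n number of independent attempts to draw (vectorised use for
#'   empirical rate checks).
#' @return character vector of length `n`, each `"settled"` or `"dead"`.
#' @export
attemptSettlement <- function(finalCell, calendarMonth, stack, config, n = 1) {
  surv <- exp(-config@propaguleMortality * config@propaguleDuration)
  alive <- runif(n) < surv
  suitable <- if (stack@landMask[finalCell[1], finalCell[2]]) FALSE else {
    v <- cellSuitability(stack, finalCell, calendarMonth, config)
    v$sstOk && v$ccOk && v$depthOk
  }
  ifelse(alive & suitable, "settled", "dead")
}

#' Initialise a simulation
#'
#' Creates the starting [SimulationState-class]: one founder population
#' kernel at the origin, already of breeding age (the model assumes a
#' breeding population persists at the origin).  When `seed` (or
#' `config@rngSeed`) is given the global RNG is seeded here; every
#' stochastic draw of the run is consumed from that single stream.
#'
#' @param config a [ModelConfig-class].
#' @param stack an [EnvironmentStack-class].
#' @param origin `c(lat, lon)` in decimal degrees; must fall on a marine
#'   cell.
#' @param seed optional integer seed.
#' @return a [SimulationState-class] with `cycle = 0`.
#' @export
initSimulation <- function(config, stack, origin, seed = NULL) {
  stopifnot(is(config, "ModelConfig"), is(stack, "EnvironmentStack"))
  if (is.null(seed) && !is.na(config@rngSeed)) seed <- config@rngSeed
  if (!is.null(seed)) set.seed(as.integer(seed))
  cell <- cellAt(stack@grid, origin[1], origin[2])
  if (stack@landMask[cell$row, cell$col])
    stop(sprintf("origin (%g, %g) falls on a land cell", origin[1], origin[2]))
  ctx <- .buildContext(stack, config)
  pop <- data.frame(row = cell$row, col = cell$col,
                    cell = .cellIndex(stack@grid@nRows, cell$row, cell$col),
                    settleCycle = 0L, age = config@breedingAge,
                    breeding = TRUE, founder = TRUE)
  new("SimulationState", config = config, stack = stack, populations = pop,
      cycle = 0L, eventsList = list(), cycleList = list(), context = ctx)
}

.emptyEvents <- function() {
  data.frame(cycle = integer(0), calendarMonth = integer(0), row = integer(0),
             col = integer(0), lat = numeric(0), lon = numeric(0),
             event = character(0))
}

.inBreedingWindow <- function(month, window) {
  if (window[1] <= window[2]) month >= window[1] & month <= window[2]
  else month >= window[1] | month <= window[2]
}

#' Advance the simulation by one monthly cycle
#'
#' Executes, in order: (1) every breeding population kernel whose calendar
#' month lies inside the breeding window emits `kernelCount` kernels per
#' spawning event; (2) each kernel draws its transport-survival Bernoulli
#' (`exp(-Z_p * D)`) and, if it survives, runs its transit walk and
#' settles where habitable, founding a new juvenile population kernel;
#' (3) every population kernel takes the adult-mortality test (founders
#' are exempt when `founderImmortal`); (4) survivors age by one month and
#' those reaching breeding age are promoted, contributing larvae from the
#' next cycle on; (5) the cycle counter and calendar month advance.
#'
#' @param state a [SimulationState-class].
#' @return the advanced state.
#' @export
stepMonth <- function(state) {
  cfg <- state@config
  ctx <- state@context
  g <- state@stack@grid
  nr <- g@nRows
  cycleNo <- state@cycle + 1L
  calMonth <- ((cfg@startingMonth - 1 + cycleNo - 1) %% 12) + 1
  pop <- state@populations
  ev <- list()
  nSpawnedKernels <- 0L
  settled <- NULL

  # (1) + (2) spawning and kernel fate
  breeders <- which(pop$breeding)
  if (length(breeders) && .inBreedingWindow(calMonth, cfg@breedingWindow) &&
      cfg@spawnsPerCycle >= 1) {
    K <- round(cfg@kernelCount)
    nSpawns <- round(cfg@spawnsPerCycle)
    originIdx <- rep(pop$cell[breeders], each = nSpawns * K)
    nSpawnedKernels <- length(originIdx)
    bc <- cellCenters(g, pop$row[breeders], pop$col[breeders])
    ev[["spawn"]] <- data.frame(cycle = cycleNo, calendarMonth = calMonth,
                                row = rep(pop$row[breeders], each = nSpawns),
                                col = rep(pop$col[breeders], each = nSpawns),
                                lat = rep(bc$lat, each = nSpawns),
                                lon = rep(bc$lon, each = nSpawns),
                                event = "spawn")
    alive <- runif(nSpawnedKernels) < ctx$hazards$larvalTransportSurvival
    survivors <- which(alive)
    if (length(survivors)) {
      out <- vector("list", length(survivors))
      nOut <- 0L
      for (i in survivors) {
        res <- cpp_trace_transit(originIdx[i] - 1L, as.integer(calMonth),
                                 cfg@propaguleDuration, ctx$nbIdx,
                                 ctx$staticScore, ctx$speedMat, ctx$dirMat,
                                 ctx$maxSpeed, ctx$cellWidth,
                                 cfg@speedFloor, cfg@currentWeight)
        if (res[5] == 1) next                    # trapped: died in transit
        fIdx <- as.integer(res[1]) + 1L
        endMonth <- as.integer(res[4])
        if (!ctx$okAll[fIdx, endMonth]) next     # inhospitable: died
        nOut <- nOut + 1L
        out[[nOut]] <- c(fIdx, endMonth)
      }
      if (nOut > 0L) {
        m <- do.call(rbind, out[seq_len(nOut)])
        srow <- ((m[, 1] - 1L) %% nr) + 1L
        scol <- ((m[, 1] - 1L) %/% nr) + 1L
        sc <- cellCenters(g, srow, scol)
        settled <- data.frame(row = srow, col = scol, cell = m[, 1],
                              settleCycle = cycleNo, age = 0L,
                              breeding = FALSE, founder = FALSE)
        ev[["settle"]] <- data.frame(cycle = cycleNo, calendarMonth = m[, 2],
                                     row = srow, col = scol,
                                     lat = sc$lat, lon = sc$lon,
                                     event = "settle")
      }
    }
  }
  if (!is.null(settled)) pop <- rbind(pop, settled)

  # (3) adult mortality over the settled pool
  nDeaths <- 0L
  if (nrow(pop)) {
    dies <- runif(nrow(pop)) < ctx$hazards$adultMonthlyDeath
    if (cfg@founderImmortal) dies[pop$founder] <- FALSE
    if (any(dies)) {
      dcells <- cellCenters(g, pop$row[dies], pop$col[dies])
      ev[["death"]] <- data.frame(cycle = cycleNo, calendarMonth = calMonth,
                                  row = pop$row[dies], col = pop$col[dies],
                                  lat = dcells$lat, lon = dcells$lon,
                                  event = "death")
      nDeaths <- sum(dies)
      pop <- pop[!dies, , drop = FALSE]
    }
  }

  # (4) ageing and promotion to breeding
  if (nrow(pop)) {
    pop$age <- pop$age + 1L
    promote <- !pop$breeding & pop$age >= cfg@breedingAge
    if (any(promote)) {
      pop$breeding[promote] <- TRUE
      pcells <- cellCenters(g, pop$row[promote], pop$col[promote])
      ev[["promote"]] <- data.frame(cycle = cycleNo, calendarMonth = calMonth,
                                    row = pop$row[promote], col = pop$col[promote],
                                    lat = pcells$lat, lon = pcells$lon,
                                    event = "promote")
    }
  }

  summaryRow <- data.frame(cycle = cycleNo, calendarMonth = calMonth,
                           nSpawnedKernels = nSpawnedKernels,
                           nSettled = if (is.null(settled)) 0L else nrow(settled),
                           nDeaths = nDeaths,
                           nAliveEnd = nrow(pop),
                           nBreedingEnd = sum(pop$breeding))
  state@populations <- pop
  state@cycle <- cycleNo
  state@eventsList[[length(state@eventsList) + 1L]] <-
    if (length(ev)) do.call(rbind, ev) else .emptyEvents()
  state@cycleList[[length(state@cycleList) + 1L]] <- summaryRow
  state
}

#' Run a full simulation
#'
#' Seeds the RNG, places one breeding founder at `origin`, advances
#' [stepMonth()] `months` times and assembles the [SimulationResult-class]
#' (event log, settlement-count raster, first-establishment raster,
#' per-cycle summary).  Runs are bit-reproducible for a fixed seed.
#'
#' @param config a [ModelConfig-class].
#' @param stack an [EnvironmentStack-class].
#' @param origin `c(lat, lon)` of the founder population (marine cell).
#' @param months number of monthly cycles (default `config@cycles`).
#' @param seed integer seed (default `config@rngSeed`).
#' @return a [SimulationResult-class].
#' @examples
#' env <- generateSyntheticEnvironment(seed = 1)
#' cfg <- simConfig(propaguleMortality = 0.075, founderImmortal = TRUE)
#' res <- runSimulation(cfg, env, origin = c(25.0, -81.0), months = 24, seed = 7)
#' sum(res@settledCount)
#' @export
runSimulation <- function(config, stack, origin, months = config@cycles,
                          seed = config@rngSeed) {
  if (months < 0) stop("months must be >= 0")
  state <- initSimulation(config, stack, origin,
                          seed = if (is.null(seed) || is.na(seed)) NULL else seed)
  for (i in seq_len(months)) state <- stepMonth(state)
  finalizeSimulation(state, seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
}

#' Assemble a result object from a simulation state
#'
#' @param state a [SimulationState-class].
#' @param seed seed recorded in the result.
#' @return a [SimulationResult-class].
#' @export
finalizeSimulation <- function(state, seed = NA_real_) {
  g <- state@stack@grid
  events <- if (length(state@eventsList)) do.call(rbind, state@eventsList) else .emptyEvents()
  rownames(events) <- NULL
  settledCount <- matrix(0L, g@nRows, g@nCols)
  st <- events[events$event == "settle", ]
  if (nrow(st)) {
    tab <- table(factor(.cellIndex(g@nRows, st$row, st$col),
                        levels = seq_len(g@nRows * g@nCols)))
    settledCount <- matrix(as.integer(tab), g@nRows, g@nCols)
  }
  estab <- matrix(NA_real_, g@nRows, g@nCols)
  pr <- events[events$event == "promote", ]
  if (nrow(pr)) {
    for (i in seq_len(nrow(pr))) {
      cur <- estab[pr$row[i], pr$col[i]]
      if (is.na(cur) || pr$cycle[i] < cur) estab[pr$row[i], pr$col[i]] <- pr$cycle[i]
    }
  }
  cycleSummary <- if (length(state@cycleList)) do.call(rbind, state@cycleList) else
    data.frame(cycle = integer(0), calendarMonth = integer(0),
               nSpawnedKernels = integer(0), nSettled = integer(0),
               nDeaths = integer(0), nAliveEnd = integer(0),
               nBreedingEnd = integer(0))
  rownames(cycleSummary) <- NULL
  new("SimulationResult", grid = g, events = events, settledCount = settledCount,
      establishmentCycle = estab, cycleSummary = cycleSummary,
      months = as.numeric(state@cycle), seed = seed, config = state@config)
}

setMethod("show", "SimulationResult", function(object) {
  cat(sprintf("SimulationResult: %g cycles on a %d x %d grid\n",
              object@months, object@grid@nRows, object@grid@nCols))
  cat(sprintf("  %d settle, %d promote, %d death events; %d cells settled\n",
              sum(object@events$event == "settle"),
              sum(object@events$event == "promote"),
              sum(object@events$event == "death"),
              sum(object@settledCount > 0)))
  if (nrow(object@cycleSummary)) {
    tail1 <- object@cycleSummary[nrow(object@cycleSummary), ]
    cat(sprintf("  final population: %d alive (%d breeding)\n",
                tail1$nAliveEnd, tail1$nBreedingEnd))
  }
  invisible(object)
})

#' Write the event log as CSV
#'
#' Columns: cycle, calendar_month, lat, lon, event.
#' @param result a [SimulationResult-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEventLog <- function(result, path) {
  ev <- result@events
  write.csv(data.frame(cycle = ev$cycle, calendar_month = ev$calendarMonth,
                       lat = ev$lat, lon = ev$lon, event = ev$event),
            path, row.names = FALSE)
  invisible(path)
}
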