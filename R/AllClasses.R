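#' @import methods
#' @importFrom stats runif setNames aggregate
#' @importFrom utils read.csv write.csv head packageVersion
#' @useDynLib invasionCA, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Simulation parameter set
#'
#' `ModelConfig` holds every tunable parameter of the invasion simulator:
#' the environmental tolerance ranges and their scoring weights, the
#' fecundity and mortality parameters that impose a time scale, and the
#' run-control fields (cycle count, starting month, seed).  Objects are
#' created with [simConfig()] or read from a YAML file with
#' [loadConfig()]; never call `new()` directly.
#'
#' Weights are standardised to sum to one at construction, so the stored
#' weights of a default configuration are 0.9375 (current) and 0.020833
#' (each static parameter) rather than the raw 0.90/0.02 inputs.
#'
#' @slot cycles number of monthly cycles a default run executes.
#' @slot gridSize lattice resolution in arc-minutes.
#' @slot sstRange,ccRange,depthRange habitable `[min, max]` intervals for
#'   sea-surface temperature (degrees C), chlorophyll concentration
#'   (micrograms per litre) and depth (metres, positive down).
#' @slot sstWeight,ccWeight,depthWeight,currentWeight normalised scoring
#'   weights (sum to 1).
#' @slot propaguleDuration larval transport duration D in days.
#' @slot propaguleMortality instantaneous larval mortality Z_p per day.
#' @slot breedingAge age at maturity in months.
#' @slot adultMortality instantaneous adult mortality Z per year.
#' @slot eggQuantity,fertilizationRate,hatchingRate fecundity inputs whose
#'   product gives the viable propagule quantity.
#' @slot propaguleQuantity viable larvae per spawning event.
#' @slot kernelCount kernels emitted per spawning event.
#' @slot breedingWindow first and last calendar month of the breeding
#'   season (wrapping windows allowed).
#' @slot spawnsPerCycle spawning events per 30-day cycle.
#' @slot startingMonth calendar month of cycle 1.
#' @slot rngSeed default seed (NA = unseeded).
#' @slot mortalityMode `"hazard"` converts the annual adult rate to a
#'   monthly death probability `1 - exp(-Z/12)`; `"literal"` uses Z itself
#'   as the per-cycle probability.
#' @slot speedFloor minimum current speed (m/s) used when computing cell
#'   dwell time, so transit terminates in stagnant water.
#' @slot founderImmortal if TRUE the founder population is exempt from the
#'   adult mortality test.
#' @slot suitabilityMode `"binary"` (default) or `"graded"` triangular
#'   suitability scores for neighbour weighting.
#'
#' @seealso [simConfig()], [loadConfig()], [perCycleHazards()]
#' @export
setClass("ModelConfig", representation(
  cycles = "numeric",
  gridSize = "numeric",
  sstRange = "numeric", sstWeight = "numeric",
  ccRange = "numeric", ccWeight = "numeric",
  depthRange = "numeric", depthWeight = "numeric",
  currentWeight = "numeric",
  propaguleDuration = "numeric",
  propaguleMortality = "numeric",
  breedingAge = "numeric",
  adultMortality = "numeric",
  eggQuantity = "numeric",
  fertilizationRate = "numeric",
  hatchingRate = "numeric",
  propaguleQuantity = "numeric",
  kernelCount = "numeric",
  breedingWindow = "numeric",
  spawnsPerCycle = "numeric",
  startingMonth = "numeric",
  rngSeed = "numeric",
  mortalityMode = "character",
  speedFloor = "numeric",
  founderImmortal = "logical",
  suitabilityMode = "character"
))

setValidity("ModelConfig", function(object) {
  errs <- character(0)
  chkRange <- function(r, nm) {
    if (length(r) != 2 || any(!is.finite(r))) return(sprintf("%s must be a finite [min, max] pair", nm))
    if (r[1] > r[2]) return(sprintf("%s: min exceeds max", nm))
    NULL
  }
  w <- c(object@currentWeight, object@sstWeight, object@ccWeight, object@depthWeight)
  if (any(w < 0)) errs <- c(errs, "weights (currentWeight/sstWeight/ccWeight/depthWeight) must be >= 0")
  if (all(w == 0)) errs <- c(errs, "at least one weight must be > 0")
  for (nm in c("sstRange", "ccRange", "depthRange")) {
    e <- chkRange(slot(object, nm), nm)
    if (!is.null(e)) errs <- c(errs, e)
  }
  if (object@propaguleDuration <= 0) errs <- c(errs, "propaguleDuration must be > 0")
  if (object@propaguleMortality < 0) errs <- c(errs, "propaguleMortality must be >= 0")
  if (object@adultMortality < 0) errs <- c(errs, "adultMortality must be >= 0")
  if (object@kernelCount < 1) errs <- c(errs, "kernelCount must be >= 1")
  if (object@propaguleQuantity < 0) errs <- c(errs, "propaguleQuantity must be >= 0")
  if (object@startingMonth < 1 || object@startingMonth > 12) errs <- c(errs, "startingMonth must lie in 1..12")
  if (object@cycles < 1) errs <- c(errs, "cycles must be >= 1")
  if (object@breedingAge < 0) errs <- c(errs, "breedingAge must be >= 0")
  if (object@fertilizationRate < 0 || object@fertilizationRate > 1) errs <- c(errs, "fertilizationRate must lie in [0, 1]")
  if (object@hatchingRate < 0 || object@hatchingRate > 1) errs <- c(errs, "hatchingRate must lie in [0, 1]")
  if (length(object@breedingWindow) != 2 || any(object@breedingWindow < 1) || any(object@breedingWindow > 12))
    errs <- c(errs, "breedingWindow months must lie in 1..12")
  if (object@spawnsPerCycle < 0) errs <- c(errs, "spawnsPerCycle must be >= 0")
  if (!object@mortalityMode %in% c("hazard", "literal")) errs <- c(errs, "mortalityMode must be 'hazard' or 'literal'")
  if (!object@suitabilityMode %in% c("binary", "graded")) errs <- c(errs, "suitabilityMode must be 'binary' or 'graded'")
  if (object@speedFloor <= 0) errs <- c(errs, "speedFloor must be > 0")
  if (object@gridSize <= 0) errs <- c(errs, "gridSize must be > 0")
  if (length(errs)) paste(errs, collapse = "; ") else TRUE
})

#' Regular latitude/longitude lattice
#'
#' Cell centres are the public coordinates: row 1 is the northernmost row,
#' column 1 the westernmost column, and the centre of cell `(r, c)` lies at
#' `latMax - (r - 0.5) * resolution/60` / `lonMin + (c - 0.5) * resolution/60`
#' decimal degrees.
#'
#' @slot latMin,latMax,lonMin,lonMax extent in decimal degrees (negative
#'   longitudes are west).
#' @slot resolution cell size in arc-minutes.
#' @slot nRows,nCols lattice dimensions.
#' @seealso [gridSpec()], [cellCenters()]
#' @export
setClass("GridSpec", representation(
  latMin = "numeric", latMax = "numeric",
  lonMin = "numeric", lonMax = "numeric",
  resolution = "numeric",
  nRows = "integer", nCols = "integer"
))

setValidity("GridSpec", function(object) {
  errs <- character(0)
  if (object@latMin >= object@latMax) errs <- c(errs, "latMin must be < latMax")
  if (object@lonMin >= object@lonMax) errs <- c(errs, "lonMin must be < lonMax")
  if (object@resolution <= 0) errs <- c(errs, "resolution must be > 0")
  nr <- round((object@latMax - object@latMin) * 60 / object@resolution)
  nc <- round((object@lonMax - object@lonMin) * 60 / object@resolution)
  if (object@nRows != nr) errs <- c(errs, "nRows inconsistent with extent and resolution")
  if (object@nCols != nc) errs <- c(errs, "nCols inconsistent with extent and resolution")
  if (length(errs)) paste(errs, collapse = "; ") else TRUE
})

#' Gridded monthly environmental climatology
#'
#' Twelve monthly layers of current speed/direction, sea-surface
#' temperature and chlorophyll, plus static depth and a land mask, all on
#' one [GridSpec-class] lattice.  Monthly layers are a representative-year
#' climatology and are recycled across simulation years.
#'
#' @slot grid the shared [GridSpec-class].
#' @slot currentSpeed,currentDirection,sst,chlorophyll `nRows x nCols x 12`
#'   arrays (speed m/s; direction degrees-from-north the current flows
#'   toward; temperature degrees C; chlorophyll micrograms per litre).
#' @slot depth `nRows x nCols` matrix, metres positive down.
#' @slot landMask logical `nRows x nCols` matrix, TRUE on land.
#' @seealso [environmentStack()], [generateSyntheticEnvironment()],
#'   [readEnvironment()]
#' @export
setClass("EnvironmentStack", representation(
  grid = "GridSpec",
  currentSpeed = "array",
  currentDirection = "array",
  sst = "array",
  chlorophyll = "array",
  depth = "matrix",
  landMask = "matrix"
))

setValidity("EnvironmentStack", function(object) {
  g <- object@grid
  dims <- c(g@nRows, g@nCols, 12L)
  errs <- character(0)
  for (nm in c("currentSpeed", "currentDirection", "sst", "chlorophyll")) {
    if (!identical(dim(slot(object, nm)), dims))
      errs <- c(errs, sprintf("%s must be a %d x %d x 12 array", nm, g@nRows, g@nCols))
  }
  if (!identical(dim(object@depth), dims[1:2])) errs <- c(errs, "depth dimensions disagree with grid")
  if (!identical(dim(object@landMask), dims[1:2])) errs <- c(errs, "landMask dimensions disagree with grid")
  if (!is.logical(object@landMask)) errs <- c(errs, "landMask must be logical")
  sea <- !object@landMask
  if (any(object@currentSpeed[sea] < 0, na.rm = TRUE)) errs <- c(errs, "currentSpeed must be >= 0 on marine cells")
  dirSea <- object@currentDirection[sea]
  if (any(dirSea < 0 | dirSea >= 360, na.rm = TRUE)) errs <- c(errs, "currentDirection must lie in [0, 360)")
  if (length(errs)) paste(errs, collapse = "; ") else TRUE
})

#' Result of one simulation run
#'
#' @slot grid the lattice the run used.
#' @slot events data frame with columns `cycle`, `calendarMonth`, `row`,
#'   `col`, `lat`, `lon`, `event` where `event` is one of `"spawn"`,
#'   `"settle"`, `"death"`, `"promote"`.  For settle events
#'   `calendarMonth` is the month in which transit ended (the month whose
#'   layers were tested for habitability).
#' @slot settledCount integer matrix of settle events per cell.
#' @slot establishmentCycle numeric matrix; first cycle a breeding
#'   population appeared in the cell (promotion event), NA where none did.
#' @slot cycleSummary per-cycle bookkeeping: kernels spawned, settled,
#'   deaths, and the population alive/breeding at cycle end.
#' @slot months number of cycles run.
#' @slot seed seed used (NA if none supplied).
#' @slot config the [ModelConfig-class] used.
#' @export
setClass("SimulationResult", representation(
  grid = "GridSpec",
  events = "data.frame",
  settledCount = "matrix",
  establishmentCycle = "matrix",
  cycleSummary = "data.frame",
  months = "numeric",
  seed = "numeric",
  config = "ANY"
))

#' Multi-run experiment summary
#'
#' Returned by [compositeExperiment()].  The pooled settlement raster is
#' the cell-wise integer sum of the member rasters.
#'
#' @slot results list of [SimulationResult-class] members.
#' @slot pooledSettled pooled settlement-count matrix.
#' @slot origins data frame of the origins used (row, col, lat, lon).
#' @slot meanSettledCount mean total settled kernels per member run.
#' @slot topKMeanEstablishment mean establishment cycle over the `k` cells
#'   with the highest pooled settlement count (NA when no establishments).
#' @slot seed master seed.
#' @export
setClass("ExperimentSummary", representation(
  results = "list",
  pooledSettled = "matrix",
  origins = "data.frame",
  meanSettledCount = "numeric",
  topKMeanEstablishment = "numeric",
  seed = "numeric"
))

#' Spread-sequence validation report
#'
#' Produced by [validationReport()].  Holds the step-wise modal
#' (representative) establishment sequence, the member run that best
#' matches it (the representative model, RM), Spearman rank correlations
#' of every member against the RM and of the RM against each null-model
#' realisation, and the permutation critical value at the common sequence
#' length.
#'
#' @slot representativeSequence character vector of quadrant ids.
#' @slot rmIndex index of the representative model among the members.
#' @slot memberRho per-member rho against the RM sequence.
#' @slot meanRhoMembersVsRm mean of `memberRho`.
#' @slot rhoRmVsNull rho of the RM sequence against each null realisation.
#' @slot criticalValue two-tailed permutation critical value at `nSteps`.
#' @slot nSteps common sequence length used.
#' @slot alpha significance level.
#' @slot membersSignificant,nullSignificant significance flags
#'   (`|rho| >= criticalValue`).
#' @slot tieNotes human-readable record of the deterministic tie rules
#'   applied.
#' @export
setClass("ValidationReport", representation(
  representativeSequence = "character",
  rmIndex = "integer",
  memberRho = "numeric",
  meanRhoMembersVsRm = "numeric",
  rhoRmVsNull = "numeric",
  criticalValue = "numeric",
  nSteps = "integer",
  alpha = "numeric",
  membersSignificant = "logical",
  nullSignificant = "logical",
  tieNotes = "character"
))

setValidity("ValidationReport", function(object) {
  errs <- character(0)
  rho <- c(object@memberRho, object@rhoRmVsNull)
  if (any(rho < -1 - 1e-12 | rho > 1 + 1e-12, na.rm = TRUE)) errs <- c(errs, "rho values must lie in [-1, 1]")
  if (!is.na(object@criticalValue) && (object@criticalValue <= 0 || object@criticalValue > 1))
    errs <- c(errs, "criticalValue must lie in (0, 1]")
  if (length(errs)) paste(errs, collapse = "; ") else TRUE
})

#' Jenks natural-breaks classification of a settlement raster
#'
#' @slot breaks strictly increasing upper class bounds (length `k`).
#' @slot classRaster integer matrix; class index 1..k for classified cells,
#'   NA elsewhere (zero-count and land cells are unclassified).
#' @slot k number of classes.
#' @export
setClass("MapClassification", representation(
  breaks = "numeric",
  classRaster = "matrix",
  k = "integer"
))

setValidity("MapClassification", function(object) {
  errs <- character(0)
  if (length(object@breaks) != object@k) errs <- c(errs, "breaks must have length k")
  if (object@k > 1 && any(diff(object@breaks) <= 0)) errs <- c(errs, "breaks must be strictly increasing")
  cls <- object@classRaster[!is.na(object@classRaster)]
  if (length(cls) && (any(cls < 1) || any(cls > object@k))) errs <- c(errs, "class indices must lie in 1..k")
  if (length(errs)) paste(errs, collapse = "; ") else TRUE
})

#' In-progress simulation state
#'
#' Functional state passed through [stepMonth()].  `cycle` counts completed
#' cycles; the calendar month of the next cycle to execute is
#' `((startingMonth - 1 + cycle) %% 12) + 1`.
#'
#' @slot config,stack the run inputs.
#' @slot populations data frame of settled population kernels (row, col,
#'   cell, settleCycle, age, breeding, founder).
#' @slot cycle completed cycle count.
#' @slot eventsList,cycleList per-cycle accumulators.
#' @slot context precomputed lattice tables (internal).
#' @export
setClass("SimulationState", representation(
  config = "ModelConfig",
  stack = "EnvironmentStack",
  populations = "data.frame",
  cycle = "integer",
  eventsList = "list",
  cycleList = "list",
  context = "list"
))
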