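#' Default parameter values
#'
#' The baseline parameterisation describes a shallow-water tropical reef
#' fish dispersed by currents: a 40-day pelagic larval phase with an
#' instantaneous mortality of 0.2/day, maturity at 18 months, adult
#' mortality 0.26/year, 15,000 viable larvae per monthly spawn carried by
#' 20 kernels, habitable between 16 and 32.82 degrees C, 1 and 40 m depth,
#' and 0.10 and 99.981 ug/L chlorophyll, with current dominating the
#' neighbour score (raw weights 0.90 vs 0.02 for each static layer).
#' @keywords internal
.configDefaults <- function() {
  list(
    cycles = 78,
    gridSize = 6,
    sstRange = c(16, 32.820), sstWeight = 0.02,
    ccRange = c(0.10, 99.981), ccWeight = 0.02,
    depthRange = c(1, 40), depthWeight = 0.02,
    currentWeight = 0.90,
    propaguleDuration = 40,
    propaguleMortality = 0.2,
    breedingAge = 18,
    adultMortality = 0.26,
    eggQuantity = 200000,
    fertilizationRate = 0.25,
    hatchingRate = 0.30,
    propaguleQuantity = NA_real_,   # derived from the three fields above
    kernelCount = 20,
    breedingWindow = c(1, 12),
    spawnsPerCycle = 1,
    startingMonth = 1,
    rngSeed = NA_real_,
    mortalityMode = "hazard",
    speedFloor = 0.01,
    founderImmortal = FALSE,
    suitabilityMode = "binary"
  )
}

#' Create a simulation configuration
#'
#' Builds a validated [ModelConfig-class].  Any field not supplied takes
#' its default value (see [loadConfig()] for the file-based equivalent).
#' Scoring weights are standardised to sum to one; `propaguleQuantity`,
#' when not given explicitly, is derived as
#' `round(eggQuantity * fertilizationRate * hatchingRate)`.
#'
#' @param ... named parameter overrides; see [ModelConfig-class] for the
#'   field list.
#' @return a [ModelConfig-class].
#' @examples
#' cfg <- simConfig()
#' cfg@propaguleQuantity           # 15000
#' simConfig(propaguleMortality = 0.18)@propaguleMortality
#' @export
simConfig <- function(...) {
  defaults <- .configDefaults()
  over <- list(...)
  if (length(over) && (is.null(names(over)) || any(names(over) == "")))
    stop("all configuration overrides must be named")
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  vals <- defaults
  vals[names(over)] <- over
  if (is.na(vals$propaguleQuantity)) {
    if (vals$fertilizationRate < 0 || vals$fertilizationRate > 1)
      stop("fertilizationRate must lie in [0, 1]")
    if (vals$hatchingRate < 0 || vals$hatchingRate > 1)
      stop("hatchingRate must lie in [0, 1]")
    vals$propaguleQuantity <- viablePropagules(vals$eggQuantity,
                                               vals$fertilizationRate,
                                               vals$hatchingRate)
  }
  w <- c(vals$currentWeight, vals$sstWeight, vals$ccWeight, vals$depthWeight)
  if (any(w < 0)) stop("weights must be >= 0")
  if (all(w == 0)) stop("at least one weight must be > 0")
  w <- w / sum(w)
  vals$currentWeight <- w[1]; vals$sstWeight <- w[2]
  vals$ccWeight <- w[3]; vals$depthWeight <- w[4]
  numeric_fields <- setdiff(names(vals), c("mortalityMode", "suitabilityMode", "founderImmortal"))
  for (nm in numeric_fields) vals[[nm]] <- as.numeric(vals[[nm]])
  obj <- new("ModelConfig",
    cycles = vals$cycles, gridSize = vals$gridSize,
    sstRange = vals$sstRange, sstWeight = vals$sstWeight,
    ccRange = vals$ccRange, ccWeight = vals$ccWeight,
    depthRange = vals$depthRange, depthWeight = vals$depthWeight,
    currentWeight = vals$currentWeight,
    propaguleDuration = vals$propaguleDuration,
    propaguleMortality = vals$propaguleMortality,
    breedingAge = vals$breedingAge,
    adultMortality = vals$adultMortality,
    eggQuantity = vals$eggQuantity,
    fertilizationRate = vals$fertilizationRate,
    hatchingRate = vals$hatchingRate,
    propaguleQuantity = vals$propaguleQuantity,
    kernelCount = vals$kernelCount,
    breedingWindow = vals$breedingWindow,
    spawnsPerCycle = vals$spawnsPerCycle,
    startingMonth = vals$startingMonth,
    rngSeed = vals$rngSeed,
    mortalityMode = vals$mortalityMode,
    speedFloor = vals$speedFloor,
    founderImmortal = as.logical(vals$founderImmortal),
    suitabilityMode = vals$suitabilityMode
  )
  validObject(obj)
  obj
}

#' Read a configuration file
#'
#' The file is flat key-value YAML; keys are the [ModelConfig-class] field
#' names, two-element fields (`sstRange`, `ccRange`, `depthRange`,
#' `breedingWindow`) are two-element YAML sequences.  Missing keys take
#' the package defaults; unknown keys and invariant violations raise an
#' error naming the offending field.
#'
#' @param path path to a YAML configuration file.
#' @return a validated [ModelConfig-class].
#' @seealso [writeConfig()] for the round-trippable writer.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  vals <- tryCatch(yaml::read_yaml(path),
                   error = function(e) stop("failed to parse configuration file '",
                                            path, "': ", conditionMessage(e)))
  if (is.null(vals)) vals <- list()
  if (!is.list(vals)) stop("configuration file must contain a key-value mapping")
  do.call(simConfig, vals)
}

#' Write a configuration file
#'
#' Writes all fields of `config` as flat YAML so that
#' `loadConfig(writeConfig(config, path))` round-trips to an equal object
#' (weight standardisation is idempotent).
#'
#' @param config a [ModelConfig-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeConfig <- function(config, path) {
  stopifnot(is(config, "ModelConfig"))
  nms <- slotNames(config)
  vals <- lapply(nms, function(nm) {
    v <- slot(config, nm)
    if (is.numeric(v)) v <- unname(v)
    v
  })
  names(vals) <- nms
  yaml::write_yaml(vals, path, precision = 15)
  invisible(path)
}

#' Viable propagules per spawning event
#'
#' The number of viable larvae released per spawn is the egg count times
#' the fertilisation and hatching rates, rounded to the nearest integer
#' (default inputs: 200,000 eggs x 25% x 30% = 15,000).
#'
#' @param eggQuantity eggs per spawning event (>= 0).
#' @param fertilizationRate,hatchingRate fractions in `[0, 1]`.
#' @return integer count of viable propagules.
#' @examples
#' viablePropagules(200000, 0.25, 0.30)  # 15000
#' @export
viablePropagules <- function(eggQuantity, fertilizationRate, hatchingRate) {
  if (any(eggQuantity < 0)) stop("eggQuantity must be >= 0")
  if (any(fertilizationRate < 0 | fertilizationRate > 1))
    stop("fertilizationRate must lie in [0, 1]")
  if (any(hatchingRate < 0 | hatchingRate > 1))
    stop("hatchingRate must lie in [0, 1]")
  round(eggQuantity * fertilizationRate * hatchingRate)
}

#' Larvae represented by each kernel
#'
#' Kernels are representative packets standing in for a fixed share of the
#' viable larvae of one spawning event.  With the defaults (15,000 larvae,
#' 20 kernels) each kernel represents about 750 larvae and the
#' kernel-to-larva ratio is 0.0013.
#'
#' @param Q viable propagules per spawn.
#' @param K kernels per spawn (>= 1).
#' @return a list with `larvaePerKernel` (integer) and `kernelRatio`
#'   (`K/Q`, rounded to 4 decimals).
#' @examples
#' larvaePerKernel(15000, 20)
#' @export
larvaePerKernel <- function(Q, K) {
  if (any(K < 1)) stop("K must be >= 1")
  if (any(Q < 0)) stop("Q must be >= 0")
  list(larvaePerKernel = round(Q / K), kernelRatio = round(K / Q, 4))
}

#' Per-cycle survival and death probabilities
#'
#' Converts the instantaneous mortality rates into the event probabilities
#' the engine draws against each cycle.  Larval transport survival over
#' the whole pelagic phase is `exp(-Z_p * D)`.  The adult rate is an
#' annual instantaneous rate; in the default `"hazard"` mode it is
#' converted to a monthly death probability `1 - exp(-Z/12)` (about 0.0214
#' for Z = 0.26/yr), while `"literal"` mode applies Z itself as the
#' per-cycle probability.
#'
#' @param config a [ModelConfig-class].
#' @return list with `larvalTransportSurvival` and `adultMonthlyDeath`.
#' @examples
#' perCycleHazards(simConfig())   # survival exp(-8), death 1 - exp(-0.26/12)
#' @export
perCycleHazards <- function(config) {
  stopifnot(is(config, "ModelConfig"))
  surv <- exp(-config@propaguleMortality * config@propaguleDuration)
  death <- switch(config@mortalityMode,
    hazard = 1 - exp(-config@adultMortality / 12),
    literal = min(config@adultMortality, 1)
  )
  list(larvalTransportSurvival = surv, adultMonthlyDeath = death)
}

#' Stable digest of a configuration
#'
#' MD5 of the canonical YAML serialisation; written into run metadata
#' sidecars for provenance.
#' @param config a [ModelConfig-class].
#' @return character MD5 hash.
#' @export
configDigest <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  writeConfig(config, tf)
  unname(tools::md5sum(tf))
}

setMethod("show", "ModelConfig", function(object) {
  hz <- perCycleHazards(object)
  cat("ModelConfig (invasion simulator parameters)\n")
  cat(sprintf("  cycles: %g   grid: %g arc-min   starting month: %g\n",
              object@cycles, object@gridSize, object@startingMonth))
  cat(sprintf("  tolerances  SST %g..%g C | CC %g..%g ug/L | depth %g..%g m\n",
              object@sstRange[1], object@sstRange[2],
              object@ccRange[1], object@ccRange[2],
              object@depthRange[1], object@depthRange[2]))
  cat(sprintf("  weights (normalised)  current %.4f | SST %.4f | CC %.4f | depth %.4f\n",
              object@currentWeight, object@sstWeight, object@ccWeight, object@depthWeight))
  cat(sprintf("  larvae: D = %g d, Z_p = %g /d (transport survival %.4g)\n",
              object@propaguleDuration, object@propaguleMortality,
              hz$larvalTransportSurvival))
  cat(sprintf("  adults: Z = %g /yr (%s mode, monthly death %.4g), maturity %g mo\n",
              object@adultMortality, object@mortalityMode, hz$adultMonthlyDeath,
              object@breedingAge))
  cat(sprintf("  fecundity: %g viable larvae / spawn in %g kernels (%g larvae/kernel)\n",
              object@propaguleQuantity, object@kernelCount,
              round(object@propaguleQuantity / object@kernelCount)))
  cat(sprintf("  breeding window: months %g..%g, %g spawn(s)/cycle\n",
              object@breedingWindow[1], object@breedingWindow[2],
              object@spawnsPerCycle))
  invisible(object)
})
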