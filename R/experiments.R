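#' Read occurrence records
#'
#' CSV with header columns `latitude`, `longitude`, `date`, `source_id`
#' (extra columns are kept).
#'
#' @param path CSV path.
#' @return data frame of records.
#' @export
readOccurrences <- function(path) {
  rec <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("latitude", "longitude")
  if (!all(need %in% names(rec)))
    stop("occurrence file must have columns: ", paste(need, collapse = ", "))
  if (!is.null(rec$date)) rec$date <- as.Date(rec$date)
  rec
}

#' Candidate origin cells near occurrence records
#'
#' All marine cells whose centre lies within `radiusDeg` of any record
#' and whose depth does not exceed `depthMax`, deduplicated.  Distance is
#' measured in plain degrees: the default `"disc"` metric is the
#' Euclidean degree distance, `"box"` an axis-aligned degree box.
#'
#' @param records data frame with `latitude`, `longitude` (e.g. from
#'   [readOccurrences()]).
#' @param stack an [EnvironmentStack-class].
#' @param radiusDeg search radius in degrees (default 1).
#' @param depthMax maximum habitable depth in metres (default 40).
#' @param metric `"disc"` or `"box"`.
#' @return data frame of candidate cells (`row`, `col`, `lat`, `lon`,
#'   `depth`); zero rows when no records or no matching cells.
#' @export
candidateOrigins <- function(records, stack, radiusDeg = 1, depthMax = 40,
                             metric = c("disc", "box")) {
  metric <- match.arg(metric)
  if (radiusDeg <= 0) stop("radiusDeg must be > 0")
  g <- stack@grid
  empty <- data.frame(row = integer(0), col = integer(0), lat = numeric(0),
                      lon = numeric(0), depth = numeric(0))
  if (is.null(records) || nrow(records) == 0) return(empty)
  rows <- rep(seq_len(g@nRows), g@nCols)
  cols <- rep(seq_len(g@nCols), each = g@nRows)
  cc <- cellCenters(g, rows, cols)
  near <- rep(FALSE, length(rows))
  for (i in seq_len(nrow(records))) {
    dlat <- abs(cc$lat - records$latitude[i])
    dlon <- abs(cc$lon - records$longitude[i])
    near <- near | if (metric == "disc") (dlat^2 + dlon^2) <= radiusDeg^2
                   else (dlat <= radiusDeg & dlon <= radiusDeg)
  }
  depth <- as.vector(stack@depth)
  keep <- near & !as.vector(stack@landMask) & !is.na(depth) & depth <= depthMax
  out <- data.frame(row = rows[keep], col = cols[keep],
                    lat = cc$lat[keep], lon = cc$lon[keep], depth = depth[keep])
  rownames(out) <- NULL
  out
}

#' Composite multi-origin hot-spot experiment
#'
#' Samples `nOrigins` candidate cells (without replacement) from the
#' candidate set around the occurrence records, runs one simulation from
#' each, and pools the settlement rasters cell-wise, removing
#' introduction-point bias from the resulting hot-spot map.
#'
#' @param records occurrence records.
#' @param stack an [EnvironmentStack-class].
#' @param config a [ModelConfig-class].
#' @param nOrigins origins to sample.
#' @param months cycles per run.
#' @param seed master seed; per-run seeds are drawn from it.
#' @param radiusDeg,depthMax,metric forwarded to [candidateOrigins()].
#' @param topK number of top cells (by pooled count) entering the mean
#'   establishment-cycle summary.
#' @return an [ExperimentSummary-class].
#' @export
compositeExperiment <- function(records, stack, config, nOrigins, months,
                                seed = 1, radiusDeg = 1, depthMax = 40,
                                metric = "disc", topK = 20) {
  cand <- candidateOrigins(records, stack, radiusDeg, depthMax, metric)
  if (nrow(cand) < nOrigins)
    stop(sprintf("candidate set (%d cells) smaller than nOrigins (%d)",
                 nrow(cand), nOrigins))
  set.seed(as.integer(seed))
  pick <- sample.int(nrow(cand), nOrigins)
  runSeeds <- sample.int(.Machine$integer.max - 1, nOrigins)
  origins <- cand[pick, , drop = FALSE]
  results <- vector("list", nOrigins)
  g <- stack@grid
  pooled <- matrix(0L, g@nRows, g@nCols)
  for (i in seq_len(nOrigins)) {
    results[[i]] <- runSimulation(config, stack,
                                  origin = c(origins$lat[i], origins$lon[i]),
                                  months = months, seed = runSeeds[i])
    pooled <- pooled + results[[i]]@settledCount
  }
  meanSettled <- mean(vapply(results, function(r) sum(r@settledCount), numeric(1)))
  topMean <- NA_real_
  if (any(pooled > 0)) {
    ord <- order(pooled, decreasing = TRUE)
    top <- ord[seq_len(min(topK, sum(pooled > 0)))]
    cellMeans <- vapply(top, function(cellIdx) {
      est <- vapply(results, function(r) r@establishmentCycle[cellIdx], numeric(1))
      if (all(is.na(est))) NA_real_ else mean(est, na.rm = TRUE)
    }, numeric(1))
    if (!all(is.na(cellMeans))) topMean <- mean(cellMeans, na.rm = TRUE)
  }
  new("ExperimentSummary", results = results, pooledSettled = pooled,
      origins = origins, meanSettledCount = meanSettled,
      topKMeanEstablishment = topMean, seed = as.numeric(seed))
}

setMethod("show", "ExperimentSummary", function(object) {
  cat(sprintf("ExperimentSummary: %d runs, %d kernels settled in total\n",
              length(object@results), sum(object@pooledSettled)))
  cat(sprintf("  mean settled per run %.1f; hottest cell count %d\n",
              object@meanSettledCount, max(object@pooledSettled)))
  if (!is.na(object@topKMeanEstablishment))
    cat(sprintf("  mean establishment cycle of top cells: %.1f\n",
                object@topKMeanEstablishment))
  invisible(object)
})

#' Case-study origin presets
#'
#' Two detailed scenario presets shipped with the package: `"CS_FK"`, a
#' Florida Keys origin (24.583 N, -81.217 W), and `"CS_BC"`, a Broward
#' County origin (26.217 N, -80.083 W); both run 78 months with 20
#' replicates.
#'
#' @param name `"CS_FK"` or `"CS_BC"`.
#' @return list with `origin` (lat, lon), `months` and `replicates`.
#' @export
caseStudyOrigin <- function(name = c("CS_FK", "CS_BC")) {
  name <- match.arg(name)
  switch(name,
    CS_FK = list(origin = c(24.583, -81.217), months = 78, replicates = 20),
    CS_BC = list(origin = c(26.217, -80.083), months = 78, replicates = 20))
}

#' Larval-mortality sensitivity experiment
#'
#' Reruns the scenario with the larval mortality rate Z_p varied by the
#' relative `deltas` (default +/-10%), all other parameters equal, using
#' common random numbers (the same replicate seeds for every scenario).
#' For each scenario the mean settled kernel count and the representative
#' model (RM) are computed, and the RM sequence is compared to the
#' baseline (delta = 0) RM by Spearman's rho.  Scenarios with too few
#' establishments to form comparable sequences are reported as not
#' calculable.
#'
#' @param baseConfig a [ModelConfig-class] (its `propaguleMortality` is
#'   the baseline Z_p).
#' @param stack an [EnvironmentStack-class].
#' @param origin `c(lat, lon)`.
#' @param months cycles per run.
#' @param deltas relative changes to Z_p; 0 (the baseline) is added if
#'   absent.
#' @param nReps replicates per scenario.
#' @param seed master seed.
#' @param quadrantDeg quadrant size for sequences.
#' @return list with `scenarios` (data frame: delta, Zp, meanSettled,
#'   rhoVsBaseline, calculable), `results` (list of per-scenario result
#'   lists) and `rmSequences`.
#' @export
sensitivityExperiment <- function(baseConfig, stack, origin, months,
                                  deltas = c(-0.1, 0.1), nReps = 20,
                                  seed = 1, quadrantDeg = 0.5) {
  if (!length(deltas)) stop("deltas must be non-empty")
  deltas <- sort(unique(c(0, deltas)))
  set.seed(as.integer(seed))
  repSeeds <- sample.int(.Machine$integer.max - 1, nReps)
  scen <- vector("list", length(deltas))
  names(scen) <- sprintf("%+.0f%%", 100 * deltas)
  rmSeqs <- vector("list", length(deltas))
  meanSettled <- numeric(length(deltas))
  for (d in seq_along(deltas)) {
    cfg <- baseConfig
    cfg@propaguleMortality <- baseConfig@propaguleMortality * (1 + deltas[d])
    validObject(cfg)
    runs <- lapply(seq_len(nReps), function(i)
      runSimulation(cfg, stack, origin, months, seed = repSeeds[i]))
    scen[[d]] <- runs
    meanSettled[d] <- mean(vapply(runs, function(r) sum(r@settledCount), numeric(1)))
    seqs <- lapply(runs, function(r) quadrantSequence(r, quadrantDeg)$quadrant)
    ns <- commonStepCount(seqs)
    rmSeqs[d] <- list(if (ns >= 3) {
      rs <- representativeSequence(seqs, ns)
      seqs[[selectRepresentativeModel(seqs, rs)]]
    } else NULL)
  }
  base <- which(deltas == 0)
  rho <- rep(NA_real_, length(deltas))
  calculable <- rep(FALSE, length(deltas))
  for (d in seq_along(deltas)) {
    if (is.null(rmSeqs[[d]]) || is.null(rmSeqs[[base]])) next
    r <- tryCatch(spearmanRho(rmSeqs[[d]], rmSeqs[[base]]), error = function(e) NULL)
    if (!is.null(r)) { rho[d] <- as.numeric(r); calculable[d] <- TRUE }
  }
  list(
    scenarios = data.frame(
      delta = deltas,
      Zp = baseConfig@propaguleMortality * (1 + deltas),
      meanSettled = meanSettled,
      rhoVsBaseline = rho,
      calculable = calculable),
    results = scen,
    rmSequences = rmSeqs)
}
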