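#' Jenks natural breaks (Fisher optimal 1-D partition)
#'
#' Partitions the sorted values into `k` contiguous classes minimising the
#' total within-class sum of squared deviations — the classification used
#' for hot/cold settlement maps.  Solved exactly by dynamic programming
#' over the distinct values (weighted by multiplicity).
#'
#' @param values numeric vector (at least `k` distinct values).
#' @param k number of classes (>= 1).
#' @return strictly increasing upper class bounds, length `k` (the last is
#'   `max(values)`).
#' @examples
#' jenksBreaks(c(1, 2, 3, 10, 11, 12), 2)   # classes {1,2,3} and {10,11,12}
#' @export
jenksBreaks <- function(values, k) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no values to classify")
  ux <- sort(unique(values))
  m <- length(ux)
  if (k < 1) stop("k must be >= 1")
  if (k > m) stop(sprintf("k (%d) exceeds the number of distinct values (%d)", k, m))
  w <- as.numeric(table(factor(values, levels = ux)))
  cw <- cumsum(w); cwx <- cumsum(w * ux); cwx2 <- cumsum(w * ux^2)
  ssq <- function(i, j) {      # weighted SSQ of ux[i..j]
    W <- cw[j] - if (i > 1) cw[i - 1] else 0
    Sx <- cwx[j] - if (i > 1) cwx[i - 1] else 0
    Sx2 <- cwx2[j] - if (i > 1) cwx2[i - 1] else 0
    Sx2 - Sx^2 / W
  }
  D <- matrix(Inf, m, k)
  B <- matrix(0L, m, k)
  for (j in seq_len(m)) D[j, 1] <- ssq(1, j)
  if (k > 1) for (cl in 2:k) {
    for (j in cl:m) {
      for (i in cl:j) {
        cost <- D[i - 1, cl - 1] + ssq(i, j)
        if (cost < D[j, cl]) { D[j, cl] <- cost; B[j, cl] <- i }
      }
    }
  }
  # recover class upper bounds
  bounds <- numeric(k)
  j <- m
  for (cl in k:1) {
    bounds[cl] <- ux[j]
    if (cl > 1) j <- B[j, cl] - 1L
  }
  bounds
}

#' Classify a settlement raster with Jenks breaks
#'
#' Nonzero cells are classified into `k` natural-breaks classes (1 = cold
#' to k = hot); zero-count and land cells stay NA.
#'
#' @param x a [SimulationResult-class], [ExperimentSummary-class] or a
#'   numeric matrix of settlement counts.
#' @param k class count.
#' @return a [MapClassification-class].
#' @export
classifySettlement <- function(x, k) {
  counts <- if (is(x, "SimulationResult")) x@settledCount
            else if (is(x, "ExperimentSummary")) x@pooledSettled
            else x
  vals <- counts[counts > 0]
  if (!length(vals)) stop("no settled cells to classify")
  brks <- jenksBreaks(vals, k)
  cls <- matrix(NA_integer_, nrow(counts), ncol(counts))
  nz <- which(counts > 0)
  cls[nz] <- as.integer(findInterval(counts[nz], c(-Inf, brks[-k]), left.open = TRUE))
  cls[nz] <- pmin(cls[nz], k)
  new("MapClassification", breaks = brks, classRaster = cls, k = as.integer(k))
}

setMethod("show", "MapClassification", function(object) {
  cat(sprintf("MapClassification: %d classes, breaks %s\n", object@k,
              paste(signif(object@breaks, 4), collapse = ", ")))
  tab <- table(object@classRaster)
  if (length(tab))
    cat("  cells per class:", paste(sprintf("%s:%d", names(tab), tab), collapse = " "), "\n")
  invisible(object)
})

#' Temporal-spatial progression table
#'
#' The first `nSteps` quadrant establishments of a run with their cycles
#' and quadrant centroids — the table behind sequence(month) progression
#' maps.
#'
#' @param result a [SimulationResult-class].
#' @param quadrantDeg quadrant size in degrees.
#' @param nSteps number of steps to keep (default: all).
#' @return data frame with `step`, `cycle`, `quadrant`, `lat`, `lon`.
#' @export
progressionMap <- function(result, quadrantDeg = 0.5, nSteps = NULL) {
  qs <- quadrantSequence(result, quadrantDeg)
  if (!nrow(qs)) stop("no establishments recorded; the progression map is empty")
  if (!is.null(nSteps)) qs <- head(qs, nSteps)
  ctr <- quadrantCentroid(qs$quadrant, quadrantDeg)
  data.frame(step = seq_len(nrow(qs)), cycle = qs$cycle, quadrant = qs$quadrant,
             lat = ctr$lat, lon = ctr$lon)
}
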