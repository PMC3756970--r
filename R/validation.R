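#' Spearman's rank correlation between two establishment sequences
#'
#' For two ordered quadrant sequences the ranks are the positions of the
#' quadrants common to both (each sequence re-ranked over the
#' intersection), and
#' `rho = 1 - 6 * sum(d^2) / (n * (n^2 - 1))` with `d` the rank
#' differences.  Numeric inputs are interpreted directly as rank vectors.
#'
#' @param seqA,seqB character vectors of quadrant ids (ordered by
#'   establishment) or numeric rank vectors of equal length.
#' @return rho in `[-1, 1]`; the number of common quadrants used is
#'   attached as attribute `"n"`.
#' @examples
#' spearmanRho(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))   # 0.8
#' @export
spearmanRho <- function(seqA, seqB) {
  if (is.numeric(seqA) && is.numeric(seqB)) {
    if (length(seqA) != length(seqB)) stop("rank vectors must have equal length")
    ra <- seqA; rb <- seqB
  } else {
    seqA <- as.character(seqA); seqB <- as.character(seqB)
    common <- intersect(seqA, seqB)
    if (length(common) < 3)
      stop("fewer than 3 common quadrants; rho is not calculable")
    ra <- rank(match(common, seqA))
    rb <- rank(match(common, seqB))
  }
  n <- length(ra)
  if (n < 3) stop("fewer than 3 ranks; rho is not calculable")
  rho <- 1 - 6 * sum((ra - rb)^2) / (n * (n^2 - 1))
  attr(rho, "n") <- n
  rho
}

#' Permutation critical value of Spearman's rho
#'
#' Smallest rho in the support of the random-permutation null such that
#' the tail probability (`P(|rho| >= c)` two-tailed, `P(rho >= c)`
#' one-tailed) does not exceed `alpha`.  The null is enumerated exactly
#' over all `n!` permutations for `n <= 10` and estimated by Monte Carlo
#' (default 10^7 draws from the current RNG stream) for larger `n`.  The
#' returned value is rounded to two decimals (the unrounded value is kept
#' in attribute `"exact"`).
#'
#' @param n sequence length (>= 4).
#' @param alpha significance level in (0, 1).
#' @param twoTailed two-tailed test (default TRUE).
#' @param mcDraws Monte-Carlo draws used when `n > 10`.
#' @return critical value in (0, 1], or NA if no support value attains the
#'   tail bound (very small n and alpha).
#' @examples
#' criticalValue(10, 0.05)   # 0.65
#' @export
criticalValue <- function(n, alpha, twoTailed = TRUE, mcDraws = 1e7) {
  if (n < 4) stop("n must be >= 4")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  counts <- if (n <= 10) cpp_spearman_exact_counts(as.integer(n))
            else cpp_spearman_mc_counts(as.integer(n), mcDraws)
  M <- n * (n^2 - 1) / 3
  S <- seq(0, M, by = 2)
  rho <- 1 - 6 * S / (n * (n^2 - 1))
  total <- sum(counts)
  cand <- sort(unique(rho[rho > 0]))
  for (c0 in cand) {
    tail <- if (twoTailed) sum(counts[abs(rho) >= c0 - 1e-12]) else
      sum(counts[rho >= c0 - 1e-12])
    if (tail / total <= alpha) {
      out <- round(c0, 2)
      attr(out, "exact") <- c0
      attr(out, "method") <- if (n <= 10) "exact" else "monte-carlo"
      return(out)
    }
  }
  NA_real_
}

.quadrantId <- function(lat, lon, quadrantDeg) {
  qlat <- floor(lat / quadrantDeg) * quadrantDeg
  qlon <- floor(lon / quadrantDeg) * quadrantDeg
  sprintf("q[%07.2f,%08.2f]", qlat, qlon)
}

#' Quadrant id centroids
#' @param ids ids produced by [quadrantSequence()].
#' @param quadrantDeg quadrant size in degrees.
#' @return data frame with `lat`, `lon` of quadrant centres.
#' @export
quadrantCentroid <- function(ids, quadrantDeg = 0.5) {
  m <- regmatches(ids, regexec("^q\\[([-0-9.]+),([-0-9.]+)\\]$", ids))
  lat <- vapply(m, function(x) as.numeric(x[2]), numeric(1))
  lon <- vapply(m, function(x) as.numeric(x[3]), numeric(1))
  data.frame(lat = lat + quadrantDeg / 2, lon = lon + quadrantDeg / 2)
}

#' Establishment sequence over coarse quadrants
#'
#' Aggregates the first-establishment raster of a run onto quadrants
#' (default 0.5 x 0.5 degrees) and orders them by the earliest
#' establishment cycle of any member cell.  Each quadrant appears once;
#' cycle ties are broken by quadrant id (lexicographic), which is
#' deterministic because ids are fixed-width.
#'
#' @param result a [SimulationResult-class] (or any object with an
#'   `establishmentCycle` matrix and `grid`).
#' @param quadrantDeg quadrant edge length in degrees.
#' @return data frame with `quadrant`, `cycle` ordered by establishment;
#'   zero rows when nothing established.
#' @export
quadrantSequence <- function(result, quadrantDeg = 0.5) {
  est <- result@establishmentCycle
  g <- result@grid
  idx <- which(!is.na(est), arr.ind = TRUE)
  if (!nrow(idx)) return(data.frame(quadrant = character(0), cycle = numeric(0)))
  cc <- cellCenters(g, idx[, 1], idx[, 2])
  q <- .quadrantId(cc$lat, cc$lon, quadrantDeg)
  cyc <- est[idx]
  agg <- aggregate(list(cycle = cyc), by = list(quadrant = q), FUN = min)
  agg <- agg[order(agg$cycle, agg$quadrant), ]
  rownames(agg) <- NULL
  agg[, c("quadrant", "cycle")]
}

.asSequences <- function(x) {
  lapply(x, function(s) {
    if (is(s, "SimulationResult")) quadrantSequence(s)$quadrant
    else if (is.data.frame(s)) as.character(s$quadrant)
    else as.character(s)
  })
}

#' Step-wise modal (representative) establishment sequence
#'
#' For each invasion step `s` (position in the sequence) the quadrant
#' occupying that position most often across the member sequences is
#' selected; ties go to the lexicographically smallest quadrant id.
#'
#' @param sequences list of quadrant-id character vectors (or
#'   [SimulationResult-class] objects / [quadrantSequence()] frames).
#' @param nSteps number of steps; defaults to the number of quadrants
#'   common to every sequence, capped at the shortest sequence length.
#' @return character vector of `nSteps` quadrant ids.
#' @export
representativeSequence <- function(sequences, nSteps = NULL) {
  seqs <- .asSequences(sequences)
  if (!length(seqs)) stop("no sequences supplied")
  if (is.null(nSteps)) nSteps <- commonStepCount(seqs)
  if (is.na(nSteps) || nSteps < 1) stop("nSteps must be >= 1")
  if (any(vapply(seqs, length, integer(1)) < nSteps))
    stop("every sequence must have at least nSteps steps")
  vapply(seq_len(nSteps), function(s) {
    tab <- sort(table(vapply(seqs, `[`, character(1), s)))
    best <- names(tab)[tab == max(tab)]
    sort(best)[1]
  }, character(1))
}

#' Number of quadrants common to all sequences
#'
#' The invasion-step count used for representative sequences: the size of
#' the intersection of the occupied quadrant sets, capped at the shortest
#' sequence length.
#' @param sequences as in [representativeSequence()].
#' @return integer.
#' @export
commonStepCount <- function(sequences) {
  seqs <- .asSequences(sequences)
  common <- Reduce(intersect, seqs)
  min(length(common), min(vapply(seqs, length, integer(1))))
}

#' Select the representative model
#'
#' The member whose sequence matches the representative sequence at the
#' most step positions; ties go to the lowest index.
#'
#' @param sequences list of member sequences.
#' @param repSequence the representative sequence.
#' @return index of the representative model, with the match score in
#'   attribute `"score"`.
#' @export
selectRepresentativeModel <- function(sequences, repSequence) {
  seqs <- .asSequences(sequences)
  if (!length(seqs) || !length(repSequence)) stop("empty input")
  scores <- vapply(seqs, function(s) {
    m <- min(length(s), length(repSequence))
    if (m == 0) 0L else sum(s[seq_len(m)] == repSequence[seq_len(m)])
  }, integer(1))
  idx <- which.max(scores)            # first maximum = lowest index
  attr(idx, "score") <- scores[idx]
  idx
}

#' Pure stochastic-contagion null model
#'
#' Spread with every environmental and life-history influence removed:
#' each cycle, every occupied marine cell establishes one uniformly
#' random unoccupied marine neighbour (8-neighbourhood).  The process
#' runs until every reachable marine cell is occupied; if a disconnected
#' marine region can never be reached a warning is issued and the run
#' stops at closure of the origin's component.
#'
#' @param stack an [EnvironmentStack-class] (only the grid and land mask
#'   are used).
#' @param origin `c(lat, lon)` of the seed cell (marine).
#' @param seed integer seed.
#' @param maxCycles safety bound.
#' @return a [SimulationResult-class] whose `establishmentCycle` raster
#'   holds the occupancy cycle of every cell (origin = 0); the per-cycle
#'   summary tracks the occupied count.
#' @export
runNullModel <- function(stack, origin, seed = NULL, maxCycles = 100000) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  g <- stack@grid
  nr <- g@nRows; nc <- g@nCols; ncells <- nr * nc
  marine <- !as.vector(stack@landMask)
  cell <- cellAt(g, origin[1], origin[2])
  if (stack@landMask[cell$row, cell$col]) stop("origin is land")
  # neighbour table (1-based; NA outside / land)
  dr <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  dc <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  rows <- rep(seq_len(nr), nc); cols <- rep(seq_len(nc), each = nr)
  nb <- matrix(NA_integer_, ncells, 8)
  for (k in seq_len(8)) {
    r2 <- rows + dr[k]; c2 <- cols + dc[k]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    idx <- (c2[ok] - 1L) * nr + r2[ok]
    val <- ifelse(marine[idx], idx, NA_integer_)
    nb[ok, k] <- val
  }
  occCycle <- rep(NA_real_, ncells)
  startIdx <- .cellIndex(nr, cell$row, cell$col)
  occCycle[startIdx] <- 0
  occupied <- startIdx
  cyc <- 0L
  summaryRows <- list()
  while (cyc < maxCycles) {
    if (all(!is.na(occCycle[marine]))) break
    cyc <- cyc + 1L
    cand <- nb[occupied, , drop = FALSE]
    open <- !is.na(cand) & is.na(occCycle[ifelse(is.na(cand), 1L, cand)])
    nOpen <- rowSums(open)
    act <- which(nOpen > 0)
    if (!length(act)) {
      warning("marine region disconnected from origin; stopping at component closure")
      break
    }
    pick <- ceiling(runif(length(act)) * nOpen[act])
    chosen <- vapply(seq_along(act), function(j) {
      r <- act[j]
      cand[r, which(open[r, ])[pick[j]]]
    }, integer(1))
    newly <- unique(chosen)
    occCycle[newly] <- cyc
    occupied <- c(occupied, newly)
    summaryRows[[cyc]] <- data.frame(cycle = cyc, nOccupied = length(occupied))
  }
  est <- matrix(occCycle, nr, nc)
  cs <- if (length(summaryRows)) do.call(rbind, summaryRows) else
    data.frame(cycle = integer(0), nOccupied = integer(0))
  new("SimulationResult", grid = g, events = .emptyEvents(),
      settledCount = matrix(0L, nr, nc), establishmentCycle = est,
      cycleSummary = cs, months = as.numeric(cyc),
      seed = if (is.null(seed)) NA_real_ else as.numeric(seed),
      config = NULL)
}

#' Validate replicate spread sequences against a random null
#'
#' Builds the quadrant sequences of the member runs, their representative
#' sequence and representative model (RM), then computes Spearman's rho
#' of every member against the RM and of the RM against each null-model
#' realisation, together with the permutation critical value at the
#' common step count.  A model whose members correlate with their RM
#' while the RM does not correlate with the null beyond the critical
#' value is reproducible but not purely random.
#'
#' @param memberResults list of >= 2 [SimulationResult-class] (or
#'   sequences).
#' @param nullResults list of null-model results (or sequences).
#' @param alpha significance level.
#' @param quadrantDeg quadrant size in degrees.
#' @param mcDraws Monte-Carlo draws for the critical value when the step
#'   count exceeds 10.
#' @return a [ValidationReport-class].
#' @export
validationReport <- function(memberResults, nullResults, alpha = 0.05,
                             quadrantDeg = 0.5, mcDraws = 1e7) {
  members <- .asSequences(memberResults)
  if (length(members) < 2) stop("at least 2 member results are required")
  nulls <- .asSequences(nullResults)
  nSteps <- commonStepCount(members)
  if (nSteps < 4)
    stop("insufficient common steps across members (need >= 4, got ", nSteps, ")")
  repSeq <- representativeSequence(members, nSteps)
  rmIdx <- selectRepresentativeModel(members, repSeq)
  rmSeq <- members[[rmIdx]]
  memberRho <- vapply(members, function(s) as.numeric(spearmanRho(s, rmSeq)), numeric(1))
  rhoNull <- vapply(nulls, function(s) as.numeric(spearmanRho(rmSeq, s)), numeric(1))
  crit <- criticalValue(nSteps, alpha, twoTailed = TRUE, mcDraws = mcDraws)
  new("ValidationReport",
      representativeSequence = repSeq,
      rmIndex = as.integer(rmIdx),
      memberRho = memberRho,
      meanRhoMembersVsRm = mean(memberRho),
      rhoRmVsNull = rhoNull,
      criticalValue = as.numeric(crit),
      nSteps = as.integer(nSteps),
      alpha = alpha,
      membersSignificant = abs(memberRho) >= as.numeric(crit),
      nullSignificant = abs(rhoNull) >= as.numeric(crit),
      tieNotes = c(
        "modal quadrant ties: lexicographically smallest quadrant id",
        "representative-model score ties: lowest member index",
        "establishment-cycle ties within a quadrant: earliest cell by id",
        sprintf("n used for rho and the critical value: %d (quadrants common to all members)", nSteps)))
}

setMethod("show", "ValidationReport", function(object) {
  cat("ValidationReport\n")
  cat(sprintf("  steps (n): %d, alpha = %g, critical value = %.2f\n",
              object@nSteps, object@alpha, object@criticalValue))
  cat(sprintf("  representative model: member %d\n", object@rmIndex))
  cat(sprintf("  mean rho(member, RM) = %.3f over %d members (%d significant)\n",
              object@meanRhoMembersVsRm, length(object@memberRho),
              sum(object@membersSignificant)))
  if (length(object@rhoRmVsNull))
    cat(sprintf("  rho(RM, null): mean %.3f over %d realisations (%d significant)\n",
                mean(object@rhoRmVsNull), length(object@rhoRmVsNull),
                sum(object@nullSignificant)))
  cat("  tie rules:\n")
  for (t in object@tieNotes) cat("    -", t, "\n")
  invisible(object)
})

#' Write a validation report
#'
#' Writes a human-readable text report and a CSV of per-member rho values.
#' @param report a [ValidationReport-class].
#' @param path output path stem; `<path>.txt` and `<path>.csv` are
#'   written.
#' @return the two paths, invisibly.
#' @export
writeValidationReport <- function(report, path) {
  txt <- paste0(path, ".txt"); csv <- paste0(path, ".csv")
  con <- file(txt, "w"); sink(con); show(report); sink(); close(con)
  write.csv(data.frame(member = seq_along(report@memberRho),
                       rhoVsRm = report@memberRho,
                       significant = report@membersSignificant),
            csv, row.names = FALSE)
  invisible(c(txt, csv))
}
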