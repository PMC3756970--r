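test_that("neighbour probabilities are symmetric in still water and follow the current", {
  cfg <- simConfig()
  still <- makeUniformStack(speed = 0)
  p <- neighborScores(still, c(5, 5), 1, cfg)
  expect_equal(unname(p), rep(1 / 8, 8))            # all suitable, no current
  east <- makeUniformStack(speed = 0.5, direction = 90)
  pe <- neighborScores(east, c(5, 5), 1, cfg)
  expect_equal(sum(pe), 1)
  expect_identical(names(which.max(pe)), "E")
  expect_gt(pe["E"], max(pe[names(pe) != "E"]))     # strictly largest
})

test_that("with no current, static suitability splits mass among habitable neighbours", {
  # only the N and S neighbours of the centre are habitable; all other
  # neighbours fail every static parameter, so their scores vanish
  stack <- makeUniformStack(nRows = 5, nCols = 5, speed = 0)
  habitable <- matrix(FALSE, 5, 5)
  habitable[cbind(c(3, 2, 4), 3)] <- TRUE
  stack@depth[!habitable] <- 60
  stack@sst[] <- array(ifelse(habitable, 28, 10), c(5, 5, 12))
  stack@chlorophyll[] <- array(ifelse(habitable, 0.5, 0.01), c(5, 5, 12))
  p <- neighborScores(stack, c(3, 3), 1, simConfig())
  expect_equal(unname(p["N"] + p["S"]), 1)
  expect_equal(unname(p["N"]), unname(p["S"]))
  expect_true(all(p[!names(p) %in% c("N", "S")] == 0))
})

test_that("probability vectors always sum to one and ignore land", {
  cfg <- simConfig()
  env <- studyEnv()
  ctx <- invasionCA:::.buildContext(env, cfg)
  marine <- which(!env@landMask, arr.ind = TRUE)
  set.seed(42)
  pick <- marine[sample.int(nrow(marine), 60), , drop = FALSE]
  for (i in seq_len(nrow(pick))) {
    m <- sample.int(12, 1)
    p <- neighborScores(env, pick[i, ], m, cfg, context = ctx)
    expect_lt(abs(sum(p) - 1), 1e-12)
    expect_true(all(p >= 0))
  }
  # an isolated cell (all 8 neighbours land) is an error
  iso <- makeUniformStack(nRows = 3, nCols = 3,
                          landCells = cbind(c(1, 1, 1, 2, 2, 3, 3, 3),
                                            c(1, 2, 3, 1, 3, 1, 2, 3)))
  expect_error(neighborScores(iso, c(2, 2), 1, cfg), "isolated")
})

test_that("transit hop counts follow the dwell-time arithmetic", {
  cfg <- simConfig()
  # 0.5 m/s everywhere near the equator: dwell ~ 11120 m / (0.5 * 86400 s)
  # = 0.2574 d per hop, so the 40-day threshold is crossed on hop 156
  wide <- makeUniformStack(nRows = 20, nCols = 200, latMax = 1,
                           speed = 0.5, direction = 90)
  set.seed(7)
  for (i in 1:5) {
    tr <- traceTransit(wide, c(10, 5), 1, cfg)
    expect_false(tr$dead)
    expect_equal(tr$hops, 156)
    expect_gte(tr$elapsedDays, 40)
    expect_lt(tr$elapsedDays, 40.3)
    expect_equal(tr$endMonth, 2)                    # 40 days = one 30-day boundary
  }
  # stagnant water: speed floored at 0.01 m/s caps dwell at ~12.87 d,
  # so settlement happens within ceiling(40 / 12.87) = 4 hops of the origin
  still <- makeUniformStack(nRows = 12, nCols = 12, latMax = 0.6, speed = 0)
  set.seed(8)
  for (i in 1:10) {
    tr <- traceTransit(still, c(6, 6), 1, cfg)
    expect_equal(tr$hops, 4)
    expect_lte(max(abs(tr$cell - c(6, 6))), 4)
  }
})

test_that("a uniform jet carries kernels downstream", {
  cfg <- simConfig()
  north <- makeUniformStack(nRows = 170, nCols = 30, latMax = 17,
                            speed = 0.5, direction = 0)
  set.seed(9)
  finals <- replicate(300, traceTransit(north, c(165, 15), 1, cfg)$cell[1])
  expect_gt(mean(finals < 165), 0.95)               # row decreases northward
  expect_lt(median(finals), 60)                     # strong net displacement
})

test_that("settlement combines the transport-survival draw with habitability", {
  safe <- makeUniformStack()
  noMort <- simConfig(propaguleMortality = 0)
  set.seed(1)
  expect_true(all(attemptSettlement(c(5, 5), 6, safe, noMort, n = 50) == "settled"))
  deep <- makeUniformStack(depth = 50)
  expect_true(all(attemptSettlement(c(5, 5), 6, deep, noMort, n = 50) == "dead"))
  # empirical survival rate matches exp(-Z_p * D) within 3 binomial SEs
  cfg <- simConfig(propaguleMortality = 0.03)       # survival exp(-1.2)
  set.seed(2)
  out <- attemptSettlement(c(5, 5), 6, safe, cfg, n = 20000)
  p <- exp(-1.2)
  se <- sqrt(p * (1 - p) / 20000)
  expect_lt(abs(mean(out == "settled") - p), 3 * se)
})

test_that("a kernel reaching breeding age is promoted and first spawns next cycle", {
  stack <- makeUniformStack()
  cfg <- simConfig(founderImmortal = TRUE, adultMortality = 0)
  state <- initSimulation(cfg, stack, origin = c(0.5, 0.5), seed = 1)
  # replace the founder with a 17-month-old non-breeding settler
  state@populations$age <- 17L
  state@populations$breeding <- FALSE
  state <- stepMonth(state)
  expect_true(state@populations$breeding)
  expect_equal(state@cycleList[[1]]$nSpawnedKernels, 0)   # promoted, not yet spawning
  ev <- state@eventsList[[1]]
  expect_identical(ev$event, "promote")
  state <- stepMonth(state)
  expect_gt(state@cycleList[[2]]$nSpawnedKernels, 0)      # contributes from next cycle
})

test_that("the calendar month wraps December to January", {
  stack <- makeUniformStack()
  cfg <- simConfig(startingMonth = 12, propaguleMortality = 1, adultMortality = 0)
  res <- runSimulation(cfg, stack, origin = c(0.5, 0.5), months = 3, seed = 1)
  expect_equal(res@cycleSummary$calendarMonth, c(12, 1, 2))
})

test_that("population counts are conserved cycle by cycle", {
  env <- studyEnv()
  res <- runSimulation(deskConfig(), env, retentionOrigin, months = 50, seed = 21)
  cs <- res@cycleSummary
  prevAlive <- c(1, cs$nAliveEnd[-nrow(cs)])        # founder before cycle 1
  expect_equal(cs$nAliveEnd, prevAlive + cs$nSettled - cs$nDeaths)
  # event log tallies agree with the summary
  expect_equal(sum(cs$nSettled), sum(res@events$event == "settle"))
  expect_equal(sum(cs$nDeaths), sum(res@events$event == "death"))
  expect_equal(sum(res@settledCount), sum(res@events$event == "settle"))
})

test_that("runs are bit-reproducible for a fixed seed and months = 0 is a no-op", {
  env <- studyEnv()
  cfg <- deskConfig()
  a <- runSimulation(cfg, env, retentionOrigin, months = 30, seed = 5)
  b <- runSimulation(cfg, env, retentionOrigin, months = 30, seed = 5)
  d <- runSimulation(cfg, env, retentionOrigin, months = 30, seed = 6)
  expect_identical(a@events, b@events)
  expect_identical(a@settledCount, b@settledCount)
  expect_false(identical(a@events, d@events))
  z <- runSimulation(cfg, env, retentionOrigin, months = 0, seed = 5)
  expect_equal(nrow(z@events), 0)
  expect_equal(sum(z@settledCount), 0)
  expect_error(runSimulation(cfg, env, c(27.8, -81.95), months = 1, seed = 1), "land")
})

test_that("no settlement ever lands outside the habitable ranges or on land", {
  env <- studyEnv()
  cfg <- deskConfig()
  res <- runSimulation(cfg, env, retentionOrigin, months = 78, seed = 31)
  st <- res@events[res@events$event == "settle", ]
  expect_gt(nrow(st), 50)                            # the scan is not vacuous
  for (i in seq_len(nrow(st))) {
    r <- st$row[i]; c <- st$col[i]; m <- st$calendarMonth[i]
    expect_false(env@landMask[r, c])
    expect_true(env@sst[r, c, m] >= cfg@sstRange[1] && env@sst[r, c, m] <= cfg@sstRange[2])
    expect_true(env@chlorophyll[r, c, m] >= cfg@ccRange[1] &&
                env@chlorophyll[r, c, m] <= cfg@ccRange[2])
    expect_true(env@depth[r, c] >= cfg@depthRange[1] && env@depth[r, c] <= cfg@depthRange[2])
  }
  expect_false(any(env@landMask[cbind(res@events$row, res@events$col)]))
})

test_that("adult lifetimes follow the exponential hazard conversion", {
  # with spawning disabled the founder's death cycle is geometric with
  # p = 1 - exp(-Z/12); compare the empirical survival curve
  stack <- makeUniformStack()
  cfg <- simConfig(spawnsPerCycle = 0, adultMortality = 0.26 * 12)  # p = 1 - exp(-0.26)
  set.seed(77)
  lifetimes <- replicate(800, {
    res <- runSimulation(cfg, stack, c(0.5, 0.5), months = 60,
                         seed = sample.int(1e8, 1))
    d <- res@events[res@events$event == "death", "cycle"]
    if (length(d)) d[1] else NA_real_
  })
  lifetimes <- lifetimes[!is.na(lifetimes)]
  p <- 1 - exp(-0.26)
  # geometric mean lifetime 1/p; 3-SE band on the mean
  expect_lt(abs(mean(lifetimes) - 1 / p),
            3 * sqrt((1 - p) / p^2 / length(lifetimes)) + 0.2)
})
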