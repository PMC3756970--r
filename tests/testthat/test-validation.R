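test_that("quadrant sequences order establishments by first cycle", {
  stack <- makeUniformStack(nRows = 20, nCols = 20, latMax = 2, lonMin = 0,
                            resolution = 6)
  # three quadrants established at cycles 20, 28, 37 (rows pick 0.5-degree bands)
  res <- makeEstablishmentResult(stack, list(c(2, 2), c(8, 8), c(14, 14)),
                                 c(20, 28, 37))
  qs <- quadrantSequence(res, 0.5)
  expect_equal(nrow(qs), 3)
  expect_equal(qs$cycle, c(20, 28, 37))
  expect_equal(qs$quadrant, unique(qs$quadrant))     # no repeats
  # two cells in one quadrant: first establishment wins
  res2 <- makeEstablishmentResult(stack, list(c(2, 2), c(3, 3)), c(9, 5))
  qs2 <- quadrantSequence(res2, 0.5)
  expect_equal(nrow(qs2), 1)
  expect_equal(qs2$cycle, 5)
  # nothing established: empty sequence
  res3 <- makeEstablishmentResult(stack, list(), numeric(0))
  res3@establishmentCycle[] <- NA_real_
  expect_equal(nrow(quadrantSequence(res3)), 0)
})

test_that("the representative sequence is the step-wise mode with lexicographic ties", {
  seqs <- list(c("A", "B"), c("A", "C"), c("A", "B"))
  expect_equal(representativeSequence(seqs, 2), c("A", "B"))
  ident <- replicate(20, c("q1", "q2", "q3"), simplify = FALSE)
  expect_equal(representativeSequence(ident, 3), c("q1", "q2", "q3"))
  # two-way tie at step 2 resolves to the lexicographically smallest id
  tied <- list(c("A", "B"), c("A", "C"))
  expect_equal(representativeSequence(tied, 2), c("A", "B"))
  expect_error(representativeSequence(seqs, 0), "nSteps")
  expect_equal(commonStepCount(list(c("A", "B", "C"), c("B", "A"))), 2)
})

test_that("the representative model maximises step-wise adherence", {
  rep <- c("A", "B", "C", "D", "E")
  members <- list(c("A", "B", "X", "Y", "E"),    # 3 matches
                  rep,                            # 5 matches
                  rep)                            # 5 matches (tie -> first)
  idx <- selectRepresentativeModel(members, rep)
  expect_equal(as.integer(idx), 2L)
  expect_equal(attr(idx, "score"), 5L)
  # brute-force oracle on random small instances
  set.seed(11)
  for (i in 1:20) {
    mem <- replicate(5, sample(LETTERS[1:6], 4), simplify = FALSE)
    rs <- sample(LETTERS[1:6], 4)
    oracle <- vapply(mem, function(s) sum(s == rs), integer(1))
    expect_equal(as.integer(selectRepresentativeModel(mem, rs)),
                 which.max(oracle))
  }
})

test_that("Spearman rho matches the closed form and the reference implementation", {
  expect_equal(as.numeric(spearmanRho(letters[1:10], letters[1:10])), 1)
  expect_equal(as.numeric(spearmanRho(letters[1:10], rev(letters[1:10]))), -1)
  expect_equal(as.numeric(spearmanRho(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))), 0.8)
  # exhaustive check against cor(..., method = "spearman") for n <= 6
  for (n in 4:6) {
    perms <- asplit(as.matrix(expand.grid(rep(list(seq_len(n)), n))), 1)
    perms <- Filter(function(p) !anyDuplicated(p), perms)
    base <- seq_len(n)
    for (p in perms[seq(1, length(perms), length.out = 40)]) {
      expect_equal(as.numeric(spearmanRho(base, as.numeric(p))),
                   cor(base, as.numeric(p), method = "spearman"))
    }
  }
  # alignment restricts to the shared quadrant set before ranking
  a <- c("q1", "q2", "x", "q3", "q4")
  b <- c("q2", "y", "q1", "q4", "q3")
  r <- spearmanRho(a, b)
  expect_equal(attr(r, "n"), 4)
  expect_equal(as.numeric(r), cor(c(1, 2, 3, 4), c(2, 1, 4, 3), method = "spearman"))
  expect_error(spearmanRho(c("a", "b", "c"), c("x", "y", "a")), "common")
})

test_that("permutation critical values match published two-tailed 0.05 points", {
  expect_equal(as.numeric(criticalValue(10, 0.05)), 0.65)
  expect_equal(as.numeric(criticalValue(5, 0.05)), 1)    # only the perfect orderings
  expect_error(criticalValue(3, 0.05), "n")
  expect_error(criticalValue(10, 0), "alpha")
  # near-degenerate alpha: the smallest positive support value
  expect_lt(as.numeric(criticalValue(5, 0.95)), 0.2)
  # monotone non-increasing in n and in alpha
  cv <- vapply(5:10, function(n) as.numeric(criticalValue(n, 0.05)), numeric(1))
  expect_true(all(diff(cv) <= 0))
  ca <- vapply(c(0.01, 0.05, 0.10), function(a) as.numeric(criticalValue(8, a)), numeric(1))
  expect_true(all(diff(ca) <= 0))
})

test_that("the null model fills a 1 x 3 strip in exactly two cycles", {
  strip <- makeUniformStack(nRows = 1, nCols = 3, latMax = 0.1)
  for (seed in 1:10) {
    nul <- runNullModel(strip, origin = c(0.05, 0.15), seed = seed)
    est <- as.vector(nul@establishmentCycle)
    expect_equal(est[2], 0)                        # origin in the middle
    expect_equal(sort(est[c(1, 3)]), c(1, 2))      # one end per cycle
    expect_equal(nul@months, 2)
  }
})

test_that("null-model occupancy grows monotonically and is seed-reproducible", {
  env <- studyEnv()
  a <- runNullModel(env, retentionOrigin, seed = 4)
  b <- runNullModel(env, retentionOrigin, seed = 4)
  expect_identical(a@establishmentCycle, b@establishmentCycle)
  expect_true(all(diff(a@cycleSummary$nOccupied) >= 0))
  # runs to full occupancy of the connected marine region
  expect_equal(sum(is.na(a@establishmentCycle[!env@landMask])), 0)
  # a disconnected pond is never reached and triggers a warning
  land <- matrix(FALSE, 5, 5); land[, 3] <- TRUE
  split <- makeUniformStack(nRows = 5, nCols = 5, landCells = which(land, arr.ind = TRUE))
  expect_warning(nulSplit <- runNullModel(split, c(0.95, 0.05), seed = 1), "disconnected")
  expect_true(all(is.na(nulSplit@establishmentCycle[, 4:5])))
})

test_that("identical members validate trivially against themselves", {
  seqs <- replicate(5, letters[1:8], simplify = FALSE)
  nulls <- list(sample(letters[1:8]), sample(letters[1:8]))
  rep <- validationReport(seqs, nulls)
  expect_equal(rep@meanRhoMembersVsRm, 1)
  expect_equal(rep@nSteps, 8L)
  expect_true(all(rep@membersSignificant))
  expect_error(validationReport(seqs[1], nulls), "at least 2")
  thin <- list(c("a", "b"), c("a", "b"))
  expect_error(validationReport(thin, nulls), "common steps")
})
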