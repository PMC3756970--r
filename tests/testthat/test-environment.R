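test_that("grid geometry maps rows/columns to coordinates and back", {
  g <- gridSpec(24, 30, -82, -76, 6)
  expect_equal(g@nRows, 60L)
  expect_equal(g@nCols, 60L)
  cc <- cellCenters(g, 1L, 1L)             # row 1 = northernmost
  expect_equal(cc$lat, 30 - 0.05)
  expect_equal(cc$lon, -82 + 0.05)
  # cellAt inverts cellCenters on every cell of a small grid
  g2 <- gridSpec(0, 0.5, 10, 10.5, 6)
  for (r in seq_len(g2@nRows)) for (c in seq_len(g2@nCols)) {
    ctr <- cellCenters(g2, r, c)
    at <- cellAt(g2, ctr$lat, ctr$lon)
    expect_identical(c(at$row, at$col), c(r, c))
  }
  expect_error(cellAt(g2, 5, 10.2), "outside")
})

test_that("synthetic environments honour their construction guarantees across seeds", {
  p <- synthParams()
  for (seed in c(1, 7, 99)) {
    env <- generateSyntheticEnvironment(seed = seed)
    g <- env@grid
    lat <- cellCenters(g, seq_len(g@nRows), 1L)$lat
    # global speed maximum equals the configured jet peak
    expect_equal(max(env@currentSpeed), p$peakSpeed)
    expect_true(all(env@currentSpeed >= 0))
    expect_true(all(env@currentDirection >= 0 & env@currentDirection < 360))
    # winter SST below the 16 C tolerance north of the cold latitude
    north <- lat > p$coldLat
    for (m in p$winterMonths)
      expect_lt(max(env@sst[north, , m]), 16)
    # shelf cells near the coast are marine and shallower than 40 m
    marineDepth <- env@depth[!env@landMask]
    expect_true(all(marineDepth > 0))
    firstSea <- apply(!env@landMask, 1, function(x) which(x)[1])
    for (r in seq_len(g@nRows)) {
      shelf <- env@depth[r, firstSea[r]:min(g@nCols, firstSea[r] + 3)]
      expect_true(all(shelf < 40))
    }
    # a weak-flow retention zone exists inshore and north of the separation
    retRows <- which(lat >= p$separationLat + 0.3)
    retSpeed <- env@currentSpeed[retRows, firstSea[1] + 1, ]
    expect_lt(min(retSpeed), 2 * p$retentionSpeed)
  }
})

test_that("synthetic generation is bit-reproducible and seed-sensitive", {
  a <- generateSyntheticEnvironment(seed = 5)
  b <- generateSyntheticEnvironment(seed = 5)
  d <- generateSyntheticEnvironment(seed = 6)
  expect_identical(a@currentSpeed, b@currentSpeed)
  expect_identical(a@sst, b@sst)
  expect_identical(a@chlorophyll, b@chlorophyll)
  expect_false(identical(a@sst, d@sst))
  # the generator must not disturb the caller's RNG stream
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(generateSyntheticEnvironment(seed = 9)); after <- runif(3)
  expect_identical(before, after)
})

test_that("a jet axis leaving the grid is rejected", {
  expect_error(
    generateSyntheticEnvironment(gridSpec(24, 30, -82, -80, 6),
                                 synthParams(separationAngle = 80), seed = 1),
    "jet axis")
})

test_that("cell suitability applies the habitable ranges per parameter", {
  stack <- makeUniformStack(sst = 28, cc = 0.5, depth = 20)
  v <- cellSuitability(stack, c(5, 5), 6, simConfig())
  expect_true(v$sstOk && v$ccOk && v$depthOk)
  expect_equal(unname(v$scores), c(1, 1, 1))
  v2 <- cellSuitability(makeUniformStack(depth = 50), c(5, 5), 6, simConfig())
  expect_false(v2$depthOk); expect_true(v2$sstOk && v2$ccOk)
  v3 <- cellSuitability(makeUniformStack(cc = 0.05), c(5, 5), 6, simConfig())
  expect_false(v3$ccOk); expect_true(v3$sstOk && v3$depthOk)
  land <- makeUniformStack(landCells = cbind(3, 3))
  expect_error(cellSuitability(land, c(3, 3), 1, simConfig()), "land")
})

test_that("ASCII grids round-trip values, NA cells and georeferencing", {
  g <- gridSpec(0, 0.5, 10, 10.6, 6)
  m <- matrix(round(runif(g@nRows * g@nCols) * 100, 3), g@nRows, g@nCols)
  m[2, 3] <- NA
  tf <- tempfile(fileext = ".asc")
  writeAsciiGrid(m, g, tf)
  back <- readAsciiGrid(tf)
  expect_equal(back$values, m)
  expect_equal(back$grid@latMin, g@latMin)
  expect_equal(back$grid@nRows, g@nRows)
  expect_equal(back$grid@resolution, g@resolution)
})

test_that("environment stacks round-trip through the raster directory layout", {
  env <- generateSyntheticEnvironment(gridSpec(25, 26, -81, -80, 6), seed = 3)
  dir <- tempfile("envdir")
  writeEnvironmentDir(env, dir)
  back <- readEnvironmentDir(dir)
  expect_equal(back@grid@nRows, env@grid@nRows)
  expect_equal(back@landMask, env@landMask)
  expect_equal(back@depth[!back@landMask], env@depth[!env@landMask])
  expect_equal(back@sst, env@sst, tolerance = 1e-7)
  expect_equal(back@currentSpeed, env@currentSpeed, tolerance = 1e-7)
})

test_that("raster reading rejects missing months and mismatched grids", {
  env <- generateSyntheticEnvironment(gridSpec(25, 26, -81, -80, 6), seed = 3)
  dir <- tempfile("envdir")
  writeEnvironmentDir(env, dir)
  unlink(file.path(dir, "sst_07.asc"))
  expect_error(readEnvironmentDir(dir), "sst.*month 7|month 7.*sst")
  # dimension mismatch named with the layer
  dir2 <- tempfile("envdir")
  writeEnvironmentDir(env, dir2)
  small <- gridSpec(25, 25.5, -81, -80.5, 6)
  writeAsciiGrid(matrix(1, small@nRows, small@nCols), small,
                 file.path(dir2, "chlorophyll_02.asc"))
  expect_error(readEnvironmentDir(dir2), "chlorophyll.*month 2")
})

test_that("cells above sea level and u/v current components are handled on read", {
  g <- gridSpec(0, 0.3, 0, 0.3, 6)
  dir <- tempfile("uvdir")
  dir.create(dir)
  mm <- sprintf("%02d", 1:12)
  for (m in mm) {
    writeAsciiGrid(matrix(1, 3, 3), g, file.path(dir, paste0("u_", m, ".asc")))
    writeAsciiGrid(matrix(0, 3, 3), g, file.path(dir, paste0("v_", m, ".asc")))
    writeAsciiGrid(matrix(28, 3, 3), g, file.path(dir, paste0("sst_", m, ".asc")))
    writeAsciiGrid(matrix(0.5, 3, 3), g, file.path(dir, paste0("chl_", m, ".asc")))
  }
  depth <- matrix(20, 3, 3); depth[1, 1] <- -5       # above sea level
  writeAsciiGrid(depth, g, file.path(dir, "depth.asc"))
  env <- readEnvironment(list(
    currentU = file.path(dir, paste0("u_", mm, ".asc")),
    currentV = file.path(dir, paste0("v_", mm, ".asc")),
    sst = file.path(dir, paste0("sst_", mm, ".asc")),
    chlorophyll = file.path(dir, paste0("chl_", mm, ".asc")),
    depth = file.path(dir, "depth.asc")))
  # pure eastward flow: direction 90 deg from north, speed 1
  expect_equal(unique(as.vector(env@currentSpeed)), 1)
  expect_equal(unique(env@currentDirection[!env@landMask]), 90)
  expect_true(env@landMask[1, 1])                     # negative depth forced land
  expect_false(any(env@landMask[-1, ]))
})
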