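test_that("Miami NPP matches direct evaluation and limits", {
  # precipitation-limited rate vanishes without rain
  expect_equal(miamiNPP(c(-10, 0, 25), c(0, 0, 0)), rep(0, 3))
  # saturates at the shared 3000 asymptote
  expect_equal(miamiNPP(1e3, 1e9), 3000, tolerance = 1e-9)
  # hand-computed interior point: min(1406.4, 1455.2)
  expect_equal(miamiNPP(10, 1000), 1406.372, tolerance = 1e-3)
  expect_equal(miamiNPP(10, 1000, "temperature"),
               3000 / (1 + exp(1.315 - 0.119 * 10)))
  expect_equal(miamiNPP(10, 1000, "precipitation"),
               3000 * (1 - exp(-0.000664 * 1000)))
})

test_that("Miami NPP is monotone and bounded on a random sweep", {
  set.seed(1)
  temp <- runif(300, -30, 40); prec <- runif(300, 0, 5000)
  v <- miamiNPP(temp, prec)
  expect_true(all(v >= 0 & v < 3000))
  expect_true(all(miamiNPP(temp + 1, prec) >= v))
  expect_true(all(miamiNPP(temp, prec + 100) >= v))
})

test_that("Miami NPP rejects invalid input naming the offending field", {
  expect_error(miamiNPP(NA, 100), "temp")
  expect_error(miamiNPP(10, Inf), "precip")
  expect_error(miamiNPP(10, -5), "non-negative")
})

test_that("wintering-season temperature averages sub-zero months", {
  mc <- monthlyClimate(c(-5, -8, -3, rep(5, 9)), c(-1, -2, -0.5, rep(8, 9)))
  expect_equal(as.numeric(winteringTemperature(mc)), -16 / 3)
  expect_false(attr(winteringTemperature(mc), "noWinter"))
  one <- monthlyClimate(c(-2, rep(4, 11)), c(-0.1, rep(6, 11)))
  expect_equal(as.numeric(winteringTemperature(one)), -2)
  warm <- monthlyClimate(c(3, rep(10, 11)), c(5, rep(12, 11)))
  expect_equal(as.numeric(winteringTemperature(warm)), 3)
  expect_true(attr(winteringTemperature(warm), "noWinter"))
  expect_error(monthlyClimate(1:12, rep(-100, 12)), "below")
  expect_error(monthlyClimate(1:6, 1:6), "12 monthly")
})

test_that("period aggregation half-weights margin steps", {
  sch <- periodScheme(cbind(0, 100))
  # margin, core, margin: (0.5*2 + 1*4 + 0.5*6) / 2 = 4
  expect_equal(aggregateToPeriods(c(0, 50, 100), c(2, 4, 6), sch), 4)
  expect_equal(aggregateToPeriods(50, 7, sch), 7)  # single covering step
  sch2 <- toyScheme(4)
  times <- seq(0, 400, by = 10)
  expect_equal(aggregateToPeriods(times, rep(3.5, length(times)), sch2),
               rep(3.5, 4))
  expect_error(aggregateToPeriods(c(200, 300), c(1, 2), sch),
               "period 1")
  # matrix values aggregate per column
  m <- cbind(c(2, 4, 6), c(10, 20, 30))
  expect_equal(aggregateToPeriods(c(0, 50, 100), m, sch),
               matrix(c(4, 20), 1, 2))
})

test_that("climate series validate and aggregate jointly", {
  expect_error(climateSeries(1, c(1500, 1500), 1:2, 1:2), "increasing")
  expect_error(climateSeries(1, 1:3, 1:3, c(1, -2, 3)), ">= 0")
  expect_error(climateSeries(1, 1:3, 1:2, 1:3), "same length")
  cs <- climateSeries(7, c(0, 50, 100), temp = c(2, 4, 6),
                      precip = c(500, 700, 900),
                      winterTemp = c(-8, -6, -4))
  agg <- aggregateToPeriods(cs, scheme = periodScheme(cbind(0, 100)))
  # margin / core / margin half-weighting applies to every field
  expect_equal(unname(agg[1, ]), c(4, 700, -6))
  expect_identical(colnames(agg), c("temp", "precip", "winter_temp"))
})

test_that("anomaly calibration uses the 31-year baseline window", {
  yrs <- 1500:2000
  const <- rep(8, length(yrs))
  expect_equal(calibrateAnomalies(yrs, const, 0), 8)
  expect_equal(calibrateAnomalies(yrs, const, c(-2.5, 1)), c(5.5, 9))
  ramp <- 0.01 * (yrs - 1500)
  # running mean of a linear ramp equals the midpoint value
  brute <- mean(ramp[yrs %in% 1835:1865])
  expect_equal(calibrateAnomalies(yrs, ramp, 0), brute)
  expect_equal(brute, 0.01 * (1850 - 1500))
  expect_error(calibrateAnomalies(1840:2000, rep(1, 161), 0),
               "31-year window")
})

test_that("LCP distances reduce to lattice distance on flat land", {
  tg <- terrainGrid(matrix(0, 12, 12), cellKm = 100, fineKm = 25)
  d <- lcpDistances(tg)
  expect_true(isSymmetric(d))
  expect_equal(diag(d), rep(0, 9))
  # 3x3 coarse grid: adjacent 1, diagonal sqrt(2)
  expect_equal(d[1, 2], 1)
  expect_equal(d[1, 5], sqrt(2), tolerance = 1e-9)
  expect_equal(d[1, 9], 2 * sqrt(2), tolerance = 1e-9)
  # triangle inequality
  for (i in 1:9) for (j in 1:9) for (k in 1:9)
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-9)
})

test_that("water forces detours and all-water errors", {
  elev <- matrix(0, 12, 4)
  water <- matrix(FALSE, 12, 4)
  water[5:8, ] <- TRUE                   # horizontal strip severs the grid
  water[5:8, 1] <- FALSE                 # except a corridor on the left
  tg <- terrainGrid(elev, water, cellKm = 100, fineKm = 25)
  d <- lcpDistances(tg)                  # 1 x 3 coarse grid
  expect_gt(d[1, 3], 2)                  # detour beats the straight line
  expect_error(lcpDistances(terrainGrid(matrix(0, 8, 8),
                                        matrix(TRUE, 8, 8),
                                        cellKm = 100, fineKm = 25)),
               "all-water")
})

test_that("LCP on a ridge matches an independent Dijkstra oracle", {
  set.seed(42)
  elev <- matrix(0, 10, 10)
  elev[, 5:6] <- 800                      # a ridge down the middle
  elev <- elev + matrix(runif(100, 0, 50), 10, 10)
  tg <- terrainGrid(elev, cellKm = 50, fineKm = 10)  # 2x2 coarse
  d <- lcpDistances(tg)

  # oracle: brute-force Dijkstra over the same 8-neighbour cost graph
  nr <- 10; nc <- 10; n <- nr * nc
  adj <- vector("list", n)
  id <- function(r, c) (c - 1) * nr + r
  for (r in 1:nr) for (c in 1:nc)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      planar <- 10 * sqrt(dr^2 + dc^2)
      w <- planar * (1 + abs(elev[r2, c2] - elev[r, c]) / planar)
      adj[[id(r, c)]] <- c(adj[[id(r, c)]], list(c(id(r2, c2), w)))
    }
  # coarse centres: fine cells nearest (3,3), (3,8), (8,3), (8,8)
  reps <- c(id(3, 3), id(3, 8), id(8, 3), id(8, 8))
  for (i in 1:4) {
    ref <- dijkstraRef(adj, n, reps[i])[reps] / 50
    expect_equal(unname(d[i, ]), ref, tolerance = 1e-9)
  }
})

test_that("the seven Holocene periods give the printed interval lengths", {
  ps <- periodScheme(holocenePeriods())
  expect_identical(nPeriods(ps), 7L)
  expect_equal(deltaT(ps), c(3500, 3500, 2250, 900, 310, 52.5))
  expect_equal(midpoints(ps)[1:2], c(-8500, -5000))
  # equal-length adjacent periods: dt equals the common length
  expect_equal(deltaT(periodScheme(cbind(c(0, 20), c(20, 40)))), 20)
  expect_error(periodScheme(cbind(c(10, 0), c(20, 5))), "ordered")
  expect_error(periodScheme(rbind(c(0, 50), c(25, 80))), "overlap")
})
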