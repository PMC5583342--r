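test_that("extinction rate is the exponentiated linear predictor", {
  cov1 <- c(lu = 0, npp = 0, wt = 0, ele = 0)
  expect_equal(extinctionRate(cov1, rep(0, 5)), 1)
  expect_equal(extinctionRate(cov1, c(-3, 0, 0, 0, 0)), exp(-3))
  lu <- seq(0, 2, by = 0.5)
  r <- extinctionRate(cbind(lu = lu, npp = 0, wt = 0, ele = 0),
                      c(0, 0.8, 0, 0, 0))
  expect_true(all(diff(r) > 0))          # monotone in LU when beta_LU > 0
  expect_error(extinctionRate(c(lu = NA, npp = 0, wt = 0, ele = 0),
                              rep(0, 5)), "non-finite")
})

test_that("connectivity is the self-excluding kernel sum", {
  d <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(connectivity(c(0, 0), d, 2), c(0, 0))
  expect_equal(connectivity(c(0, 1), d, 2), c(exp(-2), 0))
  # non-decreasing when any cell flips 0 -> 1
  set.seed(3)
  n <- 8
  dm <- as.matrix(dist(matrix(runif(2 * n, 0, 5), n, 2)))
  z <- rbinom(n, 1, 0.4)
  S0 <- connectivity(z, dm, 1)
  for (j in which(z == 0)) {
    z2 <- z; z2[j] <- 1
    expect_true(all(connectivity(z2, dm, 1) >= S0))
  }
  expect_error(connectivity(c(0, 1, 1), d, 2), "mismatch")
})

test_that("colonization rate follows the log link with lambda scaling", {
  expect_equal(colonizationRate(0), 1)   # no occupied neighbours: 1 / yr
  expect_equal(colonizationRate(exp(-2)), exp(exp(-2)))
  expect_equal(colonizationRate(0.13534), 1.1449, tolerance = 1e-4)
  S <- c(0.3, 1.2)
  expect_equal(log(colonizationRate(S, lambda = 2)),
               2 * log(colonizationRate(S, lambda = 1)))
})

test_that("rate-to-probability mapping matches the closed-form examples", {
  expect_equal(ratesToProbabilities(0.01, 0.02, 0),
               list(pPhi = 0, pGamma = 0))
  # symmetric rates, long interval: stationary 0.5 / 0.5
  pr <- ratesToProbabilities(0.01, 0.01, 1e7)
  expect_equal(pr$pPhi, 0.5, tolerance = 1e-10)
  expect_equal(pr$pGamma, 0.5, tolerance = 1e-10)
  pr <- ratesToProbabilities(0.001, 0.0005, 3500)
  expect_equal(pr$pPhi, 0.66317, tolerance = 1e-4)
  expect_equal(pr$pGamma, 0.33158, tolerance = 1e-4)
  expect_error(ratesToProbabilities(0.1, 0.1, -1), "non-negative")
  expect_error(ratesToProbabilities(0, 0.1, 1), "positive")
})

test_that("mapping agrees with the matrix-exponential oracle", {
  skip_if_not_installed("Matrix")
  for (rp in c(1e-4, 1e-3, 1e-2)) for (rg in c(5e-4, 5e-3, 5e-2))
    for (dt in c(52.5, 310, 3500)) {
      o <- expmProbs(rp, rg, dt)
      pr <- ratesToProbabilities(rp, rg, dt)
      expect_equal(pr$pPhi, o$pPhi, tolerance = 1e-10)
      expect_equal(pr$pGamma, o$pGamma, tolerance = 1e-10)
    }
})

test_that("mapping has the stationary and short-interval limits", {
  rp <- 0.004; rg <- 0.001
  pr <- ratesToProbabilities(rp, rg, 1e9)
  expect_equal(pr$pGamma, rg / (rp + rg), tolerance = 1e-8)
  expect_equal(pr$pPhi, rp / (rp + rg), tolerance = 1e-8)
  pr <- ratesToProbabilities(rp, rg, 1e-6)
  expect_equal(pr$pGamma, rg * 1e-6, tolerance = 1e-4)
  expect_equal(pr$pPhi, rp * 1e-6, tolerance = 1e-4)
  # the sub-1e-12 Taylor branch stays finite and first-order exact
  pr <- ratesToProbabilities(1e-8, 1e-8, 1e-6)
  expect_equal(pr$pPhi, 1e-14, tolerance = 1e-6)
})

test_that("occupancy transition mixes persistence and colonization", {
  expect_equal(occupancyTransition(1, 0.2, 0.9), 0.8)
  expect_equal(occupancyTransition(0, 0.2, 0.3), 0.3)
  expect_equal(occupancyTransition(c(0, 1), 1, 0), c(0, 0))
  expect_error(occupancyTransition(1, 1.2, 0), "\\[0, 1\\]")
})

test_that("detection probability follows the logit model in log NSP", {
  b <- list(intercept = 0, nsp = 0, type = c(settlement = 0))
  expect_equal(detectionProbability(1, "settlement", b), 0.5)
  b2 <- list(intercept = -1, nsp = 0.5, type = c(settlement = 0))
  expect_equal(detectionProbability(exp(2), "settlement", b2), 0.5)
  b3 <- list(intercept = -1, nsp = 0.4,
             type = c(settlement = 0, burial = 1))
  p <- detectionProbability(c(1, 10, 100, 1000), "settlement", b3)
  expect_true(all(diff(p) > 0))          # detection rises with bone count
  expect_gt(detectionProbability(10, "burial", b3),
            detectionProbability(10, "settlement", b3))
  expect_error(detectionProbability(0, "settlement", b3), ">= 1")
  expect_error(detectionProbability(5, "spaceship", b3), "unknown site type")
})

test_that("observation log-likelihood handles occupancy and perfection", {
  recs <- toyRecords()
  z <- matrix(0L, 2, 3)
  expect_equal(observationLogLik(recs, z, 0.25), -Inf)
  z[1, 2] <- 1L                           # the y=1 record's cell
  expect_equal(observationLogLik(recs, z, 0.25),
               log(0.25) + 2 * log(1))    # z=0, y=0 rows contribute 0
  z2 <- matrix(1L, 2, 3)
  expect_equal(observationLogLik(recs, z2, 0.25),
               log(0.25) + 2 * log(0.75))
  # perfect detection: y must equal z
  expect_equal(observationLogLik(recs, z2, 0.25, perfectPeriods = 2),
               -Inf)                      # y=0 record in occupied cell
  # record a (period 1) keeps p = 0.25; both period-2 records match z
  z3 <- z2; z3[2, 2] <- 0L
  expect_equal(observationLogLik(recs, z3, 0.25, perfectPeriods = 2),
               log(0.75))
  bad <- toyRecords(within(recordData(recs), cell_id[1] <- 9))
  expect_error(observationLogLik(bad, z, 0.25), "unknown cell")
})

test_that("forward simulation reproduces the analytic transition law", {
  # psi1 = 1 and a vanishing extinction rate: everything stays occupied
  sch <- toyScheme(3)
  st <- zeroStack(4, 3, sch)
  d <- as.matrix(dist(expand.grid(0:1, 0:1)))
  lat <- simulateOccupancy(st, c(-20, 0, 0, 0, 0), list(alpha = 1), 1,
                           d, seed = 2)
  expect_true(all(occupancy(lat) == 1L))
  # large independent panel: extinction fraction within 3 binomial se
  n <- 1500
  stBig <- zeroStack(n, 2, toyScheme(2))
  dBig <- matrix(1e6, n, n); diag(dBig) <- 0   # effectively no dispersal
  b0 <- log(0.004)                             # r_phi; r_gamma = 1 at S=0
  lat2 <- simulateOccupancy(stBig, c(b0, 0, 0, 0, 0), list(alpha = 1), 1,
                            dBig, seed = 7)
  pr <- ratesToProbabilities(0.004, 1, deltaT(toyScheme(2))[1])
  extFrac <- mean(occupancy(lat2)[, 2] == 0)
  se <- sqrt(pr$pPhi * (1 - pr$pPhi) / n)
  expect_lt(abs(extFrac - pr$pPhi), 3 * se)
  # goodness of fit of the two-way transition table
  exp2 <- c(pr$pPhi, 1 - pr$pPhi) * n
  obs2 <- c(sum(occupancy(lat2)[, 2] == 0), sum(occupancy(lat2)[, 2] == 1))
  gof <- suppressWarnings(chisq.test(obs2, p = exp2 / n))
  expect_gt(gof$p.value, 0.01)
  # reproducibility
  lat3 <- simulateOccupancy(stBig, c(b0, 0, 0, 0, 0), list(alpha = 1), 1,
                            dBig, seed = 7)
  expect_identical(occupancy(lat2), occupancy(lat3))
})
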