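test_that("MCMC bookkeeping matches the published schedule", {
  cfg <- mcmcConfig()
  expect_identical(cfg$nChains, 10L)
  expect_identical(retainedPerChain(cfg), 100L)
  expect_identical(cfg$nChains * retainedPerChain(cfg), 1000L)
  expect_identical(retainedPerChain(mcmcConfig(nIter = 4500, burnIn = 2000,
                                               thin = 25)), 100L)
  expect_error(mcmcConfig(nIter = 100, burnIn = 100), "smaller")
  expect_error(mcmcConfig(thin = 0), ">= 1")
})

test_that("site-type imputation follows the period frequencies", {
  tf <- matrix(0, 7, 3, dimnames = list(siteTypes(), NULL))
  tf["settlement", 1] <- 5
  expect_true(all(imputeSiteType(1, tf, 50) == "settlement"))
  tf[c("settlement", "castle"), 2] <- c(0.5, 0.5)
  set.seed(2)
  draws <- imputeSiteType(2, tf, 1e4)
  se <- sqrt(0.25 / 1e4)
  expect_lt(abs(mean(draws == "settlement") - 0.5), 3 * se)
  # counts behave as normalized probabilities
  tf[, 3] <- 0; tf[c("cave", "burial", "midden"), 3] <- c(2, 1, 1)
  set.seed(3)
  d3 <- imputeSiteType(3, tf, 2e4)
  expect_lt(abs(mean(d3 == "cave") - 0.5), 3 * sqrt(0.25 / 2e4))
  tfBad <- matrix(0, 7, 1)
  expect_error(imputeSiteType(1, tfBad), "all-zero")
})

test_that("latent updates pin certain states and match enumeration", {
  S <- 2; T <- 3
  sch <- periodScheme(cbind(c(0, 100, 200), c(50, 150, 250)))
  d <- matrix(c(0, 1, 1, 0), 2, 2)
  rPhi <- matrix(0.008, S, T)
  recs <- toyRecords()
  betaP <- list(intercept = -0.5, nsp = 0.3, type = c(settlement = 0))
  p <- detectionProbability(recordData(recs)$nsp_total,
                            recordData(recs)$site_type, betaP)
  # a y=1 record pins its cell-period occupied
  set.seed(1)
  z <- updateLatentOccupancy(matrix(0L, S, T), rPhi, d, 1, 0.4, sch,
                             recs, p)
  expect_identical(z[1, 2], 1L)
  # Gibbs marginals match the exhaustive 2^6 enumeration
  oracle <- enumerateToyPosterior(S, T, sch, d, 1, 0.4, rPhi, recs, p)
  set.seed(5)
  z <- matrix(0L, S, T); acc <- matrix(0, S, T); n <- 3000
  for (i in seq_len(n)) {
    z <- updateLatentOccupancy(z, rPhi, d, 1, 0.4, sch, recs, p)
    acc <- acc + z
  }
  expect_lt(max(abs(acc / n - oracle)), 0.03)
})

test_that("inconsistent perfect-detection states are rejected", {
  df <- recordData(toyRecords())
  df <- rbind(df, data.frame(record_id = 4:5, site_id = c("m1", "m2"),
                             site_type = "range_map", period = 3,
                             cell_id = 1, nsp_total = 1,
                             detected = c(1, 0)))
  cov <- zeroStack(2, 3)
  expect_error(
    runMCMC(archRecords(df), cov, matrix(c(0, 1, 1, 0), 2, 2),
            mcmcConfig(nChains = 1, nIter = 20, burnIn = 10, thin = 1)),
    "conflicting")
})

test_that("identical seeds give bit-identical posterior draws", {
  st <- zeroStack(4, 3)
  d <- as.matrix(dist(expand.grid(0:1, 0:1)))
  recs <- archRecords(data.frame(
    record_id = 1:4, site_id = letters[1:4], site_type = "settlement",
    period = c(1, 1, 2, 3), cell_id = 1:4, nsp_total = c(3, 9, 2, 30),
    detected = c(0, 1, 0, 1)))
  cfg <- mcmcConfig(nChains = 2, nIter = 200, burnIn = 100, thin = 2,
                    seed = 42)
  f1 <- runMCMC(recs, st, d, cfg)
  f2 <- runMCMC(recs, st, d, cfg)
  expect_identical(posteriorMatrix(f1), posteriorMatrix(f2))
  expect_identical(latentDraws(f1), latentDraws(f2))
  expect_identical(nDraws(f1), 2L * retainedPerChain(cfg))
})

test_that("with no data the posterior reproduces the priors", {
  st <- zeroStack(6, 3)
  d <- as.matrix(dist(expand.grid(0:2, 0:1)))
  recs <- archRecords(data.frame(record_id = integer(0),
    site_id = character(0), site_type = character(0), period = integer(0),
    cell_id = integer(0), nsp_total = integer(0), detected = integer(0)))
  fit <- runMCMC(recs, st, d,
                 mcmcConfig(nChains = 2, nIter = 6000, burnIn = 500,
                            thin = 2, seed = 5))
  a <- posteriorMatrix(fit)[, "alpha"]
  ess <- max(100, nrow(posteriorMatrix(fit)) /
               (1 + 2 * sum(pmax(acf(a, 40, plot = FALSE)$acf[-1], 0))))
  seMean <- sd(a) / sqrt(ess)
  expect_lt(abs(mean(a) - 3), 3 * seMean + 0.05)   # Gamma(3,1) mean
  expect_lt(abs(var(a) - 3) / 3, 0.35)             # and variance
  for (nm in paste0("I_", c("phi_lu", "phi_wt", "npp_wt", "lu_ele"))) {
    v <- posteriorMatrix(fit)[, nm]
    nb <- 40
    v <- v[seq_len(nb * (length(v) %/% nb))]
    bm <- tapply(v, rep(seq_len(nb), each = length(v) / nb), mean)
    se <- sd(bm) / sqrt(nb)
    expect_lt(abs(mean(v) - 0.5), 3 * se + 0.01)
  }
  p1 <- posteriorMatrix(fit)[, "psi1"]
  expect_lt(abs(mean(p1) - 0.5), 0.05)             # Uniform(0,1) prior
})

test_that("convergence diagnostics flag divergent chains and track ESS", {
  mk <- function(values, chains) {
    n <- length(values) / chains
    new("PosteriorDraws",
        draws = matrix(values, ncol = 1, dimnames = list(NULL, "theta")),
        chain = rep(seq_len(chains), each = n),
        iter = rep(seq_len(n), chains), z = array(0L, c(0, 0, 0)),
        scenario = rep("", length(values)), config = list())
  }
  set.seed(9)
  good <- mk(rnorm(4000), 4)
  dg <- convergenceDiagnostics(good)
  expect_lt(dg$rhat[1], 1.01)
  expect_gt(dg$ess[1], 2000)
  bad <- mk(c(rnorm(1000), rnorm(1000) + 10), 2)
  expect_gt(convergenceDiagnostics(bad)$rhat[1], 1.5)
  expect_true("theta" %in% attr(convergenceDiagnostics(bad), "warnings"))
  # AR(1), rho = 0.5: ESS/N should be near (1-rho)/(1+rho) = 1/3
  ar <- replicate(4, as.numeric(arima.sim(list(ar = 0.5), 3000)))
  dgAr <- convergenceDiagnostics(mk(as.numeric(ar), 4))
  expect_lt(abs(dgAr$ess[1] / 12000 - 1 / 3), 0.2 / 3)
  expect_error(convergenceDiagnostics(mk(rnorm(100), 1)), ">= 2 chains")
})

test_that("scenario pooling concatenates with labels intact", {
  mkFit <- function(val, scen, n = 10) {
    new("PosteriorDraws",
        draws = matrix(val, n, 1, dimnames = list(NULL, "x")),
        chain = rep(1L, n), iter = seq_len(n),
        z = array(1L, c(n, 2, 2)), scenario = rep(scen, n),
        config = list())
  }
  fits <- list(mkFit(1, "lu=constant;asia=no"),
               mkFit(2, "lu=constant;asia=yes"),
               mkFit(3, "lu=decreasing;asia=no"),
               mkFit(4, "lu=decreasing;asia=yes"))
  pooled <- poolScenarios(fits)
  expect_identical(nDraws(pooled), 40L)
  expect_equal(mean(posteriorMatrix(pooled)[, "x"]), mean(1:4))
  expect_setequal(unique(pooled@scenario),
                  vapply(fits, function(f) f@scenario[1], ""))
  # label survives a write/read round trip
  tmp <- tempfile(fileext = ".csv")
  writePosterior(pooled, tmp)
  back <- readPosterior(tmp)
  expect_identical(back@scenario, pooled@scenario)
  # unequal draw counts: error unless down-sampling is requested
  fits2 <- c(fits, list(mkFit(5, "extra", n = 6)))
  expect_error(poolScenarios(fits2), "unequal")
  expect_identical(nDraws(poolScenarios(fits2, downsample = TRUE)), 30L)
})

test_that("the Asian-colonization source strip feeds connectivity", {
  tg <- terrainGrid(matrix(0, 12, 12), cellKm = 100, fineKm = 25)
  d <- lcpDistances(tg)                    # 3x3 flat grid
  expect_null(applyAsianColonizationScenario(d, 3, 3, "no"))
  src <- applyAsianColonizationScenario(d, 3, 3, "yes")
  expect_identical(dim(src), c(9L, 3L))
  # empty interior: connectivity only from the ghost strip, strongest east
  S0 <- connectivity(rep(0, 9), d, 2, sourceDist = src)
  expect_true(all(S0 > 0))
  expect_gt(S0[3], S0[1])                  # cell 3 (east) vs cell 1 (west)
  # an eastern-edge cell sits at distance 1 from its ghost source
  expect_equal(src[3, 1], 1)
  expect_equal(connectivity(rep(0, 9), d, 2, sourceDist = src[, 1,
                                                              drop = FALSE])[3],
               exp(-2), tolerance = 1e-9)
  expect_error(applyAsianColonizationScenario(d, NULL, NULL, "yes"),
               "boundary strip")
  # flag "no" leaves connectivity unchanged
  z <- c(1, rep(0, 8))
  expect_identical(connectivity(z, d, 2),
                   connectivity(z, d, 2, sourceDist = NULL))
})
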