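test_that("landscapes are reproducible with controlled water and relief", {
  tg <- generateLandscape(4, 3, cellKm = 100, fineKm = 25, seed = 5)
  expect_identical(nCells(tg), 12L)
  expect_true(all(!tg@water))              # water fraction 0: all land
  tg2 <- generateLandscape(4, 3, cellKm = 100, fineKm = 25, seed = 5)
  expect_identical(tg2@elevation, tg@elevation)
  tgw <- generateLandscape(4, 4, cellKm = 100, fineKm = 20, seed = 6,
                           waterFraction = 0.2)
  expect_equal(mean(tgw@water), 0.2, tolerance = 0.02)
  # a single cosine has spatial variance amplitude^2 / 2
  tg1 <- generateLandscape(20, 20, cellKm = 100, fineKm = 20, seed = 8,
                           amplitude = 300, nWaves = 1)
  expect_equal(var(as.numeric(tg1@elevation)), 300^2 / 2, tolerance = 0.25)
})

test_that("covariates follow the structural path model", {
  sch <- paperScheme()
  tg <- generateLandscape(6, 6, cellKm = 100, fineKm = 50, seed = 2)
  # zero residual and cell sds: covariates equal the structural means
  tr0 <- defaultTruth(sigma_wt = 0, sigma_wt_cell = 0, sigma_npp = 0,
                      sigma_npp_cell = 0, sigma_lu = 0, sigma_lu_cell = 0)
  cov0 <- generateCovariates(tg, sch, tr0, seed = 3)
  p <- truthParams(tr0)
  T <- nPeriods(sch)
  trend <- p$wt_trend * (seq_len(T) - 1) / (T - 1) - p$wt_trend / 2
  expect_equal(cov0@wt, sweep(p$wt_ele * cov0@ele, 2, -trend))
  expect_equal(cov0@npp, p$npp_wt * cov0@wt + p$npp_ele * cov0@ele)
  expect_equal(cov0@lu, p$lu_npp * cov0@npp + p$lu_wt * cov0@wt +
                 p$lu_ele * cov0@ele)
  # regressing simulated LU on its parents recovers the slopes
  tg2 <- generateLandscape(14, 14, cellKm = 100, fineKm = 50, seed = 4)
  tr <- defaultTruth()
  cov <- generateCovariates(tg2, sch, tr, seed = 9)
  d <- data.frame(lu = as.numeric(cov@lu), npp = as.numeric(cov@npp),
                  wt = as.numeric(cov@wt), ele = as.numeric(cov@ele),
                  cell = factor(rep(seq_len(nrow(cov@lu)),
                                    nPeriods(sch))))
  fit <- lm(lu ~ npp + wt + ele + cell, data = d)
  se <- coef(summary(fit))[2:4, 2]
  est <- coef(fit)[2:4]
  truthSlopes <- c(truthParams(tr)$lu_npp, truthParams(tr)$lu_wt,
                   truthParams(tr)$lu_ele)
  expect_true(all(abs(est - truthSlopes) < 3 * se + 1e-8))
  # warming trend: last-minus-first period mean near the configured trend
  nEff <- nrow(cov@wt)
  seT <- sqrt(2 * (truthParams(tr)$sigma_wt^2) / nEff)
  expect_lt(abs(mean(cov@wt[, 7]) - mean(cov@wt[, 1]) -
                  truthParams(tr)$wt_trend), 4 * seT + 0.2)
  # land-use intensity scenario halves the final-period multiplier
  covD <- generateCovariates(tg2, sch, tr, seed = 9,
                             luScenario = "decreasing")
  expect_equal(covD@lu[, 1], cov@lu[, 1])
  expect_equal(covD@lu[, 7], 0.5 * cov@lu[, 7])
})

test_that("standardized path truth converts generating slopes exactly", {
  st <- generateStudy(seed = 21)
  ps <- standardizedPathTruth(st$covariates, st$truth)
  s <- st$covariates@scale
  p <- truthParams(st$truth)
  expect_equal(unname(ps["beta_npp_wt"]),
               p$npp_wt * s[["wt"]] / s[["npp"]])
  expect_equal(unname(ps[c("beta_npp_ele", "beta_lu_ele")]), c(0, 0))
})

test_that("record generation respects occupancy and detection structure", {
  sch <- toyScheme(4)
  z <- matrix(0L, 30, 4)
  lat <- occupancyLattice(z, sch)
  tr <- defaultTruth()
  rec <- generateRecords(lat, tr, seed = 3, recordsPerCellPeriod = 3,
                         nPerfect = 1)
  d <- recordData(rec)
  expect_true(all(d$detected == 0))        # z = 0 everywhere: no detections
  expect_true(all(d$nsp_total >= 1))
  # equal detection across types/NSP: rate near inverse-logit(beta_p0)
  trFlat <- defaultTruth(beta_p_nsp = 0,
                         beta_p_type = c(settlement = 0, castle = 0,
                                         cave = 0, burial = 0, midden = 0,
                                         cult = 0, moor_riverbed = 0),
                         unknownFraction = 0)
  z1 <- matrix(1L, 60, 4)
  lat1 <- occupancyLattice(z1, sch)
  rec1 <- generateRecords(lat1, trFlat, seed = 11,
                          recordsPerCellPeriod = 4, nPerfect = 1)
  d1 <- recordData(rec1)
  arch <- d1[d1$site_type != "range_map", ]
  pExp <- plogis(truthParams(trFlat)$beta_p0)
  se <- sqrt(pExp * (1 - pExp) / nrow(arch))
  expect_lt(abs(mean(arch$detected) - pExp), 3 * se)
  # unknown-type erasure matches its configured fraction
  rec2 <- generateRecords(lat1, defaultTruth(), seed = 12,
                          recordsPerCellPeriod = 4, nPerfect = 1)
  d2 <- recordData(rec2)
  arch2 <- d2[d2$site_type != "range_map", ]
  uf <- 272 / 4177
  seU <- sqrt(uf * (1 - uf) / nrow(arch2))
  expect_lt(abs(mean(arch2$site_type == "unknown") - uf), 3 * seU)
  # range-map rows cover every cell of the perfect period with y = z
  rng <- d2[d2$site_type == "range_map", ]
  expect_identical(sort(rng$cell_id), 1:60)
  expect_true(all(rng$detected == 1))
  # reproducibility
  expect_identical(recordData(generateRecords(lat1, defaultTruth(),
                                              seed = 12,
                                              recordsPerCellPeriod = 4,
                                              nPerfect = 1)), d2)
})

test_that("life-history tables encode the gamma identity-link truth", {
  # zero effects: no systematic correlation with covariates
  tr0 <- defaultTruth(meta_fm = 0, meta_npp = 0, meta_tws = 0)
  cors <- vapply(1:20, function(s) {
    d <- generateLifeHistoryTable(38, tr0, seed = s)
    cor(d$ls / d$li, d$t_ws)
  }, 0)
  expect_lt(mean(abs(cors) < 0.3), 1.01)     # sanity bound
  expect_gt(mean(abs(cors) < 0.3), 0.8)      # ~95% of seeds in theory
  # negative winter-temperature effect shows in the sample correlation
  trBig <- defaultTruth(meta_tws = -0.15)
  dBig <- generateLifeHistoryTable(400, trBig, seed = 5)
  expect_lt(cor(dBig$ls / dBig$li, dBig$t_ws), 0)
  d1 <- generateLifeHistoryTable(38, defaultTruth(), seed = 9)
  expect_identical(generateLifeHistoryTable(38, defaultTruth(), seed = 9),
                   d1)
  expect_error(generateLifeHistoryTable(4), "at least 6")
  # generated tables satisfy the reader's invariants
  tmp <- tempfile(fileext = ".csv")
  writePopulationTable(d1, tmp)
  back <- readPopulationTable(tmp)
  expect_equal(back$ls, d1$ls, tolerance = 1e-12)
  expect_identical(is.na(back$n_fm), is.na(d1$n_fm))
})

test_that("truth objects round-trip through YAML", {
  tr <- defaultTruth(alpha = 2.5)
  tmp <- tempfile(fileext = ".yaml")
  writeTruth(tr, tmp)
  back <- readTruth(tmp)
  expect_equal(truthParams(back)$alpha, 2.5)
  expect_equal(truthParams(back)$beta_phi, truthParams(tr)$beta_phi)
  expect_equal(truthParams(back)$beta_p_type, truthParams(tr)$beta_p_type)
  expect_identical(back@seed, tr@seed)
})

test_that("generated studies satisfy the consuming modules' invariants", {
  st <- generateStudy(defaultTruth(nx = 5, ny = 5), seed = 13)
  expect_true(validObject(st$records, complete = TRUE))
  expect_true(validObject(st$covariates, complete = TRUE))
  expect_true(validObject(st$lattice, complete = TRUE))
  expect_true(isSymmetric(st$distances))
  expect_true(all(diag(st$distances) == 0))
  # round trip through the readers preserves everything
  tmpR <- tempfile(fileext = ".csv"); tmpC <- tempfile(fileext = ".csv")
  writeRecords(st$records, tmpR)
  expect_identical(recordData(readRecords(tmpR)), recordData(st$records))
  writeCovariates(st$covariatesRaw, tmpC)
  back <- readCovariates(tmpC, st$scheme)
  expect_equal(back@lu, st$covariatesRaw@lu, tolerance = 1e-9)
})
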