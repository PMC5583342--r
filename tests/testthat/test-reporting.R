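test_that("net trend is the log10 extinction/colonization ratio", {
  expect_equal(netTrend(0.01, 0.01), 0)
  expect_equal(netTrend(0.1, 0.01), 1)
  expect_equal(netTrend(0.001, 0.02), -1.30103, tolerance = 1e-5)
  expect_error(netTrend(0, 0.1), "positive")
})

test_that("occurrence and net-trend surfaces summarize the draws", {
  nd <- 40; S <- 4; T <- 3
  z <- array(0L, c(nd, S, T))
  z[, 1, ] <- 1L                      # cell 1 always occupied
  set.seed(1)
  z[, 2, ] <- rbinom(nd * T, 1, 0.5)
  dr <- matrix(0, nd, length(archeopop:::.parNames()),
               dimnames = list(NULL, archeopop:::.parNames()))
  dr[, "alpha"] <- 2; dr[, "psi1"] <- 0.5
  fit <- new("PosteriorDraws", draws = dr, chain = rep(1L, nd),
             iter = seq_len(nd), z = z, scenario = rep("", nd),
             config = list())
  occ <- occurrenceSurface(fit)
  expect_equal(occ[1, ], rep(1, T))   # pinned-occupied cell: probability 1
  expect_equal(occ[3, ], rep(0, T))
  expect_lt(abs(mean(occ[2, ]) - 0.5), 3 * sqrt(0.25 / (nd * T)))
  # pooled probability equals the average of scenario-wise probabilities
  fitA <- fit; fitB <- fit
  fitB@z[, 3, ] <- 1L
  fitB@scenario <- rep("b", nd)
  pooled <- poolScenarios(list(fitA, fitB))
  expect_equal(occurrenceSurface(pooled)[3, 1],
               (occurrenceSurface(fitA)[3, 1] +
                  occurrenceSurface(fitB)[3, 1]) / 2)
  # net trend on a stack of zeros: r_phi = exp(b0), r_gamma from z
  cov <- zeroStack(S, T)
  d <- as.matrix(dist(1:4)) * 10      # well-separated cells
  nt <- netTrendSurface(fit, cov, d)
  expect_identical(dim(nt), as.integer(c(S, T - 1)))
  expect_equal(nt[3, 1], log10(exp(0) / 1), tolerance = 1e-6)
})

test_that("record tables reject invariant violations with row context", {
  d <- recordData(toyRecords())
  tmp <- tempfile(fileext = ".csv")
  bad <- d; bad$nsp_total[2] <- 0
  write.csv(bad, tmp, row.names = FALSE)
  expect_error(readRecords(tmp), "row 2.*nsp_total.*NSP >= 1")
  weird <- d; weird$site_type[1] <- "temple"
  write.csv(weird, tmp, row.names = FALSE)
  expect_error(readRecords(tmp), "unknown site type")
  got <- readRecords(tmp, coerceUnknownTypes = TRUE)
  expect_identical(recordData(got)$site_type[1], "unknown")
})

test_that("terrain and posterior files round-trip losslessly", {
  tg <- generateLandscape(3, 2, cellKm = 100, fineKm = 25, seed = 7,
                          waterFraction = 0.1)
  tmp <- tempfile(fileext = ".csv")
  writeTerrain(tg, tmp)
  back <- readTerrain(tmp, cellKm = 100)
  expect_equal(back@elevation, tg@elevation, tolerance = 1e-9)
  expect_identical(back@water, tg@water)
  expect_identical(back@fineKm, tg@fineKm)

  dr <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  fit <- new("PosteriorDraws", draws = dr, chain = rep(1:2, each = 5),
             iter = rep(1:5, 2), z = array(0L, c(0, 0, 0)),
             scenario = rep("lu=constant;asia=no", 10), config = list())
  tmp2 <- tempfile(fileext = ".csv")
  writePosterior(fit, tmp2)
  back2 <- readPosterior(tmp2)
  expect_equal(posteriorMatrix(back2), posteriorMatrix(fit),
               tolerance = 1e-12)
  expect_identical(chainIndex(back2), chainIndex(fit))
  # long variant has one row per draw-parameter pair
  tmp3 <- tempfile(fileext = ".csv")
  writePosteriorLong(fit, tmp3)
  lng <- read.csv(tmp3)
  expect_identical(nrow(lng), 20L)
  expect_setequal(unique(lng$parameter), c("a", "b"))
  # latent draws round trip
  fit@z <- array(rbinom(10 * 2 * 3, 1, 0.5), c(10, 2, 3))
  tmp4 <- tempfile(fileext = ".csv")
  writeLatent(fit, tmp4)
  expect_identical(readLatent(tmp4), fit@z)
})

test_that("effect tables carry inclusion probabilities and Bayes factors", {
  nd <- 50
  dr <- matrix(0, nd, length(archeopop:::.parNames()),
               dimnames = list(NULL, archeopop:::.parNames()))
  dr[, "beta_phi_wt"] <- 0.9; dr[, "beta_phi_lu"] <- 0.8
  dr[, "beta_npp_wt"] <- -0.5; dr[, "beta_phi_npp"] <- 0.6
  dr[, "I_phi_wt"] <- 1; dr[, "I_phi_lu"] <- rep(c(1, 0), c(45, 5))
  fit <- new("PosteriorDraws", draws = dr, chain = rep(1L, nd),
             iter = seq_len(nd), z = array(0L, c(0, 0, 0)),
             scenario = rep("", nd), config = list())
  tab <- effectTable(fit)
  expect_setequal(names(tab), c("effect_name", "kind", "mean", "ci_low",
                                "ci_high", "inclusion_prob",
                                "bayes_factor"))
  dw <- tab[tab$effect_name == "direct_wt", ]
  expect_equal(dw$inclusion_prob, 1)
  expect_equal(dw$bayes_factor, bayesFactor(1, M = nd))
  expect_equal(tab$mean[tab$effect_name == "dampening_pct"],
               100 * 0.3 / 0.9, tolerance = 1e-9)
  expect_true(all(tab$kind %in% c("direct", "indirect", "dampening")))
})

test_that("the CLI wires the subcommands together", {
  dir0 <- file.path(tempdir(), "apcli"); unlink(dir0, recursive = TRUE)
  sim <- file.path(dir0, "sim"); out <- file.path(dir0, "fit")
  # tiny study so the whole pipeline stays fast
  expect_identical(
    apCLI(c("simulate", "--out", sim, "--seed", "3", "--nx", "4")), 0L)
  f1 <- read.csv(file.path(sim, "records.csv"))
  apCLI(c("simulate", "--out", paste0(sim, "2"), "--seed", "3",
          "--nx", "4"))
  f2 <- read.csv(file.path(paste0(sim, "2"), "records.csv"))
  expect_identical(f1, f2)                 # same seed: identical outputs
  expect_identical(
    apCLI(c("fit", "--data", sim, "--out", out, "--seed", "2",
            "--chains", "2", "--iter", "120", "--burnin", "40",
            "--thin", "4", "--keep-latent", "yes")), 0L)
  expect_true(file.exists(file.path(out, "draws.csv")))
  expect_true(file.exists(file.path(out, "manifest.yaml")))
  expect_identical(
    apCLI(c("diagnose", "--draws", file.path(out, "draws.csv"),
            "--out", file.path(out, "diag.csv"))), 0L)
  dg <- read.csv(file.path(out, "diag.csv"))
  expect_true(all(c("parameter", "rhat", "ess") %in% names(dg)))
  expect_identical(
    apCLI(c("decompose", "--draws", file.path(out, "draws.csv"),
            "--out", file.path(out, "effects.csv"))), 0L)
  expect_identical(
    apCLI(c("report", "--draws", file.path(out, "draws.csv"),
            "--zdraws", file.path(out, "zdraws.csv"),
            "--data", sim, "--out", file.path(out, "maps"))), 0L)
  expect_true(file.exists(file.path(out, "maps", "occurrence.csv")))
  expect_true(file.exists(file.path(out, "maps", "net_trend.csv")))
  # a single-chain fit cannot be diagnosed
  expect_identical(
    apCLI(c("fit", "--data", sim, "--out", paste0(out, "1"), "--seed", "2",
            "--chains", "1", "--iter", "80", "--burnin", "20",
            "--thin", "4")), 0L)
  expect_error(
    apCLI(c("diagnose", "--draws", file.path(paste0(out, "1"), "draws.csv"),
            "--out", file.path(out, "d1.csv"))), ">= 2 chains")
  # missing required options are listed exhaustively in one pass
  expect_error(apCLI(c("fit", "--seed", "1")), "--data.*--out")
  expect_error(apCLI("unheard-of"), "unknown subcommand")
})
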