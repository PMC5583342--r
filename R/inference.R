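## MCMC engine driver: configuration, chain management, site-type
## imputation, latent-state updates, convergence diagnostics, and pooling
## across the 2x2 scenario factorial.

#' MCMC configuration
#'
#' Default schedule: 10 parallel chains of 4,500 iterations with a burn-in
#' (adaptation) phase of 2,000 iterations and a thinning interval of 25,
#' retaining 100 draws per chain (1,000 total). The dispersal parameter
#' \eqn{\alpha} carries an informative Gamma(shape 3, rate 1) prior whose
#' mode 2 corresponds to a mean dispersal distance of 50 km on a 100-km
#' grid; the initial occupancy probability is Uniform(0, 1); regression
#' coefficients not under SSVS get diffuse Normal(0, sd 10) priors.
#'
#' @param nChains,nIter,burnIn,thin MCMC schedule (burnIn < nIter,
#'   thin >= 1).
#' @param seed integer master seed; chain seeds derive from it.
#' @param alphaPrior c(shape, rate) of the Gamma prior on \eqn{\alpha}.
#' @param coefSd sd of the diffuse normal coefficient priors.
#' @param ssvs logical, apply spike-and-slab selection to the 10 candidate
#'   paths (default TRUE).
#' @param retainLatent logical, keep posterior draws of the occupancy
#'   lattice (needed for occurrence surfaces).
#' @return Named list of settings.
#' @export
mcmcConfig <- function(nChains = 10, nIter = 4500, burnIn = 2000,
                       thin = 25, seed = 1L, alphaPrior = c(3, 1),
                       coefSd = 10, ssvs = TRUE, retainLatent = TRUE) {
  if (burnIn >= nIter) stop("burnIn must be smaller than nIter")
  if (thin < 1) stop("thin must be >= 1")
  list(nChains = as.integer(nChains), nIter = as.integer(nIter),
       burnIn = as.integer(burnIn), thin = as.integer(thin),
       seed = as.integer(seed), alphaPrior = alphaPrior, coefSd = coefSd,
       ssvs = isTRUE(ssvs), retainLatent = isTRUE(retainLatent))
}

#' @describeIn mcmcConfig Retained draws per chain:
#'   \code{floor((nIter - burnIn) / thin)}.
#' @param config an \code{mcmcConfig()} list.
#' @export
retainedPerChain <- function(config) {
  as.integer((config$nIter - config$burnIn) %/% config$thin)
}

#' Impute an excavation-site type from period-specific frequencies
#'
#' Draws site types from the multinomial distribution of the seven known
#' site types in the record's period, used for records lacking a site
#' designation. Inside the sampler, the same conditional additionally
#' weighs in the record's detection likelihood and is re-drawn every
#' iteration so imputation uncertainty propagates.
#'
#' @param period period index (column of \code{typeFreq}).
#' @param typeFreq 7 x periods matrix of site-type counts or frequencies
#'   (rows ordered as \code{\link{siteTypes}}).
#' @param n number of draws.
#' @return Character vector of drawn site types (uses the R RNG).
#' @export
imputeSiteType <- function(period, typeFreq, n = 1) {
  typeFreq <- as.matrix(typeFreq)
  if (nrow(typeFreq) != 7) stop("'typeFreq' must have 7 rows")
  f <- typeFreq[, period]
  if (sum(f) <= 0)
    stop(sprintf("all-zero site-type frequency column for period %d", period))
  siteTypes()[sample.int(7, n, replace = TRUE, prob = f / sum(f))]
}

#' Observed site-type frequencies per period
#'
#' @param records an \linkS4class{ArchRecords}.
#' @param nPeriodsTotal number of periods (columns of the result).
#' @return 7 x periods matrix of counts of known types (excludes
#'   "unknown" and "range_map" rows); all-zero columns are replaced by a
#'   uniform pseudo-frequency so imputation remains defined for periods
#'   without typed records.
#' @export
siteTypeFrequencies <- function(records, nPeriodsTotal) {
  d <- recordData(records)
  d <- d[d$site_type %in% siteTypes(), , drop = FALSE]
  m <- matrix(0, 7, nPeriodsTotal,
              dimnames = list(siteTypes(), NULL))
  if (nrow(d)) {
    tab <- table(factor(d$site_type, levels = siteTypes()),
                 factor(d$period, levels = seq_len(nPeriodsTotal)))
    m <- m + as.matrix(tab)
  }
  empty <- colSums(m) == 0
  m[, empty] <- 1 / 7
  m
}

## Build pin matrix (-1 free, 0/1 pinned) from records; error on conflict.
occupancyPins <- function(records, S, T, perfectPeriods) {
  d <- recordData(records)
  pin <- matrix(-1L, S, T)
  perf <- d[d$period %in% perfectPeriods, , drop = FALSE]
  if (nrow(perf)) {
    agg <- unique(perf[, c("cell_id", "period", "detected")])
    dup <- duplicated(agg[, c("cell_id", "period")])
    if (any(dup)) {
      b <- agg[dup, ][1, ]
      stop(sprintf(
        "conflicting perfect-detection states for cell %d, period %d",
        b$cell_id, b$period))
    }
    pin[cbind(agg$cell_id, agg$period)] <- agg$detected
  }
  arch <- d[!(d$period %in% perfectPeriods) & d$detected == 1, , drop = FALSE]
  if (nrow(arch)) {
    bad <- pin[cbind(arch$cell_id, arch$period)] == 0L
    if (any(bad)) stop("detection recorded in a cell pinned unoccupied")
    pin[cbind(arch$cell_id, arch$period)] <- 1L
  }
  pin
}

#' Fit the joint metapopulation + path model by MCMC
#'
#' Metropolis-within-Gibbs sampler for the full hierarchical model:
#' single-site Gibbs sweeps over the latent occupancy lattice (accounting
#' for the connectivity feedback of each cell on its neighbours'
#' colonization rates), conjugate updates for the Gaussian path
#' regressions, cell random effects and precisions, exact Bernoulli
#' conditionals for the inclusion indicators, multinomial full
#' conditionals for unknown site types, a conjugate Beta update for the
#' initial occupancy probability, and adaptive random-walk Metropolis for
#' the extinction-rate coefficients, detection coefficients and the
#' dispersal parameter (tuned to 20--40\% acceptance during burn-in, then
#' frozen). Fully reproducible given \code{config$seed}.
#'
#' @param records an \linkS4class{ArchRecords}: archaeofaunal records plus
#'   (optionally) \code{"range_map"} rows for perfect-detection periods.
#' @param covariates a \linkS4class{CovariateStack} (standardized
#'   internally if not already).
#' @param distances LCP distance matrix (grid units), see
#'   \code{\link{lcpDistances}}.
#' @param config an \code{\link{mcmcConfig}} list.
#' @param scenario named character vector with entries \code{lu}
#'   ("constant"/"decreasing"; a label describing which land-use surface
#'   was supplied) and \code{asia} ("yes"/"no").
#' @param sourceDist external-source distance matrix for the
#'   Asian-colonization scenario (required when \code{scenario["asia"]}
#'   is "yes"); see \code{\link{applyAsianColonizationScenario}}.
#' @param perfectPeriods periods with perfect detection; defaults to the
#'   periods of any \code{"range_map"} rows.
#' @param dispersal list with fixed \code{lambda} (default 1) and
#'   colonization intercept \code{gamma0} (default 0, the model as
#'   printed).
#' @param updates optional named list of logicals switching individual
#'   update blocks off (names: z, betaPhi, betaP, alpha, psi1, path,
#'   indicators, types); used to run reduced samplers (e.g. latent states
#'   only, with all parameters held fixed).
#' @param init optional named list of initial values (entries as in the
#'   internal chain state: betaPhi, betaP, alpha, psi1, pathCoef, tau,
#'   tauCell, cellEff, slabSd, I, z, rtype); unspecified entries are drawn
#'   randomly from uniform distributions per chain.
#' @param verbose logical; report per-chain progress and acceptance.
#' @return A \linkS4class{PosteriorDraws}.
#' @export
runMCMC <- function(records, covariates, distances, config = mcmcConfig(),
                    scenario = c(lu = "constant", asia = "no"),
                    sourceDist = NULL, perfectPeriods = NULL,
                    dispersal = list(lambda = 1, gamma0 = 0),
                    updates = NULL, init = NULL, verbose = FALSE) {
  stopifnot(is(records, "ArchRecords"), is(covariates, "CovariateStack"))
  covariates <- standardizeCovariates(covariates)
  S <- nrow(covariates@lu); T <- nPeriods(covariates@scheme)
  distances <- as.matrix(distances)
  if (nrow(distances) != S)
    stop("distance matrix does not match the number of cells")
  d <- recordData(records)
  if (nrow(d) && (max(d$cell_id) > S || max(d$period) > T))
    stop("record references unknown cell/period")
  if (is.null(perfectPeriods))
    perfectPeriods <- sort(unique(d$period[d$site_type == "range_map"]))
  if (identical(unname(scenario["asia"]), "yes") && is.null(sourceDist))
    stop("asia='yes' requires a boundary-strip sourceDist; see ",
         "applyAsianColonizationScenario()")
  if (is.null(sourceDist)) sourceDist <- matrix(numeric(0), S, 0)

  arch <- d[!(d$period %in% perfectPeriods), , drop = FALSE]
  pin <- occupancyPins(records, S, T, perfectPeriods)
  typeFreq <- siteTypeFrequencies(records, T)
  knownIdx <- match(arch$site_type, siteTypes())    # NA for unknown
  unknown0 <- which(is.na(knownIdx)) - 1L           # 0-based

  dataList <- list(
    S = S, T = T, dt = deltaT(covariates@scheme),
    X = covariateMatrix(covariates), D = distances,
    srcD = as.matrix(sourceDist),
    rcell = as.integer(arch$cell_id - 1L), rper = as.integer(arch$period - 1L),
    ry = as.integer(arch$detected), rlogn = log(as.numeric(arch$nsp_total)),
    typeFreq = typeFreq,
    perfect = as.integer(seq_len(T) %in% perfectPeriods),
    pinned = as.integer(pin), unknownType = as.integer(unknown0))

  upd <- list(z = TRUE, betaPhi = TRUE, betaP = TRUE, alpha = TRUE,
              psi1 = TRUE, path = TRUE, indicators = config$ssvs,
              types = TRUE)
  if (!is.null(updates)) upd[names(updates)] <- updates

  cfg <- list(nIter = config$nIter, burnIn = config$burnIn,
              thin = config$thin, ssvs = config$ssvs,
              spikeSd = 1 / sqrt(ssvsConfig()$spikePrecision),
              slabMax = ssvsConfig()$slabMax,
              priorInclusion = ssvsConfig()$priorInclusion,
              alphaShape = config$alphaPrior[1],
              alphaRate = config$alphaPrior[2], coefSd = config$coefSd,
              gamma0 = if (is.null(dispersal$gamma0)) 0 else dispersal$gamma0,
              lambda = if (is.null(dispersal$lambda)) 1 else dispersal$lambda,
              update = upd, retainZ = config$retainLatent)

  set.seed(config$seed)
  chainSeeds <- sample.int(2^30, config$nChains)
  nKeep <- retainedPerChain(config)
  allDraws <- vector("list", config$nChains)
  allZ <- vector("list", config$nChains)
  allIter <- vector("list", config$nChains)

  drawInit <- function() {
    ini <- list(
      betaPhi = runif(5, -1, 1), betaP = runif(8, -1, 1),
      alpha = runif(1, 0.5, 4), psi1 = runif(1, 0.05, 0.95),
      pathCoef = runif(9, -1, 1), tau = rep(1, 3), tauCell = rep(1, 3),
      cellEff = matrix(0, S, 3), slabSd = runif(1, 1, 10),
      I = rbinom(10, 1, 0.5),
      z = matrix(ifelse(pin >= 0, pin, rbinom(S * T, 1, 0.5)), S, T),
      rtype = {
        ty <- knownIdx
        for (u in which(is.na(ty)))
          ty[u] <- match(imputeSiteType(arch$period[u], typeFreq),
                         siteTypes())
        as.integer(ty - 1L)
      })
    if (!is.null(init)) ini[names(init)] <- init
    if (!is.null(init$z)) ini$z <- matrix(as.integer(init$z), S, T)
    ini
  }

  for (ch in seq_len(config$nChains)) {
    if (verbose)
      message(sprintf("chain %d/%d (seed %d): %d iterations ...",
                      ch, config$nChains, chainSeeds[ch], config$nIter))
    set.seed(chainSeeds[ch])
    for (attempt in 1:5) {
      res <- .mcmc_chain(dataList, cfg, drawInit())
      if (all(is.finite(res$draws))) break
      if (attempt == 5) stop("non-finite posterior draws after 5 restarts")
    }
    if (verbose)
      message(sprintf("  chain %d done: %d draws retained; mean acceptance %.2f",
                      ch, length(res$iters),
                      mean(res$accept, na.rm = TRUE)))
    colnames(res$draws) <- .parNames()
    allDraws[[ch]] <- res$draws
    allIter[[ch]] <- res$iters
    if (config$retainLatent)
      allZ[[ch]] <- array(res$z, dim = c(nKeep, S, T))
  }
  draws <- do.call(rbind, allDraws)
  zarr <- if (config$retainLatent) {
    z <- array(0L, dim = c(nrow(draws), S, T))
    for (ch in seq_len(config$nChains))
      z[(ch - 1) * nKeep + seq_len(nKeep), , ] <- allZ[[ch]]
    z
  } else array(0L, dim = c(0, 0, 0))
  scenLab <- paste0("lu=", scenario[["lu"]], ";asia=", scenario[["asia"]])
  new("PosteriorDraws", draws = draws,
      chain = rep(seq_len(config$nChains), each = nKeep),
      iter = as.integer(unlist(allIter)), z = zarr,
      scenario = rep(scenLab, nrow(draws)),
      config = c(config, list(scenario = scenario,
                              perfectPeriods = perfectPeriods)))
}

.parNames <- function() {
  c("beta_phi_0", "beta_phi_lu", "beta_phi_npp", "beta_phi_wt",
    "beta_phi_ele",
    "beta_p_0", "beta_p_nsp", "beta_p_castle", "beta_p_cave",
    "beta_p_burial", "beta_p_midden", "beta_p_cult", "beta_p_moor_riverbed",
    "alpha", "psi1",
    "beta_wt_0", "beta_wt_ele", "beta_npp_0", "beta_npp_wt", "beta_npp_ele",
    "beta_lu_0", "beta_lu_npp", "beta_lu_wt", "beta_lu_ele",
    "tau_wt", "tau_npp", "tau_lu", "tau_wt_cell", "tau_npp_cell",
    "tau_lu_cell", "slab_sd",
    "I_phi_lu", "I_phi_npp", "I_phi_wt", "I_phi_ele", "I_wt_ele",
    "I_npp_wt", "I_npp_ele", "I_lu_npp", "I_lu_wt", "I_lu_ele")
}

#' Single-site Gibbs update of the latent occupancy lattice
#'
#' Pure-R reference implementation of the latent-state full conditional
#' used by the sampler: each free \eqn{z_{s,t}} is redrawn from
#' \eqn{P(z_{s,t} \mid \cdot) \propto P(z_{s,t} \mid z_{s,t-1})
#' \prod_{s'} P(z_{s',t+1} \mid z_{t}) \prod_i P(y_i \mid z)}, where the
#' middle product runs over all cells because \eqn{z_{s,t}} enters every
#' empty cell's colonization rate through connectivity. Cells with a
#' certain state (a detection, or a perfect-detection period) are pinned.
#' Intended for small lattices and cross-checks; the compiled sampler in
#' \code{\link{runMCMC}} implements the same conditional.
#'
#' @param z current cells x periods binary matrix.
#' @param rPhi cells x periods matrix of extinction rates (per year).
#' @param distances,alpha dispersal geometry, see
#'   \code{\link{connectivity}}.
#' @param psi1 initial occupancy probability.
#' @param scheme the \linkS4class{PeriodScheme}.
#' @param records optional \linkS4class{ArchRecords}; \code{p} gives the
#'   per-record detection probability.
#' @param p detection probabilities aligned with the rows of
#'   \code{records}.
#' @param perfectPeriods periods where y = z exactly.
#' @param sourceDist optional external-source distances.
#' @param nSweeps number of full sweeps.
#' @return Updated binary matrix (uses the R RNG).
#' @export
updateLatentOccupancy <- function(z, rPhi, distances, alpha, psi1, scheme,
                                  records = NULL, p = NULL,
                                  perfectPeriods = integer(0),
                                  sourceDist = NULL, nSweeps = 1) {
  z <- matrix(as.integer(as.matrix(z)), nrow(z), ncol(z))
  S <- nrow(z); T <- ncol(z); dts <- deltaT(scheme)
  d <- if (!is.null(records)) recordData(records) else NULL
  pin <- matrix(-1L, S, T)
  if (!is.null(d)) {
    pinObj <- occupancyPins(records, S, T, perfectPeriods)
    pin <- pinObj
    z[pin >= 0] <- pin[pin >= 0]
  }
  K <- exp(-alpha * as.matrix(distances)); diag(K) <- 0
  src <- if (is.null(sourceDist)) rep(0, S)
         else rowSums(exp(-alpha * as.matrix(sourceDist)))
  rec0 <- matrix(0, S, T)
  if (!is.null(d)) {
    arch <- which(!(d$period %in% perfectPeriods) & d$detected == 0)
    for (i in arch)
      rec0[d$cell_id[i], d$period[i]] <-
        rec0[d$cell_id[i], d$period[i]] + log1p(-p[i])
  }
  for (sweep in seq_len(nSweeps)) {
    for (t in seq_len(T)) {
      Sc <- if (t < T) connectivity(z[, t], distances, alpha) + src else NULL
      for (s in seq_len(S)) {
        if (pin[s, t] >= 0) next
        delta <- 0
        if (t == 1) delta <- delta + qlogis(psi1)
        else {
          ScPrev <- connectivity(z[, t - 1], distances, alpha) + src
          pr <- ratesToProbabilities(rPhi[s, t - 1], exp(ScPrev[s]),
                                     dts[t - 1])
          delta <- delta +
            if (z[s, t - 1] == 1) log1p(-pr$pPhi) - log(pr$pPhi)
            else log(pr$pGamma) - log1p(-pr$pGamma)
        }
        if (t < T) {
          pr <- ratesToProbabilities(rPhi[s, t], exp(Sc[s]), dts[t])
          delta <- delta +
            if (z[s, t + 1] == 1) log1p(-pr$pPhi) - log(pr$pGamma)
            else log(pr$pPhi) - log1p(-pr$pGamma)
          empty <- which(z[, t] == 0L & seq_len(S) != s)
          for (s2 in empty) {
            S1 <- Sc[s2] + (1 - z[s, t]) * K[s2, s]
            S0 <- Sc[s2] - z[s, t] * K[s2, s]
            pg1 <- ratesToProbabilities(rPhi[s2, t], exp(S1), dts[t])$pGamma
            pg0 <- ratesToProbabilities(rPhi[s2, t], exp(S0), dts[t])$pGamma
            delta <- delta +
              if (z[s2, t + 1] == 1) log(pg1) - log(pg0)
              else log1p(-pg1) - log1p(-pg0)
          }
        }
        if (!(t %in% perfectPeriods)) delta <- delta + rec0[s, t]
        znew <- as.integer(runif(1) < plogis(delta))
        if (znew != z[s, t]) {
          z[s, t] <- znew
          if (t < T) Sc <- connectivity(z[, t], distances, alpha) + src
        }
      }
    }
  }
  z
}

#' Convergence diagnostics: rank-normalized split R-hat and ESS
#'
#' Computes the rank-normalized split-\eqn{\hat R} and a combined-chain
#' effective sample size (initial monotone positive-sequence estimator on
#' the rank-normalized draws), plus the lag-1 autocorrelation, for every
#' parameter.
#'
#' @param draws a \linkS4class{PosteriorDraws} (needs >= 2 chains for
#'   \eqn{\hat R}).
#' @param rhatWarn threshold above which parameters are listed in the
#'   \code{"warnings"} attribute (default 1.1).
#' @return data.frame (parameter, rhat, ess, lag1) with a
#'   \code{"warnings"} attribute naming parameters with \eqn{\hat R}
#'   above the threshold. Constant parameters get NA diagnostics.
#' @export
convergenceDiagnostics <- function(draws, rhatWarn = 1.1) {
  stopifnot(is(draws, "PosteriorDraws"))
  chains <- unique(draws@chain)
  if (length(chains) < 2)
    stop("R-hat requires >= 2 chains")
  m <- posteriorMatrix(draws)
  out <- data.frame(parameter = colnames(m), rhat = NA_real_,
                    ess = NA_real_, lag1 = NA_real_)
  for (j in seq_len(ncol(m))) {
    per <- lapply(chains, function(ch) m[draws@chain == ch, j])
    n <- min(lengths(per))
    if (n < 4) next
    per <- lapply(per, function(v) v[seq_len(n)])
    if (sd(unlist(per)) == 0) next
    half <- n %/% 2
    split <- unlist(lapply(per, function(v)
      list(v[seq_len(half)], v[half + seq_len(half)])), recursive = FALSE)
    pooled <- unlist(split)
    rk <- rank(pooled, ties.method = "average")
    zv <- qnorm((rk - 3 / 8) / (length(rk) + 1 / 4))
    zs <- split(zv, rep(seq_along(split), each = half))
    mns <- vapply(zs, mean, 0); vrs <- vapply(zs, var, 0)
    W <- mean(vrs); B <- half * var(mns)
    varp <- (half - 1) / half * W + B / half
    out$rhat[j] <- sqrt(varp / W)
    ## combined autocovariance (Geyer initial positive sequence)
    maxLag <- half - 2
    acfs <- vapply(zs, function(v)
      as.numeric(acf(v, lag.max = maxLag, type = "covariance",
                     plot = FALSE, demean = TRUE)$acf), numeric(maxLag + 1))
    rho <- 1 - (W - rowMeans(acfs[-1, , drop = FALSE])) / varp
    psum <- 0; lag <- 1
    while (lag + 1 <= length(rho)) {
      pair <- rho[lag] + rho[lag + 1]
      if (pair < 0) break
      psum <- psum + pair
      lag <- lag + 2
    }
    out$ess[j] <- length(pooled) / (1 + 2 * psum)
    out$lag1[j] <- mean(vapply(per, function(v)
      acf(v, lag.max = 1, plot = FALSE)$acf[2], 0))
  }
  attr(out, "warnings") <-
    out$parameter[!is.na(out$rhat) & out$rhat > rhatWarn]
  out
}

#' Pool posterior draws across the scenario factorial
#'
#' Concatenates the retained draws of the four scenario fits (2 land-use
#' intensity scenarios x 2 Asian-colonization scenarios), keeping the
#' scenario labels, so summaries incorporate uncertainty in the model
#' assumptions.
#'
#' @param fits list of \linkS4class{PosteriorDraws}, one per scenario.
#' @param downsample logical; if TRUE, fits with unequal retention are
#'   down-sampled to the smallest count instead of erroring.
#' @return Pooled \linkS4class{PosteriorDraws}.
#' @export
poolScenarios <- function(fits, downsample = FALSE) {
  stopifnot(length(fits) >= 1,
            all(vapply(fits, is, TRUE, "PosteriorDraws")))
  ns <- vapply(fits, nDraws, 0L)
  if (length(unique(ns)) > 1) {
    if (!downsample)
      stop("unequal draw counts across scenarios (",
           paste(ns, collapse = ", "),
           "); rerun or set downsample = TRUE")
    keepN <- min(ns)
    fits <- lapply(fits, function(f) {
      idx <- seq_len(keepN)
      new("PosteriorDraws", draws = f@draws[idx, , drop = FALSE],
          chain = f@chain[idx], iter = f@iter[idx],
          z = if (!is.null(latentDraws(f)))
                f@z[idx, , , drop = FALSE] else f@z,
          scenario = f@scenario[idx], config = f@config)
    })
  }
  offs <- 0L; chain <- integer(0)
  for (f in fits) {
    chain <- c(chain, f@chain + offs)
    offs <- offs + max(f@chain)
  }
  zs <- lapply(fits, latentDraws)
  zarr <- if (all(!vapply(zs, is.null, TRUE))) {
    z <- do.call(abind3, zs)
    z
  } else array(0L, dim = c(0, 0, 0))
  new("PosteriorDraws",
      draws = do.call(rbind, lapply(fits, posteriorMatrix)),
      chain = chain,
      iter = unlist(lapply(fits, function(f) f@iter)),
      z = zarr,
      scenario = unlist(lapply(fits, function(f) f@scenario)),
      config = fits[[1]]@config)
}

## bind 3-d arrays along dim 1
abind3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  tot <- sum(vapply(parts, function(a) dim(a)[1], 0L))
  out <- array(0L, dim = c(tot, d[2], d[3]))
  at <- 0L
  for (a in parts) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

#' External colonization sources for the Asian-colonization scenario
#'
#' Realizes colonization pressure from outside the study grid as a strip
#' of permanently occupied ghost cells one grid unit east of the eastern
#' grid boundary: they contribute to every cell's connectivity (via the
#' LCP distance to the eastern edge plus one grid unit) but carry no
#' likelihood terms.
#'
#' @param distances LCP distance matrix over the grid cells (grid units).
#' @param nx,ny coarse grid dimensions (cells numbered x-fastest).
#' @param flag "yes" or "no".
#' @return A cells x ny source-distance matrix, or NULL when flag = "no".
#' @export
applyAsianColonizationScenario <- function(distances, nx, ny,
                                           flag = c("no", "yes")) {
  flag <- match.arg(flag)
  if (flag == "no") return(NULL)
  if (missing(nx) || missing(ny) || is.null(nx) || is.null(ny))
    stop("no eastern boundary strip defined: supply grid dimensions nx, ny")
  edge <- nx * seq_len(ny)            # eastern-edge cell ids
  as.matrix(distances)[, edge, drop = FALSE] + 1
}
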