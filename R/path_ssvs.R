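## Embedded Gaussian path analysis among covariates, spike-and-slab
## stochastic search variable selection (SSVS) with global slab
## adaptation, Bayes factors, and direct/indirect effect decomposition.

#' Default SSVS configuration
#'
#' Prior inclusion probability 0.5 for each of the 10 candidate paths;
#' spike precision \eqn{\tau_\beta = 3600} (spike sd 1/60); the shared slab
#' standard deviation is adapted globally under a Uniform(0, 20) prior;
#' paths are reported as selected when posterior inclusion exceeds 0.95.
#'
#' @return Named list of SSVS settings.
#' @export
ssvsConfig <- function() {
  list(priorInclusion = 0.5, spikePrecision = 3600, slabMax = 20,
       reportThreshold = 0.95)
}

#' Linear predictors of the three path regressions
#'
#' The path model links the covariates causally: elevation drives winter
#' temperature; winter temperature and elevation drive NPP; NPP, winter
#' temperature and elevation drive land use. Each regression carries a
#' grid-cell random effect to absorb spatial autocorrelation:
#' \deqn{\mu_{WT,s,t} = \beta_{WT,0} + \beta_{WT,ELE} ELE_{s,t} + cell_{WT,s}}
#' and analogously for NPP and LU.
#'
#' @param cov a standardized \linkS4class{CovariateStack}.
#' @param params named list with intercepts \code{wt0, npp0, lu0}, slopes
#'   \code{wt_ele, npp_wt, npp_ele, lu_npp, lu_wt, lu_ele}, and
#'   \code{cellEffects}, a list of numeric vectors \code{wt, npp, lu}
#'   (one entry per cell; zeros allowed).
#' @return List of cells x periods mean surfaces \code{muWT, muNPP, muLU}.
#' @export
pathMeans <- function(cov, params) {
  stopifnot(is(cov, "CovariateStack"))
  S <- nrow(cov@lu)
  ce <- params$cellEffects
  if (is.null(ce)) ce <- list(wt = numeric(S), npp = numeric(S),
                              lu = numeric(S))
  for (nm in c("wt", "npp", "lu"))
    if (length(ce[[nm]]) != S)
      stop(sprintf("cell random effect '%s' must have one entry per cell", nm))
  need <- c("wt0", "npp0", "lu0", "wt_ele", "npp_wt", "npp_ele",
            "lu_npp", "lu_wt", "lu_ele")
  miss <- setdiff(need, names(params))
  if (length(miss)) stop("missing path parameters: ",
                         paste(miss, collapse = ", "))
  muWT <- params$wt0 + params$wt_ele * cov@ele + ce$wt
  muNPP <- params$npp0 + params$npp_wt * cov@wt +
    params$npp_ele * cov@ele + ce$npp
  muLU <- params$lu0 + params$lu_npp * cov@npp + params$lu_wt * cov@wt +
    params$lu_ele * cov@ele + ce$lu
  list(muWT = muWT, muNPP = muNPP, muLU = muLU)
}

#' Spike-and-slab prior density of a regression coefficient
#'
#' Mixture prior \eqn{P(\beta_j | I_j) = (1 - I_j)\,N(0, \tau_\beta) +
#' I_j\,N(0, \sigma_{slab}^2)}, where \eqn{\tau_\beta = 3600} is the spike
#' precision (spike sd 1/60) and the slab sd is shared across all candidate
#' paths ("global adaptation") with an upper bound of 20.
#'
#' @param beta coefficient value(s).
#' @param I inclusion indicator, 0 (spike) or 1 (slab).
#' @param slabSd slab standard deviation, in (0, 20].
#' @param spikePrecision spike precision (default 3600).
#' @return Prior density at \code{beta}.
#' @export
ssvsPriorDensity <- function(beta, I, slabSd,
                             spikePrecision = ssvsConfig()$spikePrecision) {
  if (!all(I %in% c(0, 1))) stop("'I' must be binary")
  if (any(slabSd <= 0 | slabSd > ssvsConfig()$slabMax))
    stop("'slabSd' must lie in (0, 20]")
  spikeSd <- 1 / sqrt(spikePrecision)
  (1 - I) * dnorm(beta, 0, spikeSd) + I * dnorm(beta, 0, slabSd)
}

#' Gibbs update of an inclusion indicator
#'
#' Draws \eqn{I_j \mid \beta_j} from its exact Bernoulli full conditional
#' \deqn{P(I_j = 1 \mid \beta_j) = \frac{p\,N(\beta_j; 0, \sigma_{slab})}
#'   {p\,N(\beta_j; 0, \sigma_{slab}) + (1 - p)\,N(\beta_j; 0, 1/\sqrt{\tau_\beta})}.}
#'
#' @param beta current coefficient value(s) (vectorized).
#' @param slabSd shared slab sd.
#' @param priorInclusion prior inclusion probability (default 0.5).
#' @param spikePrecision spike precision (default 3600).
#' @return Integer 0/1 draw(s); uses the current R RNG stream.
#' @export
updateInclusionIndicator <- function(beta, slabSd, priorInclusion = 0.5,
                                     spikePrecision = ssvsConfig()$spikePrecision) {
  p1 <- inclusionProbability(beta, slabSd, priorInclusion, spikePrecision)
  as.integer(runif(length(beta)) < p1)
}

## P(I_j = 1 | beta_j), computed on the log scale for stability.
inclusionProbability <- function(beta, slabSd, priorInclusion = 0.5,
                                 spikePrecision = ssvsConfig()$spikePrecision) {
  spikeSd <- 1 / sqrt(spikePrecision)
  lSlab <- dnorm(beta, 0, slabSd, log = TRUE) + log(priorInclusion)
  lSpike <- dnorm(beta, 0, spikeSd, log = TRUE) + log1p(-priorInclusion)
  1 / (1 + exp(lSpike - lSlab))
}

#' Bayes factor for path inclusion
#'
#' Ratio of posterior to prior odds of a path's inclusion. The posterior
#' inclusion probability is clipped to \eqn{[1/(2M), 1 - 1/(2M)]} (M =
#' number of posterior samples) so paths that were always (or never)
#' included yield a large finite Bayes factor instead of infinity.
#'
#' @param postProb posterior inclusion probability (vectorized).
#' @param priorProb prior inclusion probability (default 0.5).
#' @param M number of posterior samples behind \code{postProb}.
#' @return Bayes factor(s).
#' @export
bayesFactor <- function(postProb, priorProb = 0.5, M = 1000) {
  if (any(postProb < 0 | postProb > 1)) stop("probabilities must be in [0,1]")
  p <- pmin(pmax(postProb, 1 / (2 * M)), 1 - 1 / (2 * M))
  (p / (1 - p)) / (priorProb / (1 - priorProb))
}

#' Size of the candidate model space
#'
#' With an inclusion indicator on each candidate path, the model space is
#' all subsets: \eqn{2^{n}} models (1024 for the 10 paths of the extinction
#' path model).
#'
#' @param nPaths number of candidate paths (default 10).
#' @return \code{2^nPaths}.
#' @export
enumerateModelSpace <- function(nPaths = 10) {
  if (nPaths < 0) stop("'nPaths' must be >= 0")
  2^nPaths
}

#' The ten candidate paths of the extinction path model
#'
#' Column names used for SSVS over the four extinction-rate slopes and the
#' six covariate path slopes.
#'
#' @return Character vector of 10 parameter names.
#' @export
candidatePaths <- function() {
  c("beta_phi_lu", "beta_phi_npp", "beta_phi_wt", "beta_phi_ele",
    "beta_wt_ele", "beta_npp_wt", "beta_npp_ele",
    "beta_lu_npp", "beta_lu_wt", "beta_lu_ele")
}

#' Direct and indirect effect decomposition
#'
#' Per posterior draw, arithmetic products of path slopes give the
#' mediated (indirect) effects on the extinction rate: for each
#' environmental variable X, indirect(X via LU) =
#' \eqn{\beta_{LU,X}\,\beta_{\phi,LU}} (the human-mediated pathway), and
#' for winter temperature additionally indirect(WT via NPP) =
#' \eqn{\beta_{NPP,WT}\,\beta_{\phi,NPP}} (the productivity pathway).
#' The "dampening" of the winter-temperature effect by NPP is reported per
#' draw as \eqn{100\,|\beta_{NPP,WT}\beta_{\phi,NPP}| / |\beta_{\phi,WT}|}
#' (percent of the direct effect; set \code{dampening = "total"} for the
#' alternative \eqn{100\,|indirect| / |direct + indirect|}). Draws with a
#' zero direct WT effect have undefined dampening and are excluded with
#' their count reported.
#'
#' @param draws matrix of posterior draws with (at least) the columns
#'   \code{\link{candidatePaths}}, or a \linkS4class{PosteriorDraws}.
#' @param dampening \code{"direct"} (default) or \code{"total"}.
#' @param probs credible-interval probabilities (default central 95\%).
#' @return List with \code{perDraw} (data.frame of per-draw effects),
#'   \code{summary} (mean and credible interval per effect) and
#'   \code{nDampeningExcluded}.
#' @export
decomposeEffects <- function(draws, dampening = c("direct", "total"),
                             probs = c(0.025, 0.975)) {
  dampening <- match.arg(dampening)
  if (is(draws, "PosteriorDraws")) draws <- posteriorMatrix(draws)
  need <- candidatePaths()
  miss <- setdiff(need, colnames(draws))
  if (length(miss)) stop("draws lack columns: ", paste(miss, collapse = ", "))
  d <- as.data.frame(draws[, need, drop = FALSE])
  eff <- data.frame(
    direct_lu = d$beta_phi_lu,
    direct_wt = d$beta_phi_wt,
    direct_npp = d$beta_phi_npp,
    direct_ele = d$beta_phi_ele,
    indirect_wt_via_lu = d$beta_lu_wt * d$beta_phi_lu,
    indirect_npp_via_lu = d$beta_lu_npp * d$beta_phi_lu,
    indirect_ele_via_lu = d$beta_lu_ele * d$beta_phi_lu,
    indirect_wt_via_npp = d$beta_npp_wt * d$beta_phi_npp)
  zero <- eff$direct_wt == 0
  damp <- rep(NA_real_, nrow(eff))
  if (dampening == "direct") {
    damp[!zero] <- 100 * abs(eff$indirect_wt_via_npp[!zero]) /
      abs(eff$direct_wt[!zero])
  } else {
    tot <- eff$direct_wt + eff$indirect_wt_via_npp
    zero <- zero | tot == 0
    damp[!zero] <- 100 * abs(eff$indirect_wt_via_npp[!zero]) /
      abs(tot[!zero])
  }
  eff$dampening_pct <- damp
  summ <- do.call(rbind, lapply(names(eff), function(nm) {
    v <- eff[[nm]][!is.na(eff[[nm]])]
    data.frame(effect = nm, mean = mean(v),
               ci_low = unname(quantile(v, probs[1])),
               ci_high = unname(quantile(v, probs[2])))
  }))
  list(perDraw = eff, summary = summ, nDampeningExcluded = sum(zero))
}

#' Conjugate-Gibbs SSVS for a Gaussian linear regression
#'
#' Reference implementation of spike-and-slab selection with global slab
#' adaptation on a single Gaussian regression \eqn{y = \beta_0 + X\beta +
#' \epsilon}: coefficient updates are conjugate normal given the
#' indicators, indicators follow their exact Bernoulli conditionals, the
#' residual precision is conjugate gamma, and the shared slab sd takes
#' reflected random-walk Metropolis steps under its Uniform(0, slabMax)
#' prior. The same update scheme drives the path block of the joint
#' sampler.
#'
#' @param y response vector.
#' @param X design matrix (candidate predictors; no intercept column).
#' @param nIter,burnIn,thin MCMC schedule.
#' @param seed integer seed.
#' @param priorOnly logical; if TRUE the likelihood is ignored so the
#'   chain samples the joint spike-slab prior (used to verify that the
#'   indicator Gibbs step leaves the prior invariant).
#' @param config SSVS settings, see \code{\link{ssvsConfig}}.
#' @return List with \code{draws} (matrix: intercept, coefficients,
#'   indicators, slab sd, residual sd), and \code{inclusion} (posterior
#'   inclusion probability per predictor).
#' @export
ssvsLinear <- function(y, X, nIter = 3000, burnIn = 1000, thin = 2,
                       seed = 1L, priorOnly = FALSE, config = ssvsConfig()) {
  X <- as.matrix(X); n <- nrow(X); k <- ncol(X)
  if (!priorOnly && length(y) != n) stop("length(y) != nrow(X)")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(k))
  set.seed(as.integer(seed))
  spikeVar <- 1 / config$spikePrecision
  b0 <- 0; beta <- rnorm(k, 0, 0.1); I <- rbinom(k, 1, config$priorInclusion)
  slabSd <- runif(1, 0.5, config$slabMax / 2); tau <- 1
  xtx <- colSums(X^2)
  keep <- seq(burnIn + thin, nIter, by = thin)
  out <- matrix(NA_real_, length(keep),  2 * k + 3)
  colnames(out) <- c("intercept", colnames(X), paste0("I_", colnames(X)),
                     "slab_sd", "sigma")
  row <- 0
  for (it in seq_len(nIter)) {
    if (!priorOnly) {
      resid <- y - b0 - X %*% beta
      ## intercept, diffuse N(0, 10^2)
      v <- 1 / (tau * n + 1 / 100)
      b0 <- rnorm(1, v * tau * sum(resid + b0), sqrt(v))
      resid <- y - b0 - X %*% beta
      for (j in seq_len(k)) {
        pv <- if (I[j] == 1) slabSd^2 else spikeVar
        rj <- resid + X[, j] * beta[j]
        v <- 1 / (tau * xtx[j] + 1 / pv)
        m <- v * tau * sum(X[, j] * rj)
        beta[j] <- rnorm(1, m, sqrt(v))
        resid <- rj - X[, j] * beta[j]
      }
      tau <- rgamma(1, 0.1 + n / 2, 0.1 + sum(resid^2) / 2)
    } else {
      pv <- ifelse(I == 1, slabSd^2, spikeVar)
      beta <- rnorm(k, 0, sqrt(pv))
    }
    I <- updateInclusionIndicator(beta, slabSd, config$priorInclusion,
                                  config$spikePrecision)
    ## shared slab sd: reflected RW-MH under Uniform(0, slabMax)
    prop <- slabSd + rnorm(1, 0, 1)
    if (prop < 0) prop <- -prop
    if (prop > config$slabMax) prop <- 2 * config$slabMax - prop
    if (prop > 0 && prop <= config$slabMax) {
      inc <- which(I == 1)
      logr <- sum(dnorm(beta[inc], 0, prop, log = TRUE)) -
        sum(dnorm(beta[inc], 0, slabSd, log = TRUE))
      if (log(runif(1)) < logr) slabSd <- prop
    }
    if (it %in% keep) {
      row <- row + 1
      out[row, ] <- c(b0, beta, I, slabSd, 1 / sqrt(tau))
    }
  }
  inc <- colMeans(out[, paste0("I_", colnames(X)), drop = FALSE])
  list(draws = out, inclusion = setNames(as.numeric(inc), colnames(X)))
}
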