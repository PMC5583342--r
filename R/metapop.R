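## State-space metapopulation model primitives: rate regressions, the
## Kolmogorov rate -> probability mapping over unequal intervals,
## dispersal-kernel connectivity, and the detection model.

#' Extinction rate from standardized covariates
#'
#' Log-linear extinction-rate regression
#' \deqn{\log r_\phi = \beta_0 + \beta_{LU} LU + \beta_{NPP} NPP +
#'       \beta_{WT} WT + \beta_{ELE} ELE.}
#' Covariates are expected on the standardized scale (see
#' \code{\link{standardizeCovariates}}), so slopes are standardized effect
#' sizes.
#'
#' @param cov numeric matrix with columns \code{lu, npp, wt, ele} (rows are
#'   cell-periods), or a named numeric vector for a single cell-period.
#' @param beta numeric length 5: intercept then slopes for
#'   \code{lu, npp, wt, ele}.
#' @return Extinction rate(s) per year, strictly positive.
#' @export
extinctionRate <- function(cov, beta) {
  if (is.null(dim(cov))) cov <- matrix(cov, nrow = 1,
                                       dimnames = list(NULL, names(cov)))
  cov <- as.matrix(cov)[, c("lu", "npp", "wt", "ele"), drop = FALSE]
  if (any(!is.finite(cov))) stop("non-finite covariate values")
  if (length(beta) != 5 || any(!is.finite(beta)))
    stop("'beta' must be 5 finite values (intercept, lu, npp, wt, ele)")
  as.numeric(exp(beta[1] + cov %*% beta[-1]))
}

#' Dispersal-kernel connectivity
#'
#' Distance-discounted exposure of each cell to occupied source cells,
#' \deqn{S_s = \sum_{s' \ne s} e^{-\alpha d_{s,s'}} z_{s'},}
#' with a negative-exponential kernel whose mean dispersal distance is
#' \eqn{1/\alpha} (grid units). Optional permanently occupied external
#' sources (e.g. a continental-boundary strip) add
#' \eqn{\sum_k e^{-\alpha d_{s,k}}}.
#'
#' @param z binary occupancy vector for one period (length = cells), or a
#'   cells x periods matrix (connectivity computed per column).
#' @param d symmetric distance matrix with zero diagonal, grid units.
#' @param alpha inverse mean dispersal distance, per grid unit, > 0.
#' @param sourceDist optional matrix (cells x n_sources) of distances to
#'   permanently occupied external source cells.
#' @return Connectivity: vector or matrix matching \code{z}.
#' @export
connectivity <- function(z, d, alpha, sourceDist = NULL) {
  d <- as.matrix(d)
  zm <- if (is.null(dim(z))) matrix(z, ncol = 1) else as.matrix(z)
  if (nrow(zm) != nrow(d) || nrow(d) != ncol(d))
    stop("dimension mismatch between 'z' and distance matrix")
  if (!isTRUE(alpha > 0)) stop("'alpha' must be > 0")
  K <- exp(-alpha * d)
  diag(K) <- 0                       # exclude self
  K[!is.finite(d)] <- 0              # disconnected components contribute 0
  S <- K %*% zm
  if (!is.null(sourceDist)) {
    src <- rowSums(exp(-alpha * as.matrix(sourceDist)))
    S <- S + src
  }
  if (is.null(dim(z))) as.numeric(S) else S
}

#' Colonization rate from connectivity
#'
#' Log-link colonization rate \eqn{\log r_\gamma = \beta_{\gamma,0} +
#' \lambda S_s}. The scaling constant \eqn{\lambda} is fixed to 1 by
#' default (it is redundant with the extinction-rate intercept and is not
#' estimated). As printed, the model has no colonization intercept, so a
#' fully isolated cell (\eqn{S = 0}) has \eqn{r_\gamma = 1} per year;
#' \code{intercept} allows overriding this but defaults to 0.
#'
#' @param S connectivity value(s), non-negative.
#' @param lambda connectivity scaling constant (default 1).
#' @param intercept optional colonization log-rate intercept (default 0).
#' @return Colonization rate(s) per year.
#' @export
colonizationRate <- function(S, lambda = 1, intercept = 0) {
  if (any(S < 0)) stop("connectivity must be non-negative")
  exp(intercept + lambda * S)
}

#' Map per-year rates to per-interval transition probabilities
#'
#' The occupancy process is a two-state continuous-time Markov chain with
#' colonization rate \eqn{r_\gamma} (empty -> occupied) and extinction rate
#' \eqn{r_\phi} (occupied -> empty). Because study periods are unequal,
#' per-interval transition probabilities follow Kolmogorov's forward
#' equations (equivalently the matrix exponential of the generator):
#' \deqn{p_\gamma = 1 - (r_\phi + r_\gamma e^{-(r_\phi + r_\gamma)\Delta t})
#'   / (r_\phi + r_\gamma)}
#' and symmetrically for \eqn{p_\phi}. A first-order Taylor form is used
#' when \eqn{(r_\phi + r_\gamma)\Delta t < 10^{-12}} to avoid 0/0.
#'
#' @param rPhi,rGamma extinction and colonization rates per year, > 0
#'   (vectorized).
#' @param dt interval length in years, >= 0.
#' @return List with components \code{pPhi} and \code{pGamma} in [0, 1].
#' @export
ratesToProbabilities <- function(rPhi, rGamma, dt) {
  if (any(dt < 0)) stop("'dt' must be non-negative")
  if (any(rPhi <= 0) || any(rGamma <= 0))
    stop("rates must be strictly positive")
  r <- rPhi + rGamma
  tiny <- (r * dt) < 1e-12
  grow <- -expm1(-r * dt)            # 1 - exp(-(r)dt), accurate near 0
  pGamma <- rGamma / r * grow
  pPhi <- rPhi / r * grow
  if (any(tiny)) {
    pGamma[tiny] <- (rGamma * dt)[tiny]
    pPhi[tiny] <- (rPhi * dt)[tiny]
  }
  list(pPhi = pmin(pmax(pPhi, 0), 1), pGamma = pmin(pmax(pGamma, 0), 1))
}

#' One-step occupancy transition probability
#'
#' Success probability of the Bernoulli occupancy state at the next period:
#' persistence \eqn{1 - p_\phi} if the cell is occupied, colonization
#' \eqn{p_\gamma} if it is empty:
#' \deqn{\mu_{z,t+1} = z_t (1 - p_\phi) + (1 - z_t) p_\gamma.}
#'
#' @param z current occupancy (0/1, vectorized).
#' @param pPhi,pGamma per-interval extinction and colonization
#'   probabilities in [0, 1].
#' @return Occupancy success probability \eqn{\mu \in [0, 1]}.
#' @export
occupancyTransition <- function(z, pPhi, pGamma) {
  if (any(pPhi < 0 | pPhi > 1) || any(pGamma < 0 | pGamma > 1))
    stop("transition probabilities must lie in [0, 1]")
  z * (1 - pPhi) + (1 - z) * pGamma
}

#' Record-level detection probability
#'
#' Logit-linear detection model for an archaeofaunal record:
#' \deqn{\mathrm{logit}(p_i) = \beta_{p,0} + \beta_{p,NSP} \log(NSP_i) +
#'   \beta_{p,TYP[i]},}
#' where \eqn{NSP} is the total number of bone remains in the record
#' (natural log) and the site-type effect uses reference coding with
#' "settlement" (the most frequent type) fixed at 0.
#'
#' @param nsp total bone count(s), integer >= 1.
#' @param type site type(s); see \code{\link{siteTypes}}.
#' @param beta list with elements \code{intercept}, \code{nsp} and
#'   \code{type} (named numeric over \code{siteTypes()}, reference
#'   "settlement" = 0).
#' @return Detection probability in (0, 1).
#' @export
detectionProbability <- function(nsp, type, beta) {
  if (any(!is.finite(nsp) | nsp < 1)) stop("NSP must be >= 1")
  type <- as.character(type)
  offs <- detectionTypeOffsets(beta)
  if (any(!(type %in% names(offs))))
    stop("unknown site type; impute before computing detection probability")
  unname(plogis(beta$intercept + beta$nsp * log(nsp) + offs[type]))
}

## Normalize a detection-coefficient list into full named type offsets.
detectionTypeOffsets <- function(beta) {
  offs <- setNames(numeric(length(siteTypes())), siteTypes())
  if (!is.null(beta$type)) {
    if (is.null(names(beta$type))) stop("type offsets must be named")
    offs[names(beta$type)] <- beta$type
  }
  if (abs(offs["settlement"]) > 1e-12)
    stop("reference site type 'settlement' must have offset 0")
  offs
}

#' Observation-model log-likelihood
#'
#' Bernoulli likelihood of detection outcomes conditional on latent
#' occupancy: \eqn{y_i \sim \mathrm{Bernoulli}(z_{s[i],t[i]} p_i)}. In
#' perfect-detection periods (map-informed) \eqn{p = 1}, so any mismatch
#' between y and z — and any detection in an unoccupied cell — yields
#' \code{-Inf}.
#'
#' @param records an \linkS4class{ArchRecords} or the equivalent
#'   data.frame.
#' @param z cells x periods binary occupancy matrix.
#' @param p detection probability per record (recycled); ignored (taken as
#'   1) for records in \code{perfectPeriods}.
#' @param perfectPeriods integer vector of perfectly detected periods.
#' @return Scalar log-likelihood (possibly \code{-Inf}).
#' @export
observationLogLik <- function(records, z, p, perfectPeriods = integer(0)) {
  d <- if (is(records, "ArchRecords")) recordData(records) else records
  z <- as.matrix(z)
  if (any(d$cell_id < 1 | d$cell_id > nrow(z)))
    stop("record references unknown cell")
  if (any(d$period < 1 | d$period > ncol(z)))
    stop("record references unknown period")
  p <- rep_len(p, nrow(d))
  p[d$period %in% perfectPeriods] <- 1
  zi <- z[cbind(d$cell_id, d$period)]
  pr <- zi * p                              # P(y = 1)
  ll <- ifelse(d$detected == 1, log(pr), log1p(-pr))
  sum(ll)
}

#' Forward-simulate latent occupancy dynamics
#'
#' Simulates the occupancy lattice forward through the period scheme:
#' initial states are iid Bernoulli(\eqn{\psi_1}); thereafter extinction
#' rates come from the covariate regression, colonization rates from
#' dispersal-kernel connectivity to currently occupied cells, and rates are
#' mapped to per-interval probabilities via the Kolmogorov forward
#' equations.
#'
#' @param covariates a standardized \linkS4class{CovariateStack}.
#' @param betaPhi extinction-rate coefficients (length 5; see
#'   \code{\link{extinctionRate}}).
#' @param dispersal list with \code{alpha} (> 0), optional \code{lambda}
#'   (default 1) and optional \code{gamma0} colonization intercept
#'   (default 0).
#' @param psi1 initial occupancy probability.
#' @param distances symmetric LCP distance matrix (grid units).
#' @param seed integer seed (reproducible).
#' @param sourceDist optional external-source distance matrix; see
#'   \code{\link{connectivity}}.
#' @return An \linkS4class{OccupancyLattice}.
#' @export
simulateOccupancy <- function(covariates, betaPhi, dispersal, psi1,
                              distances, seed = 1L, sourceDist = NULL) {
  stopifnot(is(covariates, "CovariateStack"))
  scheme <- covariates@scheme
  S <- nrow(covariates@lu); T <- nPeriods(scheme)
  lambda <- if (is.null(dispersal$lambda)) 1 else dispersal$lambda
  gamma0 <- if (is.null(dispersal$gamma0)) 0 else dispersal$gamma0
  X <- covariateMatrix(covariates)
  rPhi <- matrix(extinctionRate(X, betaPhi), S, T)
  set.seed(as.integer(seed))
  z <- matrix(0L, S, T)
  z[, 1] <- rbinom(S, 1, psi1)
  for (t in seq_len(T - 1)) {
    Sc <- connectivity(z[, t], distances, dispersal$alpha, sourceDist)
    rG <- colonizationRate(Sc, lambda, gamma0)
    pr <- ratesToProbabilities(rPhi[, t], rG, deltaT(scheme)[t])
    mu <- occupancyTransition(z[, t], pr$pPhi, pr$pGamma)
    z[, t + 1] <- rbinom(S, 1, mu)
  }
  occupancyLattice(z, scheme, psi1)
}
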