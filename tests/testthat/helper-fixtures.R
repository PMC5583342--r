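# Shared fixtures: tiny schemes, records and stacks built in code.

toyScheme <- function(T = 3, len = 50, gap = 50) {
  st <- seq(0, by = len + gap, length.out = T)
  periodScheme(cbind(st, st + len))
}

paperScheme <- function() periodScheme(holocenePeriods())

toyRecords <- function(df = NULL) {
  base <- data.frame(
    record_id = 1:3, site_id = c("a", "b", "c"),
    site_type = "settlement", period = c(1, 2, 2),
    cell_id = c(1, 1, 2), nsp_total = c(5, 2, 7),
    detected = c(0, 1, 0))
  if (!is.null(df)) base <- df
  archRecords(base)
}

zeroStack <- function(S, T, scheme = NULL) {
  if (is.null(scheme)) scheme <- toyScheme(T)
  standardizeCovariates(covariateStack(
    matrix(0, S, T), matrix(0, S, T), matrix(0, S, T), matrix(0, S, T),
    scheme))
}

# independent O(V^2) Dijkstra for the LCP oracle
dijkstraRef <- function(adj, n, from) {
  dist <- rep(Inf, n); dist[from] <- 0; done <- rep(FALSE, n)
  for (k in seq_len(n)) {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    for (e in adj[[u]])
      if (dist[u] + e[2] < dist[e[1]]) dist[e[1]] <- dist[u] + e[2]
  }
  dist
}

# 2-state CTMC transition probabilities via matrix exponential (oracle)
expmProbs <- function(rPhi, rGamma, dt) {
  Q <- matrix(c(-rGamma, rGamma, rPhi, -rPhi), 2, 2, byrow = TRUE)
  P <- as.matrix(Matrix::expm(Q * dt))
  list(pPhi = P[2, 1], pGamma = P[1, 2])
}

# brute-force posterior over all occupancy histories of a tiny lattice
enumerateToyPosterior <- function(S, T, scheme, d, alpha, psi1, rPhi,
                                  records, p) {
  states <- as.matrix(expand.grid(rep(list(0:1), S * T)))
  lp <- numeric(nrow(states))
  for (k in seq_len(nrow(states))) {
    z <- matrix(states[k, ], S, T)
    l <- sum(dbinom(z[, 1], 1, psi1, log = TRUE))
    for (t in seq_len(T - 1)) {
      Sc <- connectivity(z[, t], d, alpha)
      pr <- ratesToProbabilities(rPhi[, t], colonizationRate(Sc),
                                 deltaT(scheme)[t])
      mu <- occupancyTransition(z[, t], pr$pPhi, pr$pGamma)
      l <- l + sum(dbinom(z[, t + 1], 1, mu, log = TRUE))
    }
    l <- l + observationLogLik(records, z, p)
    lp[k] <- l
  }
  w <- exp(lp - max(lp)); w <- w / sum(w)
  marg <- matrix(0, S, T)
  for (k in seq_len(nrow(states)))
    marg <- marg + w[k] * matrix(states[k, ], S, T)
  marg
}
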