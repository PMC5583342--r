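## Environmental covariate derivation: Miami NPP, wintering-season
## temperature, anomaly calibration, period aggregation, LCP distances.

#' Miami-model net primary productivity
#'
#' Empirical first-order NPP model: the minimum of a temperature-limited and
#' a precipitation-limited productivity rate,
#' \deqn{NPP = \min\{3000 (1 + e^{1.315 - 0.119 T})^{-1},\;
#'       3000 (1 - e^{-0.000664 P})\}}
#' with mean annual temperature \eqn{T} (degrees C) and total annual
#' precipitation \eqn{P} (mm/yr). Both limiting rates share the 3000
#' g dry matter m^-2 a^-1 asymptote; the result is monotone non-decreasing
#' in both arguments and lies in [0, 3000).
#'
#' @param temp mean annual temperature, degrees C (vectorized).
#' @param precip total annual precipitation, mm/yr, non-negative.
#' @param limit which rate to return: the minimum (default), or one of the
#'   two limiting rates alone.
#' @return NPP in g dry matter m^-2 a^-1.
#' @examples
#' miamiNPP(10, 1000)            # precipitation not limiting here
#' miamiNPP(30, 1e9, "precipitation")  # ~ 3000 asymptote
#' @export
miamiNPP <- function(temp, precip,
                     limit = c("minimum", "temperature", "precipitation")) {
  limit <- match.arg(limit)
  if (any(!is.finite(temp)))
    stop("non-finite value in 'temp' (mean annual temperature)")
  if (any(!is.finite(precip)))
    stop("non-finite value in 'precip' (total annual precipitation)")
  if (any(precip < 0)) stop("'precip' must be non-negative")
  nppT <- 3000 / (1 + exp(1.315 - 0.119 * temp))
  nppP <- 3000 * (1 - exp(-0.000664 * precip))
  switch(limit, minimum = pmin(nppT, nppP), temperature = nppT,
         precipitation = nppP)
}

#' Class "ClimateSeries": annual climate series for one grid cell
#'
#' Calendar years are signed (BCE negative). Total annual precipitation
#' must be non-negative and all fields share one length; times increase
#' strictly.
#'
#' @slot cellId integer cell id.
#' @slot times numeric calendar years.
#' @slot temp mean annual temperature (degrees C).
#' @slot precip total annual precipitation (mm/yr).
#' @slot winterTemp mean winter temperature (degrees C).
#' @export
setClass("ClimateSeries",
  representation(cellId = "integer", times = "numeric", temp = "numeric",
                 precip = "numeric", winterTemp = "numeric"))

setValidity("ClimateSeries", function(object) {
  n <- length(object@times)
  if (length(object@temp) != n || length(object@precip) != n ||
      length(object@winterTemp) != n)
    return("all series must have the same length")
  if (n > 1 && any(diff(object@times) <= 0))
    return("times must be strictly increasing")
  if (any(object@precip < 0)) return("precipitation must be >= 0")
  TRUE
})

#' Construct an annual climate series
#'
#' @param cellId grid cell id.
#' @param times calendar years (BCE negative), strictly increasing.
#' @param temp mean annual temperatures (C).
#' @param precip total annual precipitations (mm/yr), >= 0.
#' @param winterTemp mean winter temperatures (C); defaults to NA.
#' @return A \linkS4class{ClimateSeries}.
#' @export
climateSeries <- function(cellId, times, temp, precip,
                          winterTemp = rep(NA_real_, length(times))) {
  new("ClimateSeries", cellId = as.integer(cellId),
      times = as.numeric(times), temp = as.numeric(temp),
      precip = as.numeric(precip), winterTemp = as.numeric(winterTemp))
}

setMethod("show", "ClimateSeries", function(object) {
  cat(sprintf("ClimateSeries for cell %d: %d years (%g to %g)\n",
              object@cellId, length(object@times), min(object@times),
              max(object@times)))
})

#' Monthly climate summary for one location
#'
#' @param meanTemp,maxTemp 12 monthly mean and maximum temperatures (C).
#' @param precip optional 12 monthly precipitation totals (mm).
#' @return A validated list of class \code{"MonthlyClimate"}.
#' @export
monthlyClimate <- function(meanTemp, maxTemp, precip = NULL) {
  if (length(meanTemp) != 12 || length(maxTemp) != 12)
    stop("exactly 12 monthly values required")
  if (!is.null(precip) && length(precip) != 12)
    stop("exactly 12 monthly precipitation values required")
  if (any(maxTemp < meanTemp - 1e-9))
    stop("monthly maximum temperature below monthly mean")
  structure(list(meanTemp = as.numeric(meanTemp),
                 maxTemp = as.numeric(maxTemp),
                 precip = if (is.null(precip)) NULL else as.numeric(precip)),
            class = "MonthlyClimate")
}

#' Wintering-season temperature
#'
#' Mean of the monthly mean temperatures over the months whose maximum
#' monthly temperature is below 0 C (matching denning phenology: bears
#' enter and exit the den at roughly 0 C). If no month qualifies (no
#' climatic winter), the coldest monthly mean is returned and the result
#' carries attribute \code{noWinter = TRUE} so downstream analyses can
#' drop or keep such populations explicitly.
#'
#' @param mc a \code{\link{monthlyClimate}} object.
#' @return Wintering-season temperature (C) with a \code{noWinter}
#'   attribute.
#' @export
winteringTemperature <- function(mc) {
  if (!inherits(mc, "MonthlyClimate")) stop("'mc' must be a MonthlyClimate")
  winter <- mc$maxTemp < 0
  if (any(winter))
    structure(mean(mc$meanTemp[winter]), noWinter = FALSE)
  else
    structure(min(mc$meanTemp), noWinter = TRUE)
}

#' Period-weighted aggregation of a time series
#'
#' Averages a series of interval-stamped values into the study periods.
#' Source time steps whose nominal timestamp coincides with a period
#' boundary ("margin" steps) receive half the weight of steps in the core
#' of a period; weights are renormalized to sum to one within each period.
#'
#' @param times numeric, nominal timestamps (signed calendar years) of the
#'   source series, or a \linkS4class{ClimateSeries} (its temperature,
#'   precipitation and winter-temperature fields are then aggregated
#'   jointly and \code{values} is ignored).
#' @param values numeric vector (same length as \code{times}) or matrix with
#'   one row per timestamp (e.g. one column per cell).
#' @param scheme a \linkS4class{PeriodScheme}; every period must be covered
#'   by at least one timestamp.
#' @return Per-period weighted means: a vector, or a periods x columns
#'   matrix when \code{values} is a matrix.
#' @export
aggregateToPeriods <- function(times, values, scheme) {
  stopifnot(is(scheme, "PeriodScheme"))
  if (is(times, "ClimateSeries")) {
    cs <- times
    out <- aggregateToPeriods(cs@times,
                              cbind(temp = cs@temp, precip = cs@precip,
                                    winter_temp = cs@winterTemp), scheme)
    colnames(out) <- c("temp", "precip", "winter_temp")
    return(out)
  }
  vec <- is.null(dim(values))
  vals <- if (vec) matrix(values, ncol = 1) else as.matrix(values)
  if (length(times) != nrow(vals))
    stop("'times' and 'values' length mismatch")
  nT <- nPeriods(scheme)
  out <- matrix(NA_real_, nT, ncol(vals))
  for (t in seq_len(nT)) {
    lo <- scheme@start[t]; hi <- scheme@end[t]
    inP <- which(times >= lo - 1e-9 & times <= hi + 1e-9)
    if (!length(inP))
      stop(sprintf("period %d (%g to %g) covered by no time interval",
                   t, lo, hi))
    w <- ifelse(abs(times[inP] - lo) < 1e-9 | abs(times[inP] - hi) < 1e-9,
                0.5, 1)
    w <- w / sum(w)
    out[t, ] <- as.numeric(crossprod(w, vals[inP, , drop = FALSE]))
  }
  if (vec) drop(out) else out
}

#' Calibrate climate anomalies against a recent baseline
#'
#' Pollen-based reconstructions are reported as anomalies relative to the
#' late preindustrial baseline; this converts them to absolute values by
#' adding the 31-year running average of a recent annually resolved series
#' centred on the baseline year.
#'
#' @param recentTimes,recentValues annually resolved recent series; values
#'   may be a matrix with one row per year (e.g. one column per cell).
#' @param anomalies anomaly value(s) to calibrate; a vector or matrix whose
#'   columns align with \code{recentValues} columns.
#' @param baselineYear centre of the 31-year window (default 1850 CE).
#' @return \code{anomalies} + baseline running mean (recycled over rows of
#'   a matrix of anomalies).
#' @export
calibrateAnomalies <- function(recentTimes, recentValues, anomalies,
                               baselineYear = 1850) {
  window <- (baselineYear - 15):(baselineYear + 15)
  idx <- match(window, recentTimes)
  if (any(is.na(idx)))
    stop(sprintf(
      "recent series does not cover the 31-year window %d-%d around %d",
      baselineYear - 15, baselineYear + 15, baselineYear))
  if (is.null(dim(recentValues))) {
    base <- mean(recentValues[idx])
    anomalies + base
  } else {
    base <- colMeans(as.matrix(recentValues)[idx, , drop = FALSE])
    sweep(as.matrix(anomalies), 2, base, `+`)
  }
}

#' Least-cost-path dispersal distances between coarse grid cells
#'
#' Builds an 8-neighbour graph over the land cells of the fine elevation
#' lattice; the cost of a step is its planar length times
#' \eqn{1 + |\Delta elev| / \Delta planar} (a simple monotone terrain
#' penalty), water is impassable, and shortest paths are found by
#' Dijkstra's algorithm. Each coarse cell is represented by the land fine
#' cell nearest its centre; coarse cells without land get infinite
#' distances. Distances are returned in multiples of the coarse cell size,
#' so a value of 1 means "one grid cell away" and the dispersal parameter
#' \eqn{\alpha} is in inverse grid units.
#'
#' @param terrain a \linkS4class{TerrainGrid}.
#' @return Symmetric \code{nCells x nCells} matrix with zero diagonal;
#'   \code{Inf} between disconnected land components.
#' @export
lcpDistances <- function(terrain) {
  stopifnot(is(terrain, "TerrainGrid"))
  water <- terrain@water
  if (all(water)) stop("all-water grid: no land cells to connect")
  elev <- terrain@elevation
  nr <- nrow(elev); nc <- ncol(elev)
  stepKm <- terrain@fineKm
  land <- which(!water)                   # column-major fine indices
  if (length(land) < 2) stop("fewer than 2 land fine cells")
  nodeId <- matrix(NA_integer_, nr, nc)
  nodeId[land] <- seq_along(land)

  ## edges to E, S, SE, SW neighbours (undirected graph)
  rr <- ((land - 1) %% nr) + 1
  cc <- ((land - 1) %/% nr) + 1
  edges <- list(); wts <- list(); k <- 0
  for (off in list(c(0, 1, 1), c(1, 0, 1), c(1, 1, sqrt(2)),
                   c(1, -1, sqrt(2)))) {
    r2 <- rr + off[1]; c2 <- cc + off[2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    to <- ifelse(ok, nodeId[cbind(pmin(pmax(r2, 1), nr),
                                  pmin(pmax(c2, 1), nc))],
                 NA_integer_)
    ok <- ok & !is.na(to)
    if (!any(ok)) next
    planar <- stepKm * off[3]
    dz <- abs(elev[cbind(r2[ok], c2[ok])] - elev[cbind(rr[ok], cc[ok])])
    k <- k + 1
    edges[[k]] <- rbind(nodeId[cbind(rr[ok], cc[ok])], to[ok])
    wts[[k]] <- planar * (1 + dz / planar)
  }
  g <- igraph::make_graph(edges = as.numeric(do.call(cbind, edges)),
                          n = length(land), directed = FALSE)
  igraph::E(g)$weight <- unlist(wts)

  ## representative fine node per coarse cell: land cell nearest the centre
  f <- round(terrain@cellKm / terrain@fineKm)
  S <- nCells(terrain)
  rep_node <- rep(NA_integer_, S)
  for (cell in seq_len(S)) {
    ix <- ((cell - 1) %% terrain@nx) + 1
    iy <- ((cell - 1) %/% terrain@nx) + 1
    rows <- ((iy - 1) * f + 1):(iy * f); cols <- ((ix - 1) * f + 1):(ix * f)
    sub <- !water[rows, cols, drop = FALSE]
    if (!any(sub)) next
    landIdx <- which(sub, arr.ind = TRUE)
    ctr <- (f + 1) / 2
    best <- which.min((landIdx[, 1] - ctr)^2 + (landIdx[, 2] - ctr)^2)
    rep_node[cell] <- nodeId[rows[landIdx[best, 1]], cols[landIdx[best, 2]]]
  }
  d <- matrix(Inf, S, S)
  has <- which(!is.na(rep_node))
  dk <- igraph::distances(g, v = rep_node[has], to = rep_node[has],
                          weights = igraph::E(g)$weight,
                          algorithm = "dijkstra")
  d[has, has] <- dk / terrain@cellKm
  diag(d) <- 0
  d
}
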