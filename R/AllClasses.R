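#' @import methods
#' @importFrom stats rnorm runif rbinom rpois rgamma rlnorm dnorm dgamma
#'   plogis qlogis sd var quantile median lm coef resid filter acf setNames
#'   complete.cases aggregate rmultinom
#' @importFrom utils read.csv write.csv head
#' @useDynLib archeopop, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Excavation-site types
#'
#' The seven known excavation-site categories used by the detection model,
#' in decreasing order of frequency in a typical archaeofaunal compilation.
#' \code{"settlement"} is the reference level of the site-type effect;
#' \code{"unknown"} marks records whose type is imputed during inference and
#' \code{"range_map"} marks rows that encode perfectly detected contemporary
#' range maps rather than excavation records.
#'
#' @return Character vector of the seven site types.
#' @export
siteTypes <- function() {
  c("settlement", "castle", "cave", "burial", "midden", "cult",
    "moor_riverbed")
}

.specialTypes <- c("unknown", "range_map")

## ---------------------------------------------------------------------------
## PeriodScheme
## ---------------------------------------------------------------------------

#' Class "PeriodScheme": ordered study periods on a continuous calendar axis
#'
#' Calendar years are signed (BCE negative, CE positive) on a continuous
#' axis without a year-zero adjustment. Transition intervals \eqn{\Delta t}
#' are differences between consecutive period midpoints.
#'
#' @slot start numeric, period start years.
#' @slot end numeric, period end years.
#' @slot midpoints numeric, \code{(start + end) / 2}.
#' @slot dt numeric, length \code{nPeriods - 1}; midpoint differences.
#' @export
setClass("PeriodScheme",
  representation(start = "numeric", end = "numeric",
                 midpoints = "numeric", dt = "numeric"))

setValidity("PeriodScheme", function(object) {
  n <- length(object@start)
  if (length(object@end) != n) return("start/end length mismatch")
  if (n < 1) return("at least one period required")
  if (any(object@end <= object@start)) return("period end must exceed start")
  if (n > 1 && any(object@start[-1] < object@end[-n]))
    return("periods overlap or are unordered")
  if (any(abs(object@midpoints - (object@start + object@end) / 2) > 1e-9))
    return("midpoints inconsistent with boundaries")
  if (n > 1 && any(object@dt <= 0)) return("all dt must be positive")
  TRUE
})

#' Construct a period scheme from period boundaries
#'
#' @param boundaries a two-column matrix/data.frame of (start, end) calendar
#'   years, or a list of length-2 numeric vectors. BCE years are negative.
#' @return A \linkS4class{PeriodScheme}.
#' @examples
#' ps <- periodScheme(holocenePeriods())
#' deltaT(ps)   # 3500 3500 2250 900 310 52.5
#' @export
periodScheme <- function(boundaries) {
  if (is.list(boundaries) && !is.data.frame(boundaries))
    boundaries <- do.call(rbind, boundaries)
  boundaries <- as.matrix(boundaries)
  if (ncol(boundaries) != 2)
    stop("'boundaries' must have two columns (start, end)")
  if (any(!is.finite(boundaries))) stop("non-finite period boundaries")
  s <- as.numeric(boundaries[, 1]); e <- as.numeric(boundaries[, 2])
  if (is.unsorted(s, strictly = TRUE))
    stop("period boundaries must be ordered by start year")
  mid <- (s + e) / 2
  new("PeriodScheme", start = s, end = e, midpoints = mid,
      dt = if (length(mid) > 1) diff(mid) else numeric(0))
}

#' The seven Holocene study periods
#'
#' Boundaries of the seven analysis periods spanning 10000 BCE to 2015 CE
#' (10000--7000 BCE, 7000--3000 BCE, 3000 BCE--0 CE, 0--1500 CE,
#' 1500--1800 CE, 1950--1970 CE, 2010--2015 CE).
#'
#' @return A 7 x 2 matrix of (start, end) signed calendar years.
#' @export
holocenePeriods <- function() {
  cbind(start = c(-10000, -7000, -3000, 0, 1500, 1950, 2010),
        end   = c(-7000, -3000, 0, 1500, 1800, 1970, 2015))
}

#' @describeIn periodScheme Number of periods.
#' @param x,object a \code{PeriodScheme}.
#' @export
nPeriods <- function(x) length(x@start)

#' @describeIn periodScheme Midpoint calendar years.
#' @export
midpoints <- function(x) x@midpoints

#' @describeIn periodScheme Transition interval lengths (years).
#' @export
deltaT <- function(x) x@dt

setMethod("show", "PeriodScheme", function(object) {
  cat("PeriodScheme with", nPeriods(object), "periods\n")
  cat("  midpoints:", paste(format(object@midpoints), collapse = ", "), "\n")
  if (length(object@dt))
    cat("  dt:", paste(format(object@dt), collapse = ", "), "years\n")
})

## ---------------------------------------------------------------------------
## TerrainGrid
## ---------------------------------------------------------------------------

#' Class "TerrainGrid": coarse analysis grid over a fine elevation lattice
#'
#' The analysis (coarse) grid has \code{nx} x \code{ny} square cells of side
#' \code{cellKm}. Elevation and the water mask live on a finer lattice of
#' side \code{fineKm} used for least-cost-path dispersal distances.
#' Fine matrices are indexed \code{[row = y, col = x]}.
#'
#' @slot nx,ny integer, coarse grid dimensions.
#' @slot cellKm numeric, coarse cell side (km), default 100.
#' @slot fineKm numeric, fine lattice side (km), default 5.
#' @slot elevation numeric matrix (fine lattice), metres.
#' @slot water logical matrix (fine lattice), TRUE for impassable water.
#' @export
setClass("TerrainGrid",
  representation(nx = "integer", ny = "integer", cellKm = "numeric",
                 fineKm = "numeric", elevation = "matrix",
                 water = "matrix"))

setValidity("TerrainGrid", function(object) {
  f <- object@cellKm / object@fineKm
  if (object@cellKm <= 0 || object@fineKm <= 0) return("cell sizes must be > 0")
  if (abs(f - round(f)) > 1e-9) return("cellKm must be a multiple of fineKm")
  dims <- c(object@ny, object@nx) * round(f)
  if (!all(dim(object@elevation) == dims)) return("elevation dims mismatch")
  if (!all(dim(object@water) == dims)) return("water mask dims mismatch")
  if (!is.logical(object@water)) return("water mask must be logical")
  if (any(!is.finite(object@elevation[!object@water])))
    return("elevation must be finite on land")
  TRUE
})

#' Construct a terrain grid
#'
#' @param elevation fine-lattice elevation matrix (m), rows = y, cols = x.
#' @param water logical fine-lattice water mask (default: no water).
#' @param cellKm coarse cell size in km (default 100).
#' @param fineKm fine lattice resolution in km (default 5).
#' @return A \linkS4class{TerrainGrid}.
#' @export
terrainGrid <- function(elevation, water = NULL, cellKm = 100, fineKm = 5) {
  elevation <- as.matrix(elevation)
  if (is.null(water))
    water <- matrix(FALSE, nrow(elevation), ncol(elevation))
  f <- round(cellKm / fineKm)
  new("TerrainGrid", nx = as.integer(ncol(elevation) / f),
      ny = as.integer(nrow(elevation) / f),
      cellKm = cellKm, fineKm = fineKm,
      elevation = elevation, water = water)
}

#' @describeIn terrainGrid Number of coarse cells.
#' @param x a \code{TerrainGrid}.
#' @export
nCells <- function(x) as.integer(x@nx * x@ny)

#' @describeIn terrainGrid Coarse cell centre coordinates (km) and mean
#'   elevation per coarse cell; cells are numbered column-major (x fastest).
#' @export
coarseCells <- function(x) {
  f <- round(x@cellKm / x@fineKm)
  idx <- expand.grid(ix = seq_len(x@nx), iy = seq_len(x@ny))
  ele <- numeric(nrow(idx)); land <- numeric(nrow(idx))
  for (k in seq_len(nrow(idx))) {
    rows <- ((idx$iy[k] - 1) * f + 1):(idx$iy[k] * f)
    cols <- ((idx$ix[k] - 1) * f + 1):(idx$ix[k] * f)
    w <- x@water[rows, cols, drop = FALSE]
    e <- x@elevation[rows, cols, drop = FALSE]
    land[k] <- mean(!w)
    ele[k] <- if (any(!w)) mean(e[!w]) else NA_real_
  }
  data.frame(cell_id = seq_len(nrow(idx)),
             x_km = (idx$ix - 0.5) * x@cellKm,
             y_km = (idx$iy - 0.5) * x@cellKm,
             elevation_m = ele, land_fraction = land,
             is_water = land == 0)
}

setMethod("show", "TerrainGrid", function(object) {
  cat(sprintf("TerrainGrid: %d x %d coarse cells of %g km (fine %g km)\n",
              object@nx, object@ny, object@cellKm, object@fineKm))
  cat(sprintf("  water fraction: %.3f\n", mean(object@water)))
})

## ---------------------------------------------------------------------------
## CovariateStack
## ---------------------------------------------------------------------------

#' Class "CovariateStack": per-cell, per-period covariate surfaces
#'
#' Holds land use (LU, fraction appropriated by humans), winter temperature
#' (WT, degrees C), net primary productivity (NPP, g dry matter m^-2 a^-1)
#' and elevation (ELE, m) as cells x periods matrices. When standardized,
#' the original centre/scale of each surface is retained so effects can be
#' back-converted to natural units.
#'
#' @slot lu,wt,npp,ele numeric matrices, cells x periods.
#' @slot scheme the \linkS4class{PeriodScheme}.
#' @slot standardized logical.
#' @slot center,scale named numeric vectors (one entry per covariate) when
#'   standardized, else empty.
#' @export
setClass("CovariateStack",
  representation(lu = "matrix", wt = "matrix", npp = "matrix",
                 ele = "matrix", scheme = "PeriodScheme",
                 standardized = "logical", center = "numeric",
                 scale = "numeric"))

setValidity("CovariateStack", function(object) {
  d <- dim(object@lu)
  for (nm in c("wt", "npp", "ele"))
    if (!all(dim(slot(object, nm)) == d))
      return(sprintf("dimension mismatch in covariate '%s'", nm))
  if (d[2] != nPeriods(object@scheme))
    return("number of columns must equal number of periods")
  for (nm in c("lu", "wt", "npp", "ele"))
    if (any(!is.finite(slot(object, nm))))
      return(sprintf("non-finite values in covariate '%s'", nm))
  TRUE
})

#' Construct a covariate stack
#'
#' @param lu,wt,npp,ele cells x periods numeric matrices (see
#'   \linkS4class{CovariateStack} for units).
#' @param scheme a \linkS4class{PeriodScheme} with matching period count.
#' @return A \linkS4class{CovariateStack} (unstandardized).
#' @export
covariateStack <- function(lu, wt, npp, ele, scheme) {
  new("CovariateStack", lu = as.matrix(lu), wt = as.matrix(wt),
      npp = as.matrix(npp), ele = as.matrix(ele), scheme = scheme,
      standardized = FALSE, center = numeric(0), scale = numeric(0))
}

#' Z-score standardize a covariate stack
#'
#' Each covariate is centred and scaled over all cell-periods jointly, so
#' the regression coefficients of the occupancy and path models are
#' standardized effect sizes. The transform is stored for back-conversion.
#'
#' @param x a \linkS4class{CovariateStack}.
#' @return A standardized \linkS4class{CovariateStack}.
#' @export
standardizeCovariates <- function(x) {
  stopifnot(is(x, "CovariateStack"))
  if (x@standardized) return(x)
  ctr <- numeric(0); scl <- numeric(0)
  for (nm in c("lu", "wt", "npp", "ele")) {
    v <- slot(x, nm)
    m <- mean(v); s <- sd(as.numeric(v))
    if (!is.finite(s) || s == 0) s <- 1
    slot(x, nm) <- (v - m) / s
    ctr[nm] <- m; scl[nm] <- s
  }
  x@standardized <- TRUE; x@center <- ctr; x@scale <- scl
  validObject(x)
  x
}

#' Extract covariates as a cell-period design matrix
#'
#' @param x a \linkS4class{CovariateStack}.
#' @return Numeric matrix with S*T rows (period-major: all cells of period 1
#'   first) and columns \code{lu, npp, wt, ele} — the order used by the
#'   extinction-rate regression.
#' @export
covariateMatrix <- function(x) {
  stopifnot(is(x, "CovariateStack"))
  cbind(lu = as.numeric(x@lu), npp = as.numeric(x@npp),
        wt = as.numeric(x@wt), ele = as.numeric(x@ele))
}

setMethod("show", "CovariateStack", function(object) {
  cat(sprintf("CovariateStack: %d cells x %d periods (%s)\n",
              nrow(object@lu), ncol(object@lu),
              if (object@standardized) "standardized" else "natural units"))
})

## ---------------------------------------------------------------------------
## ArchRecords
## ---------------------------------------------------------------------------

#' Class "ArchRecords": archaeofaunal detection/non-detection records
#'
#' One row per dated excavation record: the cell and period it falls in,
#' the total count of bone remains (NSP, used as a detectability proxy),
#' the excavation-site type, and whether the focal species was detected.
#' Contemporary range maps enter as rows with \code{site_type "range_map"}
#' in the perfect-detection periods.
#'
#' @slot data a data.frame with columns \code{record_id, site_id, site_type,
#'   period, cell_id, nsp_total, detected}.
#' @export
setClass("ArchRecords", representation(data = "data.frame"))

.recordCols <- c("record_id", "site_id", "site_type", "period", "cell_id",
                 "nsp_total", "detected")

setValidity("ArchRecords", function(object) {
  d <- object@data
  miss <- setdiff(.recordCols, names(d))
  if (length(miss)) return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (nrow(d)) {
    bad <- which(!(d$site_type %in% c(siteTypes(), .specialTypes)))
    if (length(bad))
      return(sprintf("row %d: unknown site type '%s'", bad[1], d$site_type[bad[1]]))
    bad <- which(!is.finite(d$nsp_total) | d$nsp_total < 1)
    if (length(bad))
      return(sprintf("row %d: column nsp_total violates NSP >= 1", bad[1]))
    bad <- which(!(d$detected %in% c(0L, 1L)))
    if (length(bad))
      return(sprintf("row %d: column detected must be 0/1", bad[1]))
    bad <- which(!is.finite(d$period) | d$period < 1)
    if (length(bad))
      return(sprintf("row %d: column period invalid", bad[1]))
    bad <- which(!is.finite(d$cell_id) | d$cell_id < 1)
    if (length(bad))
      return(sprintf("row %d: column cell_id invalid", bad[1]))
  }
  TRUE
})

#' Construct an ArchRecords object
#'
#' @param data data.frame with the columns listed in
#'   \linkS4class{ArchRecords}.
#' @return An \linkS4class{ArchRecords}.
#' @export
archRecords <- function(data) {
  data <- as.data.frame(data)[, .recordCols]
  data$period <- as.integer(data$period)
  data$cell_id <- as.integer(data$cell_id)
  data$nsp_total <- as.integer(data$nsp_total)
  data$detected <- as.integer(data$detected)
  new("ArchRecords", data = data)
}

#' @describeIn archRecords Records as a data.frame.
#' @param x an \code{ArchRecords}.
#' @export
recordData <- function(x) x@data

#' @describeIn archRecords Number of records.
#' @export
nRecords <- function(x) nrow(x@data)

setMethod("show", "ArchRecords", function(object) {
  d <- object@data
  cat(sprintf("ArchRecords: %d records, %d sites, %d detections (%.1f%%)\n",
              nrow(d), length(unique(d$site_id)), sum(d$detected),
              if (nrow(d)) 100 * mean(d$detected) else 0))
  if (nrow(d)) {
    tt <- sort(table(d$site_type), decreasing = TRUE)
    cat("  site types:", paste(names(tt), tt, sep = ":", collapse = " "), "\n")
  }
})

## ---------------------------------------------------------------------------
## OccupancyLattice
## ---------------------------------------------------------------------------

#' Class "OccupancyLattice": latent occupancy states over the grid
#'
#' @slot z integer matrix (cells x periods) of 0/1 occupancy states.
#' @slot psi1 numeric, initial occupancy probability used to generate or
#'   initialize period 1 (NA when unknown).
#' @slot scheme the \linkS4class{PeriodScheme}.
#' @export
setClass("OccupancyLattice",
  representation(z = "matrix", psi1 = "numeric", scheme = "PeriodScheme"))

setValidity("OccupancyLattice", function(object) {
  if (!all(object@z %in% c(0L, 1L))) return("z must be binary")
  if (ncol(object@z) != nPeriods(object@scheme))
    return("z columns must match period count")
  if (length(object@psi1) != 1 ||
      (!is.na(object@psi1) && (object@psi1 < 0 || object@psi1 > 1)))
    return("psi1 must be a single probability (or NA)")
  TRUE
})

#' Construct an occupancy lattice
#'
#' @param z cells x periods binary matrix.
#' @param scheme a \linkS4class{PeriodScheme}.
#' @param psi1 initial occupancy probability (NA if unknown).
#' @return An \linkS4class{OccupancyLattice}.
#' @export
occupancyLattice <- function(z, scheme, psi1 = NA_real_) {
  z <- matrix(as.integer(as.matrix(z)), nrow(z), ncol(z))
  new("OccupancyLattice", z = z, psi1 = as.numeric(psi1), scheme = scheme)
}

#' @describeIn occupancyLattice The occupancy matrix.
#' @param x an \code{OccupancyLattice}.
#' @export
occupancy <- function(x) x@z

setMethod("show", "OccupancyLattice", function(object) {
  cat(sprintf("OccupancyLattice: %d cells x %d periods\n",
              nrow(object@z), ncol(object@z)))
  cat("  occupied fraction per period:",
      paste(sprintf("%.2f", colMeans(object@z)), collapse = " "), "\n")
})

## ---------------------------------------------------------------------------
## SyntheticTruth
## ---------------------------------------------------------------------------

#' Class "SyntheticTruth": generating parameters of a synthetic study
#'
#' A serializable record of every parameter used by the synthetic-data
#' generators, sufficient to regenerate a dataset bit-identically together
#' with the seed.
#'
#' @slot params named list of generating parameters.
#' @slot seed integer seed.
#' @export
setClass("SyntheticTruth",
  representation(params = "list", seed = "integer"))

setValidity("SyntheticTruth", function(object) {
  if (length(object@seed) != 1) return("seed must be a single integer")
  if (is.null(names(object@params)) || any(names(object@params) == ""))
    return("all params must be named")
  TRUE
})

#' @describeIn syntheticTruth Access the full parameter list.
#' @param x a \code{SyntheticTruth}.
#' @export
truthParams <- function(x) x@params

#' @describeIn syntheticTruth Write/read the truth as YAML key-value text.
#' @param path file path.
#' @export
writeTruth <- function(x, path) {
  ## named vectors as explicit maps so names survive the round trip
  prep <- lapply(x@params, function(v)
    if (!is.null(names(v)) && length(v) > 1) as.list(v) else v)
  yaml::write_yaml(c(list(seed = x@seed), prep), path)
  invisible(path)
}

#' @describeIn syntheticTruth Read a truth object back from YAML.
#' @export
readTruth <- function(path) {
  obj <- yaml::read_yaml(path)
  seed <- as.integer(obj$seed); obj$seed <- NULL
  ## yaml flattens numeric vectors fine, but named lists inside stay lists
  obj <- lapply(obj, function(v) if (is.list(v)) unlist(v) else v)
  new("SyntheticTruth", params = obj, seed = seed)
}

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth with", length(object@params),
      "parameter entries, seed", object@seed, "\n")
})

## ---------------------------------------------------------------------------
## PosteriorDraws
## ---------------------------------------------------------------------------

#' Class "PosteriorDraws": retained MCMC samples
#'
#' @slot draws numeric matrix, retained draws x parameters (named columns).
#' @slot chain integer vector, chain index of each draw.
#' @slot iter integer vector, original iteration index of each draw.
#' @slot z integer 3-d array (draw, cell, period) of latent occupancy,
#'   or a 0-extent array when latent states were not retained.
#' @slot scenario character, scenario labels (one per draw; "" if unset).
#' @slot config list, sampler configuration and seed used.
#' @export
setClass("PosteriorDraws",
  representation(draws = "matrix", chain = "integer", iter = "integer",
                 z = "array", scenario = "character", config = "list"))

setValidity("PosteriorDraws", function(object) {
  n <- nrow(object@draws)
  if (length(object@chain) != n) return("chain index length mismatch")
  if (length(object@iter) != n) return("iter index length mismatch")
  if (length(object@scenario) != n) return("scenario label length mismatch")
  if (any(!is.finite(object@draws))) return("draws contain non-finite values")
  if (length(dim(object@z)) == 3 && dim(object@z)[1] > 0 &&
      dim(object@z)[1] != n) return("z draw count mismatch")
  TRUE
})

#' @describeIn runMCMC Retained parameter draws (matrix draws x parameters).
#' @param x a \code{PosteriorDraws}.
#' @export
posteriorMatrix <- function(x) x@draws

#' @describeIn runMCMC Chain index per retained draw.
#' @export
chainIndex <- function(x) x@chain

#' @describeIn runMCMC Retained latent occupancy draws (array draw x cell x
#'   period), or NULL when not stored.
#' @export
latentDraws <- function(x) {
  if (length(dim(x@z)) == 3 && dim(x@z)[1] > 0) x@z else NULL
}

#' @describeIn runMCMC Number of retained draws.
#' @export
nDraws <- function(x) nrow(x@draws)

setMethod("show", "PosteriorDraws", function(object) {
  cat(sprintf("PosteriorDraws: %d draws x %d parameters, %d chain(s)\n",
              nrow(object@draws), ncol(object@draws),
              length(unique(object@chain))))
  if (any(nzchar(object@scenario)))
    cat("  scenarios:", paste(unique(object@scenario), collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## MetaFit
## ---------------------------------------------------------------------------

#' Class "MetaFit": fitted comparative meta-analysis
#'
#' Result of the weighted gamma identity-link mixed model of reproductive
#' rate against female body mass, NPP and wintering-season temperature with
#' a continent random effect.
#'
#' @slot draws numeric matrix of posterior draws (named columns).
#' @slot summary data.frame of posterior means and 95\% credible intervals.
#' @slot vif named numeric, variance inflation factors of the predictors.
#' @slot weights numeric, observation weights used (all 1 if unweighted).
#' @slot data data.frame, the analysed (standardized) design.
#' @export
setClass("MetaFit",
  representation(draws = "matrix", summary = "data.frame", vif = "numeric",
                 weights = "numeric", data = "data.frame"))

setMethod("show", "MetaFit", function(object) {
  cat("MetaFit: gamma identity-link mixed model,",
      nrow(object@data), "populations\n")
  print(object@summary, digits = 3)
})

#' @describeIn fitGammaGLMM Posterior summary table.
#' @param x a \code{MetaFit}.
#' @export
metaSummary <- function(x) x@summary

#' @describeIn fitGammaGLMM Posterior draws matrix.
#' @export
metaDraws <- function(x) x@draws
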