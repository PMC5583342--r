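## Readers/writers for the CSV interchange formats, derived map products
## (net extinction/colonization trend, occurrence probability), effect
## tables, and the command-line entry point.

#' Net extinction/colonization trend
#'
#' \eqn{\log_{10}(r_\phi / r_\gamma)}: 0 = balance, positive = net
#' extinction, negative = net colonization.
#'
#' @param rPhi,rGamma strictly positive rates (vectorized).
#' @return log10 rate ratio.
#' @export
netTrend <- function(rPhi, rGamma) {
  if (any(rPhi <= 0) || any(rGamma <= 0))
    stop("rates must be strictly positive")
  log10(rPhi / rGamma)
}

#' Posterior net-trend surface
#'
#' For each retained draw, recomputes the extinction rate from the drawn
#' coefficients and the colonization rate from the drawn occupancy and
#' dispersal parameter, forms \eqn{\log_{10}(r_\phi/r_\gamma)} per cell
#' and transition interval, and summarizes by the posterior median.
#'
#' @param fit a \linkS4class{PosteriorDraws} with retained latent states.
#' @param covariates the standardized \linkS4class{CovariateStack} used in
#'   fitting.
#' @param distances LCP distance matrix.
#' @param sourceDist optional external-source distances (Asian
#'   colonization scenario).
#' @return cells x (periods - 1) matrix of median net trends.
#' @export
netTrendSurface <- function(fit, covariates, distances, sourceDist = NULL) {
  z <- latentDraws(fit)
  if (is.null(z)) stop("fit does not retain latent occupancy draws")
  covariates <- standardizeCovariates(covariates)
  X <- covariateMatrix(covariates)
  m <- posteriorMatrix(fit)
  S <- dim(z)[2]; T <- dim(z)[3]
  nd <- nrow(m)
  acc <- array(NA_real_, c(nd, S, T - 1))
  bcols <- c("beta_phi_0", "beta_phi_lu", "beta_phi_npp", "beta_phi_wt",
             "beta_phi_ele")
  for (dIdx in seq_len(nd)) {
    rphi <- matrix(extinctionRate(X, m[dIdx, bcols]), S, T)
    for (t in seq_len(T - 1)) {
      Sc <- connectivity(z[dIdx, , t], distances, m[dIdx, "alpha"],
                         sourceDist)
      acc[dIdx, , t] <- netTrend(rphi[, t], colonizationRate(Sc))
    }
  }
  apply(acc, c(2, 3), median)
}

#' Posterior occurrence-probability surface
#'
#' Mean of the retained latent occupancy draws per cell-period; in
#' perfect-detection periods this equals the mapped range exactly.
#'
#' @param fit a \linkS4class{PosteriorDraws} with retained latent states.
#' @return cells x periods matrix of posterior occurrence probabilities.
#' @export
occurrenceSurface <- function(fit) {
  z <- latentDraws(fit)
  if (is.null(z)) stop("fit does not retain latent occupancy draws")
  apply(z, c(2, 3), mean)
}

#' Direct/indirect effect summary table
#'
#' Combines \code{\link{decomposeEffects}} with posterior inclusion
#' probabilities and Bayes factors into the flat CSV schema
#' (effect_name, kind, mean, ci_low, ci_high, inclusion_prob,
#' bayes_factor).
#'
#' @param fit a \linkS4class{PosteriorDraws}.
#' @param dampening dampening definition, see
#'   \code{\link{decomposeEffects}}.
#' @return data.frame in the effect-table schema.
#' @export
effectTable <- function(fit, dampening = "direct") {
  dec <- decomposeEffects(fit, dampening = dampening)
  m <- posteriorMatrix(fit)
  M <- nrow(m)
  incFor <- function(nm) {
    key <- switch(nm, direct_lu = "I_phi_lu", direct_wt = "I_phi_wt",
                  direct_npp = "I_phi_npp", direct_ele = "I_phi_ele",
                  NA_character_)
    if (is.na(key) || !(key %in% colnames(m))) NA_real_
    else mean(m[, key])
  }
  s <- dec$summary
  s$kind <- ifelse(grepl("^direct", s$effect), "direct",
                   ifelse(grepl("^indirect", s$effect), "indirect",
                          "dampening"))
  s$inclusion_prob <- vapply(s$effect, incFor, 0)
  s$bayes_factor <- rep(NA_real_, nrow(s))
  ok <- !is.na(s$inclusion_prob)
  s$bayes_factor[ok] <- bayesFactor(s$inclusion_prob[ok], M = M)
  data.frame(effect_name = s$effect, kind = s$kind, mean = s$mean,
             ci_low = s$ci_low, ci_high = s$ci_high,
             inclusion_prob = s$inclusion_prob,
             bayes_factor = s$bayes_factor)
}

## ---------------------------------------------------------------------------
## CSV readers/writers
## ---------------------------------------------------------------------------

#' Read and write archaeofaunal record tables
#'
#' Schema: \code{record_id, site_id, site_type, period, cell_id,
#' nsp_total, detected} (one row per record). Validation reports the
#' first offending row and column. Site-type strings outside the known
#' vocabulary are rejected unless \code{coerceUnknownTypes = TRUE}, in
#' which case they are mapped to "unknown".
#'
#' @param path CSV file path.
#' @param coerceUnknownTypes logical (default FALSE).
#' @return \code{readRecords}: an \linkS4class{ArchRecords}.
#' @export
readRecords <- function(path, coerceUnknownTypes = FALSE) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.recordCols, names(d))
  if (length(miss))
    stop("records file lacks columns: ", paste(miss, collapse = ", "))
  if (coerceUnknownTypes) {
    bad <- !(d$site_type %in% c(siteTypes(), .specialTypes))
    d$site_type[bad] <- "unknown"
  }
  archRecords(d)
}

#' @describeIn readRecords Write records to CSV (lossless round-trip).
#' @param x the object to write.
#' @export
writeRecords <- function(x, path) {
  stopifnot(is(x, "ArchRecords"))
  write.csv(recordData(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write covariate stacks
#'
#' Long-format schema: \code{cell_id, period, lu, wt, npp, ele}; every
#' cell-period combination must appear exactly once.
#'
#' @param path CSV file path.
#' @param scheme the \linkS4class{PeriodScheme} the table must cover.
#' @return \code{readCovariates}: a \linkS4class{CovariateStack}.
#' @export
readCovariates <- function(path, scheme) {
  d <- read.csv(path)
  need <- c("cell_id", "period", "lu", "wt", "npp", "ele")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("covariate file lacks columns: ", paste(miss, collapse = ", "))
  S <- max(d$cell_id); T <- nPeriods(scheme)
  if (nrow(d) != S * T || anyDuplicated(d[, c("cell_id", "period")]))
    stop("covariate table must contain each cell-period exactly once")
  mk <- function(col) {
    m <- matrix(NA_real_, S, T)
    m[cbind(d$cell_id, d$period)] <- d[[col]]
    if (any(is.na(m))) stop(sprintf("covariate '%s' has missing cells", col))
    m
  }
  covariateStack(mk("lu"), mk("wt"), mk("npp"), mk("ele"), scheme)
}

#' @describeIn readCovariates Write a stack in the long format (natural
#'   or standardized values as stored).
#' @param x the object to write.
#' @export
writeCovariates <- function(x, path) {
  stopifnot(is(x, "CovariateStack"))
  S <- nrow(x@lu); T <- ncol(x@lu)
  d <- data.frame(cell_id = rep(seq_len(S), T),
                  period = rep(seq_len(T), each = S),
                  lu = as.numeric(x@lu), wt = as.numeric(x@wt),
                  npp = as.numeric(x@npp), ele = as.numeric(x@ele))
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write terrain grids
#'
#' Schema: one row per fine lattice cell, \code{cell_id, x_km, y_km,
#' elevation_m, is_water}. The fine resolution is inferred from the
#' coordinate spacing.
#'
#' @param path CSV file path.
#' @param cellKm coarse cell size in km (default 100).
#' @return \code{readTerrain}: a \linkS4class{TerrainGrid}.
#' @export
readTerrain <- function(path, cellKm = 100) {
  d <- read.csv(path)
  need <- c("cell_id", "x_km", "y_km", "elevation_m", "is_water")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("terrain file lacks columns: ", paste(miss, collapse = ", "))
  xs <- sort(unique(d$x_km)); ys <- sort(unique(d$y_km))
  fineKm <- min(diff(xs))
  nr <- length(ys); nc <- length(xs)
  elev <- matrix(NA_real_, nr, nc)
  water <- matrix(FALSE, nr, nc)
  ri <- match(d$y_km, ys); ci <- match(d$x_km, xs)
  elev[cbind(ri, ci)] <- d$elevation_m
  water[cbind(ri, ci)] <- as.logical(d$is_water)
  terrainGrid(elev, water, cellKm = cellKm, fineKm = fineKm)
}

#' @describeIn readTerrain Write the fine lattice to CSV.
#' @param x the object to write.
#' @export
writeTerrain <- function(x, path) {
  stopifnot(is(x, "TerrainGrid"))
  nr <- nrow(x@elevation); nc <- ncol(x@elevation)
  d <- data.frame(cell_id = seq_len(nr * nc),
                  x_km = rep((seq_len(nc) - 0.5) * x@fineKm, each = nr),
                  y_km = rep((seq_len(nr) - 0.5) * x@fineKm, nc),
                  elevation_m = as.numeric(x@elevation),
                  is_water = as.numeric(x@water))
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a population life-history table
#'
#' Schema: \code{population, continent, ls, li, fm_kg, n_ls, n_li, n_fm,
#' lon, lat, npp, t_ws}; missing values as empty fields. Invariants
#' (positive traits and body mass, sample sizes >= 1 when present) are
#' validated with row-indexed messages.
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
readPopulationTable <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("population", "continent", "ls", "li", "fm_kg", "n_ls",
            "n_li", "n_fm", "lon", "lat", "npp", "t_ws")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("population table lacks columns: ", paste(miss, collapse = ", "))
  for (col in c("ls", "li", "fm_kg")) {
    bad <- which(!is.na(d[[col]]) & d[[col]] <= 0)
    if (length(bad))
      stop(sprintf("row %d: column %s must be > 0", bad[1], col))
  }
  for (col in c("n_ls", "n_li", "n_fm")) {
    bad <- which(!is.na(d[[col]]) & d[[col]] < 1)
    if (length(bad))
      stop(sprintf("row %d: column %s must be >= 1 when present",
                   bad[1], col))
  }
  d
}

#' @describeIn readPopulationTable Write a population table.
#' @param x the object to write.
#' @export
writePopulationTable <- function(x, path) {
  write.csv(x, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write and read posterior draws
#'
#' Wide format: one row per retained draw with columns \code{chain, iter,
#' scenario} plus every parameter. \code{writePosteriorLong} additionally
#' offers the long (chain, iter, parameter, value) variant.
#'
#' @param path CSV file path.
#' @return \code{readPosterior}: a \linkS4class{PosteriorDraws} (without
#'   latent states).
#' @export
readPosterior <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  pm <- as.matrix(d[, !(names(d) %in% c("chain", "iter", "scenario")),
                    drop = FALSE])
  new("PosteriorDraws", draws = pm, chain = as.integer(d$chain),
      iter = as.integer(d$iter), z = array(0L, dim = c(0, 0, 0)),
      scenario = as.character(d$scenario), config = list())
}

#' @describeIn readPosterior Write draws in the wide format.
#' @param x the object to write.
#' @export
writePosterior <- function(x, path) {
  stopifnot(is(x, "PosteriorDraws"))
  d <- data.frame(chain = x@chain, iter = x@iter, scenario = x@scenario,
                  x@draws, check.names = FALSE)
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @describeIn readPosterior Write draws in the long format (chain, iter,
#'   parameter, value).
#' @export
writePosteriorLong <- function(x, path) {
  stopifnot(is(x, "PosteriorDraws"))
  m <- posteriorMatrix(x)
  d <- data.frame(chain = rep(x@chain, ncol(m)),
                  iter = rep(x@iter, ncol(m)),
                  parameter = rep(colnames(m), each = nrow(m)),
                  value = as.numeric(m))
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @describeIn readPosterior Write retained latent occupancy draws (long:
#'   draw, cell, period, z).
#' @export
writeLatent <- function(x, path) {
  z <- latentDraws(x)
  if (is.null(z)) stop("no latent draws retained")
  d <- dim(z)
  df <- data.frame(draw = rep(seq_len(d[1]), d[2] * d[3]),
                   cell = rep(rep(seq_len(d[2]), each = d[1]), d[3]),
                   period = rep(seq_len(d[3]), each = d[1] * d[2]),
                   z = as.integer(z))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @describeIn readPosterior Read latent draws written by
#'   \code{writeLatent} into a 3-d array.
#' @export
readLatent <- function(path) {
  d <- read.csv(path)
  array(as.integer(d$z),
        dim = c(max(d$draw), max(d$cell), max(d$period)))
}

## ---------------------------------------------------------------------------
## Command-line interface
## ---------------------------------------------------------------------------

.cliParse <- function(args) {
  out <- list(); i <- 1
  while (i <= length(args)) {
    a <- args[[i]]
    if (grepl("^--[a-z-]+=", a)) {
      kv <- sub("^--", "", a)
      key <- sub("=.*$", "", kv)
      out[[key]] <- sub("^[^=]*=", "", kv)
      i <- i + 1
    } else if (grepl("^--", a)) {
      key <- sub("^--", "", a)
      if (i + 1 <= length(args) && !grepl("^--", args[[i + 1]])) {
        out[[key]] <- args[[i + 1]]; i <- i + 2
      } else { out[[key]] <- "true"; i <- i + 1 }
    } else i <- i + 1
  }
  out
}

.cliRequire <- function(opt, keys, sub) {
  miss <- keys[!(keys %in% names(opt))]
  if (length(miss))
    stop(sprintf("subcommand '%s' is missing required option(s): %s",
                 sub, paste0("--", miss, collapse = ", ")), call. = FALSE)
}

#' Command-line entry point
#'
#' Thin shell over the package functions with subcommands
#' \code{simulate} (synthetic study to CSV), \code{fit} (MCMC on CSV
#' inputs), \code{diagnose} (R-hat/ESS table), \code{decompose} (effect
#' decomposition table) and \code{report} (net-trend and occurrence
#' surfaces). Missing required options are listed exhaustively in one
#' error. A launcher script is installed under
#' \code{system.file("scripts", "archeopop", package = "archeopop")}.
#'
#' @param args character vector of command-line arguments (first element:
#'   the subcommand).
#' @return Integer exit status, 0 on success (errors propagate as R
#'   conditions; the launcher maps them to a nonzero exit status).
#' @export
apCLI <- function(args) {
  if (length(args) < 1)
    stop("usage: archeopop <simulate|fit|diagnose|decompose|report> ",
         "[--options]", call. = FALSE)
  sub <- args[[1]]
  opt <- .cliParse(args[-1])
  seed <- as.integer(opt$seed %||% 1L)
  scheme <- periodScheme(holocenePeriods())
  switch(sub,
    simulate = {
      .cliRequire(opt, "out", sub)
      dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
      over <- list()
      if (identical(opt[["grid-scale"]], "paper"))
        over <- list(nx = 28, ny = 28, recordsPerCellPeriod = 1.07)
      if (!is.null(opt$nx)) {
        over$nx <- as.integer(opt$nx)
        over$ny <- as.integer(opt$ny %||% opt$nx)
      }
      truth <- do.call(defaultTruth, over)
      study <- generateStudy(truth, seed = seed,
                             luScenario = opt$lu %||% "constant",
                             scheme = scheme)
      writeTerrain(study$terrain, file.path(opt$out, "terrain.csv"))
      writeCovariates(study$covariatesRaw,
                      file.path(opt$out, "covariates.csv"))
      writeRecords(study$records, file.path(opt$out, "records.csv"))
      writeTruth(study$truth, file.path(opt$out, "truth.yaml"))
      message("simulated study written to ", opt$out)
      invisible(0L)
    },
    fit = {
      .cliRequire(opt, c("data", "out"), sub)
      dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
      terrain <- readTerrain(file.path(opt$data, "terrain.csv"),
                             cellKm = as.numeric(opt[["cell-km"]] %||% 100))
      cov <- readCovariates(file.path(opt$data, "covariates.csv"), scheme)
      rec <- readRecords(file.path(opt$data, "records.csv"))
      distances <- lcpDistances(terrain)
      asia <- opt$asia %||% "no"
      src <- applyAsianColonizationScenario(distances, terrain@nx,
                                            terrain@ny, asia)
      config <- mcmcConfig(
        nChains = as.integer(opt$chains %||% 4),
        nIter = as.integer(opt$iter %||% 3000),
        burnIn = as.integer(opt$burnin %||% 1000),
        thin = as.integer(opt$thin %||% 8), seed = seed)
      fit <- runMCMC(rec, cov, distances, config,
                     scenario = c(lu = opt$lu %||% "constant", asia = asia),
                     sourceDist = src)
      writePosterior(fit, file.path(opt$out, "draws.csv"))
      if (identical(opt[["keep-latent"]], "true") ||
          identical(opt[["keep-latent"]], "yes"))
        writeLatent(fit, file.path(opt$out, "zdraws.csv"))
      yaml::write_yaml(list(seed = seed, config = config[
        c("nChains", "nIter", "burnIn", "thin")],
        scenario = list(lu = opt$lu %||% "constant", asia = asia)),
        file.path(opt$out, "manifest.yaml"))
      message("posterior draws written to ", opt$out)
      invisible(0L)
    },
    diagnose = {
      .cliRequire(opt, c("draws", "out"), sub)
      fit <- readPosterior(opt$draws)
      dg <- convergenceDiagnostics(fit)
      write.csv(dg, opt$out, row.names = FALSE, quote = FALSE)
      message("diagnostics written to ", opt$out)
      invisible(0L)
    },
    decompose = {
      .cliRequire(opt, c("draws", "out"), sub)
      fit <- readPosterior(opt$draws)
      tab <- effectTable(fit, dampening = opt$dampening %||% "direct")
      write.csv(tab, opt$out, row.names = FALSE, quote = FALSE)
      message("effect decomposition written to ", opt$out)
      invisible(0L)
    },
    report = {
      .cliRequire(opt, c("draws", "zdraws", "data", "out"), sub)
      dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
      fit <- readPosterior(opt$draws)
      z <- readLatent(opt$zdraws)
      fit@z <- z
      terrain <- readTerrain(file.path(opt$data, "terrain.csv"),
                             cellKm = as.numeric(opt[["cell-km"]] %||% 100))
      cov <- readCovariates(file.path(opt$data, "covariates.csv"), scheme)
      distances <- lcpDistances(terrain)
      occ <- occurrenceSurface(fit)
      nt <- netTrendSurface(fit, cov, distances)
      S <- nrow(occ); T <- ncol(occ)
      write.csv(data.frame(cell_id = rep(seq_len(S), T),
                           period = rep(seq_len(T), each = S),
                           occurrence_prob = as.numeric(occ)),
                file.path(opt$out, "occurrence.csv"),
                row.names = FALSE, quote = FALSE)
      write.csv(data.frame(cell_id = rep(seq_len(S), T - 1),
                           interval = rep(seq_len(T - 1), each = S),
                           net_trend_log10 = as.numeric(nt)),
                file.path(opt$out, "net_trend.csv"),
                row.names = FALSE, quote = FALSE)
      message("report surfaces written to ", opt$out)
      invisible(0L)
    },
    stop(sprintf("unknown subcommand '%s'", sub), call. = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
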