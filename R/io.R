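## CSV readers/writers and the structured run report.
##
## Column conventions: RFC-4180 CSV with a header row, decimal points (no
## thousands separators), and unit-suffixed names: time_h, eh_mV, fe2_mg_L,
## fe_total_mg_L, cells_per_mL, inlet_mg_L, outlet_mg_L, molar_mass_g_mol.

.requireNumeric <- function(df, cols, path) {
  for (col in cols) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))
      stop(sprintf("%s: column '%s' has non-numeric entries (e.g. row %d)",
                   path, col, if (length(bad)) bad[1] else 1L))
    }
    if (anyNA(v)) {
      stop(sprintf("%s: column '%s' has missing values (row %d)", path, col,
                   which(is.na(v))[1]))
    }
  }
}

#' Read a bioreduction monitoring time series from CSV
#'
#' Expects a header row with a `time_h` column plus either `fe2_mg_L` or
#' both `eh_mV` and `fe_total_mg_L` (in which case Fe(II) is derived via
#' [seriesFromEh()] with the supplied calibration). An optional
#' `cells_per_mL` column becomes the cell-count channel. Non-monotone or
#' duplicate times are rejected with the offending row number.
#'
#' @param path CSV file path.
#' @param calib A [redoxCalibration()], used when Fe(II) must be derived
#'   from the redox channel.
#' @return A [bioreductionSeries()].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("time_h,fe2_mg_L", "0,0", "24,50"), f)
#' readTimeseries(f)
#' @export
readTimeseries <- function(path, calib = redoxCalibration()) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time_h" %in% names(df)) stop(path, ": missing required column time_h")
  hasFe2 <- "fe2_mg_L" %in% names(df)
  hasEh <- all(c("eh_mV", "fe_total_mg_L") %in% names(df))
  if (!hasFe2 && !hasEh) {
    stop(path, ": need fe2_mg_L or both eh_mV and fe_total_mg_L")
  }
  cols <- c("time_h", intersect(names(df), c("fe2_mg_L", "eh_mV",
                                             "fe_total_mg_L", "cells_per_mL")))
  .requireNumeric(df, cols, path)
  t <- df$time_h
  if (anyDuplicated(t)) {
    stop(sprintf("%s: duplicate time at row %d", path, anyDuplicated(t)))
  }
  bad <- which(diff(t) <= 0)
  if (length(bad)) {
    stop(sprintf("%s: times not strictly increasing at row %d", path,
                 bad[1] + 1L))
  }
  cells <- if ("cells_per_mL" %in% names(df)) df$cells_per_mL else NULL
  if (hasFe2) {
    bioreductionSeries(t, fe2 = df$fe2_mg_L,
                       eh = if ("eh_mV" %in% names(df)) df$eh_mV else NULL,
                       feTotal = if ("fe_total_mg_L" %in% names(df))
                         df$fe_total_mg_L else NULL,
                       cells = cells)
  } else {
    s <- seriesFromEh(t, df$eh_mV, df$fe_total_mg_L, calib)
    bioreductionSeries(t, fe2 = fe2(s), eh = df$eh_mV,
                       feTotal = df$fe_total_mg_L, cells = cells)
  }
}

#' Write a bioreduction series to CSV
#'
#' Writes the series with the column conventions of [readTimeseries()],
#' numbers formatted at 6 significant digits so that write/read/write
#' round-trips are byte-stable.
#'
#' @param series A [bioreductionSeries()].
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
writeTimeseries <- function(series, path) {
  df <- data.frame(time_h = sampleTimes(series), fe2_mg_L = fe2(series))
  if (length(ehValues(series))) df$eh_mV <- ehValues(series)
  if (length(feTotal(series))) df$fe_total_mg_L <- feTotal(series)
  if (length(cellCounts(series))) df$cells_per_mL <- cellCounts(series)
  df[] <- lapply(df, function(x) formatC(signif(x, 6), format = "g",
                                         digits = 6))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a nutrient concentration table from CSV
#'
#' Expects columns `species`, `inlet_mg_L`, `outlet_mg_L` and optionally
#' `molar_mass_g_mol` (looked up from [ferrokinConstants()] when absent).
#' Negative concentrations are rejected. An empty table yields an empty
#' record.
#'
#' @param path CSV file path.
#' @return A [nutrientRecord()] data frame.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("species,inlet_mg_L,outlet_mg_L", "NH4+,127,59.3"), f)
#' readNutrientTable(f)
#' @export
readNutrientTable <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(species = "character"))
  need <- c("species", "inlet_mg_L", "outlet_mg_L")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(path, ": missing column(s) ", paste(miss, collapse = ", "))
  }
  if (nrow(df) == 0L) {
    return(nutrientRecord(character(0), numeric(0), numeric(0), numeric(0)))
  }
  .requireNumeric(df, intersect(names(df), c("inlet_mg_L", "outlet_mg_L",
                                             "molar_mass_g_mol")), path)
  if (any(df$inlet_mg_L < 0) || any(df$outlet_mg_L < 0)) {
    stop(path, ": negative concentration at row ",
         which(df$inlet_mg_L < 0 | df$outlet_mg_L < 0)[1])
  }
  mm <- if ("molar_mass_g_mol" %in% names(df)) df$molar_mass_g_mol else NULL
  nutrientRecord(df$species, df$inlet_mg_L, df$outlet_mg_L, mm)
}

## 32-bit polynomial rolling hash of a string (provenance fingerprint)
.strHash <- function(s) {
  h <- 5381
  for (b in utf8ToInt(s)) {
    h <- (h * 33 + b) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

#' Run a configured analysis and write a structured report
#'
#' Executes every analysis named in the configuration and collects the
#' results into one JSON document with provenance (package version, seed,
#' configuration hash). Recognised configuration entries:
#' \describe{
#'   \item{`seed`}{Integer; seeds any stochastic step.}
#'   \item{`calibration`}{List with `formalPotential_mV`, `temperature_K`.}
#'   \item{`timeseries`}{Path to a monitoring CSV; mean/max rates are
#'     reported.}
#'   \item{`rateLawData`}{Path to a CSV with `cells_per_mL` and
#'     `rate_mg_L_h`; the fitted law is reported.}
#'   \item{`nutrients`}{List with `path`, `volume_L`, `hrt_h`; drops and
#'     fluxes are reported.}
#'   \item{`steadyState`}{List of [reductionReactorConfig()] arguments plus
#'     `inletBiomass` (and optionally `inletFe2`, `inletFe3`); the
#'     closed-form chemostat steady state is reported.}
#' }
#' Unknown entries are rejected. Deterministic inputs produce byte-identical
#' reports.
#'
#' @param config Named list as described above.
#' @param path Output JSON path, or `NULL` to skip writing.
#' @return The report, invisibly when written, as a named list.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("time_h,fe2_mg_L", "0,0", "24,50", "48,95"), f)
#' rep <- runReport(list(timeseries = f))
#' rep$rates
#' @export
runReport <- function(config, path = NULL) {
  known <- c("seed", "calibration", "timeseries", "rateLawData", "nutrients",
             "steadyState")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop("unknown config entries: ", paste(unknown, collapse = ", "))
  }
  calib <- if (!is.null(config$calibration)) {
    redoxCalibration(config$calibration$formalPotential_mV,
                     config$calibration$temperature_K)
  } else redoxCalibration()
  if (!is.null(config$seed)) set.seed(config$seed)

  report <- list(provenance = list(
    package = "ferrokin",
    version = as.character(utils::packageVersion("ferrokin")),
    seed = if (is.null(config$seed)) NA else config$seed,
    configHash = .strHash(jsonlite::toJSON(config, auto_unbox = TRUE,
                                           digits = NA))))

  if (!is.null(config$timeseries)) {
    s <- readTimeseries(config$timeseries, calib)
    report$rates <- list(mean_mg_L_h = meanRate(s), max_mg_L_h = maxRate(s))
  }
  if (!is.null(config$rateLawData)) {
    df <- utils::read.csv(config$rateLawData)
    law <- fitRateLaw(df$cells_per_mL, df$rate_mg_L_h)
    report$rateLaw <- list(slope = rateSlope(law),
                           intercept_mg_L_h = rateIntercept(law),
                           r2 = rateR2(law))
  }
  if (!is.null(config$nutrients)) {
    nc <- config$nutrients
    rec <- readNutrientTable(nc$path)
    tab <- nutrientFluxTable(rec, volume = nc$volume_L, hrt = nc$hrt_h)
    report$nutrientFluxes <- tab
  }
  if (!is.null(config$steadyState)) {
    sc <- config$steadyState
    cfg <- reductionReactorConfig(
      volume = sc$volume_L %||% 4, pulpInflow = sc$pulpInflow_mL_h %||% 26.5,
      feedFe3 = sc$feedFe3_mg_L %||% 22000, feedFlow = sc$feedFlow_mL_h %||% 3,
      rateLaw = rateLaw(sc$slope %||% 3.46e-9, sc$intercept %||% 1.55),
      kPrecip = sc$kPrecip_h %||% 0)
    ss <- steadyState(cfg, list(biomass = sc$inletBiomass %||% 0,
                                fe2 = sc$inletFe2 %||% 0,
                                fe3 = sc$inletFe3 %||% 0))
    report$steadyState <- as.list(ss)
  }
  if (!is.null(path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = 10,
                         pretty = TRUE)
    return(invisible(report))
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a
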