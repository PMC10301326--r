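#' Read a kinetic curve from CSV
#'
#' Expects an RFC-4180 CSV with header `time_s,intensity_au` (for
#' bioluminescence) or `time_s,absorbance` (for absorbance traces), UTF-8,
#' `.` decimal.  Malformed rows and non-monotone timestamps are rejected
#' with the offending line number.
#'
#' @param path CSV file path.
#' @param signal signal kind; for `time_s,absorbance` files choose
#'   `"absorbance_445"` or `"absorbance_380"` explicitly (default 445).
#' @param meta named list of condition labels attached to the curve.
#' @return A [lux_curve()].
#' @seealso [write_kinetic_curve()]
#' @export
read_kinetic_curve <- function(path, signal = NULL, meta = list()) {
  if (!file.exists(path)) stop_lux("file not found: ", path)
  df <- tryCatch(read.csv(path, check.names = FALSE),
                 error = function(e) stop_lux("cannot parse ", path, ": ",
                                              conditionMessage(e)))
  if (nrow(df) == 0) stop_lux(path, ": no data rows")
  nm <- names(df)
  if (nm[1] != "time_s" || !nm[2] %in% c("intensity_au", "absorbance"))
    stop_lux(path, ": header must be time_s,intensity_au or ",
             "time_s,absorbance (got ", paste(nm, collapse = ","), ")")
  if (is.null(signal))
    signal <- if (nm[2] == "intensity_au") "bioluminescence"
              else "absorbance_445"
  t <- suppressWarnings(as.numeric(df[[1]]))
  y <- suppressWarnings(as.numeric(df[[2]]))
  bad <- which(is.na(t) | is.na(y))
  if (length(bad))
    stop_lux(path, ": non-numeric values on line(s) ",
             paste(bad + 1L, collapse = ", "))  # +1 for the header line
  mono <- which(diff(t) <= 0)
  if (length(mono))
    stop_lux(path, ": time not strictly increasing at line ",
             mono[1] + 2L)
  lux_curve(t, y, signal, meta)
}

#' Write a kinetic curve to CSV
#'
#' @param curve a [lux_curve()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_kinetic_curve <- function(curve, path) {
  stopifnot(inherits(curve, "lux_curve"))
  col2 <- if (curve$signal == "bioluminescence") "intensity_au"
          else "absorbance"
  df <- setNames(data.frame(curve$t, curve$y), c("time_s", col2))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a rate-versus-viscosity series from CSV
#'
#' Columns: `eta_cP,k_value` with optional `cosolvent,wt_percent`.
#'
#' @param path CSV file path.
#' @return Data frame ready for [fit_power_law()].
#' @export
read_viscosity_series <- function(path) {
  if (!file.exists(path)) stop_lux("file not found: ", path)
  df <- read.csv(path, check.names = FALSE)
  if (!all(c("eta_cP", "k_value") %in% names(df)))
    stop_lux(path, ": columns eta_cP and k_value are required")
  df
}

#' Run the full kinetic-analysis pipeline on a configured dataset
#'
#' Orchestrates the analysis in the experimental order: (optional) dark
#' decay from absorbance traces, global five-curve fit with `kd`/`kdd`
#' fixed, empirical flash-curve parameters per curve, and (optional)
#' power-law viscosity fits.  Writes `fit.json`, `empirical.json`,
#' optionally `powerlaw.json`, and a human-readable `report.txt` into
#' `out_dir`, each carrying provenance (input hashes, seed, package
#' version).
#'
#' @param config a named list or path to a YAML file with fields:
#'   \describe{
#'     \item{curves}{list of entries `path`, `decanal_uM`.}
#'     \item{L0_uM, F0_uM}{post-mix concentrations (defaults 1, 15).}
#'     \item{kd, kdd}{fixed dark-decay constants, 1/s (required), or
#'       sub-lists `trace`/`windows` naming absorbance CSVs to fit.}
#'     \item{seed, n_starts}{fit reproducibility controls.}
#'     \item{viscosity_series}{optional list of CSV paths for power-law
#'       fits.}
#'     \item{out_dir}{output directory (required).}
#'   }
#' @return Invisibly, a list with the [luxfit()] object, empirical
#'   parameters, power-law fits and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop_lux("config must be a list or a YAML path")
  for (f in c("curves", "out_dir"))
    if (is.null(config[[f]])) stop_lux("config is missing '", f, "'")

  kd <- config[["kd"]]; kdd <- config[["kdd"]]
  darkfits <- list()
  if (is.list(kd)) {
    tr <- read_kinetic_curve(kd$trace, signal = "absorbance_445")
    darkfits$kd <- fit_kd(tr, kd$windows[[1]], kd$windows[[2]])
    kd <- darkfits$kd$kd
  }
  if (is.list(kdd)) {
    tr <- read_kinetic_curve(kdd$trace, signal = "absorbance_380")
    darkfits$kdd <- fit_kdd(tr, kdd$windows[[1]])
    kdd <- darkfits$kdd$k
  }
  if (is.null(kd) || is.null(kdd))
    stop_lux("config must fix kd and kdd (values or absorbance traces)")

  paths <- vapply(config[["curves"]], `[[`, character(1), "path")
  ald <- vapply(config[["curves"]], function(x) as.numeric(x$decanal_uM),
                numeric(1))
  curves <- mapply(function(p, a)
    read_kinetic_curve(p, meta = list(decanal_uM = a)),
    paths, ald, SIMPLIFY = FALSE)
  ds <- lux_dataset(curves,
                    L0 = config[["L0_uM"]] %||% 1, F0 = config[["F0_uM"]] %||% 15)

  seed <- config[["seed"]] %||% 1L
  fit <- luxfit(ds, kd = kd, kdd = kdd,
                n_starts = config[["n_starts"]] %||% 16, seed = seed)

  emp <- lapply(ds, empirical_params)
  names(emp) <- sprintf("decanal_%g_uM", ald)

  pl <- list()
  for (vs in config[["viscosity_series"]] %||% list()) {
    df <- read_viscosity_series(vs)
    pl[[basename(vs)]] <- fit_power_law(df)
  }

  dir.create(config[["out_dir"]], recursive = TRUE, showWarnings = FALSE)
  prov <- list(package = "luxkin",
               version = as.character(utils::packageVersion("luxkin")),
               seed = seed,
               inputs = as.list(tools::md5sum(paths)))

  fit_json <- file.path(config[["out_dir"]], "fit.json")
  jsonlite::write_json(list(
    provenance = prov,
    fixed = list(kd = kd, kdd = kdd),
    rates = as.list(coef(fit)),
    se_log10 = as.list(fit$se_log10),
    michaelis_uM = as.list(michaelis_constants(fit$rates) * 1e6),
    rel_error_percent = fit$rel_error,
    bounds = fit$bounds,
    dark_decay = lapply(darkfits, function(d)
      if (!is.null(d$kd)) list(kd = d$kd) else list(k = d$k))),
    fit_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  emp_json <- file.path(config[["out_dir"]], "empirical.json")
  jsonlite::write_json(list(provenance = prov,
                            params = lapply(emp, unclass)),
                       emp_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  out <- list(fit = fit, empirical = emp, powerlaw = pl,
              dark_decay = darkfits,
              files = c(fit_json, emp_json))
  if (length(pl)) {
    pl_json <- file.path(config[["out_dir"]], "powerlaw.json")
    jsonlite::write_json(list(provenance = prov,
                              fits = lapply(pl, function(f)
                                f[c("A", "delta", "se_A", "se_delta",
                                    "r_squared", "n")])),
                         pl_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    out$files <- c(out$files, pl_json)
  }

  rpt <- file.path(config[["out_dir"]], "report.txt")
  con <- file(rpt, "w"); on.exit(close(con))
  sink(con); on.exit(sink(), add = TRUE, after = FALSE)
  cat("luxkin pipeline report\n======================\n\n")
  print(summary(fit))
  cat("\nEmpirical parameters per curve:\n")
  for (nm in names(emp)) { cat("\n", nm, "\n", sep = ""); print(emp[[nm]]) }
  if (length(pl)) {
    cat("\nPower-law viscosity fits:\n")
    for (nm in names(pl)) { cat("\n", nm, "\n", sep = ""); print(pl[[nm]]) }
  }
  out$files <- c(out$files, rpt)
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
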