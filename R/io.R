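# Configuration files, output persistence, run manifests.

.stopRuleKeys <- c("maxDays", "stopOnExtinction", "failureThresholdCells",
                   "failureHorizonDays")

#' Load a configuration file
#'
#' Flat key/value YAML. Keys are either \linkS4class{SimulationParams}
#' fields (units as documented there) or stopping-rule fields
#' (`maxDays`, `stopOnExtinction`, `failureThresholdCells`,
#' `failureHorizonDays`). Unknown keys are an error; an empty file yields
#' the full base parameter set.
#'
#' @param path config file path.
#' @param overrides optional named list applied on top of the file
#'   (e.g. parsed from `--set key=value` command-line flags).
#' @return List with elements `params` (\linkS4class{SimulationParams})
#'   and `stop` (\linkS4class{StopRule}).
#' @export
loadConfig <- function(path, overrides = list()) {
  cfg <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- yaml::read_yaml(path)
    if (is.null(cfg)) cfg <- list()
    if (!is.list(cfg)) stop("config must be a flat key/value mapping")
  }
  cfg[names(overrides)] <- overrides
  # YAML reads scientific notation like "1e-5" as a string; coerce
  cfg <- lapply(cfg, function(v) {
    if (is.character(v) && length(v) == 1) {
      n <- suppressWarnings(as.numeric(v))
      if (!is.na(n)) return(n)
      if (tolower(v) %in% c("true", "false")) return(as.logical(v))
    }
    v
  })
  valid <- c(names(.paramDefaults()), .stopRuleKeys)
  unknown <- setdiff(names(cfg), valid)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "\nvalid keys: ", paste(valid, collapse = ", "))
  stopArgs <- cfg[intersect(names(cfg), .stopRuleKeys)]
  params <- validateParams(cfg[setdiff(names(cfg), .stopRuleKeys)])
  list(params = params, stop = do.call(stopRule, stopArgs))
}

.outcomeAsList <- function(o) {
  list(extinction_time = if (is.na(o@extinctionTime)) NULL else o@extinctionTime,
       max_tumor = o@maxTumor, t_max_tumor = o@tMaxTumor,
       n_relapses = o@nRelapses, failed = o@failed)
}

.writeAtomic <- function(writer, path) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  path
}

#' Write run outputs
#'
#' Persists a run into a directory: `timeseries.csv` (long-format series),
#' `summary.json` (outcome), `params.json` (fully resolved parameters) and
#' `manifest.json` (seed, package version, stop rule, and an inventory of
#' the other files with MD5 checksums). Files are written atomically
#' (temp file + rename).
#'
#' @param dir output directory (created if needed).
#' @param run a \linkS4class{HybridRun}.
#' @return Invisibly, a data.frame inventory (file, md5).
#' @export
writeOutputs <- function(dir, run) {
  stopifnot(is(run, "HybridRun"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ts <- file.path(dir, "timeseries.csv")
  .writeAtomic(function(f) utils::write.csv(run@series, f, row.names = FALSE),
               ts)
  sm <- file.path(dir, "summary.json")
  .writeAtomic(function(f) jsonlite::write_json(
    .outcomeAsList(run@outcome), f, auto_unbox = TRUE, digits = NA, null = "null"), sm)
  pj <- file.path(dir, "params.json")
  .writeAtomic(function(f) jsonlite::write_json(
    paramsAsList(run@params), f, auto_unbox = TRUE, digits = I(17)), pj)
  inv <- data.frame(file = c("timeseries.csv", "summary.json", "params.json"),
                    md5 = unname(tools::md5sum(c(ts, sm, pj))))
  manifest <- list(
    seed = run@seed,
    package_version = as.character(utils::packageVersion("tumorCTL")),
    stop_rule = list(maxDays = run@stop@maxDays,
                     stopOnExtinction = run@stop@stopOnExtinction,
                     failureThresholdCells = run@stop@failureThresholdCells,
                     failureHorizonDays = run@stop@failureHorizonDays),
    params = paramsAsList(run@params),
    files = inv)
  .writeAtomic(function(f) jsonlite::write_json(
    manifest, f, auto_unbox = TRUE, digits = I(17)),
    file.path(dir, "manifest.json"))
  invisible(inv)
}

#' Write a sensitivity sweep
#'
#' `sweep.csv` holds one row per run; `sensitivity.json` the Spearman
#' correlations and p-values per endpoint.
#'
#' @param dir output directory.
#' @param res a \linkS4class{SensitivityResult}.
#' @return Invisibly, the output paths.
#' @export
writeSweep <- function(dir, res) {
  stopifnot(is(res, "SensitivityResult"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sw <- file.path(dir, "sweep.csv")
  .writeAtomic(function(f) utils::write.csv(res@outcomes, f, row.names = FALSE),
               sw)
  sj <- file.path(dir, "sensitivity.json")
  .writeAtomic(function(f) jsonlite::write_json(
    list(param = res@param, reps = res@reps, seed0 = res@seed0,
         grid = res@grid, endpoints = res@rho),
    f, auto_unbox = TRUE, digits = NA), sj)
  invisible(c(sw, sj))
}
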