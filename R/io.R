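#' Load a run configuration from JSON
#'
#' Reads a structured JSON configuration describing model parameters,
#' circadian forcing, dose schedule and DUO settings, validates every
#' field against the constructors' invariants and fills unspecified
#' fields with the nominal defaults.  Unknown keys are rejected.
#'
#' Recognised top-level keys: \code{params} (reduced-model kinetic
#' constants), \code{calibration} (autoreceptor factor), \code{circadian},
#' \code{schedule} (\code{dose}, \code{times}, \code{half_life}),
#' \code{duo} (either \code{preset} or explicit coupling constants plus
#' \code{s_dat}), \code{fire}, \code{seed}.
#'
#' @param path file path to a JSON configuration (an empty object gives
#'   the full nominal defaults: Table of kinetic constants, circadian on,
#'   no doses).
#' @return List with elements \code{model} (a
#'   \code{\link{dopamine_model}} or \code{\link{duo_model}}),
#'   \code{schedule} (\code{\link{dose_schedule}} or NULL) and
#'   \code{seed}.
#' @export
load_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg)) cfg <- list()
  allowed <- c("params", "calibration", "circadian", "schedule", "duo",
               "fire", "seed")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("load_config: unknown configuration keys: ",
         paste(unknown, collapse = ", "))

  params <- do.call(reduced_params, as.list(cfg$params))
  calib <- do.call(autoreceptor_calibration, as.list(cfg$calibration))
  circ <- do.call(circadian_config, as.list(cfg$circadian))
  fire <- if (is.null(cfg$fire)) 1 else cfg$fire

  schedule <- NULL
  if (!is.null(cfg$schedule))
    schedule <- do.call(dose_schedule, as.list(cfg$schedule))

  model <- if (!is.null(cfg$duo)) {
    d <- as.list(cfg$duo)
    dp <- if (!is.null(d$preset)) {
      duo_preset(d$preset,
                 s_dat = if (is.null(d$s_dat)) 1 else d$s_dat,
                 reduced = params)
    } else {
      d$reduced <- params
      do.call(duo_params, d)
    }
    duo_model(dp, circadian = circ, fire = fire)
  } else {
    dopamine_model(params = params, calib = calib, circadian = circ,
                   fire = fire)
  }
  list(model = model, schedule = schedule,
       seed = if (is.null(cfg$seed)) NULL else as.integer(cfg$seed))
}

#' Save a configuration skeleton to JSON
#'
#' Writes the fields of a model (and optional schedule) in the layout read
#' back by \code{\link{load_config}}, so runs round-trip through plain
#' text.
#'
#' @param model a \code{\link{dopamine_model}}.
#' @param path output file path.
#' @param schedule optional \code{\link{dose_schedule}}.
#' @param seed optional integer seed to record.
#' @return \code{path}, invisibly.
#' @export
save_config <- function(model, path, schedule = NULL, seed = NULL) {
  cfg <- list(params = unclass(model$params),
              calibration = unclass(model$calib),
              circadian = unclass(model$circadian),
              fire = model$fire)
  if (model$kind == "duo") {
    d <- model$duo
    cfg$duo <- list(k1_pool = d$k1_pool, k2_pool = d$k2_pool,
                    k3_pool = d$k3_pool, k4_pool = d$k4_pool,
                    alpha = d$alpha, beta = d$beta, gamma = d$gamma,
                    m = d$m, s_dat = d$s_dat)
  }
  if (!is.null(schedule))
    cfg$schedule <- list(dose = schedule$dose, times = schedule$times,
                         half_life = schedule$half_life)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a results table to CSV or JSON at full precision
#'
#' Numeric columns are serialised with 17 significant digits so finite
#' doubles round-trip exactly; NA/NaN cells (failed grid points) are
#' written explicitly.  Optional units are appended to the CSV column
#' names as \code{"name (unit)"}.
#'
#' @param table a data frame.
#' @param path output file path.
#' @param format \code{"csv"} or \code{"json"}.
#' @param units optional character vector of units, one per column
#'   (\code{""} for dimensionless), used in the CSV header.
#' @return \code{path}, invisibly.
#' @export
write_table <- function(table, path, format = c("csv", "json"),
                        units = NULL) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(table, path, digits = NA, na = "string",
                         pretty = TRUE)
    return(invisible(path))
  }
  out <- table
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]))
      out[[j]] <- vapply(out[[j]], function(v)
        if (is.na(v)) NA_character_ else sprintf("%.17g", v),
        character(1))
  }
  if (!is.null(units)) {
    stopifnot(length(units) == ncol(out))
    names(out) <- ifelse(nzchar(units),
                         paste0(names(out), " (", units, ")"),
                         names(out))
  }
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     qmethod = "double", na = "NA")
  invisible(path)
}

#' Read a table written by \code{\link{write_table}}
#'
#' @param path CSV file path.
#' @return Data frame; unit annotations are stripped from column names.
#' @export
read_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  names(df) <- sub(" \\(.*\\)$", "", names(df))
  df
}

#' Machine-readable manifest of a reproducible run
#'
#' @param config_path path of the configuration the run used (hashed into
#'   the manifest), or NULL.
#' @param seed integer seed threaded through the run.
#' @param extra named list of additional fields to record.
#' @return List with package version, timestamp, seed, and configuration
#'   provenance (path and md5), suitable for \code{jsonlite} export.
#' @export
run_manifest <- function(config_path = NULL, seed = NULL, extra = list()) {
  man <- list(package = "dopadyn",
              version = as.character(utils::packageVersion("dopadyn")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              seed = seed)
  if (!is.null(config_path))
    man$config <- list(path = config_path,
                       md5 = unname(tools::md5sum(config_path)))
  c(man, extra)
}
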