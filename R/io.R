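# Versioned on-disk containers. Sessions, models, feature streams and
# decodings are stored as tagged RDS containers with explicit type checks;
# tabular artefacts (cue tables, command logs, histories) export to CSV and
# configs/reports to JSON/YAML.

BSITOOLS_FORMAT_VERSION <- 1L

save_container <- function(object, type, path) {
  saveRDS(list(format = "bsitools", type = type,
               version = BSITOOLS_FORMAT_VERSION, object = object),
          path)
  invisible(path)
}

load_container <- function(path, type) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    abort(sprintf("Cannot read '%s': %s", path, conditionMessage(e)),
          class = "bsitools_io_error")
  })
  if (!is.list(obj) || !identical(obj$format, "bsitools")) {
    abort(sprintf("'%s' is not a bsitools container.", path),
          class = "bsitools_io_error")
  }
  if (!identical(obj$type, type)) {
    abort(sprintf("'%s' holds a '%s', not a '%s'.", path, obj$type, type),
          class = "bsitools_io_error")
  }
  if (!identical(obj$version, BSITOOLS_FORMAT_VERSION)) {
    abort(sprintf("Unsupported container version %s.", obj$version),
          class = "bsitools_io_error")
  }
  obj$object
}

#' Persist and restore sessions, models, features and decodings
#'
#' Tagged, versioned containers: loading checks the container type and
#' schema version, so a features file can never be mistaken for a session
#' and truncated files fail cleanly without partial objects.
#'
#' @param session,model,features,decoding Objects to save.
#' @param path File path.
#' @return Loaders return the stored object; savers the path, invisibly.
#' @name bsi_io
NULL

#' @rdname bsi_io
#' @export
save_session <- function(session, path) {
  stopifnot(inherits(session, "bsi_session"))
  save_container(session, "session", path)
}

#' @rdname bsi_io
#' @export
load_session <- function(path) load_container(path, "session")

#' @rdname bsi_io
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "bsi_mslm"))
  save_container(model, "model", path)
}

#' @rdname bsi_io
#' @export
load_model <- function(path) load_container(path, "model")

#' @rdname bsi_io
#' @export
save_features <- function(features, path) {
  stopifnot(inherits(features, "bsi_features"))
  save_container(features, "features", path)
}

#' @rdname bsi_io
#' @export
load_features <- function(path) load_container(path, "features")

#' @rdname bsi_io
#' @export
save_decoding <- function(decoding, path) {
  stopifnot(inherits(decoding, "bsi_decoding"))
  save_container(decoding, "decoding", path)
}

#' @rdname bsi_io
#' @export
load_decoding <- function(path) load_container(path, "decoding")

#' Default pipeline configuration
#'
#' One flat configuration with one section per module; every key is
#' overridable from a YAML/JSON file or CLI flags. Unknown keys are
#' rejected on read.
#'
#' @param seed Master seed.
#' @return Nested named list.
#' @export
default_run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = list(n_channels = 64L, fs = 586,
                    states = c("rest", "hipL", "kneeL", "ankleL",
                               "hipR", "kneeR", "ankleR"),
                    n_reps = 30L, cue_duration_s = 2,
                    background_exponent = 1, effect_size = 1),
    features = list(epoch_ms = 500, n_taps = 5L, step_ms = 100),
    decoder = list(lambda = 0.99, batch_s = 15, assist_init = 1,
                   assist_batches = 10L, trans_eps = 1, ridge_rel = 1e-4),
    controller = list(theta_u = 0.1, p0 = 0.5, tick_ms = 300,
                      amplitude_range = c(14, 16)),
    paths = list(session = "session.rds", model = "model.rds",
                 decoding = "decoding.rds", commands = "commands.csv",
                 report = "report.json", history = "history.csv",
                 cues = "cues.csv", programs = "programs.json")
  )
}

#' Read and validate a pipeline configuration
#'
#' Reads YAML (`.yaml`/`.yml`) or JSON (`.json`), rejects unknown keys and
#' merges the result over [default_run_config()].
#'
#' @param path Config file path.
#' @return Validated config list.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                abort("Config must be .yaml/.yml/.json.",
                      class = "bsitools_config_error"))
  validate_run_config(raw)
}

#' @rdname read_run_config
#' @param config Partial or full config list to validate/merge.
#' @export
validate_run_config <- function(config) {
  def <- default_run_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown) > 0L) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")),
          class = "bsitools_config_error")
  }
  for (sec in names(config)) {
    if (is.list(def[[sec]]) && is.list(config[[sec]])) {
      bad <- setdiff(names(config[[sec]]), names(def[[sec]]))
      if (length(bad) > 0L) {
        abort(paste0("Unknown key(s) in section '", sec, "': ",
                     paste(bad, collapse = ", ")),
              class = "bsitools_config_error")
      }
    }
  }
  modifyList(def, config)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(config, path)
  } else {
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Export a cue table or command log to CSV
#'
#' @param x Tibble (cue blocks or dispatched commands).
#' @param path CSV path.
#' @return The path, invisibly.
#' @export
write_table_csv <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}
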