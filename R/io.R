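#' Read a canonical trial CSV
#'
#' Reads a long-format trial table (UTF-8, `.` decimal separator) with the
#' canonical columns `participant_id,task,session,modality,stimulus,
#' response,trial_index` and validates every row against the trial-schema
#' invariants (see [validate_trials()]).
#'
#' @param path path to the CSV file.
#' @param config a `pipeline_config`; units and stimulus-set membership are
#'   taken from it.
#' @return A data frame of validated trials, row order preserved.
#' @export
read_trials <- function(path, config = default_config()) {
  if (!file.exists(path)) stop("trial file does not exist: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  missing <- setdiff(TRIAL_COLUMNS, names(raw))
  if (length(missing))
    stop("trial file is missing column(s): ", paste(missing, collapse = ", "))
  raw <- raw[TRIAL_COLUMNS]
  num <- function(col) {
    x <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(x) & !is.na(raw[[col]]) & nzchar(raw[[col]]))
    if (length(bad))
      stop(sprintf("non-numeric %s value '%s' (row %d)", col,
                   raw[[col]][bad[1]], bad[1]))
    x
  }
  trials <- data.frame(
    participant_id = raw$participant_id,
    task = raw$task, session = raw$session, modality = raw$modality,
    stimulus = num("stimulus"), response = num("response"),
    trial_index = as.integer(num("trial_index")),
    stringsAsFactors = FALSE)
  validate_trials(trials, config)
  trials
}

#' Write a canonical trial CSV
#'
#' Writes trials in the canonical column order with lossless numeric
#' formatting (15 significant digits; integer-valued magnitudes round-trip
#' bit-exactly). An empty collection yields a header-only file.
#'
#' @param trials validated trial data frame.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_trials <- function(trials, path) {
  out <- trials[intersect(TRIAL_COLUMNS, names(trials))]
  missing <- setdiff(TRIAL_COLUMNS, names(out))
  if (length(missing))
    stop("trials are missing column(s): ", paste(missing, collapse = ", "))
  for (col in c("stimulus", "response"))
    out[[col]] <- vapply(out[[col]], format, "", digits = 15)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pipeline configuration from JSON or YAML
#'
#' Every field is optional; unspecified fields take the defaults of
#' [default_config()]. YAML files require the `yaml` package.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  x <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package; use JSON instead")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  as_pipeline_config(x)
}

#' Write a pipeline configuration as JSON
#'
#' @param config a `pipeline_config`.
#' @param path output path (`.json`).
#' @return Invisibly, `path`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config_to_list(config), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

# plain-list snapshot of a config (classes stripped), for JSON and manifests
config_to_list <- function(config) {
  strip <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, strip)
      attributes(x) <- list(names = names(x))
    }
    x
  }
  strip(unclass(config))
}
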