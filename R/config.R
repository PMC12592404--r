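#' @keywords internal
"_PACKAGE"

TASKS <- c("temporal", "spatial")
SESSIONS <- c("audio", "vision", "interleaved")
MODALITIES <- c("A", "V")
REGIMES <- c("veridical", "seg_audio", "seg_vision", "cte", "wcte")

#' Canonical trial-table column names
#'
#' Column order of the canonical long-format trial CSV used throughout the
#' pipeline.
#' @export
TRIAL_COLUMNS <- c("participant_id", "task", "session", "modality",
                   "stimulus", "response", "trial_index")

#' Define a stimulus set for one task and modality
#'
#' A stimulus set is the ordered list of magnitudes presented in one
#' task x modality cell, together with its physical bounds. Magnitudes are
#' milliseconds for the temporal task and degrees of visual angle for the
#' spatial task; no unit conversion happens anywhere downstream.
#'
#' @param task `"temporal"` or `"spatial"`.
#' @param modality `"A"` (auditory) or `"V"` (visual).
#' @param values strictly increasing positive magnitudes.
#' @return An object of class `stimulus_set` with elements `task`,
#'   `modality`, `values`, and bounds `a = min(values)`, `b = max(values)`.
#' @export
#' @examples
#' stimulus_set("temporal", "A", seq(490, 850, by = 45))
stimulus_set <- function(task, modality, values) {
  task <- match.arg(task, TASKS)
  modality <- match.arg(modality, MODALITIES)
  values <- as.numeric(values)
  if (length(values) < 2) stop("a stimulus set needs at least 2 values")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("stimulus values must be positive and finite")
  if (any(diff(values) <= 0))
    stop("stimulus values must be strictly increasing")
  structure(
    list(task = task, modality = modality, values = values,
         a = min(values), b = max(values)),
    class = "stimulus_set")
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf("<stimulus_set> %s/%s: %s  [a=%g, b=%g]\n", x$task, x$modality,
              paste(signif(x$values, 6), collapse = ", "), x$a, x$b))
  invisible(x)
}

#' Define the per-session trial counts for one task
#'
#' @param task `"temporal"` or `"spatial"`.
#' @param baseline trials per baseline (single-modality) session.
#' @param interleaved trials per modality within the interleaved session
#'   (the session total is twice this).
#' @return An object of class `session_design`.
#' @export
session_design <- function(task, baseline, interleaved = baseline) {
  task <- match.arg(task, TASKS)
  baseline <- as.integer(baseline); interleaved <- as.integer(interleaved)
  if (baseline < 1 || interleaved < 1) stop("trial counts must be >= 1")
  structure(list(task = task,
                 trials_per_modality_baseline = baseline,
                 trials_per_modality_interleaved = interleaved),
            class = "session_design")
}

#' Default pipeline configuration
#'
#' Encodes the default experimental design: nine equally spaced durations
#' per modality in the temporal task (auditory 490-850 ms, mean 670 ms;
#' visual 760-1120 ms, mean 940 ms; step 45 ms, the two ranges sharing
#' 760, 805 and 850 ms) and six equally spaced lengths per modality in the
#' spatial task (auditory 22-50 deg, mean 36 deg; visual 5.5-33 deg).
#' Baseline sessions have 180 (temporal) / 120 (spatial) trials per
#' modality; the interleaved session carries both modalities at the same
#' per-modality counts (360 / 240 trials in total).
#'
#' @return An object of class `pipeline_config`: a named list with
#'   `stimulus_sets`, `design`, `outlier_threshold`, `prior_provenance`,
#'   `solver` (tolerances and bounds of the prior moment solver), `cv`
#'   (cross-validation folds and seed), `schedule_seed` (fixed seed for the
#'   design-level trial ordering so that stimulus schedules do not depend on
#'   the simulation seed), `normalize`, `membership_tol`, and `units`.
#' @export
#' @examples
#' cfg <- default_config()
#' mean(cfg$stimulus_sets$temporal$A$values)  # 670
default_config <- function() {
  cfg <- list(
    stimulus_sets = list(
      temporal = list(
        A = stimulus_set("temporal", "A", seq(490, 850, by = 45)),
        V = stimulus_set("temporal", "V", seq(760, 1120, by = 45))),
      spatial = list(
        A = stimulus_set("spatial", "A", seq(22, 50, length.out = 6)),
        V = stimulus_set("spatial", "V", seq(5.5, 33, length.out = 6)))),
    design = list(
      temporal = session_design("temporal", 180L, 180L),
      spatial = session_design("spatial", 120L, 120L)),
    outlier_threshold = 3,
    prior_provenance = "discrete_set",
    solver = list(tol = 1e-8, max_iter = 500L, sigma_max_factor = 10,
                  infeasibility_slack = 0.75),
    cv = list(folds = 10L, seed = 20240101L),
    schedule_seed = 1234L,
    normalize = TRUE,
    membership_tol = 1e-9,
    precision_pooling = "unweighted",
    units = list(temporal = "ms", spatial = "deg"),
    simulation = list(n_participants = NULL, regime = NULL,
                      jitter_cv = 0.15, bias_sd = NULL, motor_sd = NULL),
    input_csv = NULL)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (task in names(x$stimulus_sets)) {
    for (m in names(x$stimulus_sets[[task]])) print(x$stimulus_sets[[task]][[m]])
    d <- x$design[[task]]
    cat(sprintf("  design %s: baseline %d, interleaved %d per modality\n",
                task, d$trials_per_modality_baseline,
                d$trials_per_modality_interleaved))
  }
  cat(sprintf("  outlier threshold: %g SD; prior provenance: %s\n",
              x$outlier_threshold, x$prior_provenance))
  invisible(x)
}

#' Validate a pipeline configuration
#'
#' Collects all schema violations at once rather than stopping at the first.
#'
#' @param config a `pipeline_config`, a plain list coercible to one, or a
#'   path to a JSON/YAML config file.
#' @param strict if `TRUE` (default) the default set sizes (9 temporal,
#'   6 spatial values) are enforced; pass `FALSE` to allow non-standard
#'   designs.
#' @return Character vector of diagnostics; `length 0` means the
#'   configuration is valid.
#' @export
validate_config <- function(config, strict = TRUE) {
  if (is.character(config)) config <- read_config(config)
  if (!inherits(config, "pipeline_config")) config <- as_pipeline_config(config)
  bad <- character(0)
  note <- function(fmt, ...) bad <<- c(bad, sprintf(fmt, ...))

  for (task in TASKS) {
    sets <- config$stimulus_sets[[task]]
    if (is.null(sets$A) || is.null(sets$V)) {
      note("stimulus_sets$%s: both modalities A and V are required", task)
      next
    }
    n_expect <- if (task == "temporal") 9L else 6L
    for (m in MODALITIES) {
      s <- sets[[m]]
      if (any(s$values <= 0)) note("stimulus_sets$%s$%s: magnitudes must be positive", task, m)
      if (strict && length(s$values) != n_expect)
        note("stimulus_sets$%s$%s: %d values given, default design requires %d (pass strict = FALSE to override)",
             task, m, length(s$values), n_expect)
    }
  }
  if (!is.numeric(config$outlier_threshold) || config$outlier_threshold <= 0)
    note("outlier_threshold: must be > 0")
  if (!config$prior_provenance %in% c("discrete_set", "continuous_uniform"))
    note("prior_provenance: must be 'discrete_set' or 'continuous_uniform'")
  if (config$cv$folds < 2) note("cv$folds: must be >= 2")
  if (config$solver$tol <= 0) note("solver$tol: must be > 0")
  sim <- config$simulation
  for (f in c("jitter_cv", "bias_sd", "motor_sd"))
    if (!is.null(sim[[f]]) && sim[[f]] < 0) note("simulation$%s: must be >= 0", f)
  if (!is.null(sim$regime) && !sim$regime %in% REGIMES)
    note("simulation$regime: unknown regime '%s'", sim$regime)
  bad
}

#' Coerce a plain list to a pipeline configuration
#'
#' Unspecified fields fall back to [default_config()]; stimulus sets and
#' session designs given as plain lists are rebuilt into their classed
#' forms.
#'
#' @param x a named list (e.g. parsed from JSON or YAML).
#' @return A `pipeline_config`.
#' @export
as_pipeline_config <- function(x) {
  if (inherits(x, "pipeline_config")) return(x)
  stopifnot(is.list(x))
  cfg <- unclass(default_config())
  cfg <- utils::modifyList(cfg, x)
  for (task in TASKS) {
    for (m in MODALITIES) {
      s <- cfg$stimulus_sets[[task]][[m]]
      if (!inherits(s, "stimulus_set")) {
        vals <- if (is.list(s)) s$values else s
        cfg$stimulus_sets[[task]][[m]] <- stimulus_set(task, m, vals)
      }
    }
    d <- cfg$design[[task]]
    if (!inherits(d, "session_design")) {
      cfg$design[[task]] <- session_design(
        task, d$trials_per_modality_baseline,
        d$trials_per_modality_interleaved %||% d$trials_per_modality_baseline)
    }
  }
  class(cfg) <- "pipeline_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a canonical trial table
#'
#' Checks the structural invariants of the trial schema: canonical columns,
#' enum membership, session/modality consistency (`audio` implies `A`,
#' `vision` implies `V`), positive stimuli drawn from the declared stimulus
#' set (absolute tolerance `config$membership_tol`), non-negative numeric
#' responses, and non-negative trial indices.
#'
#' @param trials data frame in the canonical schema (see [TRIAL_COLUMNS]).
#' @param config a `pipeline_config` declaring the stimulus sets.
#' @return Invisibly `TRUE`; stops with an informative message (citing row
#'   numbers) on the first violated invariant.
#' @export
validate_trials <- function(trials, config = default_config()) {
  missing <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(missing))
    stop("trial table is missing column(s): ", paste(missing, collapse = ", "))
  bad_row <- function(what, rows) {
    stop(sprintf("%s (row%s %s)", what, if (length(rows) > 1) "s" else "",
                 paste(utils::head(rows, 5), collapse = ", ")))
  }
  chk_enum <- function(col, levels) {
    bad <- which(!trials[[col]] %in% levels)
    if (length(bad)) bad_row(sprintf("invalid %s value", col), bad)
  }
  chk_enum("task", TASKS); chk_enum("session", SESSIONS)
  chk_enum("modality", MODALITIES)
  if (!is.numeric(trials$response))
    stop("response column must be numeric")
  if (!is.numeric(trials$stimulus))
    stop("stimulus column must be numeric")
  bad <- which(trials$session == "audio" & trials$modality != "A" |
                 trials$session == "vision" & trials$modality != "V")
  if (length(bad))
    bad_row("session/modality invariant violated: session=audio implies modality=A, session=vision implies modality=V", bad)
  bad <- which(!is.finite(trials$stimulus) | trials$stimulus <= 0)
  if (length(bad)) bad_row("stimulus must be positive and finite", bad)
  bad <- which(!is.finite(trials$response) | trials$response < 0)
  if (length(bad)) bad_row("response must be finite and >= 0", bad)
  bad <- which(trials$trial_index < 0 | trials$trial_index != round(trials$trial_index))
  if (length(bad)) bad_row("trial_index must be a non-negative integer", bad)
  tol <- config$membership_tol
  for (task in unique(trials$task)) {
    for (m in unique(trials$modality[trials$task == task])) {
      idx <- which(trials$task == task & trials$modality == m)
      values <- config$stimulus_sets[[task]][[m]]$values
      d <- vapply(trials$stimulus[idx], function(s) min(abs(s - values)), 0)
      if (any(d > tol))
        bad_row(sprintf("stimulus not a member of the declared %s/%s set", task, m),
                idx[d > tol])
    }
  }
  invisible(TRUE)
}
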