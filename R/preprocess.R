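#' Ordinary least-squares fit of perceived versus real magnitudes
#'
#' Fits `perceived = slope * real + intercept` by OLS. The RMSE uses the
#' degrees-of-freedom-adjusted denominator `sqrt(SSE / (n - 2))`, matching
#' the convention of common curve-fitting toolboxes.
#'
#' @param real presented stimulus magnitudes (>= 2 distinct values).
#' @param perceived responses, same length.
#' @return A `linear_fit`: list with `slope`, `intercept`, `rmse`,
#'   `residuals` (response minus fitted value, in input order), and `n`.
#' @export
#' @examples
#' f <- fit_line(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8))
#' f$slope
fit_line <- function(real, perceived) {
  if (length(real) != length(perceived)) stop("input lengths differ")
  n <- length(real)
  if (n < 2) stop("need at least 2 observations")
  if (length(unique(real)) < 2)
    stop("degenerate design: all stimulus values identical")
  fit <- stats::lm.fit(cbind(1, real), perceived)
  res <- perceived - (fit$coefficients[1] + fit$coefficients[2] * real)
  rmse <- if (n > 2) sqrt(sum(res^2) / (n - 2)) else NA_real_
  structure(list(slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 rmse = rmse, residuals = res, n = n),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("<linear_fit> slope=%.4g intercept=%.4g rmse=%.4g (n=%d)\n",
              x$slope, x$intercept, x$rmse, x$n))
  invisible(x)
}

#' Normalize responses of one participant and task
#'
#' Removes idiosyncratic over/under-estimation so that cohorts can be
#' compared on a common scale: within every session x modality cell the
#' responses are centered on that cell's mean response and re-anchored by
#' adding a task-level constant, the mean of the two modality sets' median
#' stimulus values. The transformation is affine per cell, so slopes,
#' regression indices and within-cell response variances are untouched;
#' only intercepts shift by a constant. Note this normalization convention
#' is one reading of an ambiguous procedure and can be switched off via
#' `config$normalize`.
#'
#' @param trials trials of a single participant and task.
#' @param config a `pipeline_config` (provides the stimulus sets defining
#'   the anchor).
#' @return The trials with adjusted responses; stimulus values untouched.
#' @export
normalize_responses <- function(trials, config = default_config()) {
  if (length(unique(trials$participant_id)) != 1 ||
      length(unique(trials$task)) != 1)
    stop("normalize_responses expects trials of one participant and one task")
  task <- trials$task[1]
  sets <- config$stimulus_sets[[task]]
  anchor <- mean(c(stats::median(sets$A$values), stats::median(sets$V$values)))
  cell <- interaction(trials$session, trials$modality, drop = TRUE)
  for (cl in levels(cell)) {
    idx <- which(cell == cl)
    if (length(idx) < 2)
      stop("cell ", cl, " has fewer than 2 trials; cannot normalize")
    trials$response[idx] <- trials$response[idx] - mean(trials$response[idx]) + anchor
  }
  trials
}

#' Normalize a whole cohort
#'
#' Applies [normalize_responses()] per participant x task.
#'
#' @inheritParams normalize_responses
#' @return Normalized trial table (row order preserved within groups).
#' @export
normalize_cohort <- function(trials, config = default_config()) {
  if (!isTRUE(config$normalize)) return(trials)
  parts <- split(trials, list(trials$participant_id, trials$task), drop = TRUE)
  out <- lapply(parts, normalize_responses, config = config)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Linear fits per participant, task, session and modality
#'
#' Fits the perceived-versus-real line in every analysis cell. Baseline
#' sessions form one cell each; interleaved-session trials are split into
#' auditory and visual bins and fitted separately.
#'
#' @param trials cohort trial table (canonical schema).
#' @return Tidy data frame: `participant_id`, `task`, `session`,
#'   `modality`, `slope`, `intercept`, `rmse`, `n`.
#' @export
fits_table <- function(trials) {
  key <- unique(trials[c("participant_id", "task", "session", "modality")])
  rows <- lapply(seq_len(nrow(key)), function(i) {
    k <- key[i, ]
    sub <- trials[trials$participant_id == k$participant_id &
                    trials$task == k$task & trials$session == k$session &
                    trials$modality == k$modality, ]
    f <- fit_line(sub$stimulus, sub$response)
    cbind(k, data.frame(slope = f$slope, intercept = f$intercept,
                        rmse = f$rmse, n = f$n))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Flag outlier participants by baseline RMSE
#'
#' Within every task x session cell, a participant is flagged when their
#' RMSE deviates from the group median by more than `threshold` group
#' standard deviations (center = median, scale = SD — the stated, if
#' unusual, pairing). A participant flagged in any session of a task is
#' excluded from that entire task.
#'
#' @param fits tidy fit table (see [fits_table()]) restricted to the
#'   sessions to screen — typically the two baseline sessions.
#' @param threshold exclusion threshold in group SDs (default 3).
#' @return An `outlier_report`: list with `table` (per participant x task x
#'   session: rmse, group median, group SD, excluded flag) and
#'   `excluded` (named list of excluded participant ids per task).
#' @export
detect_outliers <- function(fits, threshold = 3) {
  if (threshold <= 0) stop("threshold must be > 0")
  tab <- fits[c("participant_id", "task", "session", "rmse")]
  tab$group_median <- NA_real_; tab$group_sd <- NA_real_; tab$excluded <- FALSE
  for (task in unique(tab$task)) {
    for (session in unique(tab$session[tab$task == task])) {
      idx <- which(tab$task == task & tab$session == session)
      if (length(idx) < 3)
        stop(sprintf("need >= 3 participants in %s/%s to estimate the group spread",
                     task, session))
      med <- stats::median(tab$rmse[idx]); s <- stats::sd(tab$rmse[idx])
      tab$group_median[idx] <- med; tab$group_sd[idx] <- s
      tab$excluded[idx] <- abs(tab$rmse[idx] - med) > threshold * s
    }
  }
  excluded <- lapply(split(tab, tab$task), function(d)
    sort(unique(d$participant_id[d$excluded])))
  structure(list(table = tab, excluded = excluded, threshold = threshold),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("<outlier_report> threshold %g SD from group median\n", x$threshold))
  for (task in names(x$excluded)) {
    ex <- x$excluded[[task]]
    cat(sprintf("  %s: %s\n", task,
                if (length(ex)) paste(ex, collapse = ", ") else "no exclusions"))
  }
  invisible(x)
}

#' Preprocess a cohort: normalize, fit, and screen for outliers
#'
#' Runs the standard preprocessing chain: response normalization (if
#' enabled), per-cell linear fits, RMSE-based outlier screening on the
#' baseline sessions, and removal of flagged participants from the
#' affected task.
#'
#' @param trials raw cohort trial table.
#' @param config a `pipeline_config`.
#' @return List with `trials` (normalized, outliers removed), `fits`
#'   (fit table of the retained cohort), and `outliers` (the
#'   [detect_outliers()] report of the full cohort).
#' @export
preprocess_cohort <- function(trials, config = default_config()) {
  validate_trials(trials, config)
  norm <- normalize_cohort(trials, config)
  fits <- fits_table(norm)
  report <- detect_outliers(fits[fits$session %in% c("audio", "vision"), ],
                            threshold = config$outlier_threshold)
  keep <- rep(TRUE, nrow(norm))
  for (task in names(report$excluded)) {
    ex <- report$excluded[[task]]
    if (length(ex))
      keep <- keep & !(norm$task == task & norm$participant_id %in% ex)
  }
  out <- norm[keep, ]
  rownames(out) <- NULL
  list(trials = out, fits = fits_table(out), outliers = report)
}
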