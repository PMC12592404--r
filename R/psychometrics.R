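#' Regression Index: strength of the central tendency effect
#'
#' `RI = 1 - slope` of the perceived-versus-real linear fit: 0 means
#' veridical perception, 1 complete regression to the mean of the stimulus
#' distribution. Values are not clamped, so anti-regression (slope > 1)
#' yields a negative index.
#'
#' @param fit a `linear_fit` (see [fit_line()]) or a numeric slope.
#' @return Numeric regression index.
#' @export
#' @examples
#' regression_index(fit_line(1:5, c(2, 2.5, 3, 3.5, 4)))  # slope 0.5 -> 0.5
regression_index <- function(fit) {
  slope <- if (inherits(fit, "linear_fit")) fit$slope else as.numeric(fit)
  1 - slope
}

#' Per-stimulus sensory precision, corrected for central tendency
#'
#' Response variability in a baseline session understates (or overstates)
#' sensory noise whenever the regression slope differs from 1, because the
#' central tendency effect shrinks the response scale. Following the
#' residual-based correction: per stimulus value, the unbiased variance of
#' the residuals from the participant's linear fit is divided by the
#' squared slope, giving the sensory variance `SP(S_i)` net of central
#' tendency, with `sigma(S_i) = sqrt(SP(S_i))` the likelihood width used by
#' the observer models.
#'
#' @param trials baseline trials of one participant, one task, one
#'   modality.
#' @param fit the `linear_fit` of these trials (residuals aligned with the
#'   row order of `trials`).
#' @param tol absolute tolerance for grouping stimulus values.
#' @return A `precision_profile` data frame: `stimulus`, `n`, `sp_var`,
#'   `sp_sd`, with attributes `task`, `modality`, `participant_id`.
#' @export
sensory_precision <- function(trials, fit, tol = 1e-9) {
  stopifnot(inherits(fit, "linear_fit"))
  if (length(fit$residuals) != nrow(trials))
    stop("fit residuals do not align with the trials")
  if (fit$slope == 0)
    stop("slope is 0: the central-tendency correction is undefined")
  if (length(unique(trials$modality)) != 1)
    stop("sensory precision is defined per modality; got mixed modalities")
  levels <- sort(unique(round(trials$stimulus / tol) * tol))
  # collapse float keys that agree within tol
  levels <- levels[c(TRUE, diff(levels) > tol)]
  rows <- lapply(levels, function(s) {
    idx <- which(abs(trials$stimulus - s) <= tol)
    if (length(idx) < 2)
      stop(sprintf("stimulus %g has fewer than 2 trials; variance undefined", s))
    v <- stats::var(fit$residuals[idx]) / fit$slope^2
    data.frame(stimulus = s, n = length(idx), sp_var = v, sp_sd = sqrt(v))
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("precision_profile", "data.frame"),
            task = trials$task[1], modality = trials$modality[1],
            participant_id = trials$participant_id[1])
}

#' Modality reliability weights
#'
#' Pools each modality's per-stimulus sensory variances into a single
#' variance (unweighted mean across stimulus levels by default, trial-count
#' weighted on request) and computes the auditory weight
#' \deqn{\omega_A = \sigma_V^2 / (\sigma_A^2 + \sigma_V^2), \quad
#'       \omega_V = 1 - \omega_A.}
#' A weight above 0.5 means audition is the more reliable modality for the
#' task.
#'
#' @param profile_A,profile_V baseline [sensory_precision()] profiles of
#'   the two modalities, same task.
#' @param pooling `"unweighted"` (default) or `"n_weighted"`.
#' @return A `modality_weights`: list with `omega_A`, `omega_V`,
#'   `sigma2_A`, `sigma2_V`, `pooling`.
#' @export
modality_weights <- function(profile_A, profile_V,
                             pooling = c("unweighted", "n_weighted")) {
  pooling <- match.arg(pooling)
  ta <- attr(profile_A, "task"); tv <- attr(profile_V, "task")
  if (!is.null(ta) && !is.null(tv) && !identical(ta, tv))
    stop("profiles come from different tasks")
  pool <- function(p) {
    if (pooling == "unweighted") mean(p$sp_var)
    else stats::weighted.mean(p$sp_var, p$n)
  }
  s2a <- pool(profile_A); s2v <- pool(profile_V)
  if (s2a + s2v <= 0)
    stop("both pooled variances are zero: weights undefined")
  structure(list(omega_A = s2v / (s2a + s2v), omega_V = s2a / (s2a + s2v),
                 sigma2_A = s2a, sigma2_V = s2v, pooling = pooling),
            class = "modality_weights")
}

#' @export
print.modality_weights <- function(x, ...) {
  cat(sprintf("<modality_weights> omega_A=%.3f omega_V=%.3f (sigma2_A=%.4g, sigma2_V=%.4g, %s pooling)\n",
              x$omega_A, x$omega_V, x$sigma2_A, x$sigma2_V, x$pooling))
  invisible(x)
}

#' Tidy psychometric summary of a cohort
#'
#' Per participant x task x session x modality: slope, intercept, RMSE and
#' regression index; plus per-stimulus precision profiles and reliability
#' weights from the baseline sessions.
#'
#' @param trials normalized cohort trials.
#' @param config a `pipeline_config`.
#' @return List with `metrics` (tidy data frame including `ri`),
#'   `precision` (per participant x modality x stimulus), and `weights`
#'   (per participant x task).
#' @export
psychometrics_table <- function(trials, config = default_config()) {
  metrics <- fits_table(trials)
  metrics$ri <- regression_index(metrics$slope)
  prec <- list(); wrows <- list()
  for (task in intersect(TASKS, unique(trials$task))) {
    tt <- trials[trials$task == task, ]
    for (pid in unique(tt$participant_id)) {
      pt <- tt[tt$participant_id == pid, ]
      prof <- participant_profiles(pt, config)
      for (m in MODALITIES)
        prec[[length(prec) + 1L]] <- cbind(
          data.frame(participant_id = pid, task = task, modality = m),
          as.data.frame(prof[[m]]))
      w <- modality_weights(prof$A, prof$V, pooling = config$precision_pooling)
      wrows[[length(wrows) + 1L]] <- data.frame(
        participant_id = pid, task = task, omega_A = w$omega_A,
        omega_V = w$omega_V, sigma2_A = w$sigma2_A, sigma2_V = w$sigma2_V)
    }
  }
  list(metrics = metrics,
       precision = do.call(rbind, prec),
       weights = do.call(rbind, wrows))
}
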