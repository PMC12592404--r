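MODEL_NAMES <- c("SegAudio", "SegVision", "CTE", "WCTE")

#' Weight assigned to the prior by an ideal observer
#'
#' \eqn{\omega_P(S_i) = \sigma_L(S_i)^2 / (\sigma_L(S_i)^2 + \sigma_P^2)}:
#' the noisier the sensory measurement relative to the prior, the more the
#' estimate is pulled toward the prior mean. The complementary likelihood
#' weight is `1 - prior_weight(...)`.
#'
#' @param sigma_L likelihood (sensory) SD, >= 0; vectorized.
#' @param prior_sd prior SD, > 0.
#' @return Numeric in `[0, 1)`.
#' @export
prior_weight <- function(sigma_L, prior_sd) {
  if (any(prior_sd <= 0)) stop("prior sd must be > 0")
  if (any(sigma_L < 0)) stop("sigma_L must be >= 0")
  sigma_L^2 / (sigma_L^2 + prior_sd^2)
}

#' Posterior mean of the ideal-observer estimate
#'
#' Reliability-weighted average of the sensory estimate and the prior mean:
#' `mu_R = S * (1 - w_P) + prior_mean * w_P` with
#' `w_P = sigma_L^2 / (sigma_L^2 + prior_sd^2)`. With `sigma_L = 0` the
#' estimate is veridical (`mu_R = S`); as `prior_sd` grows the prior's
#' influence vanishes.
#'
#' @param S sensory estimate / stimulus magnitude; vectorized.
#' @param sigma_L likelihood SD at `S`, >= 0; vectorized.
#' @param prior_mean,prior_sd moments of the prior (`prior_sd > 0`).
#' @return Predicted response magnitude(s).
#' @export
#' @examples
#' posterior_mean(850, 60, 670, 104)
posterior_mean <- function(S, sigma_L, prior_mean, prior_sd) {
  w <- prior_weight(sigma_L, prior_sd)
  S * (1 - w) + prior_mean * w
}

#' Build the prior of one observer model
#'
#' The four models differ only in how their (single, shared across trial
#' modalities) prior is constructed:
#' \describe{
#'   \item{SegAudio}{truncated-normal prior moment-matched to the auditory
#'     stimulus set on its own bounds.}
#'   \item{SegVision}{same, for the visual set.}
#'   \item{CTE}{supra-modal prior matched to the pooled stimulus values of
#'     both modalities (duplicates included) on the combined bounds.}
#'   \item{WCTE}{weighted prior: mean `mu_A*w_A + mu_V*w_V` and SD
#'     `sqrt(w_A*sd_A^2 + w_V*sd_V^2)`, where `(mu_A, sd_A)` and
#'     `(mu_V, sd_V)` are the moments of the two solved segregation priors
#'     and `w_A` is the participant's auditory reliability weight. No
#'     separate truncated prior is re-solved.}
#' }
#'
#' @param name one of `"SegAudio"`, `"SegVision"`, `"CTE"`, `"WCTE"`.
#' @param sets list with elements `A` and `V`, the task's [stimulus_set()]s.
#' @param weights a [modality_weights()] object; required for WCTE.
#' @param provenance moment-target provenance, see [set_moment_target()].
#' @param solver solver settings (list with `tol`, `max_iter`,
#'   `sigma_max_factor`, `infeasibility_slack`), e.g.
#'   `default_config()$solver`.
#' @return A `model_spec`: list with `name`, `prior`, `task`, and for WCTE
#'   the two `components` segregation priors.
#' @export
build_model_prior <- function(name, sets, weights = NULL,
                              provenance = "discrete_set",
                              solver = default_config()$solver) {
  name <- match.arg(name, MODEL_NAMES)
  stopifnot(inherits(sets$A, "stimulus_set"), inherits(sets$V, "stimulus_set"))
  solve_set <- function(target) {
    solve_prior(target, tol = solver$tol, max_iter = solver$max_iter,
                sigma_max_factor = solver$sigma_max_factor,
                infeasibility_slack = solver$infeasibility_slack)
  }
  components <- NULL
  prior <- switch(
    name,
    SegAudio = solve_set(set_moment_target(sets$A, provenance)),
    SegVision = solve_set(set_moment_target(sets$V, provenance)),
    CTE = solve_set(moment_target_from_values(
      c(sets$A$values, sets$V$values),
      a = min(sets$A$a, sets$V$a), b = max(sets$A$b, sets$V$b),
      provenance = provenance)),
    WCTE = {
      if (is.null(weights))
        stop("the WCTE model requires modality reliability weights")
      pa <- solve_set(set_moment_target(sets$A, provenance))
      pv <- solve_set(set_moment_target(sets$V, provenance))
      components <- list(SegAudio = pa, SegVision = pv)
      weighted_prior(pa, pv, weights)
    })
  structure(list(name = name, prior = prior, task = sets$A$task,
                 components = components),
            class = "model_spec")
}

#' Combine two segregation priors by reliability weighting
#'
#' @param prior_A,prior_V solved segregation priors (any object with
#'   [prior_mean()] / [prior_sd()] methods).
#' @param weights a [modality_weights()] object.
#' @return A `weighted_prior` with elements `mean`, `sd`, `omega_A`.
#' @export
weighted_prior <- function(prior_A, prior_V, weights) {
  wa <- weights$omega_A; wv <- weights$omega_V
  mu <- prior_mean(prior_A) * wa + prior_mean(prior_V) * wv
  sd <- sqrt(wa * prior_sd(prior_A)^2 + wv * prior_sd(prior_V)^2)
  structure(list(mean = mu, sd = sd, omega_A = wa), class = "weighted_prior")
}

#' @export
prior_mean.weighted_prior <- function(prior) prior$mean
#' @export
prior_sd.weighted_prior <- function(prior) prior$sd

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s (%s): prior mean=%.4g sd=%.4g\n", x$name,
              x$task, prior_mean(x$prior), prior_sd(x$prior)))
  invisible(x)
}

# sigma_L(S) lookup in a baseline precision profile; tolerance-matched
lookup_sigma_L <- function(stimulus, profile, modality, tol = 1e-9) {
  idx <- vapply(stimulus, function(s) {
    d <- abs(profile$stimulus - s)
    j <- which.min(d)
    if (d[j] > tol) NA_integer_ else j
  }, 1L)
  if (anyNA(idx)) {
    miss <- unique(stimulus[is.na(idx)])
    stop(sprintf("no baseline precision estimate for stimulus %s in modality %s",
                 paste(signif(miss, 6), collapse = ", "), modality))
  }
  profile$sp_sd[idx]
}

#' Predict interleaved-session responses under one observer model
#'
#' For every trial the likelihood SD is looked up in the baseline precision
#' profile of the trial's own modality at the same stimulus value; the
#' model's single prior is applied to auditory and visual trials alike, and
#' the predicted response is the posterior mean.
#'
#' @param trials trials of one participant (typically the interleaved
#'   session) in the canonical schema.
#' @param profiles list with elements `A` and `V`: the participant's
#'   baseline [sensory_precision()] profiles.
#' @param spec a `model_spec` from [build_model_prior()].
#' @param tol stimulus-matching tolerance for the profile lookup.
#' @return Data frame with one row per trial: `participant_id`, `task`,
#'   `session`, `modality`, `trial_index`, `stimulus`, `sigma_L`,
#'   `prediction`, `model`.
#' @export
predict_session <- function(trials, profiles, spec, tol = 1e-9) {
  stopifnot(inherits(spec, "model_spec"))
  sdl <- numeric(nrow(trials))
  for (m in unique(trials$modality)) {
    idx <- trials$modality == m
    if (is.null(profiles[[m]]))
      stop("missing baseline precision profile for modality ", m)
    sdl[idx] <- lookup_sigma_L(trials$stimulus[idx], profiles[[m]], m, tol)
  }
  pm <- prior_mean(spec$prior); ps <- prior_sd(spec$prior)
  data.frame(
    participant_id = trials$participant_id, task = trials$task,
    session = trials$session, modality = trials$modality,
    trial_index = trials$trial_index, stimulus = trials$stimulus,
    sigma_L = sdl,
    prediction = posterior_mean(trials$stimulus, sdl, pm, ps),
    model = spec$name, stringsAsFactors = FALSE)
}

#' Predict interleaved responses for a whole cohort under several models
#'
#' Per participant: baseline precision profiles and reliability weights are
#' estimated from the two baseline sessions, the segregation/CTE priors are
#' shared across participants while the WCTE prior uses each participant's
#' own weights ("individual sensitivity"), and predictions are generated
#' for the interleaved trials.
#'
#' @param trials normalized cohort trials (canonical schema, all sessions).
#' @param config a `pipeline_config`.
#' @param models character vector of model names (default: all four).
#' @return A list with `predictions` (tidy data frame, one row per trial x
#'   model), `weights` (per participant x task), and `priors` (the shared
#'   model priors per task).
#' @export
predict_models <- function(trials, config = default_config(),
                           models = MODEL_NAMES) {
  models <- match.arg(models, MODEL_NAMES, several.ok = TRUE)
  out <- list(); wrows <- list(); priors <- list()
  for (task in intersect(TASKS, unique(trials$task))) {
    sets <- config$stimulus_sets[[task]]
    shared <- list()
    for (name in setdiff(models, "WCTE"))
      shared[[name]] <- build_model_prior(name, sets, provenance = config$prior_provenance,
                                          solver = config$solver)
    priors[[task]] <- shared
    tt <- trials[trials$task == task, ]
    for (pid in unique(tt$participant_id)) {
      pt <- tt[tt$participant_id == pid, ]
      profiles <- participant_profiles(pt, config)
      w <- modality_weights(profiles$A, profiles$V,
                            pooling = config$precision_pooling)
      wrows[[length(wrows) + 1L]] <- data.frame(
        participant_id = pid, task = task, omega_A = w$omega_A,
        omega_V = w$omega_V, sigma2_A = w$sigma2_A, sigma2_V = w$sigma2_V,
        stringsAsFactors = FALSE)
      specs <- shared
      if ("WCTE" %in% models)
        specs$WCTE <- build_model_prior("WCTE", sets, weights = w,
                                        provenance = config$prior_provenance,
                                        solver = config$solver)
      inter <- pt[pt$session == "interleaved", ]
      for (name in models)
        out[[length(out) + 1L]] <- predict_session(inter, profiles, specs[[name]])
    }
  }
  list(predictions = do.call(rbind, out),
       weights = do.call(rbind, wrows),
       priors = priors)
}

# baseline precision profiles (A and V) for one participant x task
participant_profiles <- function(trials, config) {
  prof <- list()
  for (m in MODALITIES) {
    session <- if (m == "A") "audio" else "vision"
    base <- trials[trials$session == session, ]
    if (!nrow(base)) stop("missing baseline session '", session, "'")
    fit <- fit_line(base$stimulus, base$response)
    prof[[m]] <- sensory_precision(base, fit)
  }
  prof
}
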