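# run expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Likelihood (sensory noise) SD as a function of stimulus magnitude
#'
#' Affine noise law `floor + coef * stimulus`: `coef` is a Weber-like
#' fraction (noise scaling with magnitude) and `floor` an additive SD
#' floor, so both constant and Weber-like regimes are covered.
#'
#' @param stimulus positive magnitude(s).
#' @param coef Weber-like coefficient, >= 0.
#' @param floor additive SD floor (task units), >= 0.
#' @return SD(s), same length as `stimulus`.
#' @export
#' @examples
#' likelihood_sd(670, 0.1, 0)  # 67
likelihood_sd <- function(stimulus, coef, floor = 0) {
  if (any(stimulus <= 0)) stop("stimulus must be positive")
  if (coef < 0 || floor < 0) stop("noise parameters must be >= 0")
  floor + coef * stimulus
}

#' Define a synthetic observer
#'
#' An observer is characterized by its sensory noise law per modality
#' (affine in stimulus magnitude, see [likelihood_sd()]), motor noise,
#' a constant response bias, and a generative regime naming the prior that
#' shapes its responses: `veridical` (no prior), `seg_audio` / `seg_vision`
#' (single-modality prior), `cte` (pooled supra-modal prior), or `wcte`
#' (reliability-weighted prior). An explicit `prior_mean`/`prior_sd` pair
#' overrides the regime's solved prior, which is useful for controlled
#' simulation studies.
#'
#' @param sigma_A_coef,sigma_A_floor auditory noise law.
#' @param sigma_V_coef,sigma_V_floor visual noise law.
#' @param motor_sd SD of additive response (motor) noise, task units.
#' @param bias constant additive response offset, task units.
#' @param regime generative regime, one of
#'   `r paste0('"', REGIMES, '"', collapse = ", ")`.
#' @param seed integer seed driving this observer's response noise.
#' @param prior_mean,prior_sd optional explicit prior moments overriding
#'   the regime's solved prior.
#' @return An `observer_params` object.
#' @export
observer_params <- function(sigma_A_coef = 0, sigma_A_floor = 0,
                            sigma_V_coef = 0, sigma_V_floor = 0,
                            motor_sd = 0, bias = 0,
                            regime = "veridical", seed = 1L,
                            prior_mean = NULL, prior_sd = NULL) {
  regime <- match.arg(regime, REGIMES)
  sds <- c(sigma_A_coef, sigma_A_floor, sigma_V_coef, sigma_V_floor, motor_sd)
  if (any(sds < 0)) stop("all noise parameters must be >= 0")
  if (!is.null(prior_sd) && prior_sd <= 0) stop("prior_sd must be > 0")
  structure(list(sigma_A_coef = sigma_A_coef, sigma_A_floor = sigma_A_floor,
                 sigma_V_coef = sigma_V_coef, sigma_V_floor = sigma_V_floor,
                 motor_sd = motor_sd, bias = bias, regime = regime,
                 seed = as.integer(seed),
                 prior_mean = prior_mean, prior_sd = prior_sd),
            class = "observer_params")
}

#' Default observer parameters calibrated to the task's dominant modality
#'
#' Produces constant (floor-only) noise levels calibrated against the
#' solved prior of the task's dominant modality (audition for time, vision
#' for space) so that the expected regression index is about 0.2 for the
#' dominant and about 0.6 for the non-dominant modality — the qualitative
#' ordering observed empirically. With prior SD `sigma_P`, a target
#' `RI = r` requires `sigma_L = sigma_P * sqrt(r / (1 - r))`.
#'
#' @param task `"temporal"` or `"spatial"`.
#' @param config a `pipeline_config`.
#' @param regime generative regime; defaults to the task's dominant
#'   segregation regime (`seg_audio` for temporal, `seg_vision` for
#'   spatial).
#' @param motor_sd motor noise; defaults to 10 ms (temporal) or 0.5 deg
#'   (spatial).
#' @param ri_dominant,ri_nondominant target regression indices used for
#'   the calibration.
#' @param seed observer seed.
#' @return An `observer_params` object.
#' @export
default_observer_params <- function(task, config = default_config(),
                                    regime = NULL, motor_sd = NULL,
                                    ri_dominant = 0.2, ri_nondominant = 0.6,
                                    seed = 1L) {
  task <- match.arg(task, TASKS)
  dominant <- if (task == "temporal") "A" else "V"
  if (is.null(regime)) regime <- if (task == "temporal") "seg_audio" else "seg_vision"
  if (is.null(motor_sd)) motor_sd <- if (task == "temporal") 10 else 0.5
  sets <- config$stimulus_sets[[task]]
  prior <- solve_prior(set_moment_target(sets[[dominant]], config$prior_provenance),
                       tol = config$solver$tol, max_iter = config$solver$max_iter,
                       sigma_max_factor = config$solver$sigma_max_factor,
                       infeasibility_slack = config$solver$infeasibility_slack)
  sp <- prior_sd(prior)
  sd_dom <- sp * sqrt(ri_dominant / (1 - ri_dominant))
  sd_non <- sp * sqrt(ri_nondominant / (1 - ri_nondominant))
  floors <- if (dominant == "A") c(A = sd_dom, V = sd_non) else c(A = sd_non, V = sd_dom)
  observer_params(sigma_A_floor = floors[["A"]], sigma_V_floor = floors[["V"]],
                  motor_sd = motor_sd, regime = regime, seed = seed)
}

# the generative prior implied by an observer's regime (NULL = no prior)
observer_prior <- function(params, config, task) {
  if (!is.null(params$prior_mean) && !is.null(params$prior_sd))
    return(gaussian_prior(params$prior_mean, params$prior_sd))
  if (params$regime == "veridical") return(NULL)
  sets <- config$stimulus_sets[[task]]
  if (params$regime == "wcte") {
    # ground-truth weights from the observer's own noise law, pooled over
    # each modality's stimulus values
    s2 <- function(vals, coef, floor) mean(likelihood_sd(vals, coef, floor)^2)
    s2a <- s2(sets$A$values, params$sigma_A_coef, params$sigma_A_floor)
    s2v <- s2(sets$V$values, params$sigma_V_coef, params$sigma_V_floor)
    if (s2a + s2v <= 0) stop("wcte regime needs nonzero sensory noise to define weights")
    w <- structure(list(omega_A = s2v / (s2a + s2v), omega_V = s2a / (s2a + s2v),
                        sigma2_A = s2a, sigma2_V = s2v, pooling = "unweighted"),
                   class = "modality_weights")
    return(build_model_prior("WCTE", sets, weights = w,
                             provenance = config$prior_provenance,
                             solver = config$solver)$prior)
  }
  name <- switch(params$regime, seg_audio = "SegAudio",
                 seg_vision = "SegVision", cte = "CTE")
  build_model_prior(name, sets, provenance = config$prior_provenance,
                    solver = config$solver)$prior
}

# deterministic trial schedule for one task: depends only on the design and
# config$schedule_seed, never on observer seeds, so different simulation
# seeds share identical stimulus schedules
trial_schedule <- function(config, task) {
  task <- match.arg(task, TASKS)
  sets <- config$stimulus_sets[[task]]
  design <- config$design[[task]]
  stim_block <- function(values, count, seed) {
    reps <- count %/% length(values)
    rem <- count %% length(values)
    stim <- rep(values, reps)
    if (rem > 0)
      stim <- c(stim, with_seed(seed + 7L, sample(values, rem)))
    stim
  }
  base_seed <- config$schedule_seed + match(task, TASKS) * 1000L
  blocks <- list()
  for (m in MODALITIES) {
    session <- if (m == "A") "audio" else "vision"
    stim <- stim_block(sets[[m]]$values, design$trials_per_modality_baseline,
                       base_seed + match(m, MODALITIES))
    stim <- with_seed(base_seed + 10L + match(m, MODALITIES), sample(stim))
    blocks[[session]] <- data.frame(session = session, modality = m,
                                    stimulus = stim)
  }
  inter <- do.call(rbind, lapply(MODALITIES, function(m) {
    stim <- stim_block(sets[[m]]$values, design$trials_per_modality_interleaved,
                       base_seed + 20L + match(m, MODALITIES))
    data.frame(session = "interleaved", modality = m, stimulus = stim)
  }))
  # interleaving = seeded uniform shuffle of the concatenated A and V lists
  inter <- inter[with_seed(base_seed + 99L, sample(nrow(inter))), ]
  sched <- rbind(blocks$audio, blocks$vision, inter)
  sched$task <- task
  # per-session 0-based trial index
  idx <- integer(nrow(sched))
  for (s in unique(sched$session)) idx[sched$session == s] <- seq_len(sum(sched$session == s)) - 1L
  sched$trial_index <- idx
  rownames(sched) <- NULL
  sched
}

#' Simulate one participant's trial table
#'
#' Generates the two baseline sessions and the interleaved session with the
#' design's trial counts, each stimulus repeated equally often (remainders
#' distributed by the schedule seed). On every trial the observer draws a
#' noisy sensory measurement `m ~ Normal(S, sigma_L(S))` of the stimulus,
#' reports the posterior mean of its regime's prior combined with that
#' measurement, and adds motor noise and a constant bias; responses are
#' truncated at 0 (durations and lengths cannot be negative) with
#' truncation events counted in the `truncations` attribute. Under the
#' `veridical` regime the posterior mean equals the measurement (no prior).
#'
#' @param params an [observer_params()].
#' @param config a `pipeline_config`.
#' @param task `"temporal"` or `"spatial"`.
#' @param participant_id participant label.
#' @param detail if `TRUE`, append the generative internals per trial:
#'   `sigma_L`, `measurement`, `post_mean` (posterior mean of the
#'   measurement; the response before motor noise), `pred_mean` (posterior
#'   mean of the stimulus itself, i.e. the trial's expected response), and
#'   `truncated`.
#' @return Canonical trial data frame (plus detail columns on request),
#'   with attribute `truncations`.
#' @export
simulate_participant <- function(params, config = default_config(),
                                 task = "temporal", participant_id = "P01",
                                 detail = FALSE) {
  stopifnot(inherits(params, "observer_params"))
  task <- match.arg(task, TASKS)
  sched <- trial_schedule(config, task)
  n <- nrow(sched)
  sdl <- ifelse(sched$modality == "A",
                likelihood_sd(sched$stimulus, params$sigma_A_coef, params$sigma_A_floor),
                likelihood_sd(sched$stimulus, params$sigma_V_coef, params$sigma_V_floor))
  prior <- observer_prior(params, config, task)
  noise <- with_seed(params$seed, list(meas = stats::rnorm(n),
                                       motor = stats::rnorm(n)))
  m <- sched$stimulus + noise$meas * sdl
  if (is.null(prior)) {
    post <- m
    pred <- sched$stimulus
  } else {
    pm <- prior_mean(prior); ps <- prior_sd(prior)
    post <- posterior_mean(m, sdl, pm, ps)
    pred <- posterior_mean(sched$stimulus, sdl, pm, ps)
  }
  resp <- post + noise$motor * params$motor_sd + params$bias
  truncated <- resp < 0
  resp[truncated] <- 0
  out <- data.frame(participant_id = participant_id, task = task,
                    session = sched$session, modality = sched$modality,
                    stimulus = sched$stimulus, response = resp,
                    trial_index = sched$trial_index,
                    stringsAsFactors = FALSE)
  if (detail) {
    out$sigma_L <- sdl; out$measurement <- m
    out$post_mean <- post; out$pred_mean <- pred
    out$truncated <- truncated
  }
  attr(out, "truncations") <- sum(truncated)
  out
}

#' Specify a simulated cohort
#'
#' Per-participant parameters are drawn around `base_params`: multiplicative
#' log-normal jitter with coefficient of variation `jitter_cv` on the noise
#' parameters (keeping them non-negative) and additive normal jitter with
#' SD `bias_sd` on the response bias. Per-participant seeds are derived
#' deterministically from the master seed.
#'
#' @param n_participants cohort size, >= 1.
#' @param base_params an [observer_params()] template.
#' @param jitter_cv coefficient of variation of the multiplicative jitter.
#' @param bias_sd SD of the per-participant bias (task units).
#' @param seed master seed.
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(n_participants, base_params, jitter_cv = 0.15,
                        bias_sd = 0, seed = 1L) {
  if (n_participants < 1) stop("n_participants must be >= 1")
  if (jitter_cv < 0 || bias_sd < 0) stop("jitter parameters must be >= 0")
  stopifnot(inherits(base_params, "observer_params"))
  structure(list(n_participants = as.integer(n_participants),
                 base_params = base_params, jitter_cv = jitter_cv,
                 bias_sd = bias_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a cohort of participants
#'
#' Bit-for-bit reproducible given the same spec: participant labels are
#' stable (`P01`, `P02`, ...), per-participant seeds and parameter jitters
#' derive from the master seed, and the stimulus schedule is shared by all
#' participants and seeds (it depends only on the design).
#'
#' @param spec a [cohort_spec()].
#' @param config a `pipeline_config`.
#' @param task `"temporal"` or `"spatial"`.
#' @param detail passed through to [simulate_participant()].
#' @return Multi-participant canonical trial data frame with attributes
#'   `true_params` (list of each participant's jittered parameters) and
#'   `truncations`.
#' @export
simulate_cohort <- function(spec, config = default_config(),
                            task = "temporal", detail = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_participants
  draws <- with_seed(spec$seed, list(
    seeds = sample.int(.Machine$integer.max - 1L, n),
    jitter = matrix(stats::rnorm(n * 5), n, 5),
    bias = stats::rnorm(n)))
  sdlog <- sqrt(log(1 + spec$jitter_cv^2))
  base <- spec$base_params
  out <- vector("list", n); true_params <- vector("list", n)
  for (i in seq_len(n)) {
    fac <- exp(draws$jitter[i, ] * sdlog - sdlog^2 / 2)
    p <- observer_params(
      sigma_A_coef = base$sigma_A_coef * fac[1],
      sigma_A_floor = base$sigma_A_floor * fac[2],
      sigma_V_coef = base$sigma_V_coef * fac[3],
      sigma_V_floor = base$sigma_V_floor * fac[4],
      motor_sd = base$motor_sd * fac[5],
      bias = base$bias + draws$bias[i] * spec$bias_sd,
      regime = base$regime, seed = draws$seeds[i],
      prior_mean = base$prior_mean, prior_sd = base$prior_sd)
    id <- sprintf("P%02d", i)
    true_params[[id]] <- p
    out[[i]] <- simulate_participant(p, config, task, participant_id = id,
                                     detail = detail)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "true_params") <- true_params
  attr(res, "truncations") <- sum(vapply(out, attr, 0, "truncations"))
  res
}
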