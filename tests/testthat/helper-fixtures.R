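# Reduced designs for fast cohort-level tests: same stimulus sets, fewer
# repetitions (still >= 2 trials per stimulus in every session).
tiny_config <- function() {
  cfg <- default_config()
  cfg$design$temporal <- session_design("temporal", 36L, 18L)
  cfg$design$spatial <- session_design("spatial", 24L, 12L)
  cfg$cv$folds <- 4L
  cfg
}

quick_cohort <- function(task = "temporal", n = 4, seed = 7,
                         config = tiny_config(), bias_sd = 0, ...) {
  base <- default_observer_params(task, config, ...)
  simulate_cohort(cohort_spec(n, base, bias_sd = bias_sd, seed = seed),
                  config, task)
}

# comparison-model fixture: known linear world with participant offsets
comparison_fixture <- function(n_participants = 6, n_trials = 40, seed = 1,
                               noise_sd = 5) {
  set.seed(seed)
  rows <- lapply(seq_len(n_participants), function(i) {
    stim <- runif(n_trials, 100, 200)
    offset <- rnorm(1, 0, 3)
    data.frame(participant = sprintf("P%02d", i), stimulus = stim,
               observed = 20 + 0.7 * stim + offset + rnorm(n_trials, 0, noise_sd))
  })
  do.call(rbind, rows)
}
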