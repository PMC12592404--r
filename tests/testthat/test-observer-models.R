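test_that("posterior mean: weighting, limits, and the two algebraic forms", {
  expect_equal(posterior_mean(1, 1, 0, 1), 0.5)  # equal reliabilities
  expect_equal(posterior_mean(850, 0, 670, 104), 850)  # noiseless -> veridical
  expect_equal(posterior_mean(850, 60, 670, 1e12), 850, tolerance = 1e-9)
  expect_error(posterior_mean(850, 60, 670, 0), "> 0")

  # subtraction form vs weighted form: algebraically identical, guards
  # against transcription bugs
  set.seed(3)
  for (i in 1:50) {
    S <- runif(1, 100, 1200); sl <- runif(1, 0, 300)
    pm <- runif(1, 100, 1200); ps <- runif(1, 1, 300)
    subtraction_form <- S - sl^2 * (S - pm) / (sl^2 + ps^2)
    expect_equal(posterior_mean(S, sl, pm, ps), subtraction_form,
                 tolerance = 1e-12)
  }
})

test_that("prior weight is monotone in both noise scales", {
  sl <- seq(0, 300, by = 10)
  w <- prior_weight(sl, 104)
  expect_true(all(diff(w) > 0))
  expect_true(all(w >= 0 & w < 1))
  ps <- seq(10, 500, by = 10)
  expect_true(all(diff(prior_weight(60, ps)) < 0))
})

test_that("model priors follow each model's construction rule", {
  cfg <- default_config()
  sets <- cfg$stimulus_sets$temporal
  segA <- build_model_prior("SegAudio", sets)
  segV <- build_model_prior("SegVision", sets)
  cte <- build_model_prior("CTE", sets)
  expect_equal(prior_mean(segA$prior), 670, tolerance = 1e-6)
  expect_equal(prior_mean(segV$prior), 940, tolerance = 1e-6)
  # supra-modal prior: mean of the 18 pooled durations
  expect_equal(prior_mean(cte$prior), 805, tolerance = 1e-6)
  # ordering and spread: the pooled range is the widest
  expect_lt(prior_mean(segA$prior), prior_mean(cte$prior))
  expect_lt(prior_mean(cte$prior), prior_mean(segV$prior))
  expect_gt(prior_sd(cte$prior), prior_sd(segA$prior))

  fake_w <- function(omega_A) {
    s2v <- omega_A; s2a <- 1 - omega_A  # any variances realizing the weight
    structure(list(omega_A = omega_A, omega_V = 1 - omega_A,
                   sigma2_A = s2a, sigma2_V = s2v, pooling = "unweighted"),
              class = "modality_weights")
  }
  # degenerate weights collapse WCTE onto a segregation model
  w1 <- build_model_prior("WCTE", sets, weights = fake_w(1))
  expect_equal(prior_mean(w1$prior), prior_mean(segA$prior))
  expect_equal(prior_sd(w1$prior), prior_sd(segA$prior))
  w05 <- build_model_prior("WCTE", sets, weights = fake_w(0.5))
  expect_equal(prior_mean(w05$prior),
               (prior_mean(segA$prior) + prior_mean(segV$prior)) / 2)
  # weighted mean/SD stay bracketed by the segregation priors
  for (omega in c(0.1, 0.3, 0.7, 0.9)) {
    wp <- build_model_prior("WCTE", sets, weights = fake_w(omega))$prior
    expect_gte(prior_mean(wp), prior_mean(segA$prior))
    expect_lte(prior_mean(wp), prior_mean(segV$prior))
    expect_gte(prior_sd(wp), min(prior_sd(segA$prior), prior_sd(segV$prior)))
    expect_lte(prior_sd(wp), max(prior_sd(segA$prior), prior_sd(segV$prior)))
  }
  expect_error(build_model_prior("WCTE", sets), "weights")
})

test_that("predictions match the generator's expected responses exactly", {
  cfg <- tiny_config()
  p <- observer_params(sigma_A_floor = 52, sigma_V_floor = 127,
                       motor_sd = 0, regime = "seg_audio", seed = 17)
  tr <- simulate_participant(p, cfg, "temporal", detail = TRUE)
  # ground-truth precision profiles straight from the noise law
  truth_profile <- function(values, sd) {
    structure(data.frame(stimulus = values, n = 2, sp_var = sd^2, sp_sd = sd),
              class = c("precision_profile", "data.frame"), task = "temporal")
  }
  profiles <- list(A = truth_profile(cfg$stimulus_sets$temporal$A$values, 52),
                   V = truth_profile(cfg$stimulus_sets$temporal$V$values, 127))
  spec <- build_model_prior("SegAudio", cfg$stimulus_sets$temporal)
  inter <- tr[tr$session == "interleaved", ]
  pred <- predict_session(inter, profiles, spec)
  expect_equal(pred$prediction, inter$pred_mean, tolerance = 1e-12)

  # dominant-modality trials shift less under the dominant model's prior
  shift <- abs(pred$prediction - pred$stimulus)
  expect_lt(mean(shift[pred$modality == "A"]),
            mean(shift[pred$modality == "V"]))

  # visual temporal trials are pulled down toward the auditory prior mean
  vis <- pred[pred$modality == "V", ]
  expect_true(all(vis$stimulus > 670))
  expect_true(all(vis$prediction < vis$stimulus))
  expect_true(all(vis$prediction > 670))

  bad_profiles <- profiles
  bad_profiles$V <- truth_profile(c(100, 200), 127)
  expect_error(predict_session(inter, bad_profiles, spec),
               "no baseline precision estimate")
})

test_that("WCTE predictions converge to SegAudio as the auditory weight grows", {
  cfg <- tiny_config()
  sets <- cfg$stimulus_sets$temporal
  trials <- quick_cohort("temporal", n = 1, seed = 29, config = cfg)
  pt <- trials[trials$participant_id == "P01", ]
  profiles <- list(
    A = structure(data.frame(stimulus = sets$A$values, n = 2, sp_var = 52^2,
                             sp_sd = 52),
                  class = c("precision_profile", "data.frame"), task = "temporal"),
    V = structure(data.frame(stimulus = sets$V$values, n = 2, sp_var = 127^2,
                             sp_sd = 127),
                  class = c("precision_profile", "data.frame"), task = "temporal"))
  segA <- build_model_prior("SegAudio", sets)
  inter <- pt[pt$session == "interleaved", ]
  base_pred <- predict_session(inter, profiles, segA)$prediction
  fake_w <- function(omega_A)
    structure(list(omega_A = omega_A, omega_V = 1 - omega_A,
                   sigma2_A = 1 - omega_A, sigma2_V = omega_A,
                   pooling = "unweighted"), class = "modality_weights")
  sup <- vapply(c(0.9, 0.99, 0.999), function(omega) {
    wcte <- build_model_prior("WCTE", sets, weights = fake_w(omega))
    max(abs(predict_session(inter, profiles, wcte)$prediction - base_pred))
  }, 0)
  expect_true(all(diff(sup) < 0))
  expect_lt(sup[3], 0.5)  # sup-norm in ms at omega_A = 0.999
})
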