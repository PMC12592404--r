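test_that("likelihood_sd implements the affine noise law", {
  expect_equal(likelihood_sd(670, 0.1, 0), 67)
  expect_equal(likelihood_sd(670, 0, 5), 5)
  s <- seq(100, 1000, by = 50)
  expect_true(all(diff(likelihood_sd(s, 0.07, 3)) >= 0))
  expect_error(likelihood_sd(-5, 0.1), "positive")
  expect_error(likelihood_sd(5, -0.1), ">= 0")
})

test_that("a noise-free veridical observer reproduces the stimulus exactly", {
  cfg <- tiny_config()
  p <- observer_params(regime = "veridical", seed = 5)
  tr <- simulate_participant(p, cfg, "temporal")
  expect_equal(tr$response, tr$stimulus)
})

test_that("default design produces the printed session sizes", {
  cfg <- default_config()
  tr <- simulate_participant(default_observer_params("temporal", cfg), cfg,
                             "temporal")
  expect_equal(nrow(tr), 720L)
  inter <- tr[tr$session == "interleaved", ]
  expect_equal(nrow(inter), 360L)
  expect_equal(as.vector(table(inter$modality)), c(180L, 180L))
  # each stimulus repeated equally often within each session cell
  counts <- table(tr$stimulus[tr$session == "audio"])
  expect_true(all(counts == 20L))
  expect_true(validate_trials(tr, cfg))
})

test_that("responses equal the analytic posterior mean of the measurement", {
  cfg <- tiny_config()
  p <- observer_params(sigma_A_floor = 60, sigma_V_floor = 120,
                       motor_sd = 0, regime = "seg_audio", seed = 21)
  tr <- simulate_participant(p, cfg, "temporal", detail = TRUE)
  prior <- build_model_prior("SegAudio", cfg$stimulus_sets$temporal)$prior
  pm <- prior_mean(prior); ps <- prior_sd(prior)
  # independent evaluation of the weighted-average form at the measurement
  w <- tr$sigma_L^2 / (tr$sigma_L^2 + ps^2)
  expect_equal(tr$response, tr$measurement * (1 - w) + pm * w,
               tolerance = 1e-12)
  expect_equal(tr$response, tr$post_mean, tolerance = 1e-12)

  # deterministic slope: response regressed on the internal measurement
  aud <- tr[tr$session == "audio", ]
  fit <- fit_line(aud$measurement, aud$response)
  expect_equal(fit$slope, ps^2 / (60^2 + ps^2), tolerance = 1e-9)
})

test_that("empirical regression index converges to the prior weight", {
  cfg <- tiny_config()
  cfg$design$temporal <- session_design("temporal", 1998L, 9L)
  sigma_L <- 80
  p <- observer_params(sigma_A_floor = sigma_L, motor_sd = 0,
                       regime = "seg_audio", seed = 31)
  prior <- build_model_prior("SegAudio", cfg$stimulus_sets$temporal)$prior
  w_P <- sigma_L^2 / (sigma_L^2 + prior_sd(prior)^2)
  tr <- simulate_participant(p, cfg, "temporal")
  aud <- tr[tr$session == "audio", ]
  ri <- regression_index(fit_line(aud$stimulus, aud$response))
  expect_equal(ri, w_P, tolerance = 0.05)
})

test_that("cohorts are reproducible and schedules are seed-invariant", {
  cfg <- tiny_config()
  base <- default_observer_params("temporal", cfg)
  a <- simulate_cohort(cohort_spec(3, base, seed = 11), cfg, "temporal")
  b <- simulate_cohort(cohort_spec(3, base, seed = 11), cfg, "temporal")
  c <- simulate_cohort(cohort_spec(3, base, seed = 12), cfg, "temporal")
  expect_identical(a, b)
  expect_equal(a$stimulus, c$stimulus)     # schedule depends only on design
  expect_identical(a$session, c$session)
  expect_false(any(abs(a$response - c$response) < 1e-12))
  expect_equal(unique(a$participant_id), c("P01", "P02", "P03"))
  expect_true(validate_trials(a, cfg))
})

test_that("uneven trial counts floor the repetitions and distribute the remainder", {
  cfg <- tiny_config()
  cfg$design$temporal <- session_design("temporal", 20L, 11L)
  tr <- simulate_participant(observer_params(regime = "veridical", seed = 1),
                             cfg, "temporal")
  counts <- table(tr$stimulus[tr$session == "audio"])
  expect_equal(sum(counts), 20L)
  expect_true(all(counts %in% c(2L, 3L)))
  inter_a <- table(tr$stimulus[tr$session == "interleaved" & tr$modality == "A"])
  expect_equal(sum(inter_a), 11L)
})

test_that("responses are truncated at zero and truncations counted", {
  cfg <- tiny_config()
  p <- observer_params(sigma_A_floor = 2000, sigma_V_floor = 2000,
                       motor_sd = 0, regime = "veridical", seed = 8)
  tr <- simulate_participant(p, cfg, "temporal", detail = TRUE)
  expect_true(all(tr$response >= 0))
  expect_gt(attr(tr, "truncations"), 0)
  expect_equal(attr(tr, "truncations"), sum(tr$truncated))
})

test_that("the wcte regime pulls the prior toward the reliable modality", {
  cfg <- tiny_config()
  p <- observer_params(sigma_A_floor = 20, sigma_V_floor = 400,
                       motor_sd = 0, regime = "wcte", seed = 2)
  tr <- simulate_participant(p, cfg, "temporal", detail = TRUE)
  segA <- build_model_prior("SegAudio", cfg$stimulus_sets$temporal)$prior
  # near-exclusive auditory reliability: posterior targets ~ auditory prior
  aud <- tr[tr$modality == "A", ]
  w <- aud$sigma_L^2 / (aud$sigma_L^2 + prior_sd(segA)^2)
  approx_segA <- aud$measurement * (1 - w) + prior_mean(segA) * w
  expect_equal(aud$response, approx_segA, tolerance = 1e-2)
})
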