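test_that("fit_line matches the closed-form normal equations", {
  expect_equal(unclass(fit_line(1:5, 1:5))[c("slope", "intercept", "rmse")],
               list(slope = 1, intercept = 0, rmse = 0))
  f <- fit_line(1:5, rep(7, 5))
  expect_equal(f$slope, 0)
  expect_equal(f$intercept, 7)

  set.seed(13)
  for (i in 1:5) {
    x <- runif(30, 400, 900)
    y <- 50 + 0.6 * x + rnorm(30, 0, 40)
    f <- fit_line(x, y)
    # independent oracle: explicit normal-equations solution
    sxx <- sum((x - mean(x))^2)
    slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
    intercept <- mean(y) - slope * mean(x)
    expect_equal(f$slope, slope, tolerance = 1e-10)
    expect_equal(f$intercept, intercept, tolerance = 1e-10)
    res <- y - intercept - slope * x
    expect_equal(f$rmse, sqrt(sum(res^2) / (length(x) - 2)), tolerance = 1e-10)
    expect_equal(mean(f$residuals), 0, tolerance = 1e-9 * mean(abs(y)))
  }
  expect_error(fit_line(rep(5, 4), 1:4), "degenerate")
  expect_error(fit_line(1, 1), "at least 2")
})

test_that("normalization centers cells, anchors to the set medians, and is invariant-preserving", {
  cfg <- tiny_config()
  trials <- quick_cohort("temporal", n = 1, seed = 5, config = cfg)
  anchor <- mean(c(median(cfg$stimulus_sets$temporal$A$values),
                   median(cfg$stimulus_sets$temporal$V$values)))  # 805
  norm <- normalize_responses(trials, cfg)
  cell <- interaction(norm$session, norm$modality, drop = TRUE)
  for (cl in levels(cell))
    expect_equal(mean(norm$response[cell == cl]), anchor)

  # fixed point: renormalizing changes nothing
  expect_equal(normalize_responses(norm, cfg)$response, norm$response)

  # per-cell constant offsets cancel
  shifted <- trials
  idx <- shifted$session == "audio"
  shifted$response[idx] <- shifted$response[idx] + 123.4
  expect_equal(normalize_responses(shifted, cfg)$response, norm$response)

  # slopes and within-cell variances are untouched
  aud_raw <- trials[trials$session == "audio", ]
  aud_nrm <- norm[norm$session == "audio", ]
  expect_equal(fit_line(aud_nrm$stimulus, aud_nrm$response)$slope,
               fit_line(aud_raw$stimulus, aud_raw$response)$slope)
  expect_equal(var(aud_nrm$response), var(aud_raw$response))

  tiny <- trials[c(1, which(trials$session == "vision")), ]
  expect_error(normalize_responses(tiny, cfg), "fewer than 2 trials")
})

test_that("outlier screening flags RMSE spikes and excludes whole tasks", {
  # equal RMSE everywhere: nobody excluded
  fits <- expand.grid(participant_id = sprintf("P%02d", 1:12),
                      task = "temporal", session = c("audio", "vision"),
                      stringsAsFactors = FALSE)
  fits$rmse <- 40
  rep0 <- detect_outliers(fits)
  expect_length(rep0$excluded$temporal, 0L)

  # a single-session spike excludes the participant from the whole task.
  # (n = 12: the median/SD rule cannot flag a single spike in cohorts
  # smaller than ~10, because the spike inflates the SD it is judged
  # against — the deviation/SD ratio is bounded by sqrt(n).)
  set.seed(2)
  fits$rmse <- rnorm(nrow(fits), 40, 2)
  fits$rmse[fits$participant_id == "P03" & fits$session == "vision"] <- 800
  rep1 <- detect_outliers(fits)
  expect_equal(rep1$excluded$temporal, "P03")
  tab <- rep1$table
  expect_true(all(tab$excluded ==
                    (abs(tab$rmse - tab$group_median) > 3 * tab$group_sd)))

  expect_error(detect_outliers(fits[fits$participant_id %in% c("P01", "P02"), ]),
               ">= 3 participants")
  expect_error(detect_outliers(fits, threshold = 0), "> 0")
})

test_that("a 21-participant cohort with 3 spikes yields 19 temporal / 20 spatial", {
  set.seed(7)
  fits <- expand.grid(participant_id = sprintf("P%02d", 1:21),
                      task = c("temporal", "spatial"),
                      session = c("audio", "vision"),
                      stringsAsFactors = FALSE)
  fits$rmse <- ifelse(fits$task == "temporal", rnorm(nrow(fits), 60, 4),
                      rnorm(nrow(fits), 3, 0.3))
  # one participant outlying in both temporal sessions, one in vision only,
  # one in the spatial auditory session. The two co-occurring vision spikes
  # must be near-equal: with two spikes among n the deviation/SD ratio is
  # bounded by sqrt(n/2) ~ 3.2 here, so unequal spikes mask each other.
  fits$rmse[fits$participant_id == "P05" & fits$task == "temporal"] <- 1000
  fits$rmse[fits$participant_id == "P09" & fits$task == "temporal" &
              fits$session == "vision"] <- 990
  fits$rmse[fits$participant_id == "P17" & fits$task == "spatial" &
              fits$session == "audio"] <- 60
  report <- detect_outliers(fits)
  expect_setequal(report$excluded$temporal, c("P05", "P09"))
  expect_equal(report$excluded$spatial, "P17")
  expect_equal(21 - length(report$excluded$temporal), 19)
  expect_equal(21 - length(report$excluded$spatial), 20)
})

test_that("preprocess_cohort removes flagged participants from the task only", {
  cfg <- tiny_config()
  base <- default_observer_params("temporal", cfg)
  spec <- cohort_spec(12, base, bias_sd = 10, seed = 19)
  trials <- simulate_cohort(spec, cfg, "temporal")
  # inflate one participant's audio-session scatter far beyond the cohort
  bad <- trials$participant_id == "P02" & trials$session == "audio"
  set.seed(1)
  trials$response[bad] <- pmax(trials$response[bad] + rnorm(sum(bad), 0, 2500), 0)
  prep <- preprocess_cohort(trials, cfg)
  expect_equal(prep$outliers$excluded$temporal, "P02")
  expect_false("P02" %in% prep$trials$participant_id)
  expect_equal(length(unique(prep$trials$participant_id)), 11L)
})
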