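#' Score one model's predictions with a linear mixed model
#'
#' Fits `observed ~ stimulus + prediction + (1 | participant)` by maximum
#' likelihood (not REML, so information criteria are comparable across
#' models whose prediction regressors differ) and extracts AIC, BIC,
#' log-likelihood, deviance (`-2 logLik`), and `R^2` as the squared Pearson
#' correlation between observations and fitted values.
#'
#' @param data data frame with columns `observed`, `stimulus`,
#'   `prediction`, `participant` (>= 2 participants, one prediction per
#'   observation).
#' @param model label copied into the output row.
#' @return A one-row data frame (`model_comparison_row`): `model`, `aic`,
#'   `bic`, `loglik`, `deviance`, `r2`, `n`, `converged`.
#' @export
fit_comparison_model <- function(data, model = "model") {
  need <- c("observed", "stimulus", "prediction", "participant")
  missing <- setdiff(need, names(data))
  if (length(missing))
    stop("data is missing column(s): ", paste(missing, collapse = ", "))
  if (length(unique(data$participant)) < 2)
    stop("need at least 2 participants for the random intercept")
  fit <- lme4::lmer(observed ~ stimulus + prediction + (1 | participant),
                    data = data, REML = FALSE)
  singular <- lme4::isSingular(fit)
  conv_msgs <- fit@optinfo$conv$lme4$messages
  ll <- as.numeric(stats::logLik(fit))
  row <- data.frame(
    model = model,
    aic = stats::AIC(fit), bic = stats::BIC(fit),
    loglik = ll, deviance = -2 * ll,
    r2 = stats::cor(data$observed, stats::fitted(fit))^2,
    n = nrow(data),
    converged = is.null(conv_msgs) && !singular,
    stringsAsFactors = FALSE)
  attr(row, "fit") <- fit
  row
}

#' Cross-validated predicted R-squared
#'
#' Participants are partitioned into seeded folds; each fold's observations
#' are predicted from a refit of the comparison model on the remaining
#' participants, using fixed effects only (held-out participants have no
#' estimated random intercept, so the population intercept applies). The
#' predicted R-squared is the squared Pearson correlation between the
#' observations and these held-out predictions; unlike the in-sample
#' `R^2` it can be negative in principle and cannot systematically exceed
#' it.
#'
#' @inheritParams fit_comparison_model
#' @param folds number of folds, >= 2 (capped at the number of
#'   participants).
#' @param seed seed for the fold assignment; fixed seed gives
#'   bit-reproducible values.
#' @return Numeric scalar.
#' @export
predicted_r2 <- function(data, folds = 10L, seed = 1L) {
  if (folds < 2) stop("folds must be >= 2")
  participants <- sort(unique(data$participant))
  k <- min(as.integer(folds), length(participants))
  assignment <- with_seed(seed, sample(rep(seq_len(k), length.out = length(participants))))
  names(assignment) <- participants
  cvpred <- rep(NA_real_, nrow(data))
  for (fold in seq_len(k)) {
    held <- participants[assignment == fold]
    test_idx <- data$participant %in% held
    train <- data[!test_idx, ]
    fit <- lme4::lmer(observed ~ stimulus + prediction + (1 | participant),
                      data = train, REML = FALSE)
    cvpred[test_idx] <- stats::predict(fit, newdata = data[test_idx, ],
                                       re.form = NA, allow.new.levels = TRUE)
  }
  stats::cor(data$observed, cvpred)^2
}

#' Rank models by information criteria
#'
#' Sorts the comparison rows by BIC, computes `delta_aic` / `delta_bic`
#' versus the respective best model, and flags near-degeneracy whenever a
#' model's `delta_aic` falls below 2 — the conventional range of
#' substantial support for both models.
#'
#' @param rows data frame of [fit_comparison_model()] rows (optionally with
#'   a `predicted_r2` column), >= 2 rows.
#' @param degeneracy_threshold AIC difference below which two models are
#'   considered statistically indistinguishable.
#' @return A `comparison_report`: list with `table` (rows sorted by BIC
#'   plus the delta columns and `degenerate` flag), `best_bic`, `best_aic`.
#' @export
rank_models <- function(rows, degeneracy_threshold = 2) {
  if (nrow(rows) < 2) stop("need at least 2 models to rank")
  tab <- rows[order(rows$bic), ]
  tab$delta_aic <- tab$aic - min(tab$aic)
  tab$delta_bic <- tab$bic - min(tab$bic)
  tab$degenerate <- tab$delta_aic < degeneracy_threshold
  rownames(tab) <- NULL
  structure(list(table = tab,
                 best_bic = tab$model[which.min(tab$bic)],
                 best_aic = tab$model[which.min(tab$aic)],
                 degeneracy_threshold = degeneracy_threshold),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> best by BIC: %s; best by AIC: %s\n",
              x$best_bic, x$best_aic))
  cols <- intersect(c("model", "aic", "bic", "loglik", "deviance", "r2",
                      "predicted_r2", "delta_aic", "degenerate"),
                    names(x$table))
  print(format(x$table[cols], digits = 6), row.names = FALSE)
  invisible(x)
}

#' Compare observer models against observed interleaved responses
#'
#' Joins each model's predictions to the observed interleaved responses
#' (by participant, modality and trial index), fits the mixed-model harness
#' per model, computes the cross-validated predicted R-squared, and ranks
#' the models.
#'
#' @param trials normalized cohort trials (the interleaved rows are used).
#' @param predictions tidy prediction table from [predict_models()].
#' @param folds,seed cross-validation settings (see [predicted_r2()]);
#'   `folds = 0` skips the predicted R-squared (faster, e.g. in recovery
#'   sweeps).
#' @return A `comparison_report` whose table mirrors the standard summary
#'   layout (model, AIC, logLik, deviance, R2, predicted R2).
#' @export
compare_models <- function(trials, predictions, folds = 10L, seed = 1L) {
  obs <- trials[trials$session == "interleaved",
                c("participant_id", "task", "modality", "trial_index", "response")]
  rows <- list()
  for (model in unique(predictions$model)) {
    pred <- predictions[predictions$model == model, ]
    merged <- merge(obs, pred[c("participant_id", "task", "modality",
                                "trial_index", "stimulus", "prediction")],
                    by = c("participant_id", "task", "modality", "trial_index"))
    if (nrow(merged) != nrow(obs))
      stop(sprintf("model %s: %d predictions matched %d observations",
                   model, nrow(merged), nrow(obs)))
    dat <- data.frame(observed = merged$response,
                      stimulus = merged$stimulus,
                      prediction = merged$prediction,
                      participant = merged$participant_id)
    row <- fit_comparison_model(dat, model = model)
    attr(row, "fit") <- NULL
    row$predicted_r2 <- if (folds >= 2) predicted_r2(dat, folds, seed) else NA_real_
    rows[[model]] <- row
  }
  rank_models(do.call(rbind, rows))
}
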