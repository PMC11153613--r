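#' Assemble the five baseline predictors of treatment resistance
#'
#' Builds one row per participant from visit-A measurements: right-amygdala
#' (decision phase), left-pallidum and mPFC (feedback phase) parameter
#' estimates from the emotional condition, the Glu/tCr ratio, and the
#' overall proportion of ideal choices (all conditions pooled). The binary
#' outcome is treatment resistance at visit C.
#'
#' @param roi ROI tibble (`participant_id`, `visit`, `region`, `beta`).
#' @param metabolites Metabolite tibble (QC-passed Glu rows).
#' @param flagged_trials Trial table with `ideal` flags.
#' @param labels Tibble with `participant_id`, `label`.
#' @return Feature tibble: `participant_id`, `amygdala_beta`,
#'   `pallidum_beta`, `mpfc_beta`, `glu_tcr`, `ideal_choice_overall`,
#'   `label` (1 = resistant).
#' @export
build_feature_table <- function(roi, metabolites, flagged_trials, labels) {
  betas <- roi |>
    dplyr::filter(.data$visit == "A") |>
    dplyr::select("participant_id", "region", "beta") |>
    tidyr::pivot_wider(names_from = "region", values_from = "beta") |>
    dplyr::rename(amygdala_beta = "right_amygdala",
                  pallidum_beta = "left_pallidum",
                  mpfc_beta = "mPFC")
  glu <- metabolites |>
    dplyr::filter(.data$metabolite == "Glu", .data$visit == "A") |>
    dplyr::select("participant_id", glu_tcr = "value")
  behav <- flagged_trials |>
    dplyr::filter(.data$visit == "A", !.data$missing) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(ideal_choice_overall = mean(.data$ideal), .groups = "drop")
  labels |>
    dplyr::filter(.data$label %in% c("resistant", "responsive")) |>
    dplyr::transmute(.data$participant_id,
                     label = as.integer(.data$label == "resistant")) |>
    dplyr::inner_join(betas, by = "participant_id") |>
    dplyr::inner_join(glu, by = "participant_id") |>
    dplyr::inner_join(behav, by = "participant_id") |>
    dplyr::select("participant_id", "amygdala_beta", "pallidum_beta",
                  "mpfc_beta", "glu_tcr", "ideal_choice_overall", "label")
}

#' Logistic regression of treatment resistance on baseline features
#'
#' Maximum-likelihood logistic fit of the binary resistance label on the
#' five baseline features. Features are z-scored by default so
#' coefficients are comparable across heterogeneous units (parameter
#' estimates, a metabolite ratio, a proportion); set `scale = FALSE` for a
#' raw-unit fit. Complete cases only. Quasi-complete separation is
#' detected and flagged.
#'
#' @param features Feature tibble from [build_feature_table()] (or any
#'   tibble with a binary `label` column and numeric predictors).
#' @param scale Z-score the predictors before fitting (default TRUE).
#' @return List of class `psytrs_logit`: `model` (the glm), `coefficients`
#'   tibble (term, estimate, se, z, p), `L0`, `L1` (null / model
#'   log-likelihoods), `n`, `n_dropped`, `separation`, `scaled`.
#' @export
fit_logistic <- function(features, scale = TRUE) {
  check_columns(features, "label", "features")
  predictors <- setdiff(names(features), c("participant_id", "label"))
  if (length(predictors) == 0L) abort("no predictor columns found")
  d <- as.data.frame(features[, c(predictors, "label")])
  cc <- stats::complete.cases(d)
  n_dropped <- sum(!cc)
  d <- d[cc, , drop = FALSE]
  if (length(unique(d$label)) < 2L) {
    abort("need at least one case in each outcome class")
  }
  if (scale) for (p in predictors) d[[p]] <- as.numeric(base::scale(d[[p]]))

  separation <- FALSE
  model <- withCallingHandlers(
    glm(label ~ ., data = d, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (any(abs(coef(model)[-1]) > 15)) separation <- TRUE
  if (separation) {
    warn("possible (quasi-)separation: coefficients may be unbounded")
  }
  null_model <- glm(label ~ 1, data = d, family = binomial())
  sm <- summary(model)$coefficients
  structure(
    list(model = model,
         coefficients = tibble::tibble(
           term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
           z = sm[, 3], p = sm[, 4]),
         L1 = as.numeric(logLik(model)),
         L0 = as.numeric(logLik(null_model)),
         n = nrow(d), n_dropped = n_dropped,
         separation = separation, scaled = scale),
    class = "psytrs_logit")
}

#' Nagelkerke pseudo-R-squared
#'
#' Cox-Snell `R2cs = 1 - exp(2 (L0 - L1) / n)` rescaled by its maximum
#' attainable value: `R2 = R2cs / (1 - exp(2 L0 / n))`.
#'
#' @param L0 Log-likelihood of the intercept-only model.
#' @param L1 Log-likelihood of the fitted model (must be >= L0).
#' @param n Number of observations.
#' @return Value in \[0, 1\].
#' @export
nagelkerke_r2 <- function(L0, L1, n) {
  check_number(n, "n", lower = 1)
  if (L1 < L0 - 1e-8) {
    abort("L1 < L0: the fitted model cannot have lower likelihood than its null")
  }
  L1 <- max(L1, L0)
  r2_cs <- 1 - exp(2 * (L0 - L1) / n)
  denom <- 1 - exp(2 * L0 / n)
  if (denom <= 0) abort("degenerate null likelihood; cannot rescale")
  min(r2_cs / denom, 1)
}

#' Classification metrics from confusion counts
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)` and accuracy
#' `(TP+TN)/N`, reported both as exact fractions and as whole percentages.
#'
#' @param tp,fn,tn,fp Confusion counts.
#' @return List: `confusion`, `sensitivity`, `specificity`, `accuracy`
#'   (fractions; `NA` when a denominator is empty) and the `_pct`
#'   whole-percent versions.
#' @examples
#' confusion_metrics(10, 5, 33, 2) # sensitivity 67%, specificity 94%, accuracy 86%
#' @export
confusion_metrics <- function(tp, fn, tn, fp) {
  counts <- c(TP = tp, FN = fn, TN = tn, FP = fp)
  if (any(counts < 0)) abort("confusion counts must be non-negative")
  n <- sum(counts)
  if (n == 0) abort("no observations")
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / n
  list(confusion = counts,
       sensitivity = sens, specificity = spec, accuracy = acc,
       sensitivity_pct = round(100 * sens),
       specificity_pct = round(100 * spec),
       accuracy_pct = round(100 * acc))
}

#' In-sample classification report for the prediction model
#'
#' Classifies each participant as resistant when the fitted probability
#' meets `threshold`, tabulates the confusion counts and reports
#' sensitivity, specificity and accuracy as whole percentages (exact
#' fractions retained), alongside Nagelkerke R-squared and the
#' coefficient table.
#'
#' @param fit A `psytrs_logit` from [fit_logistic()].
#' @param threshold Classification threshold on the fitted probability
#'   (default 0.5).
#' @return List of class `psytrs_prediction_report`: `confusion` (TP, FN,
#'   TN, FP), `sensitivity_pct`, `specificity_pct`, `accuracy_pct`
#'   (rounded), `sensitivity`, `specificity`, `accuracy` (exact),
#'   `nagelkerke_r2`, `coefficients`, `threshold`, `n`.
#' @export
classify_and_report <- function(fit, threshold = 0.5) {
  stopifnot(inherits(fit, "psytrs_logit"))
  check_number(threshold, "threshold", 0, 1)
  prob <- stats::fitted(fit$model)
  obs <- fit$model$model$label
  pred <- as.integer(prob >= threshold)
  tp <- sum(pred == 1 & obs == 1); fn <- sum(pred == 0 & obs == 1)
  tn <- sum(pred == 0 & obs == 0); fp <- sum(pred == 1 & obs == 0)
  stopifnot(tp + fn == sum(obs == 1), tn + fp == sum(obs == 0))
  metrics <- confusion_metrics(tp, fn, tn, fp)
  structure(
    c(metrics,
      list(nagelkerke_r2 = nagelkerke_r2(fit$L0, fit$L1, fit$n),
           coefficients = fit$coefficients,
           threshold = threshold, n = length(obs))),
    class = "psytrs_prediction_report")
}

#' @export
print.psytrs_prediction_report <- function(x, ...) {
  cat(sprintf("logistic prediction of treatment resistance (n = %d, threshold = %.2f)\n",
              x$n, x$threshold))
  cat(sprintf("  Nagelkerke R2 = %.2f\n", x$nagelkerke_r2))
  cat(sprintf("  confusion: TP=%d FN=%d TN=%d FP=%d\n",
              x$confusion["TP"], x$confusion["FN"],
              x$confusion["TN"], x$confusion["FP"]))
  cat(sprintf("  sensitivity %d%%, specificity %d%%, accuracy %d%%\n",
              x$sensitivity_pct, x$specificity_pct, x$accuracy_pct))
  invisible(x)
}
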