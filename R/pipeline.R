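#' Configuration for an end-to-end pipeline run
#'
#' Bundles every tunable of the simulation and analysis stages with the
#' study defaults: 15 resistant / 35 responsive participants, 30-trial
#' blocks at 60/40 contingencies, alpha 0.05, Bonferroni-adjusted chance
#' threshold 0.00625 (0.05 / 8), the strict QC triple (CRLB < 20%,
#' SNR > 10, FWHM < 0.1 ppm) and classification threshold 0.5.
#'
#' @param n_resistant,n_responsive Cohort sizes.
#' @param task A [task_config()].
#' @param agent_map Agent parameter map ([default_agent_map()]).
#' @param mrs_effects MRS/ROI generator settings ([default_mrs_effects()]).
#' @param alpha Nominal significance level.
#' @param chance_alpha Adjusted threshold for the eight chance tests.
#' @param qc List with `crlb_max`, `snr_min`, `fwhm_max`.
#' @param threshold Classification threshold for the prediction model.
#' @param n_starts Multi-start count for each RL fit.
#' @param fit_rl If `FALSE`, skip maximum-likelihood fitting and classify
#'   ideal choices from the generating agent parameters (fast path for
#'   calibration studies on synthetic data).
#' @return List of class `psytrs_config`.
#' @export
pipeline_config <- function(n_resistant = 15, n_responsive = 35,
                            task = task_config(),
                            agent_map = default_agent_map(),
                            mrs_effects = default_mrs_effects(),
                            alpha = 0.05, chance_alpha = 0.05 / 8,
                            qc = list(crlb_max = 20, snr_min = 10, fwhm_max = 0.1),
                            threshold = 0.5, n_starts = 10, fit_rl = TRUE) {
  check_number(alpha, "alpha", 0, 1, closed_lower = FALSE)
  check_number(chance_alpha, "chance_alpha", 0, 1, closed_lower = FALSE)
  stopifnot(qc$crlb_max > 0, qc$snr_min > 0, qc$fwhm_max > 0)
  structure(
    list(n_resistant = n_resistant, n_responsive = n_responsive,
         task = task, agent_map = agent_map, mrs_effects = mrs_effects,
         alpha = alpha, chance_alpha = chance_alpha, qc = qc,
         threshold = threshold, n_starts = n_starts, fit_rl = fit_rl),
    class = "psytrs_config")
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes cohort generation, task simulation, RL fitting and
#' ideal-choice classification, the behavioural statistics battery, the
#' MRS stage (QC gate, glutamate ANOVA, creatine stability, coupling
#' comparison) and the logistic prediction model, in sequence. All
#' randomness derives from `seed`, so identical configuration and seed
#' give an identical bundle. A user-supplied trial table can replace the
#' simulation stage.
#'
#' @param config A [pipeline_config()].
#' @param seed Integer seed.
#' @param trials Optional externally supplied trial table in the
#'   [simulate_agent()] schema (skips task simulation; requires `labels`).
#' @param labels Optional label table accompanying `trials`.
#' @return List of class `psytrs_bundle` holding every stage's inputs and
#'   outputs plus an exclusion/reconciliation log.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1,
                         trials = NULL, labels = NULL) {
  stopifnot(inherits(config, "psytrs_config"))
  log <- list()

  if (is.null(trials)) {
    cohort <- generate_cohort(config$n_resistant, config$n_responsive,
                              seed = stage_seed(seed, "cohort"))
    relab <- classify_treatment_response(cohort$participants)
    labels <- relab[, c("participant_id", "label")]
    log$unclassified <- relab[relab$label == "unclassified", ]
    trials <- simulate_visits(labels, config$agent_map, config$task,
                              seed = stage_seed(seed, "trials"))
  } else {
    if (is.null(labels)) abort("`labels` must accompany a user-supplied trial table")
    cohort <- NULL
  }

  true_params <- attr(trials, "agent_params")
  if (config$fit_rl || is.null(true_params)) {
    rl <- fit_rl_models(trials, n_starts = config$n_starts,
                        seed = stage_seed(seed, "fit"))
  } else {
    po <- tidyr::crossing(true_params[, c("participant_id", "visit", "alpha", "beta")],
                          condition = c("emotional", "neutral"))
    rl <- fit_rl_models(trials, params_override = po)
  }

  props <- ideal_choice_proportions(rl$trials, labels)
  chance <- chance_tests(props, alpha_adjusted = config$chance_alpha)
  behav_anova <- mixed_anova_2x2x2(props)
  bias <- emotional_bias(rl$trials)
  b_anova <- bias_anova(bias, labels)

  mrs <- generate_mrs_roi_data(labels, config$mrs_effects,
                               seed = stage_seed(seed, "mrs"))
  qc <- qc_filter(mrs$metabolites, crlb_max = config$qc$crlb_max,
                  snr_min = config$qc$snr_min, fwhm_max = config$qc$fwhm_max)
  log$qc_excluded <- qc$excluded
  log$counts <- c(metabolite_rows_in = nrow(mrs$metabolites),
                  metabolite_rows_kept = nrow(qc$included),
                  metabolite_rows_excluded = nrow(qc$excluded))
  glu_anova <- glutamate_anova(qc$included, labels)
  tcr <- creatine_stability(mrs$metabolites)
  coupling <- coupling_comparison(mrs$roi, qc$included, labels)

  features <- build_feature_table(mrs$roi, qc$included, rl$trials, labels)
  logit <- fit_logistic(features, scale = TRUE)
  # raw-unit companion fit; identical separation structure to the scaled fit,
  # so its duplicate warnings are muffled
  logit_raw <- suppressWarnings(fit_logistic(features, scale = FALSE))
  report <- classify_and_report(logit, threshold = config$threshold)

  structure(
    list(config = config, seed = seed, cohort = cohort, labels = labels,
         trials = rl$trials, fits = rl$fits, props = props,
         chance_tests = chance, behaviour_anova = behav_anova,
         bias_scores = bias, bias_anova = b_anova,
         metabolites = mrs$metabolites, metabolites_qc = qc$included,
         roi = mrs$roi, glutamate_anova = glu_anova,
         creatine_stability = tcr, coupling = coupling,
         features = features, logistic_fit = logit,
         logistic_fit_raw = logit_raw,
         prediction_report = report, log = log),
    class = "psytrs_bundle")
}

#' Consolidated analysis report
#'
#' Summarises a pipeline bundle into a structured list mirroring the
#' analysis sequence (cell summary of ideal choices, chance tests, the
#' three ANOVAs, creatine stability, coupling comparison, prediction
#' report) together with plain-text lines. Sections whose stage output is
#' absent from the bundle are marked as such.
#'
#' @param bundle A `psytrs_bundle` from [run_pipeline()].
#' @return List with `summary` (structured) and `text` (character lines).
#' @export
make_report <- function(bundle) {
  stopifnot(inherits(bundle, "psytrs_bundle"))
  grab <- function(name) if (is.null(bundle[[name]])) "absent" else bundle[[name]]

  cells <- if (!is.null(bundle$props)) {
    bundle$props |>
      dplyr::group_by(.data$group, .data$visit, .data$condition) |>
      dplyr::summarise(n = dplyr::n(), mean = mean(.data$prop),
                       sd = sd(.data$prop), .groups = "drop")
  } else "absent"

  summary <- list(
    seed = bundle$seed,
    cell_summary = cells,
    chance_tests = grab("chance_tests"),
    behaviour_anova = grab("behaviour_anova"),
    bias_anova = grab("bias_anova"),
    glutamate_anova = grab("glutamate_anova"),
    creatine_stability = grab("creatine_stability"),
    coupling = grab("coupling"),
    prediction = grab("prediction_report"))

  text <- c(
    sprintf("pipeline report (seed %s)", bundle$seed),
    if (!identical(cells, "absent")) {
      c("ideal-choice cell means:",
        utils::capture.output(print(as.data.frame(cells), digits = 3)))
    } else "behaviour section absent",
    if (!identical(summary$coupling, "absent") &&
        !is.null(summary$coupling$comparison)) {
      sprintf("visit-C mPFC-glutamate coupling: responsive rho = %.3f (n = %d), resistant rho = %.3f (n = %d), Fisher Z = %.3f (p = %.3f)",
              summary$coupling$responsive$rho, summary$coupling$responsive$n,
              summary$coupling$resistant$rho, summary$coupling$resistant$n,
              summary$coupling$comparison$Z, summary$coupling$comparison$p)
    } else NULL,
    if (!identical(summary$prediction, "absent")) {
      sprintf("prediction: Nagelkerke R2 = %.2f; sensitivity %d%%, specificity %d%%, accuracy %d%%",
              summary$prediction$nagelkerke_r2,
              summary$prediction$sensitivity_pct,
              summary$prediction$specificity_pct,
              summary$prediction$accuracy_pct)
    } else "prediction section absent")

  list(summary = summary, text = text)
}

#' Write a pipeline bundle to disk
#'
#' Persists every tabular stage output as CSV plus the text report, so a
#' run can be inspected or re-analysed outside R.
#'
#' @param bundle A `psytrs_bundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "psytrs_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- list(
    participants = bundle$cohort$participants, labels = bundle$labels,
    trials = bundle$trials, rl_fits = bundle$fits, props = bundle$props,
    chance_tests = bundle$chance_tests,
    behaviour_anova = bundle$behaviour_anova,
    bias_scores = bundle$bias_scores, bias_anova = bundle$bias_anova,
    metabolites = bundle$metabolites, roi = bundle$roi,
    glutamate_anova = bundle$glutamate_anova, features = bundle$features,
    qc_exclusions = bundle$log$qc_excluded)
  paths <- character()
  for (nm in names(tables)) {
    if (is.null(tables[[nm]])) next
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  rep <- make_report(bundle)
  p <- file.path(dir, "report.txt")
  writeLines(rep$text, p)
  paths <- c(paths, p)
  invisible(paths)
}
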