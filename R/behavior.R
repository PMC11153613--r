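# Shared mixed-design ANOVA engine: one between-subjects factor, one or two
# two-level within-subject factors. Uses the multivariate repeated-measures
# route with type-III sums of squares (sum-to-zero contrasts on the group
# factor), the same computation SPSS-style mixed ANOVAs report. With
# two-level within factors no sphericity correction is needed.
.mixed_anova <- function(data, dv, subject, between, within) {
  data <- as.data.frame(data)
  data[[between]] <- droplevels(factor(data[[between]]))
  for (w in within) data[[w]] <- factor(data[[w]])

  cells <- do.call(expand.grid, c(lapply(within, function(w) levels(data[[w]])),
                                  list(stringsAsFactors = FALSE)))
  names(cells) <- within
  cell_key <- apply(cells, 1, paste, collapse = ".")

  data$.cell <- apply(data[, within, drop = FALSE], 1, paste, collapse = ".")
  wide <- tidyr::pivot_wider(
    data[, c(subject, between, ".cell", dv)],
    names_from = ".cell", values_from = dplyr::all_of(dv))
  complete <- stats::complete.cases(wide[, cell_key, drop = FALSE])
  n_dropped <- sum(!complete)
  if (n_dropped > 0) {
    message(sprintf("mixed ANOVA: dropped %d participant(s) with incomplete within-subject cells",
                    n_dropped))
  }
  wide <- wide[complete, , drop = FALSE]
  if (nrow(wide) < 3L) abort("too few complete participants for a mixed ANOVA")

  y <- as.matrix(wide[, cell_key, drop = FALSE])
  grp <- droplevels(factor(wide[[between]]))
  idata <- cells
  for (w in within) idata[[w]] <- factor(idata[[w]])
  idesign <- stats::as.formula(paste("~", paste(within, collapse = "*")))

  if (nlevels(grp) > 1L) {
    mod <- lm(y ~ grp, contrasts = list(grp = "contr.sum"))
  } else {
    mod <- lm(y ~ 1)
  }
  av <- car::Anova(mod, idata = idata, idesign = idesign, type = 3)
  st <- summary(av, multivariate = FALSE)$univariate.tests
  tab <- as.data.frame(unclass(st))
  tab$effect <- rownames(st)
  tab <- tab[tab$effect != "(Intercept)", , drop = FALSE]
  tab$effect <- gsub("grp", between, tab$effect)
  tibble::tibble(
    effect = tab$effect,
    df_num = tab[["num Df"]],
    df_den = tab[["den Df"]],
    ss = tab[["Sum Sq"]],
    ss_error = tab[["Error SS"]],
    F = tab[["F value"]],
    p = tab[["Pr(>F)"]],
    pes = tab[["Sum Sq"]] / (tab[["Sum Sq"]] + tab[["Error SS"]])
  )
}

#' Per-cell ideal-choice proportions
#'
#' Computes each participant's proportion of ideal choices per visit x
#' condition (missing trials excluded) from a flagged trial table, joined
#' with group labels.
#'
#' @param flagged_trials Trial table carrying an `ideal` column, e.g.
#'   `fit_rl_models(...)$trials`.
#' @param labels Tibble with `participant_id` and `label`.
#' @return Tibble: `participant_id`, `group`, `visit`, `condition`, `n`
#'   (non-missing trials), `prop`.
#' @export
ideal_choice_proportions <- function(flagged_trials, labels) {
  check_columns(flagged_trials,
                c("participant_id", "visit", "condition", "ideal", "missing"),
                "flagged_trials")
  flagged_trials |>
    dplyr::filter(!.data$missing) |>
    dplyr::group_by(.data$participant_id, .data$visit, .data$condition) |>
    dplyr::summarise(n = dplyr::n(), prop = mean(.data$ideal), .groups = "drop") |>
    dplyr::inner_join(labels, by = "participant_id") |>
    dplyr::rename(group = "label") |>
    dplyr::mutate(group = as.character(.data$group)) |>
    dplyr::select("participant_id", "group", "visit", "condition", "n", "prop")
}

#' Chance-level tests of learning
#'
#' One-sample t-tests of the per-participant ideal-choice proportions
#' against chance (0.5) in each of the eight group x visit x condition
#' cells, with a Bonferroni-adjusted significance threshold (0.05 / 8 =
#' 0.00625 by default).
#'
#' @param props Per-participant proportions from
#'   [ideal_choice_proportions()].
#' @param mu Chance level (default 0.5).
#' @param alpha_adjusted Adjusted significance threshold (default 0.00625).
#' @return Tibble with one row per cell: `group`, `visit`, `condition`,
#'   `n`, `mean`, `sd`, `t`, `df`, `p`, `above_chance` (logical at the
#'   adjusted threshold), `note` for skipped cells.
#' @export
chance_tests <- function(props, mu = 0.5, alpha_adjusted = 0.05 / 8) {
  check_columns(props, c("group", "visit", "condition", "prop"), "props")
  props |>
    dplyr::group_by(.data$group, .data$visit, .data$condition) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 2L) {
        return(tibble::tibble(
          n = nrow(d), mean = mean(d$prop), sd = NA_real_,
          t = NA_real_, df = NA_real_, p = NA_real_, above_chance = NA,
          note = "skipped: fewer than 2 observations"))
      }
      if (sd(d$prop) == 0) {
        # degenerate cell: zero variance. At the chance level itself t = 0;
        # away from it the statistic diverges.
        at_mu <- mean(d$prop) == mu
        return(tibble::tibble(
          n = nrow(d), mean = mean(d$prop), sd = 0,
          t = if (at_mu) 0 else sign(mean(d$prop) - mu) * Inf,
          df = nrow(d) - 1, p = if (at_mu) 1 else 0,
          above_chance = !at_mu && mean(d$prop) > mu,
          note = "zero variance"))
      }
      tt <- t.test(d$prop, mu = mu)
      tibble::tibble(
        n = nrow(d), mean = mean(d$prop), sd = sd(d$prop),
        t = unname(tt$statistic), df = unname(tt$parameter),
        p = tt$p.value,
        above_chance = tt$p.value < alpha_adjusted && mean(d$prop) > mu,
        note = NA_character_)
    }) |>
    dplyr::ungroup()
}

#' 2 x 2 x 2 mixed ANOVA on ideal-choice proportions
#'
#' Group (between-subjects) x visit x condition (within-subjects) mixed
#' ANOVA on per-participant ideal-choice proportions, reporting F, degrees
#' of freedom, p and partial eta squared for every main effect and
#' interaction. Participants with incomplete within-subject cells are
#' dropped (with a message).
#'
#' @param props Per-participant proportions from
#'   [ideal_choice_proportions()].
#' @return Tidy ANOVA tibble (`effect`, `df_num`, `df_den`, `ss`,
#'   `ss_error`, `F`, `p`, `pes`).
#' @export
mixed_anova_2x2x2 <- function(props) {
  check_columns(props, c("participant_id", "group", "visit", "condition", "prop"),
                "props")
  .mixed_anova(props, dv = "prop", subject = "participant_id",
               between = "group", within = c("visit", "condition"))
}

#' Emotional-bias scores
#'
#' For each participant x visit, using emotional-condition trials only:
#' the proportion of trials on which the happy face was chosen given the
#' model determined the angry face ideal, minus the proportion on which the
#' angry face was chosen given the happy face was ideal. Positive scores
#' indicate a prepotent pull toward the happy face. Trials where the model
#' prefers neither face (tied Q, e.g. the first trial of a block) and
#' missing trials never enter the conditional proportions. The score is
#' undefined (NA, flagged) when either conditioning set is empty.
#'
#' @param flagged_trials Trial table with `ideal_option` column from
#'   [classify_ideal_choices()] / [fit_rl_models()]; option 1 is the happy
#'   face, option 2 the angry face.
#' @return Tibble: `participant_id`, `visit`, `n_angry_ideal`,
#'   `n_happy_ideal`, `score` in \[-1, 1\] (`NA` when undefined),
#'   `defined`.
#' @export
emotional_bias <- function(flagged_trials) {
  check_columns(flagged_trials,
                c("participant_id", "visit", "condition", "choice",
                  "missing", "ideal_option"), "flagged_trials")
  flagged_trials |>
    dplyr::filter(.data$condition == "emotional", !.data$missing,
                  !is.na(.data$ideal_option)) |>
    dplyr::group_by(.data$participant_id, .data$visit) |>
    dplyr::summarise(
      n_angry_ideal = sum(.data$ideal_option == 2L),
      n_happy_ideal = sum(.data$ideal_option == 1L),
      p_happy_given_angry_ideal =
        ifelse(.data$n_angry_ideal > 0,
               sum(.data$choice == 1L & .data$ideal_option == 2L) /
                 .data$n_angry_ideal, NA_real_),
      p_angry_given_happy_ideal =
        ifelse(.data$n_happy_ideal > 0,
               sum(.data$choice == 2L & .data$ideal_option == 1L) /
                 .data$n_happy_ideal, NA_real_),
      .groups = "drop") |>
    dplyr::mutate(
      score = .data$p_happy_given_angry_ideal - .data$p_angry_given_happy_ideal,
      defined = !is.na(.data$score)) |>
    dplyr::select("participant_id", "visit", "n_angry_ideal", "n_happy_ideal",
                  "score", "defined")
}

#' Mixed ANOVA on emotional-bias scores
#'
#' Group (between) x visit (within) mixed ANOVA on per-participant
#' emotional-bias scores; participants with an undefined score at either
#' visit are excluded.
#'
#' @param scores Output of [emotional_bias()].
#' @param labels Tibble with `participant_id` and `label`.
#' @return Tidy ANOVA tibble as in [mixed_anova_2x2x2()].
#' @export
bias_anova <- function(scores, labels) {
  check_columns(scores, c("participant_id", "visit", "score"), "scores")
  d <- scores |>
    dplyr::filter(!is.na(.data$score)) |>
    dplyr::inner_join(labels, by = "participant_id") |>
    dplyr::rename(group = "label") |>
    dplyr::mutate(group = as.character(.data$group))
  .mixed_anova(d, dv = "score", subject = "participant_id",
               between = "group", within = "visit")
}
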