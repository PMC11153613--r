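#' Task configuration for the emotion-yoked reward learning task
#'
#' The task presents two faces per trial; the participant learns over 30
#' iterative trials per block which face carries the higher reward
#' probability (60/40 contingencies). There are two emotional blocks (happy
#' vs angry expression, same identity; option 1 is always the happy face)
#' and two neutral blocks (two neutral identities).
#'
#' @param trials_per_block Trials per block (default 30).
#' @param blocks_per_condition Blocks per condition (default 2).
#' @param reward_contingencies Length-2 probability vector `(rich, lean)`;
#'   each must lie strictly inside (0, 1) and the pair must sum to 1.
#' @param block_order Character vector of conditions defining the block
#'   sequence; default alternates emotional / neutral.
#' @return An object of class `psytrs_task_config`.
#' @export
task_config <- function(trials_per_block = 30,
                        blocks_per_condition = 2,
                        reward_contingencies = c(0.6, 0.4),
                        block_order = NULL) {
  check_number(trials_per_block, "trials_per_block", lower = 1)
  check_number(blocks_per_condition, "blocks_per_condition", lower = 1)
  if (length(reward_contingencies) != 2L ||
      any(reward_contingencies <= 0) || any(reward_contingencies >= 1)) {
    abort("`reward_contingencies` must be two probabilities strictly inside (0, 1)")
  }
  if (abs(sum(reward_contingencies) - 1) > 1e-12) {
    abort("`reward_contingencies` must sum to 1")
  }
  n_blocks <- 2L * as.integer(blocks_per_condition)
  if (is.null(block_order)) {
    block_order <- rep(c("emotional", "neutral"), blocks_per_condition)
  }
  if (length(block_order) != n_blocks ||
      !all(block_order %in% c("emotional", "neutral")) ||
      sum(block_order == "emotional") != blocks_per_condition) {
    abort("`block_order` must contain each condition `blocks_per_condition` times")
  }
  structure(
    list(trials_per_block = as.integer(trials_per_block),
         blocks_per_condition = as.integer(blocks_per_condition),
         reward_contingencies = reward_contingencies,
         block_order = block_order),
    class = "psytrs_task_config"
  )
}

#' Generate a latent reward schedule
#'
#' For each block one option is designated "rich" (reward probability 0.6 by
#' default) and the other "lean" (0.4); latent reward availability is drawn
#' independently per trial for both options. The reward a simulated (or
#' real) participant receives on a trial is the availability of the chosen
#' option only - the counterfactual outcome is never shown. Within each
#' condition the rich option is counterbalanced across that condition's
#' blocks (which of the two comes first is randomised), so in the emotional
#' condition the happy and the angry face each serve once as the rich
#' option.
#'
#' @param config A [task_config()].
#' @param seed Integer seed; identical seeds give identical schedules.
#' @return Tibble with one row per block x trial: `block`, `condition`,
#'   `trial`, `rich_option` (1 or 2), `avail_opt1`, `avail_opt2` (0/1).
#' @export
generate_reward_schedule <- function(config = task_config(), seed = 1) {
  stopifnot(inherits(config, "psytrs_task_config"))
  tpb <- config$trials_per_block
  n_blocks <- length(config$block_order)
  withr::with_seed(as.integer(seed %% .SEED_MOD), {
    rich_by_block <- integer(n_blocks)
    for (cond in unique(config$block_order)) {
      idx <- which(config$block_order == cond)
      # counterbalance: cycle both options through the condition's blocks
      rich_by_block[idx] <- (sample(0:1, 1) + seq_along(idx)) %% 2L + 1L
    }
    blocks <- lapply(seq_len(n_blocks), function(b) {
      rich <- rich_by_block[b]
      p <- numeric(2)
      p[rich] <- config$reward_contingencies[1]
      p[-rich] <- config$reward_contingencies[2]
      tibble::tibble(
        block = b,
        condition = config$block_order[b],
        trial = seq_len(tpb),
        rich_option = rich,
        avail_opt1 = rbinom(tpb, 1, p[1]),
        avail_opt2 = rbinom(tpb, 1, p[2])
      )
    })
    dplyr::bind_rows(blocks)
  })
}

#' Parameters of a simulated task agent
#'
#' @param alpha Learning rate in \[0, 1\].
#' @param beta Softmax inverse temperature (>= 0); 0 gives random choice.
#' @param happy_bias Additive decision-value offset toward the happy face
#'   (option 1), applied in emotional blocks only. Captures the prepotent
#'   pull toward positive expressions that the task's cognitive-control
#'   demand works against.
#' @param miss_rate Probability a trial is missed (no response), in \[0, 1).
#' @return An object of class `psytrs_agent_params`.
#' @export
agent_params <- function(alpha, beta, happy_bias = 0, miss_rate = 0) {
  check_number(alpha, "alpha", 0, 1)
  check_number(beta, "beta", lower = 0)
  check_number(happy_bias, "happy_bias")
  check_number(miss_rate, "miss_rate", 0, 1, closed_upper = FALSE)
  structure(list(alpha = alpha, beta = beta, happy_bias = happy_bias,
                 miss_rate = miss_rate),
            class = "psytrs_agent_params")
}

#' Simulate one agent performing the task
#'
#' The agent chooses by softmax over current Q values (plus `happy_bias` in
#' emotional blocks), receives the chosen option's latent reward, and
#' updates both Q values by the double-update rule. Q resets to (0.5, 0.5)
#' at every block start. Missed trials produce no choice, no reward and no
#' update.
#'
#' @param params An [agent_params()] object.
#' @param config A [task_config()].
#' @param seed Integer seed.
#' @param participant_id,visit Identifiers copied into the output table.
#' @return Trial tibble: `participant_id`, `visit`, `condition`, `block`,
#'   `trial`, `choice` (1 = first option; the happy face in emotional
#'   blocks), `reward` (0/1), `missing` (logical). `choice` and `reward`
#'   are `NA` on missing trials.
#' @export
simulate_agent <- function(params, config = task_config(), seed = 1,
                           participant_id = "agent", visit = "A") {
  stopifnot(inherits(params, "psytrs_agent_params"))
  sched <- generate_reward_schedule(config, seed = derive_seed(seed, stage_offset("schedule")))
  tpb <- config$trials_per_block
  n_blocks <- length(config$block_order)
  avail <- cbind(sched$avail_opt1, sched$avail_opt2)

  choice <- integer(nrow(sched))
  reward <- integer(nrow(sched))
  missing <- logical(nrow(sched))

  withr::with_seed(derive_seed(seed, stage_offset("choices")), {
    miss_draw <- runif(nrow(sched)) < params$miss_rate
    u <- runif(nrow(sched))
    row <- 0L
    for (b in seq_len(n_blocks)) {
      q1 <- 0.5; q2 <- 0.5
      bias <- if (config$block_order[b] == "emotional") params$happy_bias else 0
      for (t in seq_len(tpb)) {
        row <- row + 1L
        if (miss_draw[row]) {
          missing[row] <- TRUE
          choice[row] <- NA_integer_
          reward[row] <- NA_integer_
          next
        }
        p1 <- plogis(params$beta * (q1 - q2) + bias)
        ch <- if (u[row] < p1) 1L else 2L
        r <- avail[row, ch]
        choice[row] <- ch
        reward[row] <- r
        a <- params$alpha
        if (ch == 1L) {
          q1 <- q1 + a * (r - q1)
          q2 <- q2 + a * ((1 - r) - q2)
        } else {
          q2 <- q2 + a * (r - q2)
          q1 <- q1 + a * ((1 - r) - q1)
        }
      }
    }
  })

  tibble::tibble(
    participant_id = participant_id,
    visit = visit,
    condition = sched$condition,
    block = sched$block,
    trial = sched$trial,
    choice = choice,
    reward = reward,
    missing = missing
  )
}

#' Default agent parameter map for the synthetic cohort
#'
#' One row per group x visit cell giving the population distribution of
#' agent parameters. The defaults are calibrated so the simulated cohort
#' reproduces the qualitative behavioural pattern of the study design:
#' responsive participants (and resistant participants at baseline) learn
#' clearly above chance in every cell, while resistant participants at
#' visit C show degraded learning together with a stronger happy bias, so
#' their emotional-condition ideal-choice proportion approaches chance
#' (population mean near 0.55) while the neutral condition stays above
#' chance. The cohort-wide emotional bias is positive (pull toward the
#' happy face).
#'
#' @return Tibble with columns `group`, `visit`, `alpha_mean`, `alpha_sd`,
#'   `beta_mean`, `beta_sd`, `bias_mean`, `bias_sd`, `miss_rate`.
#' @export
default_agent_map <- function() {
  tibble::tribble(
    ~group,       ~visit, ~alpha_mean, ~alpha_sd, ~beta_mean, ~beta_sd, ~bias_mean, ~bias_sd, ~miss_rate,
    "responsive", "A",    0.35,        0.10,      3.5,        1.2,      0.20,       0.20,     0.02,
    "responsive", "C",    0.35,        0.10,      3.5,        1.2,      0.20,       0.20,     0.02,
    "resistant",  "A",    0.35,        0.10,      3.5,        1.2,      0.20,       0.20,     0.02,
    "resistant",  "C",    0.15,        0.06,      1.1,        0.4,      1.00,       0.35,     0.02
  )
}

#' Simulate the full cohort's trial data across visits
#'
#' Draws individual agent parameters from the group x visit cells of
#' `param_map` (truncated-normal for alpha and beta, normal for the happy
#' bias) and simulates every participant at visits A and C.
#'
#' @param labels Tibble with `participant_id` and `label` (resistant /
#'   responsive); unclassified participants are skipped.
#' @param param_map Parameter map, see [default_agent_map()].
#' @param config A [task_config()].
#' @param seed Integer seed; fans out deterministically per participant and
#'   visit, so the same seed reproduces the full trial table.
#' @return Trial tibble in the [simulate_agent()] schema for all
#'   participants and both scanning visits.
#' @export
simulate_visits <- function(labels, param_map = default_agent_map(),
                            config = task_config(), seed = 1) {
  check_columns(labels, c("participant_id", "label"), "labels")
  labels <- labels[labels$label %in% c("resistant", "responsive"), ]
  needed <- expand.grid(group = unique(as.character(labels$label)),
                        visit = c("A", "C"), stringsAsFactors = FALSE)
  have <- paste(param_map$group, param_map$visit)
  miss <- !(paste(needed$group, needed$visit) %in% have)
  if (any(miss)) {
    abort(paste0("param_map lacks cell(s): ",
                 paste(paste(needed$group, needed$visit)[miss], collapse = "; ")))
  }

  rtrunc_norm <- function(mean, sd, lo, hi) {
    x <- rnorm(1, mean, sd)
    min(max(x, lo), hi)
  }

  out <- vector("list", nrow(labels) * 2L)
  drawn <- vector("list", nrow(labels) * 2L)
  k <- 0L
  for (i in seq_len(nrow(labels))) {
    id <- labels$participant_id[i]
    grp <- as.character(labels$label[i])
    for (v_idx in 1:2) {
      visit <- c("A", "C")[v_idx]
      cell <- param_map[param_map$group == grp & param_map$visit == visit, ]
      pv_seed <- derive_seed(seed, stage_offset("trials"), i, v_idx)
      params <- withr::with_seed(derive_seed(pv_seed, stage_offset("params")), {
        agent_params(
          alpha = rtrunc_norm(cell$alpha_mean, cell$alpha_sd, 0.02, 0.98),
          beta = rtrunc_norm(cell$beta_mean, cell$beta_sd, 0.2, 20),
          happy_bias = rnorm(1, cell$bias_mean, cell$bias_sd),
          miss_rate = cell$miss_rate
        )
      })
      k <- k + 1L
      out[[k]] <- simulate_agent(params, config, seed = pv_seed,
                                 participant_id = id, visit = visit)
      out[[k]]$group <- grp
      drawn[[k]] <- tibble::tibble(
        participant_id = id, visit = visit, group = grp,
        alpha = params$alpha, beta = params$beta,
        happy_bias = params$happy_bias)
    }
  }
  trials <- dplyr::bind_rows(out)
  attr(trials, "agent_params") <- dplyr::bind_rows(drawn)
  trials
}

#' Generating agent parameters attached to a simulated trial table
#'
#' Returns the per-participant x visit parameters that [simulate_visits()]
#' drew, useful for parameter-recovery and calibration studies where the
#' ground truth is needed.
#'
#' @param trials A trial table produced by [simulate_visits()].
#' @return Tibble: `participant_id`, `visit`, `group`, `alpha`, `beta`,
#'   `happy_bias`.
#' @export
generating_params <- function(trials) {
  p <- attr(trials, "agent_params")
  if (is.null(p)) abort("`trials` carries no generating-parameter attribute")
  p
}
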