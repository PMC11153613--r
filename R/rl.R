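#' Double-update Q-learning step
#'
#' Updates the expected-reward values of both options after a choice: the
#' chosen option moves toward the received reward and the unchosen option
#' moves toward the complementary outcome `1 - r`, both with the shared
#' learning rate `alpha`. This is the canonical double-update rule for a
#' two-option task with anticorrelated 60/40 contingencies; with rewards in
#' \{0, 1\} and `q1 + q2 = 1` initially, the update preserves `q1 + q2 = 1`
#' exactly.
#'
#' @param q Numeric length-2 vector of current Q values.
#' @param chosen 1 or 2, the option chosen.
#' @param reward 0 or 1, the outcome received.
#' @param alpha Learning rate in \[0, 1\].
#' @return Updated length-2 Q vector.
#' @examples
#' double_update(c(0.5, 0.5), chosen = 1, reward = 1, alpha = 0.5) # 0.75 0.25
#' @export
double_update <- function(q, chosen, reward, alpha) {
  check_number(alpha, "alpha", 0, 1)
  if (!chosen %in% c(1, 2)) abort("`chosen` must be 1 or 2")
  if (!reward %in% c(0, 1)) abort("`reward` must be 0 or 1")
  unchosen <- 3L - as.integer(chosen)
  q_new <- q
  q_new[chosen] <- q[chosen] + alpha * (reward - q[chosen])
  q_new[unchosen] <- q[unchosen] + alpha * ((1 - reward) - q[unchosen])
  q_new
}

#' Softmax probability of choosing option 1
#'
#' `p1 = 1 / (1 + exp(-(beta * (q1 - q2) + bias)))`, evaluated through
#' [stats::plogis()] so it is overflow-safe for any magnitude of the
#' decision value.
#'
#' @param q Numeric length-2 vector of Q values.
#' @param beta Inverse temperature (>= 0).
#' @param bias Additive decision-value offset toward option 1 (default 0).
#' @return Probability of choosing option 1.
#' @export
choice_probability <- function(q, beta, bias = 0) {
  check_number(beta, "beta", lower = 0)
  plogis(beta * (q[1] - q[2]) + bias)
}

# Split a single participant x visit x condition trial set into per-block
# lists of (choice, outcome-target) with missing trials removed. The
# outcome target x_t is r when option 1 was chosen and 1 - r otherwise:
# under the conservation property q1 + q2 = 1, the option-1 value follows
# q1(t+1) = (1 - alpha) q1(t) + alpha x_t, a first-order recursion.
.block_traces <- function(trials) {
  check_columns(trials, c("block", "trial", "choice", "reward", "missing"), "trials")
  trials <- trials[order(trials$block, trials$trial), ]
  keep <- !trials$missing
  trials <- trials[keep, , drop = FALSE]
  split_idx <- split(seq_len(nrow(trials)), trials$block)
  lapply(split_idx, function(idx) {
    ch <- trials$choice[idx]
    r <- trials$reward[idx]
    list(choice = ch, x = ifelse(ch == 1L, r, 1 - r))
  })
}

.nll_from_traces <- function(alpha, beta, traces, bias = 0, eps = 1e-12) {
  nll <- 0
  for (tr in traces) {
    n <- length(tr$choice)
    if (n == 0L) next
    q1_after <- stats::filter(alpha * tr$x, 1 - alpha,
                              method = "recursive", init = 0.5)
    q1_before <- c(0.5, head(as.numeric(q1_after), -1L))
    p1 <- plogis(beta * (2 * q1_before - 1) + bias)
    p <- ifelse(tr$choice == 1L, p1, 1 - p1)
    nll <- nll - sum(log(pmax(p, eps)))
  }
  nll
}

#' Negative log-likelihood of the double-update model
#'
#' Sums `-log p(choice_t)` over non-missing trials of one participant x
#' visit x condition, with Q reset to (0.5, 0.5) at every block start and
#' the double-update applied after each non-missing trial. Missing trials
#' are skipped entirely (no likelihood contribution, no update).
#' Probabilities are clipped below at `eps` before taking logs.
#'
#' @param params Named list or vector with `alpha` and `beta`.
#' @param trials Trial table (one participant x visit x condition) with
#'   columns `block`, `trial`, `choice`, `reward`, `missing`.
#' @param bias Optional additive option-1 decision offset (default 0).
#' @param eps Likelihood floor (default 1e-12).
#' @return Negative log-likelihood in nats.
#' @export
negative_log_likelihood <- function(params, trials, bias = 0, eps = 1e-12) {
  alpha <- params[["alpha"]]; beta <- params[["beta"]]
  check_number(alpha, "alpha", 0, 1)
  check_number(beta, "beta", lower = 0)
  traces <- .block_traces(trials)
  if (sum(vapply(traces, function(tr) length(tr$choice), 1L)) == 0L) {
    abort("no non-missing trials: likelihood undefined")
  }
  .nll_from_traces(alpha, beta, traces, bias = bias, eps = eps)
}

#' Maximum-likelihood fit of the double-update model
#'
#' Bounded multi-start optimisation of [negative_log_likelihood()] with
#' L-BFGS-B from Latin-hypercube start points; the best start is returned.
#' Deterministic for a fixed seed.
#'
#' @param trials Trial table for one participant x visit x condition.
#' @param n_starts Number of Latin-hypercube starts (default 10).
#' @param seed Integer seed controlling the start points.
#' @param bounds List with `alpha` and `beta` length-2 bounds; defaults
#'   alpha in \[0.001, 1\], beta in \[0, 50\].
#' @param bias Fixed decision offset passed to the likelihood (default 0;
#'   the fitted model is the two-parameter model).
#' @return List of class `psytrs_fit`: `alpha`, `beta`, `nll`,
#'   `n_trials_used`, `converged`, `n_starts`.
#' @export
fit_mle <- function(trials, n_starts = 10, seed = 1,
                    bounds = list(alpha = c(0.001, 1), beta = c(0, 50)),
                    bias = 0) {
  traces <- .block_traces(trials)
  n_used <- sum(vapply(traces, function(tr) length(tr$choice), 1L))
  if (n_used == 0L) abort("no non-missing trials to fit")
  if (n_used < 20L) {
    warn(sprintf("only %d non-missing trials; parameter estimates may be unstable", n_used))
  }
  obj <- function(par) .nll_from_traces(par[1], par[2], traces, bias = bias)

  lo <- c(bounds$alpha[1], bounds$beta[1])
  hi <- c(bounds$alpha[2], bounds$beta[2])
  starts <- withr::with_seed(as.integer(seed %% .SEED_MOD), {
    u <- lhs::randomLHS(n_starts, 2)
    # alpha starts uniform; beta starts log-uniform so both the
    # near-random (small beta) and near-deterministic regimes are probed
    blo <- log(max(lo[2], 0.05)); bhi <- log(hi[2])
    cbind(lo[1] + u[, 1] * (hi[1] - lo[1]),
          exp(blo + u[, 2] * (bhi - blo)))
  })
  # keep starts off hard bounds
  starts[, 1] <- pmin(pmax(starts[, 1], lo[1] + 1e-4), hi[1] - 1e-4)
  starts[, 2] <- pmin(pmax(starts[, 2], lo[2] + 1e-3), hi[2] - 1e-3)

  best <- NULL
  any_conv <- FALSE
  for (s in seq_len(n_starts)) {
    res <- tryCatch(
      # factr scales machine epsilon: 4.5e7 * eps is a ~1e-8 NLL tolerance
      optim(starts[s, ], obj, method = "L-BFGS-B", lower = lo, upper = hi,
            control = list(factr = 4.5e7)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    any_conv <- any_conv || res$convergence == 0
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    return(structure(list(alpha = NA_real_, beta = NA_real_, nll = NA_real_,
                          n_trials_used = n_used, converged = FALSE,
                          n_starts = n_starts),
                     class = "psytrs_fit"))
  }
  structure(
    list(alpha = unname(best$par[1]), beta = unname(best$par[2]),
         nll = best$value, n_trials_used = n_used,
         converged = any_conv, n_starts = n_starts),
    class = "psytrs_fit"
  )
}

#' @export
print.psytrs_fit <- function(x, ...) {
  cat(sprintf(
    "double-update ML fit: alpha = %.3f, beta = %.2f, NLL = %.3f (%d trials, %s)\n",
    x$alpha, x$beta, x$nll, x$n_trials_used,
    if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}

#' Model-based ideal-choice classification
#'
#' Replays the fitted Q trajectory over a participant's trials (Q reset to
#' (0.5, 0.5) at block starts, double-update after each non-missing trial)
#' and flags each non-missing choice as *ideal* when the chosen option's Q
#' at decision time is at least the unchosen option's Q. Ties count as
#' ideal, so the first trial of a block - where both Q values are 0.5 - is
#' always ideal. The option with the strictly higher Q is recorded as the
#' trial's `ideal_option` (`NA` on ties, where neither face is preferred
#' by the model).
#'
#' @param params Named list or vector with `alpha` (and optionally `beta`,
#'   unused for classification).
#' @param trials Trial table for one participant x visit x condition.
#' @return List with `trials` (input plus `q1`, `q2` at decision time,
#'   `ideal`, `ideal_option`) and `proportion` (ideal-choice proportion
#'   over non-missing trials).
#' @export
classify_ideal_choices <- function(params, trials) {
  alpha <- params[["alpha"]]
  check_number(alpha, "alpha", 0, 1)
  check_columns(trials, c("block", "trial", "choice", "reward", "missing"), "trials")
  trials <- trials[order(trials$block, trials$trial), ]
  n <- nrow(trials)
  q1_col <- q2_col <- rep(NA_real_, n)
  ideal <- rep(NA, n)
  ideal_opt <- rep(NA_integer_, n)
  for (b in unique(trials$block)) {
    idx <- which(trials$block == b)
    q <- c(0.5, 0.5)
    for (i in idx) {
      if (trials$missing[i]) next
      q1_col[i] <- q[1]; q2_col[i] <- q[2]
      ch <- trials$choice[i]
      ideal[i] <- q[ch] >= q[3 - ch]
      if (q[1] != q[2]) ideal_opt[i] <- which.max(q)
      q <- double_update(q, ch, trials$reward[i], alpha)
    }
  }
  trials$q1 <- q1_col
  trials$q2 <- q2_col
  trials$ideal <- ideal
  trials$ideal_option <- ideal_opt
  list(trials = trials, proportion = mean(ideal[!trials$missing]))
}

#' Fit the RL model for every participant x visit x condition
#'
#' Convenience wrapper applying [fit_mle()] and
#' [classify_ideal_choices()] across a full trial table, pooling each
#' condition's blocks (with Q reset between blocks) into one fit.
#'
#' @param trial_table Trial tibble covering multiple participants/visits.
#' @param n_starts,seed,bounds Passed to [fit_mle()]; the seed fans out
#'   per fitted unit.
#' @param params_override Optional tibble (`participant_id`, `visit`,
#'   `condition`, `alpha`, `beta`). When supplied, fitting is skipped and
#'   these parameters drive the ideal-choice classification (useful for
#'   calibration studies where the generating parameters are known).
#' @return List with `fits` (one row per participant x visit x condition)
#'   and `trials` (input plus ideal-choice columns).
#' @export
fit_rl_models <- function(trial_table, n_starts = 10, seed = 1,
                          bounds = list(alpha = c(0.001, 1), beta = c(0, 50)),
                          params_override = NULL) {
  check_columns(trial_table,
                c("participant_id", "visit", "condition", "block", "trial",
                  "choice", "reward", "missing"), "trial_table")
  units <- dplyr::distinct(trial_table,
                           .data$participant_id, .data$visit, .data$condition)
  fits <- vector("list", nrow(units))
  flagged <- vector("list", nrow(units))
  for (i in seq_len(nrow(units))) {
    u <- units[i, ]
    tr <- trial_table[trial_table$participant_id == u$participant_id &
                        trial_table$visit == u$visit &
                        trial_table$condition == u$condition, ]
    if (is.null(params_override)) {
      fit <- suppressWarnings(
        fit_mle(tr, n_starts = n_starts,
                seed = derive_seed(seed, stage_offset("fit"), i),
                bounds = bounds))
      pars <- list(alpha = fit$alpha, beta = fit$beta)
      fits[[i]] <- tibble::tibble(
        participant_id = u$participant_id, visit = u$visit,
        condition = u$condition, alpha = fit$alpha, beta = fit$beta,
        nll = fit$nll, n_trials_used = fit$n_trials_used,
        converged = fit$converged)
    } else {
      po <- params_override
      row <- po[po$participant_id == u$participant_id &
                  po$visit == u$visit & po$condition == u$condition, ]
      if (nrow(row) != 1L) {
        abort(paste0("params_override lacks a row for ",
                     u$participant_id, "/", u$visit, "/", u$condition))
      }
      pars <- list(alpha = row$alpha, beta = row$beta)
      fits[[i]] <- tibble::tibble(
        participant_id = u$participant_id, visit = u$visit,
        condition = u$condition, alpha = row$alpha, beta = row$beta,
        nll = NA_real_, n_trials_used = sum(!tr$missing), converged = NA)
    }
    cls <- classify_ideal_choices(pars, tr)
    flagged[[i]] <- cls$trials
  }
  list(fits = dplyr::bind_rows(fits), trials = dplyr::bind_rows(flagged))
}
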