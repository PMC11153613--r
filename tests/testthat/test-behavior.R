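# build per-participant proportion tables directly
make_props <- function(values, groups = c("g1", "g2")) {
  # values: named list group -> matrix subjects x 4 (A.em, A.ne, C.em, C.ne)
  rows <- list()
  for (g in names(values)) {
    m <- values[[g]]
    for (i in seq_len(nrow(m))) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        participant_id = paste0(g, "s", i), group = g,
        visit = rep(c("A", "C"), each = 2),
        condition = rep(c("emotional", "neutral"), 2),
        n = 60, prop = m[i, ])
    }
  }
  dplyr::bind_rows(rows)
}

test_that("chance tests recover the closed-form one-sample t", {
  # exact mean 0.54, sd 0.094, n = 15 (the near-chance resistant cell)
  withr::with_seed(5, {
    x <- rnorm(15)
    x <- 0.54 + 0.094 * (x - mean(x)) / sd(x)
  })
  props <- tibble::tibble(participant_id = paste0("p", 1:15), group = "resistant",
                          visit = "C", condition = "emotional", n = 60, prop = x)
  res <- chance_tests(props)
  t_closed <- (0.54 - 0.5) / (0.094 / sqrt(15))
  expect_equal(res$t, t_closed, tolerance = 1e-10)
  expect_equal(res$t, 1.648, tolerance = 1e-3)
  expect_gt(res$p, 0.00625)
  expect_false(res$above_chance)
})

test_that("chance tests handle degenerate cells", {
  at_chance <- tibble::tibble(participant_id = paste0("p", 1:10), group = "g",
                              visit = "A", condition = "neutral", n = 60, prop = 0.5)
  res <- chance_tests(at_chance)
  expect_equal(res$t, 0)
  expect_false(res$above_chance)
  single <- at_chance[1, ]
  res <- chance_tests(single)
  expect_true(is.na(res$t))
  expect_match(res$note, "skipped")
})

test_that("chance tests hold their adjusted false-positive rate under the null", {
  # proportions fluctuating around 0.5 with no true learning signal
  n_cells <- 2000
  rej <- 0L
  withr::with_seed(55, {
    for (i in seq_len(n_cells)) {
      props <- tibble::tibble(participant_id = paste0("p", 1:35), group = "g",
                              visit = "A", condition = "emotional", n = 60,
                              prop = 0.5 + rnorm(35, 0, 0.1))
      if (isTRUE(chance_tests(props)$above_chance)) rej <- rej + 1L
    }
  })
  rate <- rej / n_cells
  # one-sided test at 0.00625 (only above-chance means flag): expected
  # rejection rate 0.00625 / 2, allow two Monte-Carlo SEs above it
  bound <- 0.003125 + 2 * sqrt(0.003125 * (1 - 0.003125) / n_cells)
  expect_lte(rate, bound)
})

test_that("responsive cells reject chance under the default generator", {
  labels <- generate_cohort(seed = 2)$labels
  hits <- 0L
  n_seeds <- 8
  for (s in 1:n_seeds) {
    tr <- simulate_visits(labels, seed = 400 + s)
    gp <- generating_params(tr)
    po <- tidyr::crossing(gp[, c("participant_id", "visit", "alpha", "beta")],
                          condition = c("emotional", "neutral"))
    rl <- fit_rl_models(tr, params_override = po)
    props <- ideal_choice_proportions(rl$trials, labels)
    ct <- chance_tests(props)
    resp <- ct[ct$group == "responsive", ]
    if (all(resp$above_chance)) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("three-way mixed ANOVA matches the balanced split-plot oracle", {
  withr::with_seed(31, {
    vals <- list(g1 = matrix(runif(4 * 4, 0.4, 0.9), 4),
                 g2 = matrix(runif(4 * 4, 0.4, 0.9), 4))
  })
  props <- make_props(vals)
  got <- mixed_anova_2x2x2(props)
  orc <- oracle_split_plot(props, dv = "prop", subject = "participant_id",
                           between = "group", within = c("visit", "condition"))
  for (eff in orc$effect) {
    g <- got[got$effect == eff, ]
    o <- orc[orc$effect == eff, ]
    expect_equal(g$F, o$F, tolerance = 1e-8,
                 label = paste("F for", eff))
    expect_equal(g$pes, o$pes, tolerance = 1e-8,
                 label = paste("pes for", eff))
    expect_equal(unname(c(g$df_num, g$df_den)), unname(c(o$df_num, o$df_den)))
  }
})

test_that("a pure visit x condition effect is detected selectively", {
  n_sims <- 60
  vc_sig <- 0L; group_sig <- 0L
  withr::with_seed(99, {
    for (i in seq_len(n_sims)) {
      base <- rnorm(20, 0.7, 0.05)
      rows <- list()
      for (s in 1:20) {
        g <- if (s <= 8) "g1" else "g2"
        for (v in c("A", "C")) for (cond in c("emotional", "neutral")) {
          eff <- if (v == "C" && cond == "emotional") -0.08 else 0
          rows[[length(rows) + 1L]] <- tibble::tibble(
            participant_id = paste0("s", s), group = g, visit = v,
            condition = cond, n = 60,
            prop = base[s] + eff + rnorm(1, 0, 0.04))
        }
      }
      av <- mixed_anova_2x2x2(dplyr::bind_rows(rows))
      if (av$p[av$effect == "visit:condition"] < 0.05) vc_sig <- vc_sig + 1L
      gp <- av$p[grepl("group", av$effect)]
      if (any(gp < 0.05)) group_sig <- group_sig + 1L
    }
  })
  expect_gte(vc_sig / n_sims, 0.9)   # injected interaction recovered
  expect_lte(group_sig / n_sims, 0.35) # group terms stay near nominal false-positive rates
})

test_that("emotional bias score counts conditional choices correctly", {
  bias_fixture <- function(ideal_opt, choice) {
    tibble::tibble(participant_id = "p", visit = "A", condition = "emotional",
                   block = 1L, trial = seq_along(choice),
                   choice = as.integer(choice), reward = 1L, missing = FALSE,
                   ideal_option = as.integer(ideal_opt))
  }
  # 4 angry-ideal trials, 3 happy chosen; 4 happy-ideal, 1 angry chosen
  tr <- bias_fixture(c(2, 2, 2, 2, 1, 1, 1, 1), c(1, 1, 1, 2, 1, 1, 1, 2))
  sc <- emotional_bias(tr)
  expect_equal(sc$score, 0.75 - 0.25)
  expect_equal(sc$n_angry_ideal, 4L)
  expect_equal(sc$n_happy_ideal, 4L)

  # always choosing happy -> maximal bias 1
  tr <- bias_fixture(c(2, 2, 1, 1), c(1, 1, 1, 1))
  expect_equal(emotional_bias(tr)$score, 1)

  # perfect ideal tracker -> both conditional error rates 0
  tr <- bias_fixture(c(2, 2, 1, 1), c(2, 2, 1, 1))
  expect_equal(emotional_bias(tr)$score, 0)

  # empty conditioning set -> undefined and flagged
  tr <- bias_fixture(c(1, 1, 1, 1), c(1, 2, 1, 1))
  sc <- emotional_bias(tr)
  expect_true(is.na(sc$score))
  expect_false(sc$defined)

  # missing and tied trials never enter the proportions
  tr <- bias_fixture(c(2, 2, NA, 1, 1), c(1, 2, 1, 2, 1))
  tr$missing[2] <- TRUE
  sc <- emotional_bias(tr)
  expect_equal(sc$score, 1 - 0.5)
})

test_that("uniform-map generator yields the expected small positive bias", {
  # no group effect: every cell uses the baseline parameters; the happy-bias
  # offset of 0.20 is calibrated to an overall emotional-bias score near 0.07
  labels <- generate_cohort(seed = 2)$labels
  map <- default_agent_map()
  map$alpha_mean <- 0.35; map$alpha_sd <- 0.10
  map$beta_mean <- 3.5; map$beta_sd <- 1.2
  map$bias_mean <- 0.20; map$bias_sd <- 0.20
  grand <- sapply(1:15, function(s) {
    tr <- simulate_visits(labels, map, seed = 800 + s)
    gp <- generating_params(tr)
    po <- tidyr::crossing(gp[, c("participant_id", "visit", "alpha", "beta")],
                          condition = c("emotional", "neutral"))
    rl <- fit_rl_models(tr, params_override = po)
    mean(emotional_bias(rl$trials)$score, na.rm = TRUE)
  })
  expect_lt(abs(mean(grand) - 0.07), 0.02)
  expect_gt(mean(grand), 0)
})

test_that("bias ANOVA matches the two-way split-plot oracle", {
  withr::with_seed(41, {
    rows <- list()
    for (g in c("g1", "g2")) for (s in 1:3) for (v in c("A", "C")) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        participant_id = paste0(g, s), visit = v,
        n_angry_ideal = 10L, n_happy_ideal = 10L,
        score = rnorm(1, 0.07, 0.1), defined = TRUE)
    }
  })
  scores <- dplyr::bind_rows(rows)
  labels <- tibble::tibble(participant_id = unique(scores$participant_id),
                           label = rep(c("g1", "g2"), each = 3))
  got <- bias_anova(scores, labels)
  df <- dplyr::inner_join(scores, labels, by = "participant_id")
  df$group <- df$label
  orc <- oracle_split_plot(df, dv = "score", subject = "participant_id",
                           between = "group", within = "visit")
  for (eff in orc$effect) {
    expect_equal(got$F[got$effect == eff], orc$F[orc$effect == eff],
                 tolerance = 1e-8, label = paste("F for", eff))
  }
})
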