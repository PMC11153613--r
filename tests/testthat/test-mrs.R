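met_row <- function(crlb, snr, fwhm, id = "p", visit = "A", met = "Glu", value = 1.2) {
  tibble::tibble(participant_id = id, visit = visit, metabolite = met,
                 value = value, crlb_pct = crlb, snr = snr, fwhm = fwhm)
}

test_that("QC gate applies the three strict criteria", {
  expect_equal(nrow(qc_filter(met_row(19.9, 10.1, 0.099))$included), 1)
  res <- qc_filter(met_row(20.0, 15, 0.05))
  expect_equal(nrow(res$included), 0)
  expect_match(res$excluded$qc_reason, "CRLB")
  # one record failing each criterion, three clean
  tab <- dplyr::bind_rows(
    met_row(25, 15, 0.05), met_row(5, 8, 0.05), met_row(5, 15, 0.12),
    met_row(5, 15, 0.05), met_row(10, 12, 0.08), met_row(2, 30, 0.03))
  res <- qc_filter(tab)
  expect_equal(nrow(res$included), 3)
  expect_equal(nrow(res$excluded), 3)
  # missing QC field -> incomplete
  res <- qc_filter(met_row(NA, 15, 0.05))
  expect_equal(nrow(res$included), 0)
  expect_match(res$excluded$qc_reason, "incomplete")
})

test_that("QC survivors always satisfy all predicates on fuzzed tables", {
  withr::with_seed(8, {
    tab <- met_row(runif(300, 0, 40), runif(300, 0, 25), runif(300, 0, 0.2))
    res <- qc_filter(tab)
    expect_equal(nrow(res$included) + nrow(res$excluded), 300)
    with(res$included, {
      expect_true(all(crlb_pct < 20 & snr > 10 & fwhm < 0.1))
    })
    with(res$excluded, {
      expect_true(all(!(crlb_pct < 20 & snr > 10 & fwhm < 0.1)))
    })
  })
})

test_that("glutamate ANOVA matches the split-plot oracle on a balanced fixture", {
  withr::with_seed(12, {
    rows <- list()
    for (g in c("resistant", "responsive")) for (s in 1:4) for (v in c("A", "C")) {
      rows[[length(rows) + 1L]] <- met_row(5, 15, 0.05,
                                           id = paste0(g, s), visit = v,
                                           value = rnorm(1, 1.2, 0.1))
    }
  })
  records <- dplyr::bind_rows(rows)
  labels <- tibble::tibble(participant_id = unique(records$participant_id),
                           label = rep(c("resistant", "responsive"), each = 4))
  got <- glutamate_anova(records, labels)
  df <- dplyr::inner_join(records, labels, by = "participant_id")
  df$group <- df$label
  orc <- oracle_split_plot(df, dv = "value", subject = "participant_id",
                           between = "group", within = "visit")
  for (eff in orc$effect) {
    expect_equal(got$F[got$effect == eff], orc$F[orc$effect == eff],
                 tolerance = 1e-8, label = paste("F for", eff))
  }
})

test_that("creatine stability recovers the closed-form paired t", {
  a <- c(7.1, 7.4, 7.9, 7.0, 7.6); c_ <- c(7.0, 7.5, 7.7, 7.2, 7.4)
  rec <- dplyr::bind_rows(
    met_row(5, 15, 0.05, id = paste0("p", 1:5), visit = "A", met = "tCr", value = a),
    met_row(5, 15, 0.05, id = paste0("p", 1:5), visit = "C", met = "tCr", value = c_))
  res <- creatine_stability(rec)
  d <- a - c_
  expect_equal(res$t, mean(d) / (sd(d) / sqrt(5)), tolerance = 1e-12)
  expect_equal(res$df, 4)
  # identical values -> t = 0
  rec2 <- rec
  rec2$value <- rep(a, 2)
  expect_equal(creatine_stability(rec2)$t, 0)
})

test_that("paired t has nominal coverage under the null", {
  withr::with_seed(23, {
    inside <- 0L
    for (i in 1:200) {
      a <- rnorm(50, 7.5, 0.5); c_ <- a + rnorm(50, 0, 0.3)
      tt <- t.test(a, c_, paired = TRUE)
      rec <- dplyr::bind_rows(
        met_row(5, 15, 0.05, id = paste0("p", 1:50), visit = "A", met = "tCr", value = a),
        met_row(5, 15, 0.05, id = paste0("p", 1:50), visit = "C", met = "tCr", value = c_))
      res <- creatine_stability(rec)
      expect_equal(res$t, unname(tt$statistic), tolerance = 1e-12)
      if (abs(res$t) < qt(0.975, 49)) inside <- inside + 1L
    }
    expect_gte(inside / 200, 0.90)
  })
})

test_that("Spearman correlation handles monotonicity, sign and ties", {
  x <- c(1, 2, 3, 5, 8, 13)
  y <- x^2
  expect_equal(spearman_corr(x, y)$rho, 1)
  expect_equal(spearman_corr(-x, y)$rho, -1)
  # tie fixture against the explicit midrank oracle
  x <- c(1, 2, 2, 3, 4, 5)
  y <- c(2, 1, 4, 4, 3, 6)
  expect_equal(spearman_corr(x, y)$rho, oracle_spearman(x, y), tolerance = 1e-12)
  # fuzzed fixtures with duplicates
  withr::with_seed(3, {
    for (i in 1:25) {
      n <- sample(5:12, 1)
      x <- sample(1:6, n, replace = TRUE)
      y <- sample(1:6, n, replace = TRUE)
      if (sd(x) == 0 || sd(y) == 0) next
      expect_equal(spearman_corr(x, y)$rho, oracle_spearman(x, y),
                   tolerance = 1e-12)
    }
  })
  # constant input undefined
  res <- spearman_corr(rep(1, 6), 1:6)
  expect_false(res$defined)
  expect_error(spearman_corr(1:3, 1:3), "at least 4")
})

test_that("Fisher r-to-z comparison matches its defining transform", {
  expect_equal(fisher_z_compare(0.3, 20, 0.3, 40)$Z, 0)
  res <- fisher_z_compare(-0.46, 35, 0.18, 15)
  expect_equal(res$Z, (atanh(-0.46) - atanh(0.18)) / sqrt(1 / 32 + 1 / 12),
               tolerance = 1e-12)
  # antisymmetry
  expect_equal(fisher_z_compare(0.18, 15, -0.46, 35)$Z, -res$Z, tolerance = 1e-12)
  # fuzzed re-derivation
  withr::with_seed(6, {
    for (i in 1:50) {
      r1 <- runif(1, -0.95, 0.95); r2 <- runif(1, -0.95, 0.95)
      n1 <- sample(5:80, 1); n2 <- sample(5:80, 1)
      expect_equal(fisher_z_compare(r1, n1, r2, n2)$Z,
                   (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3)),
                   tolerance = 1e-12)
    }
  })
  expect_error(fisher_z_compare(1, 10, 0.2, 10), "range")
})

test_that("rank correlation is invariant to monotone shifts of both variables", {
  withr::with_seed(9, {
    x <- rnorm(30); y <- 0.5 * x + rnorm(30)
    base <- spearman_corr(x, y)$rho
    expect_equal(spearman_corr(x + 100, y - 3)$rho, base, tolerance = 1e-12)
    expect_equal(spearman_corr(exp(x), y)$rho, base, tolerance = 1e-12)
  })
})

test_that("synthetic MRS/ROI generator is deterministic with plausible QC yield", {
  labels <- generate_cohort(seed = 4)$labels
  g1 <- generate_mrs_roi_data(labels, seed = 10)
  g2 <- generate_mrs_roi_data(labels, seed = 10)
  expect_identical(g1, g2)
  expect_equal(nrow(g1$metabolites), 50 * 2 * 2)
  expect_equal(nrow(g1$roi), 50 * 2 * 3)
  # QC pass rate near 95% over several seeds
  rates <- sapply(1:10, function(s) {
    m <- generate_mrs_roi_data(labels, seed = s)$metabolites
    glu <- m[m$metabolite == "Glu", ]
    nrow(qc_filter(glu)$included) / nrow(glu)
  })
  expect_gt(mean(rates), 0.88)
  expect_lt(mean(rates), 0.995)
})

test_that("generated coupling appears only in the responsive group at visit C", {
  labels <- generate_cohort(seed = 5)$labels
  rhos <- sapply(1:25, function(s) {
    d <- generate_mrs_roi_data(labels, seed = 200 + s)
    cc <- coupling_comparison(d$roi, d$metabolites, labels)
    c(cc$responsive$rho, cc$resistant$rho)
  })
  expect_lt(mean(rhos[1, ]), -0.3)   # responsive strongly negative on average
  expect_lt(abs(mean(rhos[2, ])), 0.15) # resistant near zero
})
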