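#' Quality-control gate for MRS metabolite estimates
#'
#' Keeps a metabolite record only when all three spectral-quality criteria
#' hold strictly: Cramer-Rao lower bound below 20%, signal-to-noise ratio
#' above 10 and linewidth (FWHM) below 0.1 ppm. Records with any missing
#' QC field are excluded as incomplete. Every exclusion is logged with the
#' failing criteria.
#'
#' @param records Tibble with at least `crlb_pct`, `snr`, `fwhm` columns.
#' @param crlb_max,snr_min,fwhm_max QC thresholds (defaults 20, 10, 0.1).
#' @return List with `included` (surviving rows) and `excluded` (rows plus
#'   a `qc_reason` column).
#' @export
qc_filter <- function(records, crlb_max = 20, snr_min = 10, fwhm_max = 0.1) {
  check_columns(records, c("crlb_pct", "snr", "fwhm"), "records")
  reason <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (anyNA(c(r$crlb_pct, r$snr, r$fwhm))) {
      reason[i] <- "incomplete QC fields"
      next
    }
    fails <- c(
      if (!(r$crlb_pct < crlb_max)) sprintf("CRLB %.3g%% >= %g%%", r$crlb_pct, crlb_max),
      if (!(r$snr > snr_min)) sprintf("SNR %.3g <= %g", r$snr, snr_min),
      if (!(r$fwhm < fwhm_max)) sprintf("FWHM %.3g ppm >= %g ppm", r$fwhm, fwhm_max)
    )
    reason[i] <- paste(fails, collapse = "; ")
  }
  keep <- reason == ""
  excluded <- records[!keep, , drop = FALSE]
  if (nrow(excluded) > 0) excluded$qc_reason <- reason[!keep]
  list(included = records[keep, , drop = FALSE], excluded = excluded)
}

#' Group x visit mixed ANOVA on glutamate levels
#'
#' Mixed ANOVA (group between-subjects, visit within-subjects) on the
#' Glu/tCr ratio of QC-passed records. Participants missing either visit
#' are dropped.
#'
#' @param records Metabolite tibble (`participant_id`, `visit`,
#'   `metabolite`, `value`), typically the `included` element of
#'   [qc_filter()].
#' @param labels Tibble with `participant_id` and `label`.
#' @param metabolite Which metabolite to analyse (default "Glu").
#' @return Tidy ANOVA tibble (`effect`, `df_num`, `df_den`, `F`, `p`,
#'   `pes`).
#' @export
glutamate_anova <- function(records, labels, metabolite = "Glu") {
  check_columns(records, c("participant_id", "visit", "metabolite", "value"),
                "records")
  d <- records |>
    dplyr::filter(.data$metabolite == !!metabolite) |>
    dplyr::inner_join(labels, by = "participant_id") |>
    dplyr::rename(group = "label") |>
    dplyr::mutate(group = as.character(.data$group))
  if (nrow(d) == 0L) abort(paste0("no records for metabolite ", metabolite))
  .mixed_anova(d, dv = "value", subject = "participant_id",
               between = "group", within = "visit")
}

#' Stability of the creatine reference across visits
#'
#' Paired t-test of total-creatine levels between visits A and C; a
#' non-significant change supports using tCr as the reference denominator.
#' Participants without both visits are dropped.
#'
#' @param records Metabolite tibble containing `tCr` rows with
#'   `participant_id`, `visit`, `value`.
#' @return List: `t`, `df`, `p`, `mean_diff` (A minus C), `n_pairs`,
#'   `n_dropped`.
#' @export
creatine_stability <- function(records) {
  check_columns(records, c("participant_id", "visit", "metabolite", "value"),
                "records")
  d <- records[records$metabolite == "tCr" & records$visit %in% c("A", "C"), ]
  wide <- tidyr::pivot_wider(d[, c("participant_id", "visit", "value")],
                             names_from = "visit", values_from = "value")
  n_dropped <- sum(!stats::complete.cases(wide[, c("A", "C")]))
  wide <- wide[stats::complete.cases(wide[, c("A", "C")]), ]
  if (nrow(wide) < 2L) abort("fewer than 2 complete visit pairs for tCr")
  if (sd(wide$A - wide$C) == 0) {
    d <- mean(wide$A - wide$C)
    return(list(t = if (d == 0) 0 else sign(d) * Inf,
                df = nrow(wide) - 1, p = if (d == 0) 1 else 0,
                mean_diff = d, n_pairs = nrow(wide), n_dropped = n_dropped))
  }
  tt <- t.test(wide$A, wide$C, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_diff = unname(tt$estimate), n_pairs = nrow(wide),
       n_dropped = n_dropped)
}

#' Spearman rank correlation
#'
#' Rank correlation with midrank tie handling and a two-tailed p-value via
#' the t approximation.
#'
#' @param x,y Numeric vectors; incomplete pairs are dropped.
#' @return List: `rho`, `n`, `p`, `defined` (FALSE when an input is
#'   constant, where the correlation is undefined).
#' @export
spearman_corr <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) abort("need at least 4 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(rho = NA_real_, n = n, p = NA_real_, defined = FALSE))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), n = n, p = ct$p.value, defined = TRUE)
}

#' Compare two independent correlations via Fisher's r-to-z
#'
#' Transforms each coefficient with `atanh` and compares
#' `Z = (z1 - z2) / sqrt(1/(n1-3) + 1/(n2-3))` against the standard
#' normal (two-tailed). Applied here to Spearman coefficients exactly as in
#' common practice; note the transform is exact variance-stabilising only
#' for Pearson correlations and is an approximation for rank correlations.
#'
#' @param r1,n1 Correlation and sample size of group 1.
#' @param r2,n2 Correlation and sample size of group 2.
#' @return List of class `psytrs_fisher_z`: `r1`, `n1`, `r2`, `n2`, `z1`,
#'   `z2`, `Z`, `p`.
#' @examples
#' fisher_z_compare(-0.46, 35, 0.18, 15) # Z approximately -2.006
#' @export
fisher_z_compare <- function(r1, n1, r2, n2) {
  check_number(r1, "r1", -1, 1, closed_lower = FALSE, closed_upper = FALSE)
  check_number(r2, "r2", -1, 1, closed_lower = FALSE, closed_upper = FALSE)
  check_number(n1, "n1", lower = 4)
  check_number(n2, "n2", lower = 4)
  z1 <- atanh(r1); z2 <- atanh(r2)
  Z <- (z1 - z2) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  structure(list(r1 = r1, n1 = n1, r2 = r2, n2 = n2,
                 z1 = z1, z2 = z2, Z = Z, p = 2 * pnorm(-abs(Z))),
            class = "psytrs_fisher_z")
}

#' @export
print.psytrs_fisher_z <- function(x, ...) {
  cat(sprintf("Fisher r-to-z comparison: r1 = %.3f (n = %d) vs r2 = %.3f (n = %d): Z = %.3f, p = %.4f\n",
              x$r1, as.integer(x$n1), x$r2, as.integer(x$n2), x$Z, x$p))
  invisible(x)
}

#' Default effect configuration for the synthetic MRS / ROI generator
#'
#' Cell means and SDs for the three regions of interest (peak-voxel
#' parameter estimates, emotional condition), the Glu/tCr distribution,
#' the responsive-group visit-C glutamate-mPFC coupling, and the QC-field
#' distributions (drawn so roughly 95% of records pass the QC gate).
#' The ROI means encode the group x visit interaction directions of the
#' study design: resistant amygdala and pallidum activity starts low and
#' rises over time while mPFC falls; responsive mPFC rises and pallidum
#' falls.
#'
#' @return A nested list of generator settings.
#' @export
default_mrs_effects <- function() {
  list(
    roi = list(
      right_amygdala = list(phase = "decision",
                            mean = c(resistant_A = -0.5, resistant_C = 0.3,
                                     responsive_A = 0.3, responsive_C = 0.3),
                            sd = 0.6),
      left_pallidum = list(phase = "feedback",
                           mean = c(resistant_A = -0.4, resistant_C = 0.4,
                                    responsive_A = 0.4, responsive_C = -0.1),
                           sd = 0.6),
      mPFC = list(phase = "feedback",
                  mean = c(resistant_A = 0.3, resistant_C = -0.3,
                           responsive_A = 0.3, responsive_C = 0.6),
                  sd = 0.6)
    ),
    glu = list(mean = 1.20, sd = 0.12),
    tcr = list(mean = 7.5, sd = 0.5, visit_shift = 0, visit_noise_sd = 0.25),
    coupling = list(responsive_C = -0.48, resistant_C = 0),
    qc = list(crlb_meanlog = log(10), crlb_sdlog = 0.33,
              snr_mean = 16, snr_sd = 3,
              fwhm_mean = 0.065, fwhm_sd = 0.017)
  )
}

#' Generate synthetic MRS and ROI tables
#'
#' Draws per-participant x visit metabolite records (Glu/tCr with QC
#' fields, plus a tCr reference row) and peak-voxel ROI parameter
#' estimates for right amygdala (decision phase), left pallidum and mPFC
#' (feedback phase), emotional condition. The responsive group's visit-C
#' mPFC betas are drawn jointly with glutamate at the configured negative
#' coupling (Pearson -0.48, giving a Spearman correlation near -0.46);
#' the resistant group's coupling defaults to zero.
#'
#' @param labels Tibble with `participant_id` and `label`.
#' @param effects Effect configuration, see [default_mrs_effects()].
#' @param seed Integer seed.
#' @return List with `metabolites` (rows: Glu ratio and tCr level per
#'   participant x visit, with `crlb_pct`, `snr`, `fwhm`) and `roi` (one
#'   row per participant x visit x region).
#' @export
generate_mrs_roi_data <- function(labels, effects = default_mrs_effects(),
                                  seed = 1) {
  check_columns(labels, c("participant_id", "label"), "labels")
  labels <- labels[labels$label %in% c("resistant", "responsive"), ]
  n <- nrow(labels)
  if (n == 0L) abort("no classified participants to generate data for")
  for (region in names(effects$roi)) {
    if (any(effects$roi[[region]]$sd <= 0)) abort("ROI SDs must be positive")
  }

  ids <- labels$participant_id
  grp <- as.character(labels$label)
  qc <- effects$qc
  met <- list(); roi <- list()
  withr::with_seed(derive_seed(seed, stage_offset("mrs")), {
    tcr_a <- rnorm(n, effects$tcr$mean, effects$tcr$sd)
    for (visit in c("A", "C")) {
      glu <- rnorm(n, effects$glu$mean, effects$glu$sd)
      tcr <- if (visit == "A") tcr_a else
        tcr_a + effects$tcr$visit_shift + rnorm(n, 0, effects$tcr$visit_noise_sd)
      met[[visit]] <- tibble::tibble(
        participant_id = rep(ids, 2),
        visit = visit,
        metabolite = rep(c("Glu", "tCr"), each = n),
        value = c(glu, tcr),
        crlb_pct = c(stats::rlnorm(n, qc$crlb_meanlog, qc$crlb_sdlog),
                     stats::rlnorm(n, log(4), 0.25)),
        snr = c(rnorm(n, qc$snr_mean, qc$snr_sd),
                rnorm(n, qc$snr_mean + 4, qc$snr_sd)),
        fwhm = pmax(c(rnorm(n, qc$fwhm_mean, qc$fwhm_sd),
                      rnorm(n, qc$fwhm_mean, qc$fwhm_sd)), 0.01))
      for (region in names(effects$roi)) {
        spec <- effects$roi[[region]]
        mu <- unname(spec$mean[paste(grp, visit, sep = "_")])
        rho <- if (region == "mPFC" && visit == "C") {
          vapply(grp, function(g) {
            v <- effects$coupling[[paste0(g, "_C")]]
            if (is.null(v)) 0 else v
          }, numeric(1), USE.NAMES = FALSE)
        } else rep(0, n)
        beta <- mu + rho * spec$sd * (glu - effects$glu$mean) / effects$glu$sd +
          sqrt(1 - rho^2) * spec$sd * rnorm(n)
        roi[[paste(visit, region)]] <- tibble::tibble(
          participant_id = ids, visit = visit, region = region,
          phase = spec$phase, condition = "emotional", beta = beta)
      }
    }
  })
  list(metabolites = dplyr::bind_rows(met), roi = dplyr::bind_rows(roi))
}

#' Glutamate-mPFC coupling comparison at follow-up
#'
#' Computes the Spearman correlation between visit-C mPFC parameter
#' estimates and visit-C Glu/tCr within each group, then compares the two
#' coefficients with [fisher_z_compare()].
#'
#' @param roi ROI tibble (needs mPFC rows).
#' @param metabolites Metabolite tibble (QC-passed Glu rows).
#' @param labels Tibble with `participant_id`, `label`.
#' @param visit Visit to analyse (default "C").
#' @return List: per-group correlation results (`responsive`,
#'   `resistant`) and `comparison` (a `psytrs_fisher_z`).
#' @export
coupling_comparison <- function(roi, metabolites, labels, visit = "C") {
  glu <- metabolites[metabolites$metabolite == "Glu" &
                       metabolites$visit == visit, ]
  mpfc <- roi[roi$region == "mPFC" & roi$visit == visit, ]
  d <- dplyr::inner_join(
    glu[, c("participant_id", "value")],
    mpfc[, c("participant_id", "beta")], by = "participant_id") |>
    dplyr::inner_join(labels, by = "participant_id")
  by_group <- lapply(split(d, as.character(d$label)), function(g) {
    if (sum(stats::complete.cases(g$beta, g$value)) < 4) {
      return(list(rho = NA_real_, n = nrow(g), p = NA_real_, defined = FALSE))
    }
    spearman_corr(g$beta, g$value)
  })
  res <- by_group[["responsive"]]; rst <- by_group[["resistant"]]
  cmp <- if (!is.null(res) && !is.null(rst) && res$defined && rst$defined) {
    fisher_z_compare(res$rho, res$n, rst$rho, rst$n)
  } else NULL
  list(responsive = res, resistant = rst, comparison = cmp)
}
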