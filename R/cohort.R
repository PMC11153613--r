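#' PANSS positive-symptom threshold
#'
#' Tests whether a set of PANSS positive-subscale item scores meets the
#' symptom threshold used for treatment-resistance categorisation: at least
#' one item rated 5 (moderate severe) or higher, or at least two items rated
#' 4 (moderate) or higher.
#'
#' @param items Numeric vector of 7 PANSS positive item scores, each in 1-7.
#' @return `TRUE` if the threshold is met, otherwise `FALSE`.
#' @examples
#' meets_symptom_threshold(c(5, 1, 1, 1, 1, 1, 1)) # TRUE, one item >= 5
#' meets_symptom_threshold(c(4, 4, 1, 1, 1, 1, 1)) # TRUE, two items >= 4
#' meets_symptom_threshold(c(4, 3, 3, 3, 3, 3, 3)) # FALSE
#' @export
meets_symptom_threshold <- function(items) {
  if (length(items) != 7L || anyNA(items) || !is.numeric(items)) {
    abort("`items` must be 7 non-missing PANSS positive item scores")
  }
  if (any(items < 1 | items > 7)) {
    abort("PANSS item scores must lie in [1, 7]")
  }
  max(items) >= 5 || sum(items >= 4) >= 2
}

#' Classify treatment response from longitudinal clinical records
#'
#' Applies TRRIP-style consensus rules to per-visit participant records.
#' A participant is *treatment-resistant* when, at the one-year visit C, the
#' PANSS positive symptom threshold is met, at least two adequate
#' antipsychotic trials have been completed, medication adherence is
#' adequate, and social-occupational functioning is low (SOFAS below 60).
#' A participant is *treatment-responsive* when adherence is adequate and
#' the symptom threshold is met at neither visit B nor visit C (six-month
#' symptom stability). Anyone else is *unclassified* and is excluded from
#' downstream analyses, with the failing rule recorded.
#'
#' @param records Data frame with one row per participant x visit. Required
#'   columns: `participant_id`, `visit` ("A", "B" or "C"), `panss_p1` ..
#'   `panss_p7` (item scores 1-7), `sofa` (0-100), `adequate_med_trials`
#'   (count), `adherent` (logical). Visit-B rows only need the PANSS items.
#' @return A tibble with columns `participant_id`, `label` (factor:
#'   resistant / responsive / unclassified) and `reason` (why a participant
#'   was left unclassified, `NA` otherwise).
#' @export
classify_treatment_response <- function(records) {
  item_cols <- paste0("panss_p", 1:7)
  check_columns(records, c("participant_id", "visit", item_cols), "records")
  records <- as.data.frame(records)

  classify_one <- function(rec) {
    b <- rec[rec$visit == "B", , drop = FALSE]
    c_ <- rec[rec$visit == "C", , drop = FALSE]
    if (nrow(c_) != 1L || nrow(b) != 1L) {
      return(list(label = "unclassified", reason = "missing visit B or C record"))
    }
    thr_b <- meets_symptom_threshold(as.numeric(b[1, item_cols]))
    thr_c <- meets_symptom_threshold(as.numeric(c_[1, item_cols]))
    adherent <- isTRUE(c_$adherent[1])
    if (thr_c) {
      if (!adherent) {
        return(list(label = "unclassified", reason = "symptoms met threshold but not adherent"))
      }
      if (is.na(c_$adequate_med_trials[1]) || c_$adequate_med_trials[1] < 2) {
        return(list(label = "unclassified", reason = "fewer than two adequate medication trials"))
      }
      if (is.na(c_$sofa[1]) || c_$sofa[1] >= 60) {
        return(list(label = "unclassified", reason = "symptom threshold met but SOFAS >= 60"))
      }
      return(list(label = "resistant", reason = NA_character_))
    }
    if (adherent && !thr_b) {
      return(list(label = "responsive", reason = NA_character_))
    }
    reason <- if (!adherent) "not medication adherent" else
      "symptom threshold met at visit B only (no 6-month stability)"
    list(label = "unclassified", reason = reason)
  }

  ids <- unique(records$participant_id)
  out <- lapply(ids, function(id) {
    res <- classify_one(records[records$participant_id == id, , drop = FALSE])
    tibble::tibble(participant_id = id, label = res$label, reason = res$reason)
  })
  out <- dplyr::bind_rows(out)
  out$label <- factor(out$label, levels = c("resistant", "responsive", "unclassified"))
  out
}

#' Compare a binary demographic split between two groups
#'
#' Pearson chi-square (uncorrected) on a 2 x 2 table built from per-group
#' counts of a binary attribute, e.g. number of males per group in a
#' demographics table.
#'
#' @param k1,n1 Count with the attribute and total size of group 1.
#' @param k2,n2 Count with the attribute and total size of group 2.
#' @return List: `chisq`, `df`, `p`.
#' @examples
#' demographic_chisq(11, 15, 25, 35) # chi-square approximately 0.019
#' @export
demographic_chisq <- function(k1, n1, k2, n2) {
  if (k1 > n1 || k2 > n2 || any(c(k1, n1, k2, n2) < 0)) {
    abort("counts must be non-negative and bounded by their group sizes")
  }
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(chisq = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Generate a synthetic early-psychosis cohort
#'
#' Builds per-visit clinical records for a two-group longitudinal cohort
#' whose fields are sampled to satisfy the treatment-response rules for the
#' intended label, so that [classify_treatment_response()] recovers the
#' generating labels exactly. Defaults mirror the study design: 15
#' treatment-resistant and 35 treatment-responsive participants followed
#' over visits A (baseline), B (6 months) and C (1 year).
#'
#' Resistant participants are given visit-C PANSS positive items that meet
#' the symptom threshold, two or more adequate medication trials, adequate
#' adherence and SOFAS below 60; responsive participants get sub-threshold
#' items at visits B and C. Negative/general PANSS totals and CPZ-equivalent
#' doses are descriptive pass-through fields drawn near the group means of
#' the cohort being emulated.
#'
#' @param n_resistant,n_responsive Group sizes (non-negative integers).
#' @param seed Integer seed; the same seed reproduces the same cohort.
#' @return A list with `participants` (one row per participant x visit) and
#'   `labels` (participant_id, label).
#' @export
generate_cohort <- function(n_resistant = 15, n_responsive = 35, seed = 1) {
  check_number(n_resistant, "n_resistant", lower = 0)
  check_number(n_responsive, "n_responsive", lower = 0)
  if (n_resistant != round(n_resistant) || n_responsive != round(n_responsive)) {
    abort("group sizes must be whole numbers")
  }
  n <- n_resistant + n_responsive
  if (n < 1) abort("cohort must contain at least one participant")

  labels <- rep(c("resistant", "responsive"), c(n_resistant, n_responsive))
  ids <- sprintf("P%03d", seq_len(n))

  sample_items <- function(lambda_shift) {
    # baseline severity: items 1..7 clipped to [1, 7]
    pmin(pmax(round(rnorm(7, mean = lambda_shift, sd = 0.9)), 1), 7)
  }

  make_resistant_visit <- function(visit) {
    items <- sample_items(if (visit == "A") 2.3 else 2.8)
    if (visit == "C") {
      items[sample.int(7, 1)] <- sample(5:6, 1) # guarantee threshold clause 1
    } else {
      items <- pmin(items, 6)
    }
    items
  }
  make_responsive_visit <- function(visit) {
    items <- sample_items(1.6)
    if (visit %in% c("B", "C")) {
      items <- pmin(items, 3)                   # sub-threshold: no item >= 4
    }
    items
  }

  rows <- list()
  withr::with_seed(derive_seed(seed, stage_offset("cohort")), {
    for (i in seq_len(n)) {
      lab <- labels[i]
      sofa <- if (lab == "resistant") sample(30:55, 1) else sample(55:90, 1)
      trials <- if (lab == "resistant") sample(2:4, 1) else sample(1:3, 1)
      cpz <- round(rnorm(1, mean = if (lab == "resistant") 240 else 230, sd = 90))
      for (visit in c("A", "B", "C")) {
        items <- if (lab == "resistant") make_resistant_visit(visit)
                 else make_responsive_visit(visit)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          participant_id = ids[i],
          visit = visit,
          panss_p1 = items[1], panss_p2 = items[2], panss_p3 = items[3],
          panss_p4 = items[4], panss_p5 = items[5], panss_p6 = items[6],
          panss_p7 = items[7],
          panss_positive_total = sum(items),
          panss_negative_total = round(rnorm(1, if (lab == "resistant") 17 else 12, 4)),
          panss_general_total = round(rnorm(1, if (lab == "resistant") 36 else 29, 6)),
          sofa = sofa,
          adequate_med_trials = trials,
          adherent = TRUE,
          cpz_equivalent = max(cpz, 25)
        )
      }
    }
  })
  participants <- dplyr::bind_rows(rows)
  list(
    participants = participants,
    labels = tibble::tibble(
      participant_id = ids,
      label = factor(labels, levels = c("resistant", "responsive", "unclassified"))
    )
  )
}
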