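# Independent reference implementations used as oracles. These deliberately
# avoid the package's vectorised code paths: everything here is scalar,
# loop-based and written directly from the defining formulas.

# --- double-update / likelihood trace ---------------------------------------

# Scalar per-trial trace of the double-update likelihood: replays blocks one
# trial at a time with explicit two-element Q arithmetic.
oracle_nll <- function(alpha, beta, trials, bias = 0, eps = 1e-12) {
  nll <- 0
  for (b in unique(trials$block)) {
    blk <- trials[trials$block == b, ]
    blk <- blk[order(blk$trial), ]
    q <- c(0.5, 0.5)
    for (i in seq_len(nrow(blk))) {
      if (blk$missing[i]) next
      p1 <- 1 / (1 + exp(-(beta * (q[1] - q[2]) + bias)))
      p <- if (blk$choice[i] == 1) p1 else 1 - p1
      nll <- nll - log(max(p, eps))
      ch <- blk$choice[i]; r <- blk$reward[i]
      q_new <- q
      q_new[ch] <- q[ch] + alpha * (r - q[ch])
      q_new[3 - ch] <- q[3 - ch] + alpha * ((1 - r) - q[3 - ch])
      q <- q_new
    }
  }
  nll
}

# Scalar trace of the ideal-choice rule: returns per-row ideal flags and the
# model-preferred option, NA on missing rows.
oracle_ideal_trace <- function(alpha, trials) {
  trials <- trials[order(trials$block, trials$trial), ]
  ideal <- rep(NA, nrow(trials))
  pref <- rep(NA_integer_, nrow(trials))
  for (b in unique(trials$block)) {
    idx <- which(trials$block == b)
    q <- c(0.5, 0.5)
    for (i in idx) {
      if (trials$missing[i]) next
      ch <- trials$choice[i]
      ideal[i] <- q[ch] >= q[3 - ch]
      if (q[1] != q[2]) pref[i] <- which.max(q)
      r <- trials$reward[i]
      q_new <- q
      q_new[ch] <- q[ch] + alpha * (r - q[ch])
      q_new[3 - ch] <- q[3 - ch] + alpha * ((1 - r) - q[3 - ch])
      q <- q_new
    }
  }
  list(ideal = ideal, pref = pref)
}

# --- symptom-threshold clauses ----------------------------------------------

oracle_threshold <- function(items) {
  clause1 <- FALSE
  for (x in items) if (x >= 5) clause1 <- TRUE
  n4 <- 0
  for (x in items) if (x >= 4) n4 <- n4 + 1
  clause1 || n4 >= 2
}

# --- Spearman via explicit midranks and hand-coded Pearson ------------------

oracle_midranks <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    below <- 0; ties <- 0
    for (j in seq_len(n)) {
      if (x[j] < x[i]) below <- below + 1
      if (j != i && x[j] == x[i]) ties <- ties + 1
    }
    r[i] <- 1 + below + ties / 2
  }
  r
}

oracle_spearman <- function(x, y) {
  rx <- oracle_midranks(x); ry <- oracle_midranks(y)
  mx <- mean(rx); my <- mean(ry)
  num <- sum((rx - mx) * (ry - my))
  den <- sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
  num / den
}

# --- balanced split-plot sums of squares ------------------------------------

# Hand-rolled decomposition for a balanced design: one between factor
# (equal group sizes), one or two 2+-level within factors. Returns F and
# partial eta squared per effect, computed purely from cell/marginal means.
oracle_split_plot <- function(df, dv, subject, between, within) {
  y <- df[[dv]]
  A <- factor(df[[between]]); S <- factor(df[[subject]])
  W <- lapply(within, function(w) factor(df[[w]]))
  names(W) <- within
  a <- nlevels(A)
  n <- length(unique(S)) / a
  M <- mean(y)
  mean_by <- function(...) tapply(y, interaction(..., drop = TRUE), mean)

  m_i <- mean_by(A); m_il <- mean_by(S)
  grp_of_subj <- tapply(as.character(A), S, function(v) v[1])
  SS_A <- prod(vapply(W, nlevels, 1L)) * n * sum((m_i - M)^2)
  SS_S <- prod(vapply(W, nlevels, 1L)) *
    sum((m_il - m_i[grp_of_subj[names(m_il)]])^2)

  out <- list()
  out[[between]] <- c(ss = SS_A, df1 = a - 1, ss_err = SS_S, df2 = a * (n - 1))

  if (length(W) == 1L) {
    B <- W[[1]]; b <- nlevels(B)
    m_j <- mean_by(B); m_ij <- mean_by(A, B)
    SS_B <- a * n * sum((m_j - M)^2)
    SS_AB <- n * sum((m_ij - m_i[sub("\\..*", "", names(m_ij))] -
                        m_j[sub(".*\\.", "", names(m_ij))] + M)^2)
    SS_tot <- sum((y - M)^2)
    SS_BS <- SS_tot - SS_A - SS_S - SS_B - SS_AB
    df_bs <- (b - 1) * a * (n - 1)
    out[[names(W)[1]]] <- c(ss = SS_B, df1 = b - 1, ss_err = SS_BS, df2 = df_bs)
    out[[paste0(between, ":", names(W)[1])]] <-
      c(ss = SS_AB, df1 = (a - 1) * (b - 1), ss_err = SS_BS, df2 = df_bs)
  } else {
    B <- W[[1]]; C <- W[[2]]; b <- nlevels(B); cc <- nlevels(C)
    key_a <- function(nm) sub("\\..*", "", nm)
    key_b <- function(nm) sub("^[^.]*\\.([^.]*).*", "\\1", nm)
    m_j <- mean_by(B); m_k <- mean_by(C)
    m_ij <- mean_by(A, B); m_ik <- mean_by(A, C); m_jk <- mean_by(B, C)
    m_ijk <- mean_by(A, B, C)
    m_ilj <- mean_by(S, B); m_ilk <- mean_by(S, C)

    SS_B <- a * n * cc * sum((m_j - M)^2)
    SS_AB <- n * cc * sum((m_ij - m_i[key_a(names(m_ij))] -
                             m_j[key_b(names(m_ij))] + M)^2)
    subj_of <- key_a(names(m_ilj))
    SS_BS <- cc * sum((m_ilj - m_il[subj_of] -
                         m_ij[paste(grp_of_subj[subj_of], key_b(names(m_ilj)), sep = ".")] +
                         m_i[grp_of_subj[subj_of]])^2)

    SS_C <- a * n * b * sum((m_k - M)^2)
    SS_AC <- n * b * sum((m_ik - m_i[key_a(names(m_ik))] -
                            m_k[key_b(names(m_ik))] + M)^2)
    subj_of_k <- key_a(names(m_ilk))
    SS_CS <- b * sum((m_ilk - m_il[subj_of_k] -
                        m_ik[paste(grp_of_subj[subj_of_k], key_b(names(m_ilk)), sep = ".")] +
                        m_i[grp_of_subj[subj_of_k]])^2)

    SS_BC <- a * n * sum((m_jk - m_j[key_a(names(m_jk))] -
                            m_k[key_b(names(m_jk))] + M)^2)
    nm3 <- names(m_ijk)
    p1 <- sub("\\..*", "", nm3)
    p2 <- sub("^[^.]*\\.([^.]*)\\..*", "\\1", nm3)
    p3 <- sub(".*\\.", "", nm3)
    SS_ABC <- n * sum((m_ijk - m_ij[paste(p1, p2, sep = ".")] -
                         m_ik[paste(p1, p3, sep = ".")] -
                         m_jk[paste(p2, p3, sep = ".")] +
                         m_i[p1] + m_j[p2] + m_k[p3] - M)^2)
    SS_tot <- sum((y - M)^2)
    SS_BCS <- SS_tot - SS_A - SS_S - SS_B - SS_AB - SS_BS -
      SS_C - SS_AC - SS_CS - SS_BC - SS_ABC
    df_bs <- (b - 1) * a * (n - 1)
    df_cs <- (cc - 1) * a * (n - 1)
    df_bcs <- (b - 1) * (cc - 1) * a * (n - 1)

    out[[names(W)[1]]] <- c(ss = SS_B, df1 = b - 1, ss_err = SS_BS, df2 = df_bs)
    out[[paste0(between, ":", names(W)[1])]] <-
      c(ss = SS_AB, df1 = (a - 1) * (b - 1), ss_err = SS_BS, df2 = df_bs)
    out[[names(W)[2]]] <- c(ss = SS_C, df1 = cc - 1, ss_err = SS_CS, df2 = df_cs)
    out[[paste0(between, ":", names(W)[2])]] <-
      c(ss = SS_AC, df1 = (a - 1) * (cc - 1), ss_err = SS_CS, df2 = df_cs)
    out[[paste0(names(W)[1], ":", names(W)[2])]] <-
      c(ss = SS_BC, df1 = (b - 1) * (cc - 1), ss_err = SS_BCS, df2 = df_bcs)
    out[[paste0(between, ":", names(W)[1], ":", names(W)[2])]] <-
      c(ss = SS_ABC, df1 = (a - 1) * (b - 1) * (cc - 1), ss_err = SS_BCS, df2 = df_bcs)
  }
  tab <- do.call(rbind, out)
  data.frame(effect = rownames(tab),
             F = (tab[, "ss"] / tab[, "df1"]) / (tab[, "ss_err"] / tab[, "df2"]),
             df_num = tab[, "df1"], df_den = tab[, "df2"],
             pes = tab[, "ss"] / (tab[, "ss"] + tab[, "ss_err"]),
             row.names = NULL)
}

# --- IRLS logistic regression ----------------------------------------------

oracle_irls_logistic <- function(X, y, tol = 1e-12, max_iter = 200) {
  X <- cbind(1, as.matrix(X))
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(X, w * X), crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  drop(beta)
}

# --- small fixture builders -------------------------------------------------

make_trials <- function(choice, reward, block = 1L, missing = NULL) {
  n <- length(choice)
  if (is.null(missing)) missing <- rep(FALSE, n)
  tibble::tibble(
    participant_id = "P", visit = "A",
    condition = "emotional",
    block = rep_len(block, n),
    trial = stats::ave(seq_len(n), rep_len(block, n), FUN = seq_along),
    choice = as.integer(choice), reward = as.integer(reward),
    missing = missing)
}

random_trials <- function(n_blocks = 2, tpb = 20, miss_rate = 0, seed = 1) {
  withr::with_seed(seed, {
    dplyr::bind_rows(lapply(seq_len(n_blocks), function(b) {
      miss <- runif(tpb) < miss_rate
      ch <- ifelse(miss, NA_integer_, sample(1:2, tpb, replace = TRUE))
      rw <- ifelse(miss, NA_integer_, rbinom(tpb, 1, 0.55))
      make_trials(ch, rw, block = rep(b, tpb), missing = miss)
    }))
  })
}
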