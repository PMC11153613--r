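#' @importFrom stats aov coef cor.test filter glm lm logLik na.omit pchisq
#'   plogis pnorm pt qt rbinom rnorm runif sd t.test optim binomial predict
#'   chisq.test complete.cases
#' @importFrom rlang .data abort warn
#' @importFrom utils head
NULL

# Deterministic seed fan-out: every stage (and every participant x visit
# stream) gets its own 31-bit seed derived from the run seed by a fixed
# affine map modulo the Mersenne prime 2^31 - 1.  Multipliers are small
# enough that all products stay exact in double precision.
.SEED_MOD <- 2147483647

derive_seed <- function(seed, ...) {
  offs <- c(...)
  s <- as.numeric(seed) %% .SEED_MOD
  for (k in seq_along(offs)) {
    s <- (48271 * s + 7919 * as.numeric(offs[k]) + k) %% .SEED_MOD
  }
  as.integer(s)
}

stage_offset <- function(stage) {
  i <- match(stage, c("cohort", "schedule", "choices", "trials",
                      "params", "mrs", "fit", "report"))
  if (is.na(i)) abort(paste0("unknown pipeline stage: ", stage))
  i * 101L
}

stage_seed <- function(seed, stage) derive_seed(seed, stage_offset(stage))

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         closed_lower = TRUE, closed_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(paste0("`", name, "` must be a single non-missing number"))
  }
  lo_ok <- if (closed_lower) x >= lower else x > lower
  hi_ok <- if (closed_upper) x <= upper else x < upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf("`%s` = %g is outside its allowed range [%g, %g]",
                  name, x, lower, upper))
  }
  invisible(x)
}

check_columns <- function(df, cols, name = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(paste0("`", name, "` is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  invisible(df)
}
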