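# Shared fixtures, all generated in code.

# Slopes and common SE printed for the no-transformation analysis of the
# Edmonton-style worked example (lags 0..9); lag 9 is the negative one.
WORKED_BETAS_A <- c(0.00183, 0.00115, 0.00104, 0.00184, 0.00195,
                    0.00131, 0.00151, 0.00171, 0.00144, -0.00004)
WORKED_SE_A <- 0.00039

# Flexible-transformation worked example, lag 0.
WORKED_1C <- list(beta = 0.0467, se = 0.0070, A = 15.2, mu = 14.0, tau = 0.005)

# Pooled flexible-curve parameter sets (central / lower / upper).
WORKED_2C <- list(
  central = c(theta = 0.0816, A = 50.99, mu = 13.07, tau = 0.0274),
  lower   = c(theta = 0.0420, A = 39.60, mu = 13.01, tau = 0.0267),
  upper   = c(theta = 0.1240, A = 57.86, mu = 13.10, tau = 0.0277))

# Representative 8-h max ozone range (ppb) for desk-scale curve evaluation;
# the logistic weight is ~1 at 30 ppb for any plausible range.
REF_RANGE <- 50

# Small random case-crossover instance for oracle comparisons:
# up to `max_strata` strata of up to 5 rows, 2 covariates, Poisson counts
# with stratum intercepts.
random_cc_instance <- function(seed, max_strata = 10) {
  set.seed(seed)
  ns <- sample(3:max_strata, 1)
  sizes <- sample(3:5, ns, replace = TRUE)
  st <- rep(seq_len(ns), sizes)
  n <- length(st)
  X <- cbind(x1 = stats::rnorm(n), x2 = stats::rnorm(n))
  eta <- 0.4 * X[, 1] - 0.25 * X[, 2] + rep(stats::rnorm(ns, 1.5, 0.5), sizes)
  y <- stats::rpois(n, exp(eta))
  # ensure every stratum is informative for the conditional likelihood
  for (s in seq_len(ns)) if (sum(y[st == s]) == 0) y[which(st == s)[1]] <- 1
  list(y = y, X = X, strata = st)
}

# Small simulated series + lag-0 design, cached per test file run.
small_series <- function(seed = 99, n_days = 731, ...) {
  simulate_daily_series(edmonton_like_config(n_days = n_days, ...), seed = seed)
}
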