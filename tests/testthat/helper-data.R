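# Small fixtures built in code.

# Right-censored dataset with a single strong positive effect on column 1.
make_signal_data <- function(n = 100, p = 10, beta1 = 3, seed = 1,
                             rate = 0.05) {
  with_seed <- survscreen:::with_seed
  with_seed(seed, {
    X <- matrix(stats::rnorm(n * p), n, p)
    tt <- stats::rexp(n, rate * exp(beta1 * X[, 1]))
    cc <- stats::rexp(n, rate)
    survival_dataset(pmin(tt, cc), as.numeric(tt <= cc), X)
  })
}

# Pure-noise dataset: outcome independent of all covariates.
make_noise_data <- function(n = 100, p = 10, seed = 1, rate = 0.05) {
  make_signal_data(n, p, beta1 = 0, seed = seed, rate = rate)
}

# Tiny deterministic dataset for hand computations.
make_tiny <- function(times, events, x = NULL) {
  n <- length(times)
  X <- if (is.null(x)) matrix(seq_len(n), n, 1) else matrix(x, nrow = n)
  survival_dataset(times, events, X)
}

# Brute-force Harrell's C over all ordered pairs (independent oracle).
brute_force_c <- function(risk, times, events) {
  num <- 0; den <- 0
  n <- length(risk)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    usable <- (times[i] < times[j] && events[i] == 1) ||
      (times[i] == times[j] && i < j && events[i] + events[j] == 1)
    if (!usable) next
    ri <- if (times[i] == times[j] && events[j] == 1) risk[j] else risk[i]
    rj <- if (times[i] == times[j] && events[j] == 1) risk[i] else risk[j]
    den <- den + 1
    num <- num + if (ri > rj) 1 else if (ri == rj) 0.5 else 0
  }
  num / den
}
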