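#' Define a simulation scenario
#'
#' A scenario fixes the data-generating mechanism for one simulated study
#' arm: covariate distribution (standard normal, optionally block-correlated
#' or partly Bernoulli), the true main-effect and interaction coefficients
#' on the log-hazard scale, and the exponential baseline rate used for both
#' event and censoring times.
#'
#' @param name Scenario label.
#' @param n Sample size (default 150).
#' @param p Number of covariates (default 1000).
#' @param main_effects Named by position: a list of `(index, size)` pairs,
#'   given as a 2-column matrix or a list; sizes are log-hazard-ratio
#'   coefficients.
#' @param interactions A list of `((a, b), size)` entries, given as a
#'   3-column matrix `(a, b, size)`.
#' @param corr Within-block correlation (0 = independent covariates).
#' @param block_size Size of the correlated blocks (default 5).
#' @param binary_vars Indices of Bernoulli(1/2) covariates coded {0, 1}.
#' @param base_rate Baseline hazard of the exponential event and censoring
#'   times (default 1/20).
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(name, n = 150L, p = 1000L,
                          main_effects = cbind(index = integer(0),
                                               size = numeric(0)),
                          interactions = cbind(a = integer(0),
                                               b = integer(0),
                                               size = numeric(0)),
                          corr = 0, block_size = 5L,
                          binary_vars = integer(0), base_rate = 1 / 20) {
  main_effects <- matrix(as.numeric(main_effects), ncol = 2,
                         dimnames = list(NULL, c("index", "size")))
  interactions <- matrix(as.numeric(interactions), ncol = 3,
                         dimnames = list(NULL, c("a", "b", "size")))
  stopifnot(n >= 2, p >= 1, corr >= 0, corr < 1, base_rate > 0)
  idx <- c(main_effects[, "index"], interactions[, c("a", "b")])
  if (length(idx) && max(idx) > p)
    stop(ss_error("effect index exceeds p", "ss_invalid_scenario"))
  structure(list(name = name, n = as.integer(n), p = as.integer(p),
                 main_effects = main_effects, interactions = interactions,
                 corr = corr, block_size = as.integer(block_size),
                 binary_vars = as.integer(binary_vars),
                 base_rate = base_rate),
            class = "scenario_spec")
}

#' Built-in simulation scenarios
#'
#' The twelve study scenarios: `Sim42` has four main effects (3, 3, -3, -3)
#' and two interactions (5, -5) composed of those main-effect variables;
#' the `Sim22_x` family has two main effects (0.9, -0.9) and two
#' interactions (x, -x) built from four *different* variables that carry no
#' main effect; `Sim22_bin` makes those four interaction variables binary;
#' and `Sim22_corr01..07` draw all covariates in 5-variable blocks with
#' within-block correlation 0.1..0.7. In the correlated scenarios the two
#' main effects share one block -- so their opposite-signed effects cancel
#' marginally as the correlation grows -- and each interaction pair sits
#' inside its own block, disjoint from the main-effect block. Throughout,
#' n = 150, p = 1000, and event and censoring times are exponential with
#' baseline hazard 1/20.
#'
#' @return A named list of `scenario_spec` objects.
#' @export
builtin_scenarios <- function() {
  sim42 <- scenario_spec("Sim42",
    main_effects = cbind(index = 1:4, size = c(3, 3, -3, -3)),
    interactions = cbind(a = c(1, 3), b = c(2, 4), size = c(5, -5)))
  sim22 <- function(name, e, binary = FALSE, corr = 0) {
    if (corr > 0) {
      # the two main effects share block 1 (their +/-0.9 effects cancel
      # marginally as the within-block correlation grows); each
      # interaction pair sits inside its own block, away from the mains
      me_idx <- c(1L, 2L); int_idx <- c(6L, 7L, 11L, 12L)
    } else {
      me_idx <- c(1L, 2L); int_idx <- c(3L, 4L, 5L, 6L)
    }
    scenario_spec(name,
      main_effects = cbind(index = me_idx, size = c(0.9, -0.9)),
      interactions = cbind(a = int_idx[c(1, 3)], b = int_idx[c(2, 4)],
                           size = c(e, -e)),
      corr = corr, block_size = 5L,
      binary_vars = if (binary) int_idx else integer(0))
  }
  specs <- list(
    sim42,
    sim22("Sim22_1.0", 1.0),
    sim22("Sim22_0.5", 0.5),
    sim22("Sim22_0.25", 0.25),
    sim22("Sim22_1.5", 1.5),
    sim22("Sim22_2.0", 2.0),
    sim22("Sim22_2.5", 2.5),
    sim22("Sim22_bin", 1.0, binary = TRUE),
    sim22("Sim22_corr01", 1.0, corr = 0.1),
    sim22("Sim22_corr03", 1.0, corr = 0.3),
    sim22("Sim22_corr05", 1.0, corr = 0.5),
    sim22("Sim22_corr07", 1.0, corr = 0.7)
  )
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

#' Generate one dataset from a scenario
#'
#' Covariates are standard normal, drawn blockwise from a multivariate
#' normal with unit variances and constant off-diagonal correlation when
#' `corr > 0`, or Bernoulli(1/2) for the indices in `binary_vars`. The
#' linear predictor is \eqn{\eta_i = \sum_m \beta_m x_{im} +
#' \sum_{(a,b)} \gamma_{ab} x_{ia} x_{ib}}; event times are
#' Exponential(rate \eqn{\lambda e^{\eta_i}}), censoring times
#' Exponential(rate \eqn{\lambda}) independent of everything, and the
#' observed pair is \eqn{(\min(T_i, C_i), I(T_i \le C_i))}. With equal
#' rates at \eqn{\eta = 0} this yields roughly 50% censoring.
#'
#' @param spec A `scenario_spec`.
#' @param seed Integer seed; generation is bit-reproducible per seed.
#' @return A list of class `simulated_dataset` with `data` (a
#'   `survival_dataset`), `truth` (list: `main_idx`, `main_size`, `pairs`,
#'   `pair_size`), `eta` and the `spec`.
#' @export
generate_dataset <- function(spec, seed = 1L) {
  n <- spec$n; p <- spec$p
  with_seed(seed, {
    if (spec$corr > 0) {
      bs <- spec$block_size
      nb <- ceiling(p / bs)
      Sigma <- matrix(spec$corr, bs, bs); diag(Sigma) <- 1
      L <- chol(Sigma)
      X <- matrix(NA_real_, n, nb * bs)
      for (b in seq_len(nb)) {
        Z <- matrix(stats::rnorm(n * bs), n, bs)
        X[, ((b - 1) * bs + 1):(b * bs)] <- Z %*% L
      }
      X <- X[, seq_len(p), drop = FALSE]
    } else {
      X <- matrix(stats::rnorm(n * p), n, p)
    }
    for (j in spec$binary_vars) X[, j] <- stats::rbinom(n, 1, 0.5)
    eta <- numeric(n)
    me <- spec$main_effects
    for (r in seq_len(nrow(me)))
      eta <- eta + me[r, "size"] * X[, me[r, "index"]]
    it <- spec$interactions
    for (r in seq_len(nrow(it)))
      eta <- eta + it[r, "size"] * X[, it[r, "a"]] * X[, it[r, "b"]]
    T_ev <- stats::rexp(n, rate = spec$base_rate * exp(eta))
    C_cen <- stats::rexp(n, rate = spec$base_rate)
    times <- pmin(T_ev, C_cen)
    events <- as.numeric(T_ev <= C_cen)
    colnames(X) <- paste0("V", seq_len(p))
    structure(list(
      data = survival_dataset(times, events, X),
      truth = list(main_idx = as.integer(me[, "index"]),
                   main_size = me[, "size"],
                   pairs = as_pairs(it[, "a"], it[, "b"]),
                   pair_size = it[, "size"]),
      eta = eta, spec = spec, seed = as.integer(seed)),
      class = "simulated_dataset")
  })
}

# Unordered pair membership: rows of `pairs` found in rows of `pool`.
pair_in <- function(pairs, pool) {
  if (nrow(pairs) == 0) return(logical(0))
  if (nrow(pool) == 0) return(rep(FALSE, nrow(pairs)))
  key <- function(m) paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  key(pairs) %in% key(pool)
}

#' Score strategy results against simulation ground truth
#'
#' Aggregates, over replicate datasets, the selection and prediction
#' metrics of the screening pipeline: mean pre-selected pair count
#' (IntScreen), availability of the true interactions after screening
#' (IntSensiA), mean nonzero terms in the final model (VarsTotal),
#' sensitivity for true main effects (MainSensi) and true interactions
#' (IntSensi) in the final model, and mean rIPEC of the first-pass and
#' final models. Dispersion is the standard error of the mean across
#' replicates (the parenthesized values of the study tables).
#'
#' @param results A list of `strategy_result` objects.
#' @param truths A list (same length) of ground-truth lists as stored in
#'   `simulated_dataset$truth`.
#' @return A list of class `metrics_row`: each metric with mean and `se_`
#'   dispersion, plus the replicate count.
#' @export
score_replicates <- function(results, truths) {
  if (length(results) == 0)
    stop(ss_error("no results to score", "ss_empty_results"))
  stopifnot(length(results) == length(truths))
  per <- lapply(seq_along(results), function(i) {
    r <- results[[i]]; tr <- truths[[i]]
    n_main <- length(tr$main_idx)
    n_int <- nrow(tr$pairs)
    c(IntScreen = r$int_screen,
      IntSensiA = if (n_int) mean(pair_in(tr$pairs, r$preselected)) else NA,
      VarsTotal = length(r$final_main) + nrow(r$final_pairs),
      MainSensi = if (n_main) mean(tr$main_idx %in% r$final_main) else NA,
      IntSensi = if (n_int) mean(pair_in(tr$pairs, r$final_pairs)) else NA,
      rIPEC_main = r$ripec_main,
      rIPEC_final = r$ripec_final)
  })
  mat <- do.call(rbind, per)
  out <- as.list(colMeans(mat, na.rm = TRUE))
  disp <- apply(mat, 2, stats::sd, na.rm = TRUE) / sqrt(nrow(mat))
  names(disp) <- paste0("se_", colnames(mat))
  structure(c(out, as.list(disp), list(replicates = length(results))),
            class = "metrics_row")
}

#' @export
print.metrics_row <- function(x, ...) {
  cat(sprintf(
    "metrics over %d replicates:\n  IntScreen %.2f | IntSensiA %.2f | VarsTotal %.2f | MainSensi %.3f (%.2f) | IntSensi %.3f (%.2f)\n  rIPEC main %.3f final %.3f\n",
    x$replicates, x$IntScreen, x$IntSensiA, x$VarsTotal,
    x$MainSensi, x$se_MainSensi, x$IntSensi, x$se_IntSensi,
    x$rIPEC_main, x$rIPEC_final))
  invisible(x)
}
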