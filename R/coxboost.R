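#' Configuration for componentwise likelihood-based Cox boosting
#'
#' @param nu Relative step size in (0,1]; enters through the default penalty.
#' @param penalty Ridge penalty rho applied to each candidate update. If
#'   `NULL` it is derived at fit time as `sum(events) * (1/nu - 1)`.
#' @param max_steps Cap on the number of boosting steps searched by
#'   cross-validation (default 100, the customary cap for this boosting
#'   family).
#' @param cv_folds Number of cross-validation folds.
#' @param unpenalized Integer indices of mandatory covariates updated without
#'   penalty at the start of every boosting step.
#' @return A list of class `boost_config`.
#' @export
boost_config <- function(nu = 0.05, penalty = NULL, max_steps = 100L,
                         cv_folds = 10L, unpenalized = integer(0)) {
  stopifnot(nu > 0, nu <= 1, max_steps >= 0, cv_folds >= 2)
  if (!is.null(penalty)) stopifnot(penalty >= 0)
  structure(list(nu = nu, penalty = penalty,
                 max_steps = as.integer(max_steps),
                 cv_folds = as.integer(cv_folds),
                 unpenalized = sort(unique(as.integer(unpenalized)))),
            class = "boost_config")
}

# Risk-set bookkeeping shared by PLL / score / boosting. The risk set of
# subject i is {j : t_j >= t_i} (Breslow convention for ties). With times
# sorted in decreasing order, sums over risk sets are cumulative sums; k_map
# sends each subject to its cumulative-sum position.
riskset_index <- function(times) {
  ord <- order(times, decreasing = TRUE)
  k_map <- length(times) - rank(times, ties.method = "min") + 1L
  list(ord = ord, k = k_map)
}

#' Cox partial log-likelihood
#'
#' Evaluates the Breslow partial log-likelihood
#' \deqn{\mathrm{PLL}(\beta) = \sum_i \delta_i \{ x_i'\beta -
#'   \log \sum_j I(t_i \le t_j) \exp(x_j'\beta) \}.}
#' Risk-set sums are computed on the log scale (log-sum-exp), so finite
#' inputs never produce overflow.
#'
#' @param beta Coefficient vector of length p.
#' @param data A `survival_dataset`; the covariates are used as stored (no
#'   internal standardization).
#' @return The partial log-likelihood, a single number.
#' @export
partial_log_likelihood <- function(beta, data) {
  eta <- drop(data$covariates %*% beta)
  pll_from_eta(eta, data$times, data$events)
}

pll_from_eta <- function(eta, times, events) {
  rs <- riskset_index(times)
  shift <- max(eta)
  w <- exp(eta - shift)
  logS0 <- log(cumsum(w[rs$ord]))[rs$k] + shift
  sum(events * (eta - logS0))
}

# First and second derivatives of the PLL in direction j at theta_j = 0,
# holding the remaining coordinates at the linear predictor eta. Returns all
# p columns at once (compiled kernel; risk sets via cumulative sums over
# rows sorted by decreasing time, Breslow ties).
score_info_all <- function(X, times, events, eta, rs = NULL) {
  if (is.null(rs)) rs <- riskset_index(times)
  w <- exp(eta - max(eta))
  score_info_cpp(X, rs$ord, rs$k, w, which(events == 1))
}

#' Score and Fisher information for one covariate direction
#'
#' Computes \eqn{U_j = \partial \mathrm{PLL}/\partial\theta_j} and
#' \eqn{I_j = -\partial^2 \mathrm{PLL}/\partial\theta_j^2}, both evaluated at
#' \eqn{\theta_j = 0} with all other coefficients held at `beta`. These are
#' the ingredients of the penalized score statistic \eqn{U_j^2/(I_j+\rho)}
#' used to pick the covariate updated in a boosting step.
#'
#' @param j Covariate index.
#' @param beta Current coefficient vector.
#' @param data A `survival_dataset`.
#' @return A list with elements `U` and `I` (scalars, `I >= 0`).
#' @export
score_and_information <- function(j, beta, data) {
  eta <- drop(data$covariates %*% beta)
  si <- score_info_all(data$covariates[, j, drop = FALSE],
                       data$times, data$events, eta)
  list(U = unname(si$U), I = unname(si$I))
}

# Core boosting loop on an already-standardized covariate matrix.
# Returns beta path bookkeeping; optionally evaluates a per-step criterion
# callback (used by cross-validation).
cb_engine <- function(X, times, events, steps, rho, unpen = integer(0),
                      step_hook = NULL) {
  n <- nrow(X); p <- ncol(X)
  beta <- numeric(p)
  eta <- numeric(n)
  trace <- integer(0)
  rs <- riskset_index(times)
  pen_idx <- setdiff(seq_len(p), unpen)
  if (steps > 0 && sum(events) < 1)
    stop(ss_error("boosting requires at least one event", "ss_no_events"))
  if (!is.null(step_hook)) step_hook(0L, beta)
  if (steps == 0L)
    return(list(beta = beta, trace = trace))
  for (k in seq_len(steps)) {
    # mandatory covariates: one unpenalized componentwise update cycle first
    for (m in unpen) {
      si <- score_info_all(X[, m, drop = FALSE], times, events, eta, rs)
      if (si$I > 1e-12) {
        th <- si$U / si$I
        beta[m] <- beta[m] + th
        eta <- eta + th * X[, m]
      }
    }
    if (length(pen_idx)) {
      si <- score_info_all(X[, pen_idx, drop = FALSE], times, events, eta, rs)
      den <- si$I + rho
      stat <- ifelse(den > 0, si$U^2 / den, 0)
      if (!all(is.finite(stat)))
        stop(ss_error(sprintf("non-finite score statistic at step %d", k),
                      "ss_nonfinite_score"))
      jstar <- pen_idx[which.max(stat)]
      jloc <- match(jstar, pen_idx)
      th <- if (den[jloc] > 0) si$U[jloc] / den[jloc] else 0
      beta[jstar] <- beta[jstar] + th
      eta <- eta + th * X[, jstar]
      trace <- c(trace, jstar)
    }
    if (!is.null(step_hook)) step_hook(k, beta)
  }
  list(beta = beta, trace = trace)
}

#' Fit a Cox model by componentwise likelihood-based boosting
#'
#' Starting from \eqn{\beta^{(0)} = 0}, each boosting step evaluates the
#' penalized score statistic \eqn{U_j^2/(I_j+\rho)} for every penalized
#' covariate, updates the maximizing covariate by
#' \eqn{\hat\theta_{j^*} = U_{j^*}/(I_{j^*}+\rho)}, and leaves all others
#' unchanged. Mandatory covariates (`config$unpenalized`) receive an
#' unpenalized componentwise update at the start of every step. Covariates
#' are standardized internally so that score statistics are comparable
#' across columns; the scaling is stored with the model and reapplied at
#' prediction time.
#'
#' @param data A `survival_dataset`.
#' @param config A [boost_config()].
#' @param steps Number of boosting steps; use [cv_select_steps()] to choose.
#' @return An object of class `coxboost_model`: `beta` (standardized scale),
#'   `steps`, `trace` of updated indices, `penalty`, `scaling`, `baseline`
#'   (Breslow cumulative baseline hazard) and covariate `names`.
#' @export
fit_coxboost <- function(data, config = boost_config(), steps) {
  steps <- as.integer(steps)
  stopifnot(steps >= 0)
  std <- standardize(data)
  rho <- if (is.null(config$penalty))
    sum(data$events) * (1 / config$nu - 1) else config$penalty
  unpen <- sort(unique(c(config$unpenalized, data$mandatory)))
  fit <- cb_engine(std$data$covariates, data$times, data$events,
                   steps, rho, unpen)
  model <- structure(list(beta = fit$beta, steps = steps, trace = fit$trace,
                          penalty = rho, nu = config$nu,
                          unpenalized = unpen,
                          scaling = std$params, names = data$names,
                          baseline = NULL),
                     class = "coxboost_model")
  model$baseline <- breslow_baseline(model, data)
  model
}

#' @export
print.coxboost_model <- function(x, ...) {
  nz <- which(x$beta != 0)
  cat(sprintf("coxboost_model: %d boosting steps, %d nonzero coefficients\n",
              x$steps, length(nz)))
  if (length(nz)) {
    show <- utils::head(order(abs(x$beta), decreasing = TRUE), 10)
    show <- show[x$beta[show] != 0]
    cat("  largest effects (standardized scale):\n")
    for (j in show)
      cat(sprintf("    %s: %+0.4f\n", x$names[j], x$beta[j]))
  }
  invisible(x)
}

#' Nonzero coefficients of a boosted Cox model
#'
#' @param model A `coxboost_model`.
#' @param exclude Indices to leave out (e.g. mandatory covariates when
#'   collecting the detected main effects).
#' @return Integer vector of covariate indices with nonzero coefficients.
#' @export
selected_covariates <- function(model, exclude = integer(0)) {
  setdiff(which(model$beta != 0), exclude)
}

#' Select the number of boosting steps by cross-validation
#'
#' Folds are stratified by event status. For each fold the model is fit on
#' the remaining data for `0..max_steps` steps; the out-of-fold criterion at
#' step k is the full-data partial log-likelihood at the fold's coefficients
#' minus the training-fold partial log-likelihood (the Verweij-van
#' Houwelingen decomposition). The step count maximizing the mean criterion
#' across folds is returned.
#'
#' @param data A `survival_dataset`.
#' @param config A [boost_config()]; `max_steps` and `cv_folds` are used.
#' @param seed Integer seed for the fold assignment.
#' @return Selected number of steps (0..max_steps).
#' @export
cv_select_steps <- function(data, config = boost_config(), seed = 1L) {
  if (config$max_steps == 0L) return(0L)
  n <- length(data$times)
  folds <- stratified_folds(data$events, config$cv_folds, seed)
  rho <- if (is.null(config$penalty))
    sum(data$events) * (1 / config$nu - 1) else config$penalty
  unpen <- sort(unique(c(config$unpenalized, data$mandatory)))
  crit <- matrix(NA_real_, config$cv_folds, config$max_steps + 1L)
  for (f in seq_len(config$cv_folds)) {
    tr <- which(folds != f)
    dtr <- subset_rows(data, tr)
    std <- standardize(dtr)
    Xtr <- std$data$covariates
    Xall <- apply_standardization(data$covariates, std$params)
    hook <- local({
      f0 <- f
      function(k, beta) {
        full <- pll_from_eta(drop(Xall %*% beta), data$times, data$events)
        train <- pll_from_eta(drop(Xtr %*% beta), dtr$times, dtr$events)
        crit[f0, k + 1L] <<- full - train
      }
    })
    cb_engine(Xtr, dtr$times, dtr$events, config$max_steps, rho, unpen,
              step_hook = hook)
  }
  m <- colMeans(crit)
  as.integer(which.max(m) - 1L)
}

# Event-stratified fold assignment; refolds (incrementing the seed) until
# every fold used for training retains at least one event.
stratified_folds <- function(events, k, seed, max_redraws = 100L) {
  n <- length(events)
  for (attempt in 0:max_redraws) {
    folds <- integer(n)
    with_seed(derive_seed(seed, attempt), {
      for (g in c(0, 1)) {
        idx <- which(events == g)
        folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
    })
    ok <- all(vapply(seq_len(k),
                     function(f) sum(events[folds != f]) >= 1, logical(1)))
    if (ok) return(folds)
  }
  stop(ss_error("could not build folds with events in every training part",
                "ss_no_event_subsample"))
}

#' Breslow estimate of the cumulative baseline hazard
#'
#' \deqn{\hat H_0(t) = \sum_{s \le t} d_s / \sum_{j: t_j \ge s}
#'   \exp(x_j'\hat\beta)} over the distinct event times s. With
#' \eqn{\beta = 0} this reduces to the Nelson-Aalen estimator.
#'
#' @param model A `coxboost_model` fit on `data`.
#' @param data The `survival_dataset` the model was fit on.
#' @return A list of class `baseline_hazard` with `times` (increasing event
#'   times) and `cumhaz` (nondecreasing).
#' @export
breslow_baseline <- function(model, data) {
  Xs <- apply_standardization(data$covariates, model$scaling)
  eta <- drop(Xs %*% model$beta)
  w <- exp(eta - max(eta))
  ev_times <- sort(unique(data$times[data$events == 1]))
  d <- vapply(ev_times,
              function(s) sum(data$events == 1 & data$times == s), numeric(1))
  denom <- vapply(ev_times, function(s) sum(w[data$times >= s]), numeric(1))
  inc <- d / (denom * exp(max(eta)))
  structure(list(times = ev_times, cumhaz = cumsum(inc)),
            class = "baseline_hazard")
}

# Step-function evaluation of the cumulative baseline hazard (0 below the
# first event time, right-continuous).
baseline_at <- function(baseline, t) {
  if (length(baseline$times) == 0) return(rep(0, length(t)))
  idx <- findInterval(t, baseline$times)
  c(0, baseline$cumhaz)[idx + 1L]
}

#' Predicted survival / event probability from a boosted Cox model
#'
#' Survival is \eqn{S(t|x) = \exp\{-\hat H_0(t) \exp(x'\hat\beta)\}}; the
#' companion event probability is \eqn{1 - S(t|x)}, the quantity entering
#' the Brier score. Covariates are given on their original scale; the
#' model's stored standardization is applied internally.
#'
#' @param model A `coxboost_model`.
#' @param x A p-vector or an n x p matrix of covariate values.
#' @param t Nonnegative evaluation time(s).
#' @return For a single time, a vector of probabilities (one per row of
#'   `x`); for multiple times, a matrix (rows = cases, cols = times).
#' @export
predict_survival <- function(model, x, t) {
  if (any(t < 0)) stop(ss_error("negative evaluation time", "ss_invalid_time"))
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  Xs <- apply_standardization(x, model$scaling)
  risk <- exp(drop(Xs %*% model$beta))
  H0 <- baseline_at(model$baseline, t)
  out <- exp(-outer(risk, H0))
  if (length(t) == 1L) drop(out) else out
}

#' @rdname predict_survival
#' @export
predict_event_prob <- function(model, x, t) {
  1 - predict_survival(model, x, t)
}
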