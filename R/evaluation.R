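#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function; the curve drops only at
#' event times. Computed through [survival::survfit()].
#'
#' @param times Observed times.
#' @param events 0/1 event indicators.
#' @return A list of class `survival_curve` with `times` (drop times) and
#'   `surv`; evaluate with [surv_at()]. `surv_at(curve, 0)` is 1.
#' @export
kaplan_meier <- function(times, events) {
  stopifnot(length(times) >= 1, length(times) == length(events))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  keep <- fit$n.event > 0
  structure(list(times = fit$time[keep], surv = fit$surv[keep]),
            class = "survival_curve")
}

#' Censoring survival curve (reverse Kaplan-Meier)
#'
#' Kaplan-Meier estimate of the censoring distribution
#' \eqn{\hat P(s) = P(C > s)}: the product-limit estimator with the event
#' indicator flipped, so censorings are the "events". Marginal
#' (covariate-free); used to form inverse-probability-of-censoring weights.
#'
#' @param times Observed times.
#' @param events 0/1 event indicators (of the original outcome).
#' @return A `survival_curve`.
#' @export
censoring_survival <- function(times, events) {
  kaplan_meier(times, 1 - events)
}

#' Evaluate a survival step function
#'
#' @param curve A `survival_curve` (right-continuous, 1 before the first
#'   drop).
#' @param t Evaluation time(s).
#' @param left If `TRUE`, return the left limit \eqn{S(t-)}.
#' @return Survival probabilities.
#' @export
surv_at <- function(curve, t, left = FALSE) {
  if (length(curve$times) == 0) return(rep(1, length(t)))
  idx <- findInterval(t, curve$times, left.open = left)
  c(1, curve$surv)[idx + 1L]
}

#' IPCW Brier score curve
#'
#' Expected squared deviation between predicted event probability and
#' observed event status, tracked over time and reweighted for right
#' censoring: at each grid time t,
#' \deqn{\widehat{Err}(t) = \frac1n \sum_i W_i(t)\,\{\delta_i(t) -
#'   \hat\pi(t, x_i)\}^2,}
#' with \eqn{\delta_i(t) = I(t_i \le t, \delta_i = 1)} and weights
#' \eqn{W_i(t) = I(t_i \le t)\delta_i / \hat P(t_i-) + I(t_i > t)/\hat P(t)}.
#' Cases censored before t get weight zero. Grid times where the censoring
#' survival reaches zero are dropped.
#'
#' @param event_prob Function `(t, X) ->` vector of predicted event
#'   probabilities \eqn{\hat\pi(t,x)} for the rows of X.
#' @param test A `survival_dataset` to evaluate on.
#' @param cens A `survival_curve` for the censoring distribution, estimated
#'   on the training part.
#' @param grid Evaluation times.
#' @return A list of class `prediction_error_curve` with `times` and `err`.
#' @export
brier_curve <- function(event_prob, test, cens, grid) {
  grid <- sort(grid)
  keep <- surv_at(cens, grid) > 0
  if (!all(keep)) {
    message(sprintf("dropping %d grid time(s) with zero censoring survival",
                    sum(!keep)))
    grid <- grid[keep]
  }
  n <- length(test$times)
  Pg <- surv_at(cens, grid)
  Pminus <- surv_at(cens, test$times, left = TRUE)
  err <- vapply(seq_along(grid), function(g) {
    t <- grid[g]
    d_t <- as.numeric(test$times <= t & test$events == 1)
    w <- ifelse(test$times > t, 1 / Pg[g],
                ifelse(test$events == 1, 1 / Pminus, 0))
    pi_hat <- event_prob(t, test$covariates)
    mean(w * (d_t - pi_hat)^2)
  }, numeric(1))
  structure(list(times = grid, err = err), class = "prediction_error_curve")
}

#' Integrated prediction error curve (IPEC)
#'
#' Trapezoidal integral of the Brier score curve over its grid.
#'
#' @param curve A `prediction_error_curve`.
#' @return The integrated error, a single number.
#' @export
ipec <- function(curve) {
  stopifnot(length(curve$times) >= 2)
  sum(diff(curve$times) * (utils::head(curve$err, -1) +
                             utils::tail(curve$err, -1)) / 2)
}

#' Relative integrated prediction error versus Kaplan-Meier
#'
#' \deqn{\mathrm{rIPEC} = (\mathrm{IPEC}_{KM} - \mathrm{IPEC}_{S}) /
#'   \mathrm{IPEC}_{KM}.} Positive values mean the model predicts better
#' than the covariate-free Kaplan-Meier; negative values are possible.
#'
#' @param ipec_model IPEC of the model under evaluation.
#' @param ipec_km IPEC of the Kaplan-Meier reference (must be > 0).
#' @return The relative improvement.
#' @export
ripec <- function(ipec_model, ipec_km) {
  if (ipec_km <= 0)
    stop(ss_error("Kaplan-Meier IPEC must be positive", "ss_zero_reference"))
  (ipec_km - ipec_model) / ipec_km
}

# Evaluation grid: distinct test-part event times up to the last time where
# the censoring survival stays above `floor` (weight stability).
evaluation_grid <- function(test, cens, floor = 0.05) {
  ev <- sort(unique(test$times[test$events == 1]))
  tau_ok <- surv_at(cens, ev) > floor
  g <- ev[tau_ok]
  if (length(g) < 2) g <- utils::head(ev, 2)
  g
}
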