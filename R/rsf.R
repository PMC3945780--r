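#' Configuration for a random survival forest
#'
#' @param ntree Number of trees (default 1000).
#' @param mtry Number of candidate covariates per split; defaults to
#'   `round(sqrt(p))` at fit time when `NULL`.
#' @param min_node_events Minimum number of distinct event times a node must
#'   contain to attempt a split (default 3).
#' @param resample_fraction Per-tree subsample fraction, drawn without
#'   replacement (default 0.632, the package-wide subsampling convention).
#' @param seed Integer seed for resampling and split-candidate draws.
#' @return A list of class `forest_config`.
#' @export
forest_config <- function(ntree = 1000L, mtry = NULL, min_node_events = 3L,
                          resample_fraction = 0.632, seed = 1L) {
  stopifnot(ntree >= 1, min_node_events >= 1,
            resample_fraction > 0, resample_fraction < 1)
  structure(list(ntree = as.integer(ntree), mtry = mtry,
                 min_node_events = as.integer(min_node_events),
                 resample_fraction = resample_fraction,
                 seed = as.integer(seed)),
            class = "forest_config")
}

#' Nelson-Aalen estimate of the cumulative hazard
#'
#' \eqn{\hat H(t) = \sum_{l: t_l \le t} d_l / Y_l} over the distinct event
#' times, with \eqn{d_l} deaths and \eqn{Y_l} cases at risk at \eqn{t_l}.
#' This is the estimator stored in every terminal node of a survival tree.
#'
#' @param times Observed times.
#' @param events 0/1 event indicators.
#' @return A list of class `hazard_curve` with `times` (distinct event
#'   times, increasing) and `cumhaz` (nondecreasing); evaluate it with
#'   [hazard_at()].
#' @export
nelson_aalen <- function(times, events) {
  stopifnot(length(times) >= 1, length(times) == length(events))
  ev <- sort(unique(times[events == 1]))
  d <- vapply(ev, function(s) sum(events == 1 & times == s), numeric(1))
  Y <- vapply(ev, function(s) sum(times >= s), numeric(1))
  structure(list(times = ev, cumhaz = cumsum(d / Y)), class = "hazard_curve")
}

#' Evaluate a cumulative hazard step function
#'
#' @param curve A `hazard_curve` (right-continuous, 0 before the first
#'   event time).
#' @param t Evaluation time(s).
#' @return Cumulative hazard values.
#' @export
hazard_at <- function(curve, t) {
  if (length(curve$times) == 0) return(rep(0, length(t)))
  c(0, curve$cumhaz)[findInterval(t, curve$times) + 1L]
}

#' Standardized two-sample log-rank split statistic
#'
#' For the daughter nodes `x_j <= c` versus `x_j > c`, returns
#' \eqn{|O - E| / \sqrt{V}} of the left daughter, where O, E and V are the
#' observed deaths, their expectation and hypergeometric variance summed
#' over the pooled distinct event times. Symmetric in the daughters; larger
#' values mean better separation of the survival experience.
#'
#' @param data A `survival_dataset` holding the node's cases.
#' @param j Covariate index to split on.
#' @param c Threshold; both daughters must be nonempty.
#' @return The absolute standardized log-rank statistic (NA if the variance
#'   vanishes, e.g. identical daughters at every event time).
#' @export
logrank_split_statistic <- function(data, j, c) {
  grp <- data$covariates[, j] <= c
  if (all(grp) || !any(grp))
    stop(ss_error("empty daughter node: split undefined", "ss_empty_daughter"))
  ev <- sort(unique(data$times[data$events == 1]))
  O <- 0; E <- 0; V <- 0
  for (s in ev) {
    atrisk <- data$times >= s
    Y <- sum(atrisk); Y1 <- sum(atrisk & grp)
    d <- sum(data$events == 1 & data$times == s)
    d1 <- sum(data$events == 1 & data$times == s & grp)
    O <- O + d1
    E <- E + d * Y1 / Y
    if (Y > 1) V <- V + d * (Y1 / Y) * (1 - Y1 / Y) * (Y - d) / (Y - 1)
  }
  if (V <= 1e-12) return(NA_real_)
  abs(O - E) / sqrt(V)
}

#' Grow a single survival tree
#'
#' Recursively splits the in-bag cases: at every node `mtry` candidate
#' covariates are drawn without replacement, all midpoints between adjacent
#' distinct in-node values are tried, and the split with the largest
#' log-rank statistic is taken. A node with fewer than `min_node_events`
#' distinct event times, or without any admissible split, becomes a
#' terminal node carrying the Nelson-Aalen cumulative hazard of its cases
#' evaluated on the forest's event-time grid. Trees are unpruned.
#'
#' @param data A `survival_dataset`.
#' @param in_bag Integer row indices the tree is grown on.
#' @param config A [forest_config()].
#' @param seed Integer seed; the tree is deterministic given
#'   (data, in_bag, seed).
#' @return A list of class `survival_tree` (flat node arrays `var`, `split`,
#'   `left`, `right`, terminal `chf` matrix, the `grid`, and `inbag`).
#' @export
grow_tree <- function(data, in_bag, config = forest_config(), seed = 1L) {
  if (sum(data$events[in_bag]) < 1)
    stop(ss_error("in-bag part contains no event", "ss_no_events"))
  p <- ncol(data$covariates)
  mtry <- if (is.null(config$mtry)) max(1L, round(sqrt(p))) else
    as.integer(config$mtry)
  stopifnot(mtry >= 1, mtry <= p)
  grid <- sort(unique(data$times[data$events == 1]))
  tr <- grow_tree_cpp(data$covariates, data$times, as.integer(data$events),
                      grid, as.integer(in_bag), mtry,
                      config$min_node_events, as.integer(seed))
  tr$grid <- grid
  class(tr) <- "survival_tree"
  tr
}

#' Fit a random survival forest
#'
#' Grows `ntree` unpruned log-rank trees, each on an independent subsample
#' of `resample_fraction * n` cases drawn without replacement (redrawn if it
#' contains no event). Terminal nodes store Nelson-Aalen cumulative hazards
#' on the grid of distinct training event times; per-tree in-bag sets are
#' recorded for out-of-bag error and importance estimation.
#'
#' @param data A `survival_dataset`.
#' @param config A [forest_config()].
#' @return An object of class `survival_forest`.
#' @export
fit_forest <- function(data, config = forest_config()) {
  p <- ncol(data$covariates)
  mtry <- if (is.null(config$mtry)) max(1L, round(sqrt(p))) else
    as.integer(config$mtry)
  stopifnot(mtry >= 1, mtry <= p)
  grid <- sort(unique(data$times[data$events == 1]))
  trees <- fit_forest_cpp(data$covariates, data$times,
                          as.integer(data$events), grid, config$ntree,
                          mtry, config$min_node_events,
                          config$resample_fraction, config$seed)
  structure(list(trees = trees, grid = grid, config = config,
                 n = length(data$times), p = p, names = data$names),
            class = "survival_forest")
}

#' @export
print.survival_forest <- function(x, ...) {
  cat(sprintf("survival_forest: %d trees, p = %d, %d grid times\n",
              length(x$trees), x$p, length(x$grid)))
  invisible(x)
}

#' Ensemble cumulative hazard and mortality
#'
#' The ensemble cumulative hazard of a case is the mean of the terminal-node
#' Nelson-Aalen estimates the case drops into, one per tree; its mortality
#' is that ensemble CHF summed over the forest's event-time grid. Higher
#' mortality means higher predicted risk. With `oob_only = TRUE`, `x` must
#' be the training covariate matrix and each case is averaged only over
#' trees where it was out of bag.
#'
#' @param forest A `survival_forest`.
#' @param x A p-vector or matrix of covariate values.
#' @param oob_only Average only over out-of-bag trees (training rows).
#' @return A numeric vector of mortalities, one per row of `x`.
#' @export
ensemble_mortality <- function(forest, x, oob_only = FALSE) {
  chf <- ensemble_chf(forest, x, oob_only)
  mort <- rowSums(chf)
  if (oob_only && anyNA(mort))
    stop(ss_error("case is in-bag in every tree: OOB prediction undefined",
                  "ss_no_oob"))
  mort
}

#' @rdname ensemble_mortality
#' @export
ensemble_chf <- function(forest, x, oob_only = FALSE) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  ensemble_chf_cpp(forest$trees, x, length(forest$grid), oob_only)
}

#' Harrell's concordance index
#'
#' Fraction of usable pairs (shorter time has an event, or tied times with
#' exactly one event) in which the case failing earlier has the higher risk
#' score; ties in the score count 1/2.
#'
#' @param risk_scores Predicted risk (higher = shorter expected survival).
#' @param times Observed times.
#' @param events 0/1 event indicators.
#' @return Concordance in `[0, 1]`.
#' @export
harrell_c <- function(risk_scores, times, events) {
  stopifnot(length(risk_scores) == length(times),
            length(times) == length(events))
  out <- harrell_c_cpp(as.numeric(risk_scores), as.numeric(times),
                       as.integer(events))
  if (is.na(out))
    stop(ss_error("no usable pair for the concordance index",
                  "ss_no_usable_pairs"))
  out
}

#' Permutation accuracy importance of one covariate
#'
#' Permutes the values of covariate `j` across all cases (seeded), recomputes
#' the out-of-bag ensemble mortality and returns the increase in prediction
#' error, where error is one minus Harrell's concordance of the out-of-bag
#' mortality. A covariate never split on in any tree leaves the predictions
#' unchanged, so its importance is exactly zero.
#'
#' @param forest A `survival_forest` fit on `data`.
#' @param data The training `survival_dataset`.
#' @param j Covariate index.
#' @param seed Integer seed for the permutation.
#' @param baseline_error Optional precomputed unpermuted OOB error (reused
#'   when importances for many covariates are collected).
#' @return The importance value (can be negative).
#' @export
permutation_importance <- function(forest, data, j, seed = 1L,
                                   baseline_error = NULL) {
  if (is.null(baseline_error)) baseline_error <- oob_error(forest, data)
  Xp <- data$covariates
  perm <- with_seed(derive_seed(seed, j), sample.int(nrow(Xp)))
  Xp[, j] <- Xp[perm, j]
  mort <- ensemble_mortality(forest, Xp, oob_only = TRUE)
  err <- 1 - harrell_c(mort, data$times, data$events)
  err - baseline_error
}

# Unpermuted out-of-bag prediction error (1 - Harrell's C).
oob_error <- function(forest, data) {
  mort <- ensemble_mortality(forest, data$covariates, oob_only = TRUE)
  1 - harrell_c(mort, data$times, data$events)
}

#' Permutation importance for every covariate
#'
#' @param forest A `survival_forest` fit on `data`.
#' @param data The training `survival_dataset`.
#' @param seed Integer seed; each covariate's permutation is derived from it.
#' @return A named numeric vector of importance values (one per covariate).
#' @export
importance_table <- function(forest, data, seed = 1L) {
  base <- oob_error(forest, data)
  out <- vapply(seq_len(ncol(data$covariates)), function(j)
    permutation_importance(forest, data, j, seed, baseline_error = base),
    numeric(1))
  names(out) <- data$names
  out
}
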