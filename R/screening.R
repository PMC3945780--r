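#' Configuration for an interaction screening strategy
#'
#' Four assembled strategies are available, differing in how candidate
#' interaction pairs are pre-selected before the final boosted Cox fit:
#' \describe{
#'   \item{`rsf-VIF-res`}{orthogonalize against detected main effects, then
#'     survival forests with permutation importance on S inner subsamples;
#'     pairs of jointly important covariates ranked by inclusion frequency.}
#'   \item{`rsf-VIF`}{the same without orthogonalization.}
#'   \item{`cb-VIF`}{boosted Cox fits on S inner subsamples; pairs ranked by
#'     the per-variable inclusion frequencies.}
#'   \item{`cb-crossp`}{all cross products of the detected main effects, no
#'     subsampling.}
#' }
#'
#' @param name One of `"rsf-VIF-res"`, `"rsf-VIF"`, `"cb-VIF"`,
#'   `"cb-crossp"`.
#' @param S Number of inner subsamples for pre-selection (default 50).
#' @param R Number of pre-selected interaction terms (default 10000). Ties
#'   at rank R are always included.
#' @param mandatory Indices of mandatory (clinical) covariates K.
#' @param boost A [boost_config()] used for every boosted Cox fit.
#' @param ntree,mtry Forest size and split-candidate count for the
#'   rsf-based strategies (defaults 1000 and `round(sqrt(p))`).
#' @param min_node_events Terminal-node size rule for the forests.
#' @return A list of class `strategy_config`.
#' @export
strategy_config <- function(name = c("rsf-VIF-res", "rsf-VIF", "cb-VIF",
                                     "cb-crossp"),
                            S = 50L, R = 10000L, mandatory = integer(0),
                            boost = boost_config(), ntree = 1000L,
                            mtry = NULL, min_node_events = 3L) {
  name <- match.arg(name)
  stopifnot(S >= 1, R >= 1)
  structure(list(name = name, S = as.integer(S), R = as.integer(R),
                 mandatory = sort(unique(as.integer(mandatory))),
                 boost = boost, ntree = as.integer(ntree), mtry = mtry,
                 min_node_events = as.integer(min_node_events)),
            class = "strategy_config")
}

# Pairs are 2-column integer matrices with a < b per row.
empty_pairs <- function() matrix(integer(0), ncol = 2,
                                 dimnames = list(NULL, c("a", "b")))

as_pairs <- function(a, b) {
  lo <- pmin(a, b); hi <- pmax(a, b)
  cbind(a = as.integer(lo), b = as.integer(hi))
}

#' First-pass main effect detection
#'
#' Fits a boosted Cox model with cross-validated step count on the training
#' part; the detected main effects M are the covariates with nonzero
#' coefficients, excluding the mandatory set K (which is fit without
#' penalty and reported separately).
#'
#' @param train A `survival_dataset`.
#' @param config A [strategy_config()].
#' @param seed Integer seed (cross-validation folds).
#' @param steps Optional fixed number of boosting steps; when `NULL` the
#'   count is cross-validated on `train`. [run_strategy()] passes the count
#'   cross-validated once on the full dataset, treating the step number as
#'   a per-dataset setting shared by all fits on its subsamples.
#' @return A list with `model` (the `coxboost_model`, "CoxBoostM"),
#'   `M` (integer indices of detected main effects) and `steps`.
#' @export
detect_main_effects <- function(train, config, seed = 1L, steps = NULL) {
  bc <- config$boost
  bc$unpenalized <- sort(unique(c(bc$unpenalized, config$mandatory)))
  if (is.null(steps)) steps <- cv_select_steps(train, bc, seed = seed)
  model <- fit_coxboost(train, bc, steps = steps)
  M <- selected_covariates(model, exclude = bc$unpenalized)
  list(model = model, M = M, steps = steps)
}

#' Orthogonalize covariates against detected main effects
#'
#' Every covariate outside the anchor set is replaced by the residual of
#' its least-squares regression (with intercept) on the anchor columns;
#' anchor columns are left unchanged. With an empty anchor the dataset is
#' returned as is. Rank-deficient anchor designs are handled by the pivoted
#' QR (dependent columns drop out of the projection) with a warning.
#'
#' @param train A `survival_dataset`.
#' @param anchor Integer indices of the anchor columns (detected main
#'   effects plus mandatory covariates).
#' @return A `survival_dataset` with residualized non-anchor columns.
#' @export
orthogonalize <- function(train, anchor) {
  anchor <- sort(unique(as.integer(anchor)))
  if (length(anchor) == 0) return(train)
  n <- length(train$times)
  if (length(anchor) >= n)
    stop(ss_error("anchor set as large as the sample: regression unsolvable",
                  "ss_anchor_too_large"))
  X <- train$covariates
  A <- cbind(1, X[, anchor, drop = FALSE])
  qrA <- qr(A)
  if (qrA$rank < ncol(A))
    warning("rank-deficient anchor design; dependent columns dropped from the projection")
  rest <- setdiff(seq_len(ncol(X)), anchor)
  X[, rest] <- qr.resid(qrA, X[, rest, drop = FALSE])
  out <- train
  out$covariates <- X
  out
}

# Rank pair counts, keep the top R including all ties at rank R.
top_pairs_by_count <- function(pairs, counts, R) {
  ord <- order(-counts, pairs[, 1], pairs[, 2])
  pairs <- pairs[ord, , drop = FALSE]
  counts <- counts[ord]
  if (nrow(pairs) > R) {
    thr <- counts[R]
    keep <- counts >= thr
    pairs <- pairs[keep, , drop = FALSE]
    counts <- counts[keep]
  }
  list(pairs = pairs, counts = counts)
}

#' Pre-select interaction pairs with survival forests
#'
#' On each of S inner 0.632 subsamples a survival forest is fit and the
#' permutation importance of every covariate computed; all unordered pairs
#' of covariates with strictly positive importance are recorded. Pairs are
#' ranked by their inclusion frequency across the S subsamples and the R
#' most frequent are returned, including every pair tied with the one at
#' rank R.
#'
#' @param train A `survival_dataset` (already orthogonalized for the
#'   `rsf-VIF-res` strategy).
#' @param config A [strategy_config()].
#' @param seed Integer master seed for the inner subsamples, forests and
#'   permutations.
#' @param orthogonalized Bookkeeping flag recorded in the result.
#' @return A list with `pairs` (2-column matrix), `counts`, `S` and
#'   `orthogonalized`.
#' @export
preselect_rsf <- function(train, config, seed = 1L, orthogonalized = FALSE) {
  p <- ncol(train$covariates)
  enc_all <- numeric(0)
  for (s in seq_len(config$S)) {
    sp <- subsample(train, 0.632, derive_seed(seed, 2, s))
    inner <- subset_rows(train, sp$train_idx)
    fc <- forest_config(ntree = config$ntree, mtry = config$mtry,
                        min_node_events = config$min_node_events,
                        seed = derive_seed(seed, 3, s))
    forest <- fit_forest(inner, fc)
    pam <- importance_table(forest, inner, seed = derive_seed(seed, 4, s))
    pos <- which(pam > 0)
    if (length(pos) < 2) {
      message(sprintf("inner subsample %d: fewer than 2 covariates with positive importance", s))
      next
    }
    cmb <- utils::combn(pos, 2)
    enc_all <- c(enc_all, (cmb[1, ] - 1) * p + cmb[2, ])
  }
  if (length(enc_all) == 0)
    return(list(pairs = empty_pairs(), counts = numeric(0), S = config$S,
                orthogonalized = orthogonalized))
  tab <- table(enc_all)
  enc <- as.numeric(names(tab))
  pairs <- as_pairs((enc - 1) %/% p + 1, (enc - 1) %% p + 1)
  top <- top_pairs_by_count(pairs, as.numeric(tab), config$R)
  c(top, list(S = config$S, orthogonalized = orthogonalized))
}

#' Pre-select interaction pairs from boosted-Cox inclusion frequencies
#'
#' On each of S inner 0.632 subsamples a boosted Cox model with
#' cross-validated step count is fit; each covariate's inclusion frequency
#' (VIF) is the fraction of subsamples selecting it. Candidate pairs are
#' all pairs of covariates with positive VIF, ranked by
#' `min(VIF_a, VIF_b)` (ties: larger `VIF_a + VIF_b`, then lexicographic);
#' the top R are returned, including ties with the pair at rank R.
#'
#' @param train A `survival_dataset`.
#' @param config A [strategy_config()].
#' @param seed Integer master seed.
#' @param steps Optional fixed boosting step count shared by the inner
#'   fits; when `NULL`, each inner fit cross-validates its own.
#' @return A list with `pairs`, `vif` (per-pair min-VIF), `var_counts`
#'   (per-variable selection counts) and `S`.
#' @export
preselect_cb_vif <- function(train, config, seed = 1L, steps = NULL) {
  p <- ncol(train$covariates)
  counts <- integer(p)
  bc <- config$boost
  bc$unpenalized <- sort(unique(c(bc$unpenalized, config$mandatory)))
  for (s in seq_len(config$S)) {
    sp <- subsample(train, 0.632, derive_seed(seed, 5, s))
    inner <- subset_rows(train, sp$train_idx)
    st <- if (is.null(steps))
      cv_select_steps(inner, bc, seed = derive_seed(seed, 6, s)) else steps
    mod <- fit_coxboost(inner, bc, steps = st)
    sel <- selected_covariates(mod, exclude = bc$unpenalized)
    counts[sel] <- counts[sel] + 1L
  }
  pos <- which(counts > 0)
  if (length(pos) < 2)
    return(list(pairs = empty_pairs(), vif = numeric(0),
                var_counts = counts, S = config$S))
  cmb <- utils::combn(pos, 2)
  vif <- counts / config$S
  lo_vif <- pmin(vif[cmb[1, ]], vif[cmb[2, ]])
  sum_vif <- vif[cmb[1, ]] + vif[cmb[2, ]]
  ord <- order(-lo_vif, -sum_vif, cmb[1, ], cmb[2, ])
  pairs <- as_pairs(cmb[1, ord], cmb[2, ord])
  lo_vif <- lo_vif[ord]; sum_vif <- sum_vif[ord]
  if (nrow(pairs) > config$R) {
    thr_lo <- lo_vif[config$R]; thr_sum <- sum_vif[config$R]
    keep <- lo_vif > thr_lo | (lo_vif == thr_lo & sum_vif >= thr_sum)
    pairs <- pairs[keep, , drop = FALSE]
    lo_vif <- lo_vif[keep]
  }
  list(pairs = pairs, vif = lo_vif, var_counts = counts, S = config$S)
}

#' Cross products of the detected main effects
#'
#' All distinct pairs of the detected main-effect covariates; if there are
#' more than R pairs, a seeded uniform subset of R is drawn. Fewer than two
#' main effects yield no pairs.
#'
#' @param train A `survival_dataset` (unused; kept for a uniform signature).
#' @param M Integer indices of detected main effects.
#' @param K Mandatory indices (excluded from pairing).
#' @param R Maximum number of pairs.
#' @param seed Integer seed for the random subset.
#' @return A 2-column matrix of pairs.
#' @export
preselect_cb_crossp <- function(train, M, K = integer(0), R = 10000L,
                                seed = 1L) {
  M <- setdiff(sort(unique(as.integer(M))), K)
  if (length(M) < 2) return(empty_pairs())
  cmb <- utils::combn(M, 2)
  pairs <- as_pairs(cmb[1, ], cmb[2, ])
  if (nrow(pairs) > R) {
    keep <- with_seed(derive_seed(seed, 7), sample.int(nrow(pairs), R))
    pairs <- pairs[sort(keep), , drop = FALSE]
  }
  pairs
}

# Candidate design for the final model: mandatory + detected-main columns of
# the ORIGINAL covariates, then the product columns of the selected pairs.
build_final_design <- function(X, names, main_idx, pairs) {
  cols <- X[, main_idx, drop = FALSE]
  colnames(cols) <- names[main_idx]
  if (nrow(pairs)) {
    prod_cols <- X[, pairs[, 1], drop = FALSE] * X[, pairs[, 2], drop = FALSE]
    colnames(prod_cols) <- paste0(names[pairs[, 1]], ":", names[pairs[, 2]])
    cols <- cbind(cols, prod_cols)
  }
  cols
}

#' Run one interaction screening strategy on one outer subsample
#'
#' Executes the full pipeline: (a) an outer 0.632 split and first-pass main
#' effect detection (on the training part or on all rows, see `selection`),
#' with the boosting step count cross-validated once on the full dataset (a
#' per-dataset setting shared by all fits on its subsamples); (b)
#' strategy-specific
#' pre-selection of interaction pairs; (c) a final boosted Cox fit on the
#' training part over mandatory covariates, detected main effects and the
#' product columns of the pre-selected pairs (products of the original,
#' non-residualized covariates), with cross-validated step count; (d) IPCW
#' Brier score curve of the final model on the held-out part, integrated
#' and compared against the Kaplan-Meier reference. All randomness derives
#' from `outer_seed`.
#'
#' @param data A `survival_dataset`.
#' @param config A [strategy_config()].
#' @param outer_seed Integer master seed for this run.
#' @param selection Which rows the selection steps (a)-(c) are fit on:
#'   `"subsample"` fits on the training part Z_b (the resampling protocol
#'   used to assess selection stability on real data, where inclusion
#'   frequencies across repeated outer splits are the point);
#'   `"full"` fits on all rows for maximal selection power, shares the
#'   per-dataset step number across every boosted fit (first pass, inner
#'   inclusion-frequency fits, final model), and uses the split only for
#'   prediction-error tracking. Either way the Brier curve is computed on
#'   the held-out part with censoring weights estimated on the training
#'   part.
#' @return A list of class `strategy_result`: `main_model`, `M`,
#'   `preselected` (pair matrix), `int_screen` (its row count),
#'   `final_model` (`NULL` when the candidate set is empty),
#'   `final_main` / `final_pairs` (indices/pairs with nonzero final
#'   coefficients) with their coefficient values (`final_main_beta`,
#'   `final_pairs_beta`), `brier` (curve), `ripec_main`, `ripec_final`,
#'   `seed`.
#' @export
run_strategy <- function(data, config, outer_seed = 1L,
                         selection = c("subsample", "full")) {
  selection <- match.arg(selection)
  K <- config$mandatory
  split <- subsample(data, 0.632, derive_seed(outer_seed, 1))
  train <- subset_rows(data, split$train_idx)
  test <- subset_rows(data, split$test_idx)
  sel <- if (selection == "full") data else train

  # boosting step number: cross-validated once on the full dataset and
  # shared by the first-pass fits on its subsamples (a per-dataset setting,
  # like the penalty)
  bc0 <- config$boost
  bc0$unpenalized <- sort(unique(c(bc0$unpenalized, K)))
  step_a <- cv_select_steps(data, bc0, seed = derive_seed(outer_seed, 8))

  # (a) first-pass main effects
  det <- detect_main_effects(sel, config, seed = derive_seed(outer_seed, 8),
                             steps = step_a)
  M <- det$M

  # (b) strategy-specific pre-selection
  pre <- switch(config$name,
    "rsf-VIF-res" = {
      zt <- orthogonalize(sel, union(M, K))
      preselect_rsf(zt, config, seed = derive_seed(outer_seed, 9),
                    orthogonalized = length(union(M, K)) > 0)
    },
    "rsf-VIF" = preselect_rsf(sel, config,
                              seed = derive_seed(outer_seed, 9)),
    "cb-VIF" = preselect_cb_vif(sel, config,
                                seed = derive_seed(outer_seed, 9),
                                steps = if (selection == "full") step_a),
    "cb-crossp" = list(pairs = preselect_cb_crossp(
      sel, M, K, config$R, seed = derive_seed(outer_seed, 9)))
  )
  pairs <- pre$pairs

  # (c) final model over {K, M, products of original covariates}
  cand_main <- sort(unique(c(K, M)))
  final_model <- NULL
  final_main <- integer(0)
  final_pairs <- empty_pairs()
  if (length(cand_main) > 0 || nrow(pairs) > 0) {
    Xf <- build_final_design(sel$covariates, sel$names, cand_main, pairs)
    dfinal <- survival_dataset(sel$times, sel$events, Xf,
                               mandatory = match(K, cand_main))
    bc <- config$boost
    bc$unpenalized <- integer(0)  # mandatory carried by the dataset
    # full mode: the per-dataset step number is shared by every boosted
    # fit; subsample mode cross-validates on the candidate design
    fsteps <- if (selection == "full") step_a else
      cv_select_steps(dfinal, bc, seed = derive_seed(outer_seed, 10))
    final_model <- fit_coxboost(dfinal, bc, steps = fsteps)
    nz <- which(final_model$beta != 0)
    final_main <- cand_main[nz[nz <= length(cand_main)]]
    final_main_beta <- final_model$beta[nz[nz <= length(cand_main)]]
    pk <- nz[nz > length(cand_main)] - length(cand_main)
    final_pairs <- pairs[pk, , drop = FALSE]
    final_pairs_beta <- final_model$beta[nz[nz > length(cand_main)]]
  } else {
    final_main_beta <- numeric(0)
    final_pairs_beta <- numeric(0)
  }

  # (d) prediction error on the held-out part
  cens <- censoring_survival(train$times, train$events)
  grid <- evaluation_grid(test, cens)
  km_train <- kaplan_meier(train$times, train$events)
  km_prob <- function(t, X) rep(1 - surv_at(km_train, t), nrow(X))
  bs_km <- brier_curve(km_prob, test, cens, grid)
  ipec_km <- ipec(bs_km)

  main_prob <- function(t, X) predict_event_prob(det$model, X, t)
  bs_main <- brier_curve(main_prob, test, cens, grid)

  if (is.null(final_model)) {
    bs_final <- bs_km
  } else {
    fm <- final_model
    final_prob <- function(t, X) {
      Xf <- build_final_design(X, data$names, cand_main, pairs)
      predict_event_prob(fm, Xf, t)
    }
    bs_final <- brier_curve(final_prob, test, cens, grid)
  }

  structure(list(
    strategy = config$name, selection = selection,
    main_model = det$model, M = M,
    preselected = pairs, int_screen = nrow(pairs),
    vif = pre$counts %||% pre$vif,
    final_model = final_model, cand_main = cand_main,
    final_main = final_main, final_pairs = final_pairs,
    final_main_beta = final_main_beta, final_pairs_beta = final_pairs_beta,
    brier = bs_final,
    ripec_main = ripec(ipec(bs_main), ipec_km),
    ripec_final = ripec(ipec(bs_final), ipec_km),
    ipec_km = ipec_km,
    split = split, seed = outer_seed
  ), class = "strategy_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf("strategy_result (%s): |M| = %d, IntScreen = %d\n",
              x$strategy, length(x$M), x$int_screen))
  cat(sprintf("  final model: %d main + %d interaction terms; rIPEC %.3f (CoxBoostM %.3f)\n",
              length(x$final_main), nrow(x$final_pairs),
              x$ripec_final, x$ripec_main))
  invisible(x)
}
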