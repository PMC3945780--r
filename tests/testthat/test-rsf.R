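test_that("Nelson-Aalen estimator matches hand computations", {
  na <- nelson_aalen(c(1, 2, 3), c(1, 1, 1))
  expect_equal(hazard_at(na, 3), 11 / 6, tolerance = 1e-12)
  expect_equal(hazard_at(na, 1.5), 1 / 3)
  expect_equal(hazard_at(na, 0.5), 0)

  # all censored: flat at zero
  na0 <- nelson_aalen(c(1, 2), c(0, 0))
  expect_equal(hazard_at(na0, 10), 0)

  # tied events: d = 2, Y = 3 at t = 1, then d = 1, Y = 1 at t = 2
  nat <- nelson_aalen(c(1, 1, 2), c(1, 1, 1))
  expect_equal(hazard_at(nat, 1), 2 / 3, tolerance = 1e-12)
  expect_equal(hazard_at(nat, 2), 5 / 3, tolerance = 1e-12)

  # nondecreasing everywhere
  set.seed(21)
  nar <- nelson_aalen(rexp(30), rbinom(30, 1, 0.6))
  expect_true(all(diff(nar$cumhaz) >= 0))
})

test_that("log-rank split statistic agrees with survdiff and is symmetric", {
  set.seed(22)
  d <- make_signal_data(n = 24, p = 2, beta1 = 1.5, seed = 22)
  st <- logrank_split_statistic(d, 1, median(d$covariates[, 1]))
  sdf <- survival::survdiff(
    survival::Surv(d$times, d$events) ~
      (d$covariates[, 1] <= median(d$covariates[, 1])))
  expect_equal(st, sqrt(sdf$chisq), tolerance = 1e-10)

  # invariant under daughter relabeling: flip the covariate sign
  dflip <- d
  dflip$covariates[, 1] <- -dflip$covariates[, 1]
  expect_equal(logrank_split_statistic(dflip, 1,
                                       -median(d$covariates[, 1])), st,
               tolerance = 1e-10)

  # identical time/event multisets in both daughters: statistic 0 (or NA
  # when the variance degenerates)
  dsame <- survival_dataset(c(1, 2, 3, 1, 2, 3), c(1, 1, 0, 1, 1, 0),
                            cbind(c(0, 0, 0, 1, 1, 1)))
  s0 <- logrank_split_statistic(dsame, 1, 0.5)
  expect_equal(unname(s0), 0, tolerance = 1e-12)

  expect_error(logrank_split_statistic(d, 1, 1e9),
               class = "ss_empty_daughter")
})

test_that("tree growth is deterministic and respects structure rules", {
  d <- make_signal_data(n = 40, p = 4, seed = 23)
  tr1 <- grow_tree(d, 1:30, forest_config(ntree = 1), seed = 7)
  tr2 <- grow_tree(d, 1:30, forest_config(ntree = 1), seed = 7)
  expect_identical(tr1$var, tr2$var)
  expect_identical(tr1$split, tr2$split)
  expect_identical(tr1$chf, tr2$chf)

  # terminal CHFs are nondecreasing along the grid
  term <- which(tr1$var < 0)
  for (nd in term)
    expect_true(all(diff(tr1$chf[nd, ]) >= 0))

  # all-identical covariate rows: a single leaf
  dc <- survival_dataset(1:10, rep(c(1, 0), 5), matrix(1, 10, 2))
  trc <- grow_tree(dc, 1:10, forest_config(ntree = 1, mtry = 2), seed = 1)
  expect_identical(trc$var, -1L)

  # a binary covariate perfectly separating early events splits the root
  x <- rep(c(0, 1), each = 10)
  times <- c(1:10, 101:110)
  dper <- survival_dataset(times, rep(1, 20), cbind(x, rnorm(20)))
  trp <- grow_tree(dper, 1:20, forest_config(ntree = 1, mtry = 2), seed = 3)
  expect_identical(trp$var[1], 0L)  # 0-based index of the binary covariate
  expect_equal(trp$split[1], 0.5)
})

test_that("forest predictions: ensembles, invariances, OOB behavior", {
  d <- make_signal_data(n = 80, p = 5, seed = 24)
  f1 <- fit_forest(d, forest_config(ntree = 1, seed = 9))
  # ensemble of one equals that tree's prediction
  tr <- f1$trees[[1]]
  chf1 <- ensemble_chf(f1, d$covariates[2, ])
  node <- 1
  x <- d$covariates[2, ]
  while (tr$var[node] >= 0)
    node <- if (x[tr$var[node] + 1] <= tr$split[node]) tr$left[node] + 1
      else tr$right[node] + 1
  expect_equal(drop(chf1), tr$chf[node, ], tolerance = 1e-12)

  # duplicating a tree leaves the ensemble unchanged
  f2 <- f1
  f2$trees <- c(f1$trees, f1$trees)
  expect_equal(ensemble_chf(f2, d$covariates[1:5, ]),
               ensemble_chf(f1, d$covariates[1:5, ]), tolerance = 1e-12)

  # ensemble CHF nondecreasing in t
  f <- fit_forest(d, forest_config(ntree = 30, seed = 10))
  chf <- ensemble_chf(f, d$covariates[1:10, ])
  expect_true(all(apply(chf, 1, function(r) all(diff(r) >= -1e-12))))

  # splits depend only on the ordering of covariate values: monotone
  # transforms leave every tree's structure and terminal hazards intact
  # (threshold VALUES move, since midpoints are not transform-equivariant)
  dmono <- d
  dmono$covariates[, 1] <- exp(d$covariates[, 1])
  dmono$covariates[, 2] <- d$covariates[, 2]^3
  fmono <- fit_forest(dmono, forest_config(ntree = 30, seed = 10))
  for (k in seq_along(f$trees)) {
    expect_identical(fmono$trees[[k]]$var, f$trees[[k]]$var)
    expect_identical(fmono$trees[[k]]$left, f$trees[[k]]$left)
    expect_identical(fmono$trees[[k]]$inbag, f$trees[[k]]$inbag)
    expect_equal(fmono$trees[[k]]$chf, f$trees[[k]]$chf, tolerance = 1e-12)
  }
})

test_that("Harrell's C matches brute force and known extremes", {
  # all-tied scores: exactly 1/2
  expect_equal(harrell_c(rep(1, 6), 1:6, rep(1, 6)), 0.5)

  # perfect anti-ranking without censoring: exactly 1
  expect_equal(harrell_c(6:1, 1:6, rep(1, 6)), 1)

  # mixed censoring: exhaustive pair enumeration oracle
  times <- c(2, 4, 4, 7, 9)
  events <- c(1, 0, 1, 1, 0)
  risk <- c(5, 1, 4, 4, 2)
  expect_equal(harrell_c(risk, times, events),
               brute_force_c(risk, times, events))

  set.seed(25)
  for (i in 1:5) {
    tt <- sample(1:8, 12, replace = TRUE)
    ev <- rbinom(12, 1, 0.6)
    rk <- sample(1:5, 12, replace = TRUE)
    if (sum(ev) == 0) next
    expect_equal(harrell_c(rk, tt, ev), brute_force_c(rk, tt, ev))
  }

  expect_error(harrell_c(c(1, 2), c(3, 3), c(0, 0)),
               class = "ss_no_usable_pairs")
})

test_that("OOB concordance separates signal from noise", {
  # pure noise: concordance near 1/2
  cs <- vapply(1:8, function(s) {
    d <- make_noise_data(n = 100, p = 20, seed = 100 + s)
    f <- fit_forest(d, forest_config(ntree = 200, seed = s))
    harrell_c(ensemble_mortality(f, d$covariates, oob_only = TRUE),
              d$times, d$events)
  }, numeric(1))
  expect_true(all(cs > 0.4 & cs < 0.6))

  # one strong effect: clearly above chance
  d <- make_signal_data(n = 100, p = 10, beta1 = 3, seed = 30)
  f <- fit_forest(d, forest_config(ntree = 200, seed = 1))
  expect_gt(harrell_c(ensemble_mortality(f, d$covariates, oob_only = TRUE),
                      d$times, d$events), 0.6)
})

test_that("permutation importance: unused zero, noise centered, signal top", {
  # covariate never split on has importance exactly 0: grow a forest where
  # column 2 is constant (never admissible)
  d <- make_signal_data(n = 60, p = 3, seed = 31)
  d$covariates[, 2] <- 1
  f <- fit_forest(d, forest_config(ntree = 50, seed = 2))
  expect_identical(permutation_importance(f, d, 2, seed = 1), 0)

  # strong effect is the top-ranked covariate in most replicates, and noise
  # importances stay near zero with many non-positive values
  top <- logical(10); noise_mean <- numeric(10); frac_nonpos <- numeric(10)
  for (s in 1:10) {
    ds <- make_signal_data(n = 90, p = 10, beta1 = 3, seed = 200 + s)
    fs <- fit_forest(ds, forest_config(ntree = 150, seed = s))
    pam <- importance_table(fs, ds, seed = s)
    top[s] <- which.max(pam) == 1
    noise_mean[s] <- mean(pam[-1])
    frac_nonpos[s] <- mean(pam[-1] <= 0)
  }
  expect_gte(mean(top), 0.9)
  expect_lt(abs(mean(noise_mean)), 0.02)
  expect_gte(mean(frac_nonpos), 0.4)
})
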