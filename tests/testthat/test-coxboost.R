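test_that("partial log-likelihood matches hand-computed risk sets", {
  # 3 subjects, all events, beta = 0: risk sets of sizes 3, 2, 1
  d <- make_tiny(c(1, 2, 3), c(1, 1, 1))
  expect_equal(partial_log_likelihood(0, d), -log(6), tolerance = 1e-12)

  # single event in a sample of 5 at the earliest time: -log m with m = 5
  d5 <- make_tiny(c(1, 2, 3, 4, 5), c(1, 0, 0, 0, 0))
  expect_equal(partial_log_likelihood(0, d5), -log(5), tolerance = 1e-12)

  # dead covariate: shifting its coefficient never changes the PLL
  X <- cbind(rnorm(8), 0)
  dd <- survival_dataset(seq_len(8), rep(c(1, 0), 4), X)
  expect_equal(partial_log_likelihood(c(0.7, 0), dd),
               partial_log_likelihood(c(0.7, 5), dd))

  # ties follow the Breslow convention: agree with coxph's breslow loglik
  dt <- make_tiny(c(1, 1, 2, 3, 3), c(1, 1, 1, 0, 1), x = c(2, 1, 0, 1, 3))
  cx <- survival::coxph(survival::Surv(dt$times, dt$events) ~ dt$covariates,
                        ties = "breslow", init = 0.4,
                        control = survival::coxph.control(iter.max = 0))
  expect_equal(partial_log_likelihood(0.4, dt), cx$loglik[1],
               tolerance = 1e-10)

  # large linear predictors do not overflow
  db <- make_tiny(c(1, 2, 3), c(1, 1, 1), x = c(100, 200, 300))
  expect_true(is.finite(partial_log_likelihood(5, db)))
})

test_that("score and information match central finite differences", {
  d <- make_signal_data(n = 10, p = 3, seed = 11)
  beta <- c(0.3, -0.2, 0.1)
  h <- 1e-4
  for (j in 1:3) {
    si <- score_and_information(j, beta, d)
    f <- function(th) {
      b <- beta; b[j] <- b[j] + th
      partial_log_likelihood(b, d)
    }
    expect_lt(abs(si$U - (f(h) - f(-h)) / (2 * h)), 1e-5)
    expect_lt(abs(si$I + (f(h) - 2 * f(0) + f(-h)) / h^2), 1e-4)
    expect_gte(si$I, 0)
  }

  # identically-zero covariate carries no information
  dz <- survival_dataset(c(1, 2, 3), c(1, 1, 0), cbind(c(1, 0, 2), 0))
  si0 <- score_and_information(2, c(0, 0), dz)
  expect_equal(si0$U, 0)
  expect_equal(si0$I, 0)

  # positive association with hazard gives positive score at beta = 0:
  # events concentrated at high covariate values
  dp <- make_tiny(c(1, 2, 3, 4, 5, 6), c(1, 1, 1, 0, 0, 0),
                  x = c(3, 2, 1, -1, -2, -3))
  expect_gt(score_and_information(1, 0, dp)$U, 0)
})

test_that("boosting reduces to known limits", {
  d <- make_signal_data(n = 40, p = 4, seed = 12)

  # zero steps: null model
  m0 <- fit_coxboost(d, boost_config(), steps = 0)
  expect_true(all(m0$beta == 0))
  expect_length(m0$trace, 0)

  # enormous penalty: updates shrink to nothing
  mR <- fit_coxboost(d, boost_config(penalty = 1e12), steps = 3)
  expect_true(all(abs(mR$beta) < 1e-9))
  expect_length(mR$trace, 3)

  # selection sparsity: distinct trace entries bounded by steps
  m5 <- fit_coxboost(d, boost_config(), steps = 5)
  expect_lte(length(unique(m5$trace)), 5)
})

test_that("unpenalized single covariate converges to the Cox MLE", {
  d <- make_signal_data(n = 60, p = 1, beta1 = 0.8, seed = 2)
  m <- fit_coxboost(d, boost_config(penalty = 0), steps = 200)
  z <- scale(d$covariates[, 1])
  cx <- survival::coxph(survival::Surv(d$times, d$events) ~ z,
                        ties = "breslow")
  expect_equal(unname(m$beta[1]), unname(coef(cx)), tolerance = 1e-4)
})

test_that("training PLL is nondecreasing along the boosting path", {
  d <- make_signal_data(n = 50, p = 8, seed = 13)
  std <- standardize(d)
  plls <- numeric(0)
  hook <- function(k, beta)
    plls[k + 1] <<- partial_log_likelihood(beta, std$data)
  survscreen:::cb_engine(std$data$covariates, d$times, d$events, 25,
                         rho = sum(d$events) * 19, step_hook = hook)
  expect_true(all(diff(plls) >= -1e-10))
})

test_that("mandatory covariates are refit without penalty each step", {
  d <- make_signal_data(n = 60, p = 5, beta1 = 1.2, seed = 14)
  d$mandatory <- 2L
  m <- fit_coxboost(d, boost_config(), steps = 4)
  # mandatory covariate gets a (near-MLE) coefficient even with few steps
  expect_true(m$beta[2] != 0)
  # and is never chosen by the penalized selection
  expect_false(2L %in% m$trace)
  expect_false(2L %in% selected_covariates(m, exclude = 2L))
})

test_that("cross-validated step count behaves at the extremes", {
  cfgs <- boost_config(max_steps = 0L)
  d <- make_signal_data(n = 50, p = 5, seed = 3)
  expect_identical(cv_select_steps(d, cfgs, seed = 1), 0L)

  # strong single effect: at least one step always
  cfg <- boost_config(max_steps = 30L, cv_folds = 5L)
  steps_signal <- vapply(1:5, function(s)
    cv_select_steps(make_signal_data(n = 100, p = 5, beta1 = 3, seed = s),
                    cfg, seed = s), integer(1))
  expect_true(all(steps_signal >= 1))

  # pure noise: the step distribution is concentrated near zero (the
  # out-of-fold criterion on noise is a near-flat random walk, so single
  # draws occasionally wander high; the bulk stops early) and clearly
  # below the step counts chosen under strong signal
  steps_noise <- vapply(1:10, function(s)
    cv_select_steps(make_noise_data(n = 50, p = 20, seed = s),
                    cfg, seed = s), integer(1))
  expect_lte(median(steps_noise), 5)
  expect_lt(mean(steps_noise), mean(steps_signal) + 10)
})

test_that("Breslow baseline reduces to Nelson-Aalen at beta = 0", {
  d <- make_tiny(c(1, 2, 3), c(1, 1, 1))
  m <- fit_coxboost(d, boost_config(), steps = 0)
  expect_equal(survscreen:::baseline_at(m$baseline, 3), 11 / 6,
               tolerance = 1e-12)
  expect_equal(survscreen:::baseline_at(m$baseline, 0.5), 0)
  na <- nelson_aalen(d$times, d$events)
  expect_equal(m$baseline$cumhaz, na$cumhaz, tolerance = 1e-12)
})

test_that("survival predictions are proper and monotone", {
  d <- make_signal_data(n = 60, p = 3, seed = 15)
  m <- fit_coxboost(d, boost_config(), steps = 10)
  x <- d$covariates[1, ]
  expect_equal(unname(predict_survival(m, x, 0)), 1)
  expect_error(predict_survival(m, x, -1), class = "ss_invalid_time")

  tgrid <- c(0, 1, 5, 20, 50)
  s <- predict_survival(m, x, tgrid)
  expect_true(all(diff(s) <= 0))
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(unname(predict_event_prob(m, x, tgrid)), unname(1 - s))

  # beta = 0: survival is exp(-H0(t)) for any x
  m0 <- fit_coxboost(d, boost_config(), steps = 0)
  for (t in c(2, 10)) {
    expect_equal(unname(predict_survival(m0, d$covariates[3, ], t)),
                 exp(-survscreen:::baseline_at(m0$baseline, t)))
  }

  # higher linear predictor implies lower survival everywhere
  std_x <- survscreen:::apply_standardization(d$covariates[1:10, ], m$scaling)
  lp <- drop(std_x %*% m$beta)
  hi <- which.max(lp); lo <- which.min(lp)
  s_hi <- predict_survival(m, d$covariates[hi, ], tgrid)
  s_lo <- predict_survival(m, d$covariates[lo, ], tgrid)
  expect_true(all(s_hi <= s_lo + 1e-12))
})
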