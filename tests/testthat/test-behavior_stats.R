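test_that("Weibull learning curve has its analytic anchors", {
  expect_equal(weibull_curve(0, a = 30, l = 1000, s = 2), 50)
  expect_equal(weibull_curve(1000, 30, 1000, 2), 50 + 15)  # half-rise at l
  # flat chance-level data fit with near-zero amplitude
  set.seed(1)
  fw <- fit_weibull(rbinom(2000, 1, 0.5))
  expect_lt(fw$a, 3)
})

test_that("Weibull parameters are recovered from Bernoulli cohorts", {
  true <- list(a = 35, l = 1500, s = 1.6)
  co <- generate_cohort(1, true, 5000, seed = 5)
  fw <- fit_weibull(co$correct[, 1])
  expect_true(fw$converged)
  expect_lt(abs(fw$a - true$a), 6)
  expect_lt(abs(fw$l - true$l), 400)
  expect_lt(abs(fw$s - true$s), 0.6)
  expect_gt(fw$max_performance, 75)
  expect_gt(fw$max_learning_rate, 0)
})

test_that("trial cleaning drops short sessions, starts and disengagement", {
  tr <- data.frame(session_idx = rep(c(1, 2), c(30, 100)),
                   correct = 1,
                   inter_trial_interval = c(rep(2, 30), rep(2, 95),
                                            rep(30, 5)))
  out <- clean_learning_trials(tr)
  expect_true(all(out$session_idx == 2))  # session 1 too short
  expect_equal(nrow(out), 100 - 5 - 5)    # first 5 + 5 disengaged dropped
})

test_that("shuffle bias test detects extreme effects and nulls", {
  # stimulated trials forced fully to the reference port vs 50% baseline
  set.seed(2)
  tr <- data.frame(type = rep(1:2, each = 200),
                   choice = rep(c("left", "right"), 200),
                   stimulated = FALSE)
  stim_rows <- c(sample(which(tr$type == 1), 30),
                 sample(which(tr$type == 2), 30))
  tr$stimulated[stim_rows] <- TRUE
  tr$choice[stim_rows] <- "left"
  res <- shuffle_bias_test(tr, n_shuffles = 500, seed = 3)
  expect_gt(res$session_bias, 0.4)
  expect_lt(res$p_value, 0.01)

  # identical choice distributions: bias near zero, p not extreme
  tr0 <- data.frame(type = rep(1:2, each = 200),
                    choice = rep(c("left", "right"), 200),
                    stimulated = rep(c(TRUE, FALSE), c(40, 360)))
  res0 <- shuffle_bias_test(tr0, n_shuffles = 500, seed = 4)
  expect_lt(abs(res0$session_bias), 0.1)
  expect_gt(res0$p_value, 0.05)

  # a type without stimulated trials is excluded, not fatal
  tr$stimulated[tr$type == 2] <- FALSE
  res2 <- shuffle_bias_test(tr, n_shuffles = 200, seed = 5)
  expect_equal(res2$excluded_types, "2")
})

test_that("repeat/switch logistic recovers planted dopamine effects", {
  set.seed(6)
  n <- 8000
  p_high <- sample(seq(0, 1, length.out = 7), n, replace = TRUE)
  resp <- rnorm(n, 1, 0.5)
  unc <- log_uncertainty(p_high)
  choice <- character(n)
  choice[1] <- "left"
  for (t in 2:n) {
    pr <- stats::plogis(0.8 * resp[t - 1] - 0.2 + 0.3 * unc[t])
    choice[t] <- if (runif(1) < pr) choice[t - 1] else {
      setdiff(c("left", "right"), choice[t - 1])
    }
  }
  tr <- data.frame(p_high = p_high, choice = choice, correct = TRUE,
                   response = resp)
  rc <- repeat_choice_logistic(tr)
  expect_false(rc$regularized)
  expect_lt(abs(rc$coefficients[["prev_response"]] - 0.8), 0.15)
  expect_lt(abs(rc$coefficients[["log_uncertainty"]] - 0.3), 0.15)

  # null: responses unrelated to repetition
  choice0 <- sample(c("left", "right"), n, replace = TRUE)
  tr0 <- data.frame(p_high = p_high, choice = choice0, correct = TRUE,
                    response = resp)
  rc0 <- repeat_choice_logistic(tr0)
  expect_lt(abs(rc0$coefficients[["prev_response"]]), 0.15)

  # ambiguous-only coin-flip behaviour: both coefficients near zero
  tra <- data.frame(p_high = 0.5, choice = choice0, correct = FALSE,
                    response = resp)
  rca <- suppressWarnings(repeat_choice_logistic(tra))
  expect_lt(abs(rca$coefficients[["prev_response"]]), 0.15)
})

test_that("per-lag history regression finds planted choice effects", {
  set.seed(7)
  n <- 3000
  stimulus <- sample(c("A", "B"), n, replace = TRUE)
  choice <- sample(c("left", "right"), n, replace = TRUE)
  # response smaller when the same side was chosen for the same stimulus
  same1 <- rep(NA, n)
  for (t in 2:n) {
    prev <- which(stimulus[1:(t - 1)] == stimulus[t])
    if (length(prev)) same1[t] <- choice[t] == choice[max(prev)]
  }
  resp <- 1 - 0.4 * ifelse(is.na(same1), 0, same1) + rnorm(n, sd = 0.2)
  out <- dopamine_history_regression(stimulus, choice, resp,
                                     max_lag = 3L)
  expect_lt(abs(out$coefficient[1] + 0.4), 0.05)

  # independent responses: all lags near zero
  out0 <- dopamine_history_regression(stimulus, choice,
                                      rnorm(n), max_lag = 3L)
  expect_true(all(abs(out0$coefficient) < 0.1))
})

test_that("discrete Frechet distance matches the brute-force recursion", {
  p <- cbind(0:3, c(0, 0, 0, 0))
  expect_equal(frechet_distance(p, p), 0)
  q <- cbind(0:3, rep(2, 4))  # parallel offset by 2
  expect_equal(frechet_distance(p, q), 2)

  set.seed(8)
  for (i in 1:200) {
    a <- matrix(rnorm(12), 6)
    b <- matrix(rnorm(2 * sample(3:6, 1)), ncol = 2)
    d <- frechet_distance(a, b)
    expect_identical(d, frechet_naive(a, b))
    expect_identical(d, frechet_distance(b, a))      # symmetry
    # never below the endpoint distances
    expect_gte(d, max(sqrt(sum((a[1, ] - b[1, ])^2)),
                      sqrt(sum((a[6, ] - b[nrow(b), ])^2))))
  }
})

test_that("movement-similarity regression recovers planted couplings", {
  set.seed(9)
  n <- 80
  resp <- runif(n, 0, 2)
  base <- cbind(seq(0, 1, length.out = 15), 0)
  offs <- numeric(n)
  for (i in 2:n) {
    offs[i] <- offs[i - 1] + max(0, 1 - 0.45 * resp[i - 1] +
                                   rnorm(1, sd = 0.05))
  }
  trajs <- lapply(offs, function(o) cbind(base[, 1], base[, 2] + o))
  sr <- similarity_regression(resp, trajs)
  expect_lt(sr$slope, -0.3)

  # independent responses: slope near zero
  sr0 <- similarity_regression(sample(resp), trajs)
  expect_lt(abs(sr0$slope), abs(sr$slope))

  # identical trajectories: all distances zero, slope zero
  same <- lapply(1:10, function(i) base)
  srs <- similarity_regression(runif(10), same)
  expect_true(all(srs$distances == 0))
  expect_equal(srs$slope, 0)
})

test_that("residual trend regression separates movement from trial drift", {
  set.seed(10)
  n <- 600
  speed <- runif(n, 0.1, 0.6)
  turn <- rnorm(n, 45, 10)
  trial <- seq_len(n)
  # response depends only on log trial number
  resp <- 2 - 0.3 * log(trial) + rnorm(n, sd = 0.05)
  rt <- residual_trend_regression(resp, speed, turn, trial)
  expect_lt(abs(rt$residual_slope + 0.3), 0.03)
  expect_lt(rt$ev_decomposition[["speed"]] +
              rt$ev_decomposition[["turn_angle"]], 0.01)
  expect_gt(rt$ev_decomposition[["log_trial"]], 0.5)

  # response depends only on speed: no residual trend
  resp2 <- 1 + 2 * speed + rnorm(n, sd = 0.05)
  rt2 <- residual_trend_regression(resp2, speed, turn, trial)
  expect_lt(abs(rt2$residual_slope), 0.03)

  # collinear kinematics: least-norm with a warning (one per solve)
  w <- testthat::capture_warnings(
    residual_trend_regression(resp, speed, 2 * speed, trial))
  expect_true(any(grepl("minimum-norm", w)))
})
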