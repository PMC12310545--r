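test_that("lock-in demodulation recovers carrier envelopes", {
  rate <- 5000
  t <- (0:(rate * 10 - 1)) / rate
  settled <- (rate * 1):(rate * 9)

  # pure first carrier of amplitude A: signal envelope A, background ~ 0
  x <- 2.5 * sin(2 * pi * 211 * t)
  dm <- demodulate(x, c(211, 531), rate)
  expect_lt(max(abs(dm$signal[settled] - 2.5)), 0.01)
  expect_lt(max(abs(dm$background[settled])), 0.01)

  # both carriers with slow known envelopes: each within 2% RMS
  envA <- 2 + 0.5 * sin(2 * pi * 0.3 * t)
  envB <- 1.5 + 0.3 * cos(2 * pi * 0.2 * t)
  x2 <- envA * sin(2 * pi * 211 * t) + envB * sin(2 * pi * 531 * t)
  dm2 <- demodulate(x2, c(211, 531), rate)
  expect_lt(sqrt(mean((dm2$signal[settled] - envA[settled])^2)) /
              mean(envA), 0.02)
  expect_lt(sqrt(mean((dm2$background[settled] - envB[settled])^2)) /
              mean(envB), 0.02)

  expect_equal(max(abs(demodulate(numeric(1000), rate = 5000)$signal)), 0)
  expect_error(demodulate(x, c(3000, 531), 5000), "Nyquist")
})

test_that("preprocessing z-scores and rejects the shared motion artifact", {
  cfg <- synth_config(rate = 50, duration = 240, noise_sd = 0.01)
  set.seed(201)
  dur <- 240
  events <- list(cue = sort(runif(60, 5, dur - 10)),
                 movement = sort(runif(60, 5, dur - 10)),
                 outcome = sort(runif(60, 5, dur - 10)))
  ph <- generate_photometry(events, cfg, seed = 1)
  pt <- preprocess_photometry(ph$signal, ph$background, ph$rate)
  expect_equal(mean(pt$dff_z), 0, tolerance = 1e-6)
  expect_equal(sd(pt$dff_z), 1, tolerance = 1e-6)
  expect_lt(abs(cor(pt$dff_z, ph$ground_truth$artifact)), 0.05)
  # ground-truth transients survive: processed trace tracks the clean
  # event signal with peak SNR well above 5
  expect_gt(cor(pt$dff_z, ph$ground_truth$clean_signal), 0.9)

  # degenerate constant input
  expect_warning(ptc <- preprocess_photometry(rep(2, 500), rep(1, 500),
                                              50), "degenerate")
  expect_true(all(ptc$dff_z == 0))
  expect_error(preprocess_photometry(1:10, 1:10, 50), "warm-up")
})

test_that("preprocessing is shift-equivariant away from the edges", {
  cfg <- synth_config(rate = 50, duration = 200, noise_sd = 0.005)
  events <- list(cue = seq(10, 180, by = 9))
  ph <- generate_photometry(events, cfg, seed = 4)
  shift_n <- 50 * 5  # 5 s
  pad <- function(x) c(rep(x[1], shift_n), x)
  a <- preprocess_photometry(ph$signal, ph$background, 50)$dff_z
  b <- preprocess_photometry(pad(ph$signal), pad(ph$background), 50)$dff_z
  core <- (50 * 20):(50 * 180)
  expect_gt(cor(a[core], b[core + shift_n]), 0.999)
})

test_that("event-locked responses use peaks with a maximum fallback", {
  rate <- 100
  ramp <- seq(0, 1, length.out = 101)
  expect_equal(extract_response(ramp, rate, c(0, 1)), 1)      # no interior peak
  expect_equal(extract_response(ramp, rate, c(0, 1), "mean"), 0.5)
  bump <- c(seq(0, 3, length.out = 26), seq(3, 0, length.out = 26)[-1])
  expect_equal(extract_response(bump, rate, c(0, 0.5)), 3)
  # largest local maximum wins over the window edge value
  two <- c(seq(0, 2, length.out = 21), seq(2, 0.5, length.out = 16)[-1],
           seq(0.5, 1, length.out = 10)[-1])
  expect_equal(extract_response(two, rate, c(0, length(two) / rate)), 2)
  expect_error(extract_response(ramp, rate, c(2, 3)), "window")
})

test_that("kernel regression recovers noiseless kernels to 1e-6", {
  rate <- 25
  n <- rate * 200
  spec <- kernel_spec(list(cue = c(0, 1), movement = c(0.5, 1.5)))
  ev <- list(cue = seq(5, 190, by = 7) + 0.1,
             movement = seq(8, 190, by = 9) + 0.3)
  des <- apemodel:::kernel_design(n, rate, ev, spec)
  ktrue <- list(cue = gamma_kernel(des$lags$cue, 1.5, 0.3, 0.2),
                movement = gamma_kernel(des$lags$movement, 2, 0.4, 0.25))
  y <- drop(cbind(1, des$X) %*% c(0.2, unlist(ktrue)))
  fit <- fit_kernels(y, rate, ev, spec)
  for (evn in names(ktrue)) {
    expect_lt(max(abs(fit$kernels[[evn]]$weight - ktrue[[evn]])),
              1e-6 * max(abs(ktrue[[evn]])))
  }
  expect_equal(fit$g0, 0.2, tolerance = 1e-8)
  expect_gt(fit$v_full, 99.999)

  # zero trace: all kernels and the intercept vanish
  fit0 <- fit_kernels(numeric(n), rate, ev, spec)
  expect_equal(fit0$g0, 0)
  expect_true(all(abs(unlist(lapply(fit0$kernels, `[[`,
                                    "weight"))) < 1e-12))
})

test_that("non-overlapping event types are recovered independently", {
  rate <- 20
  n <- rate * 120
  spec <- kernel_spec(list(cue = c(0, 1), outcome = c(0, 1)))
  # events far apart: block-diagonal design
  ev <- list(cue = seq(5, 55, by = 5), outcome = seq(65, 115, by = 5))
  des <- apemodel:::kernel_design(n, rate, ev, spec)
  ktrue <- list(cue = gamma_kernel(des$lags$cue, 1, 0.25, 0.15),
                outcome = gamma_kernel(des$lags$outcome, -0.8, 0.3, 0.2))
  y <- drop(des$X %*% unlist(ktrue))
  fit <- fit_kernels(y, rate, ev, spec)
  expect_equal(fit$kernels$cue$weight, ktrue$cue, tolerance = 1e-7)
  expect_equal(fit$kernels$outcome$weight, ktrue$outcome,
               tolerance = 1e-7)
})

test_that("rank-deficient designs fall back to the least-norm solution", {
  rate <- 10
  n <- rate * 30
  # two event types with identical times: perfectly collinear columns
  ev <- list(cue = c(5, 12, 19), movement = c(5, 12, 19))
  spec <- kernel_spec(list(cue = c(0, 1), movement = c(0, 1)))
  y <- rnorm(n)
  expect_warning(fit <- fit_kernels(y, rate, ev, spec), "rank-deficient")
  expect_true(all(is.finite(unlist(lapply(fit$kernels, `[[`, "weight")))))
})

test_that("per-regressor explained variance isolates true contributors", {
  rate <- 25
  n <- rate * 200
  spec <- kernel_spec(list(cue = c(0, 1), movement = c(0.5, 1.5),
                           outcome = c(0, 1)))
  set.seed(31)
  ev <- list(cue = seq(5, 190, by = 7) + 0.1,
             movement = seq(8, 190, by = 9) + 0.3,
             outcome = seq(6, 190, by = 11) + 0.2)
  des <- apemodel:::kernel_design(n, rate, ev[1:2], spec[1:2])
  ktrue <- list(cue = gamma_kernel(des$lags$cue, 1.5, 0.3, 0.2),
                movement = gamma_kernel(des$lags$movement, 1, 0.4, 0.25))
  y <- drop(des$X %*% unlist(ktrue)) + rnorm(n, sd = 0.1)
  fit <- fit_kernels(y, rate, ev, spec)
  pev <- vapply(c("cue", "movement", "outcome"),
                function(r) partial_explained_variance(fit, r),
                numeric(1))
  expect_lt(pev[["outcome"]], 2)       # null regressor
  expect_equal(names(which.max(pev)), "cue")
  expect_true(all(pev >= 0))           # v_partial <= v_full for OLS fits

  # sole contributor removed: essentially all explained variance goes
  y1 <- drop(des$X[, seq_along(ktrue$cue)] %*% ktrue$cue)
  fit1 <- fit_kernels(y1, rate, ev["cue"], spec["cue"])
  expect_gt(partial_explained_variance(fit1, "cue"), 99)

  # trimming restricts scoring to event epochs and stays finite
  expect_true(is.finite(partial_explained_variance(fit, "cue",
                                                   trim = TRUE)))
})
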