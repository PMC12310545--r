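# Synthetic ground-truth generators: photometry sessions built from known
# event kernels plus bleaching, shared motion artifacts and noise;
# behavioural cohorts following known Weibull learning curves; and linked
# behaviour-photometry-kinematics datasets with planted effects.

#' Gamma-shaped response kernel
#'
#' A smooth transient bump parameterized by amplitude (peak height),
#' latency (time to peak, s) and width (s), evaluated on a lag grid.
#' Negative lags (before the event) are zero.
#'
#' @param lags Lag grid in seconds.
#' @param amplitude Peak height.
#' @param latency Time-to-peak in seconds.
#' @param width Shape-controlling width in seconds.
#' @return Kernel values on `lags`.
#' @export
gamma_kernel <- function(lags, amplitude = 1, latency = 0.3,
                         width = 0.2) {
  rate <- latency / width^2
  shape <- (latency / width)^2 + 1  # gamma mode (shape-1)/rate = latency
  v <- ifelse(lags > 0, stats::dgamma(lags, shape = shape, rate = rate), 0)
  if (max(v) > 0) v <- v / max(v) * amplitude
  v
}

#' Configuration of a synthetic photometry session
#'
#' @param rate Sampling rate in Hz (>= 2500 when `modulation = TRUE`).
#' @param duration Session length in seconds.
#' @param kernels Named list per event type: list with `amplitude`,
#'   `latency`, `width` of the true [gamma_kernel()].
#' @param bleach Double-exponential bleaching: list with `offset`,
#'   `amps` (two amplitudes) and `taus` (two time constants, s).
#' @param bleach_background Same for the background channel (defaults to
#'   a scaled copy).
#' @param artifact_gain Per-channel gains `c(signal, background)` of the
#'   shared motion artifact.
#' @param artifact_cutoff Low-pass cutoff (Hz) of the band-limited
#'   artifact process.
#' @param artifact_sd Artifact standard deviation before gains.
#' @param noise_sd Independent white-noise SD per channel.
#' @param modulation Emit a single carrier-modulated trace instead of the
#'   two demodulated channels.
#' @param carrier_freqs Carrier frequencies (signal, background) in Hz.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(rate = 100, duration = 120,
                         kernels = list(
                           cue = list(amplitude = 1, latency = 0.2,
                                      width = 0.15),
                           movement = list(amplitude = 2, latency = 0.3,
                                           width = 0.2),
                           outcome = list(amplitude = 1.5, latency = 0.25,
                                          width = 0.15)),
                         bleach = list(offset = 5, amps = c(1, 0.5),
                                       taus = c(1200, 300)),
                         bleach_background = NULL,
                         artifact_gain = c(0.5, 0.4),
                         artifact_cutoff = 1, artifact_sd = 1,
                         noise_sd = 0.02, modulation = FALSE,
                         carrier_freqs = c(211, 531)) {
  if (modulation && rate < 2500) {
    stop_domain("modulated sessions require rate >= 2500 Hz")
  }
  if (is.null(bleach_background)) {
    # both channels read the same fluorophore pool through the same fiber
    # coupling, so bleaching and motion scale with channel brightness:
    # the background channel is a dimmer copy (ratio 0.8 by default,
    # matching artifact_gain[2] / artifact_gain[1])
    bleach_background <- list(offset = bleach$offset * 0.8,
                              amps = bleach$amps * 0.8,
                              taus = bleach$taus)
  }
  structure(list(rate = rate, duration = duration, kernels = kernels,
                 bleach = bleach, bleach_background = bleach_background,
                 artifact_gain = artifact_gain,
                 artifact_cutoff = artifact_cutoff,
                 artifact_sd = artifact_sd, noise_sd = noise_sd,
                 modulation = modulation, carrier_freqs = carrier_freqs),
            class = "synth_config")
}

bleach_trace <- function(t, b) {
  b$offset + b$amps[1] * exp(-t / b$taus[1]) +
    b$amps[2] * exp(-t / b$taus[2])
}

#' Generate a synthetic photometry session with known ground truth
#'
#' The signal channel is the sum of per-event kernel convolutions (with
#' optional per-event amplitude scaling), a double-exponential bleaching
#' trend, a shared band-limited motion artifact and white noise; the
#' background channel carries the bleaching and artifact (with its own
#' gain) but no event signal, emulating the isosbestic channel. With
#' `modulation = TRUE` a single carrier-modulated trace is returned
#' instead.
#'
#' @param events Named list of event-time vectors in seconds; optionally
#'   each with an `amplitudes` attribute giving a per-event scaling of
#'   the kernel.
#' @param config A [synth_config()].
#' @param seed Optional seed.
#' @return List of class `photometry_session`: `signal`, `background`
#'   (or `modulated`), `rate`, `events`, and `ground_truth` (kernel
#'   parameters, clean event signal, artifact and bleach traces).
#' @export
generate_photometry <- function(events, config = synth_config(),
                                seed = NULL) {
  with_seed(seed, {
    rate <- config$rate
    n <- round(config$duration * rate)
    t <- (seq_len(n) - 1) / rate
    for (ev in names(events)) {
      if (any(events[[ev]] < 0 | events[[ev]] > config$duration)) {
        stop_domain("event times outside the session span")
      }
    }
    clean <- numeric(n)
    for (ev in intersect(names(config$kernels), names(events))) {
      kp <- config$kernels[[ev]]
      lag_grid <- seq(0, max(2, 6 * kp$width + kp$latency), by = 1 / rate)
      k <- gamma_kernel(lag_grid, kp$amplitude, kp$latency, kp$width)
      amps <- attr(events[[ev]], "amplitudes")
      if (is.null(amps)) amps <- rep(1, length(events[[ev]]))
      for (j in seq_along(events[[ev]])) {
        i0 <- round(events[[ev]][j] * rate) + 1L
        span <- i0:min(n, i0 + length(k) - 1L)
        clean[span] <- clean[span] + amps[j] * k[seq_along(span)]
      }
    }
    artifact <- butter_lowpass(rnorm(n), config$artifact_cutoff, rate)
    if (sd(artifact) > 0) {
      artifact <- artifact / sd(artifact) * config$artifact_sd
    }
    sig <- clean + bleach_trace(t, config$bleach) +
      config$artifact_gain[1] * artifact +
      rnorm(n, sd = config$noise_sd)
    bg <- bleach_trace(t, config$bleach_background) +
      config$artifact_gain[2] * artifact +
      rnorm(n, sd = config$noise_sd)
    gt <- list(kernels = config$kernels, clean_signal = clean,
               artifact = artifact,
               bleach_signal = bleach_trace(t, config$bleach),
               bleach_background = bleach_trace(t,
                                                config$bleach_background))
    out <- list(rate = rate, events = events, ground_truth = gt,
                config = config)
    if (config$modulation) {
      f <- config$carrier_freqs
      out$modulated <- sig * sin(2 * pi * f[1] * t) +
        bg * sin(2 * pi * f[2] * t)
    } else {
      out$signal <- sig
      out$background <- bg
    }
    structure(out, class = "photometry_session")
  })
}

#' Generate a behavioural cohort with known learning curves
#'
#' Per mouse, per-trial correct/error outcomes are Bernoulli draws whose
#' success probability follows the modified Weibull curve
#' `(50 + a (1 - 2^(-(t/l)^s))) / 100`.
#'
#' @param n_mice Number of mice.
#' @param weibull_params List or data frame with `a`, `l`, `s`; recycled
#'   across mice.
#' @param n_trials Trials per mouse.
#' @param seed Optional seed.
#' @return List of class `synthetic_cohort`: `correct` (trials x mice
#'   matrix) and `params` (per-mouse data frame).
#' @export
generate_cohort <- function(n_mice, weibull_params, n_trials,
                            seed = NULL) {
  check_count(n_mice, "n_mice")
  check_count(n_trials, "n_trials")
  wp <- as.data.frame(weibull_params)
  wp <- wp[rep_len(seq_len(nrow(wp)), n_mice), , drop = FALSE]
  with_seed(seed, {
    trials <- seq_len(n_trials)
    correct <- vapply(seq_len(n_mice), function(i) {
      p <- weibull_curve(trials, wp$a[i], wp$l[i], wp$s[i]) / 100
      rbinom(n_trials, 1, pmin(pmax(p, 0), 1))
    }, numeric(n_trials))
    structure(list(correct = correct, params = wp),
              class = "synthetic_cohort")
  })
}

#' Generate a linked behaviour-photometry-kinematics dataset
#'
#' Builds one coherent synthetic dataset from semi-Markov agent traces:
#' the session's APE values become the per-trial choice-locked transient
#' amplitudes in a raw photometry session, and per-trial kinematic
#' covariates and movement trajectories are generated with planted
#' couplings (speed/turn contributions to the response and a negative
#' response-to-trajectory-change coupling), so every downstream analysis
#' has a known expected outcome.
#'
#' @param sim Output of [simulate_learning()] for a single agent.
#' @param config A [synth_config()] (kernels should include `cue`,
#'   `movement`, `outcome`).
#' @param trial_spacing Seconds between consecutive trial starts.
#' @param traj_coupling Planted coefficient linking the response to the
#'   next trial's trajectory displacement (negative: larger responses
#'   give more similar movements).
#' @param kinematic_coefs Planted `c(speed, turn)` contributions to the
#'   recorded response.
#' @param seed Optional seed.
#' @return List of class `linked_dataset` with `session` (trial table),
#'   `photometry` ([generate_photometry()] output), `kinematics` (data
#'   frame), `trajectories` (list) and `ground_truth`.
#' @export
generate_linked_dataset <- function(sim, config = synth_config(),
                                    trial_spacing = 6,
                                    traj_coupling = -0.5,
                                    kinematic_coefs = c(speed = 0.3,
                                                        turn = 0.1),
                                    seed = NULL) {
  tl <- sim$trials[sim$trials$agent == sim$trials$agent[1], ]
  tr <- sim$transitions[sim$transitions$agent == tl$agent[1], ]
  n <- nrow(tl)
  ape <- tr$ape[tr$phase == "choice"]
  rpe_out <- tr$rpe_signal[tr$phase == "outcome"]
  with_seed(seed, {
    # self-paced timing: jittered offsets keep the kernel design
    # identifiable (regular spacing would make event columns collinear)
    t_start <- (seq_len(n) - 1) * trial_spacing + 1 +
      runif(n, 0, trial_spacing / 3)
    t_cue <- t_start
    t_move <- t_cue + runif(n, 0.3, 1.0)
    t_outcome <- t_move + runif(n, 0.4, 1.1)
    needed <- max(t_outcome) + 5
    if (config$duration < needed) config$duration <- needed
    events <- list(cue = t_cue, movement = t_move, outcome = t_outcome)
    attr(events$movement, "amplitudes") <- ape
    attr(events$outcome, "amplitudes") <- rpe_out
    phot <- generate_photometry(events, config,
                                seed = sample.int(2^30, 1))

    speed <- pmax(0.05, rnorm(n, 0.3, 0.05))
    turn <- rnorm(n, 45, 10)
    response <- ape + kinematic_coefs[["speed"]] * speed +
      kinematic_coefs[["turn"]] * (turn - 45) / 45 +
      rnorm(n, sd = 0.02)

    # trajectories: a common arc plus a lateral offset whose step size
    # shrinks with the planted response coupling
    base_t <- seq(0, 1, length.out = 20)
    arc <- cbind(base_t, 0.5 * sin(pi * base_t))
    offsets <- numeric(n)
    for (i in 2:n) {
      step <- pmax(0, 0.6 + traj_coupling * response[i - 1] +
                     rnorm(1, sd = 0.05))
      offsets[i] <- offsets[i - 1] + sample(c(-1, 1), 1) * step
    }
    trajectories <- lapply(seq_len(n), function(i) {
      cbind(arc[, 1], arc[, 2] + offsets[i])
    })

    session <- cbind(tl, t_cue_on = t_cue, t_center_out = t_move,
                     t_outcome = t_outcome, response = response)
    structure(list(session = session, photometry = phot,
                   kinematics = data.frame(trial = tl$trial,
                                           speed = speed,
                                           turn_angle = turn,
                                           response = response),
                   trajectories = trajectories,
                   ground_truth = list(ape = ape, rpe_outcome = rpe_out,
                                       traj_coupling = traj_coupling,
                                       kinematic_coefs = kinematic_coefs)),
              class = "linked_dataset")
  })
}
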