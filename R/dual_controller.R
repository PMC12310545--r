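# Dual value-based / value-free controller network: a two-state,
# two-action model in which an actor-critic (updated by RPE) and a
# tail-of-striatum-like controller (updated by APE) jointly drive choice.
#
# Time semantics: one simulation time unit per trial; the predicted-action
# filter, the actor weight decay and the performance readout are integrated
# by forward Euler with dt = 1 in those units.

#' Parameters of the dual-controller network
#'
#' @param alpha RPE learning rate (actor and critic).
#' @param beta APE learning rate (tail controller).
#' @param tau_tail Time constant of the predicted-action low-pass filter.
#' @param tau_decay Time constant of the actor weight decay towards 1.
#' @param perf_tau Time constant of the performance (filtered reward)
#'   readout.
#' @param perf_init Initial value of the performance readout.
#' @param n_trials Default number of trials per run.
#' @param steps_per_trial Euler sub-steps per trial for the relaxation
#'   terms (1 means the time constants are in trial units).
#' @return An object of class `network_params`.
#' @export
network_params <- function(alpha = 0.04, beta = 0.02, tau_tail = 100,
                           tau_decay = 100, perf_tau = 10,
                           perf_init = 0.5, n_trials = 100L,
                           steps_per_trial = 1L) {
  stopifnot(tau_tail > 0, tau_decay > 0, perf_tau > 0,
            alpha > 0, alpha < 1, beta > 0, beta < 1)
  structure(list(alpha = alpha, beta = beta, tau_tail = tau_tail,
                 tau_decay = tau_decay, perf_tau = perf_tau,
                 perf_init = perf_init, n_trials = as.integer(n_trials),
                 steps_per_trial = as.integer(steps_per_trial)),
            class = "network_params")
}

#' Initialize the network state
#'
#' Actor and tail weights start at 1 (their decay steady state), the
#' critic at 0, and the predicted-action filter at 0. Weight matrices are
#' actions x states.
#'
#' @param params [network_params()].
#' @return An environment of class `network_state`.
#' @export
network_init <- function(params = network_params()) {
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$W_actor <- matrix(1, 2, 2)
  st$W_tail <- matrix(1, 2, 2)
  st$W_critic <- c(0, 0)
  st$p_a <- c(0, 0)
  st$clock <- 0L
  st$frozen <- character(0)
  class(st) <- c("network_state", "environment")
  st
}

#' Forward pass: choose an action
#'
#' `A_total = W_actor s + W_tail s + noise` with independent uniform(0, 1)
#' noise per action component; the chosen action is the argmax (ties,
#' measure-zero under the noise, break to the lower index).
#'
#' @param s Sensory state: a two-component non-negative vector (one-hot or
#'   graded `(1 - d, d)`).
#' @param state [network_init()] environment.
#' @param noise Optional fixed noise vector (for testing); drawn if `NULL`.
#' @return List with `a` (1 or 2), `A_total`, `A_actor`, `A_tail`, `noise`.
#' @export
network_forward <- function(s, state, noise = NULL) {
  stopifnot(length(s) == 2L, all(s >= 0))
  if (is.null(noise)) noise <- runif(2)
  a_actor <- drop(state$W_actor %*% s)
  a_tail <- drop(state$W_tail %*% s)
  total <- a_actor + a_tail + noise
  list(a = which.max(total), A_total = total, A_actor = a_actor,
       A_tail = a_tail, noise = noise)
}

#' Reward rule
#'
#' Reward 1 when the chosen action index matches the (dominant) stimulus
#' index: `s = 1, a = 1` or `s = 2, a = 2`; graded stimuli reward the
#' argmax of `s`.
#'
#' @param s Stimulus vector (length 2).
#' @param a Chosen action index.
#' @return 0 or 1.
#' @export
reward_rule <- function(s, a) {
  as.numeric(a == which.max(s))
}

#' Network APE
#'
#' Binarizes the instantaneous tail output (1 at its argmax), advances the
#' predicted-action filter `tau_tail dp/dt = -p + binary` by one Euler
#' step, and returns `delta_APE = 1 - p_a[a]` for the taken action.
#' Mutates `state$p_a`.
#'
#' @param a Taken action index.
#' @param a_tail Tail controller output vector from the forward pass.
#' @param state [network_init()] environment.
#' @return Scalar `delta_APE`.
#' @export
network_ape <- function(a, a_tail, state) {
  p <- state$params
  binary <- c(0, 0)
  binary[which.max(a_tail)] <- 1
  dt <- 1 / p$steps_per_trial
  state$p_a <- state$p_a + dt * (binary - state$p_a) / p$tau_tail
  1 - state$p_a[a]
}

#' Apply the three-factor weight updates
#'
#' `W_tail += beta * delta_APE * (a x s)`, `W_actor += alpha * delta_RPE *
#' (a x s)`, `W_critic += alpha * delta_RPE * s`; the actor additionally
#' relaxes towards its steady state of 1 with time constant `tau_decay`.
#' All weights are clipped at 0. Controllers named in `state$frozen`
#' ("tail", "actor") receive no update.
#'
#' @param state [network_init()] environment (mutated).
#' @param s Stimulus vector.
#' @param a Taken action index.
#' @param delta_rpe,delta_ape The two teaching signals.
#' @return The state, invisibly.
#' @export
network_update <- function(state, s, a, delta_rpe, delta_ape) {
  p <- state$params
  avec <- c(0, 0)
  avec[a] <- 1
  outer_as <- avec %o% s
  dt <- 1 / p$steps_per_trial
  if (!"tail" %in% state$frozen) {
    state$W_tail <- pmax(state$W_tail + p$beta * delta_ape * outer_as, 0)
  }
  if (!"actor" %in% state$frozen) {
    w <- state$W_actor + p$alpha * delta_rpe * outer_as
    for (i in seq_len(p$steps_per_trial)) {
      w <- w + dt * (1 - w) / p$tau_decay
    }
    state$W_actor <- pmax(w, 0)
    state$W_critic <- pmax(state$W_critic + p$alpha * delta_rpe * s, 0)
  }
  state$clock <- state$clock + 1L
  invisible(state)
}

run_network_trials <- function(params, n_trials,
                               controllers = c("actor", "tail"),
                               lesion = NULL, lesion_time = NULL,
                               stimulation = "none", contra_state = 2L,
                               fixed_s = NULL, stimulus_levels = NULL,
                               stim_onset = 0L,
                               stim_trigger = c("choice", "stimulus")) {
  stim_trigger <- match.arg(stim_trigger)
  state <- network_init(params)
  if (!"tail" %in% controllers) {
    state$W_tail[] <- 0
    state$frozen <- c(state$frozen, "tail")
  }
  if (!"actor" %in% controllers) {
    state$W_actor[] <- 0
    state$W_critic[] <- 0
    state$frozen <- c(state$frozen, "actor")
  }
  perf <- params$perf_init
  out <- data.frame(trial = seq_len(n_trials), s = NA_integer_,
                    a = NA_integer_, r = NA_real_,
                    delta_rpe = NA_real_, delta_ape = NA_real_,
                    performance = NA_real_)
  wt <- matrix(NA_real_, n_trials, 4)  # tail weight snapshots
  wa <- matrix(NA_real_, n_trials, 4)
  for (t in seq_len(n_trials)) {
    if (!is.null(lesion) && !is.null(lesion_time) && t == lesion_time + 1L) {
      if (lesion == "tail") {
        state$W_tail[] <- 0
        state$frozen <- union(state$frozen, "tail")
      } else if (lesion == "actor") {
        state$W_actor[] <- 0
        state$W_critic[] <- 0
        state$frozen <- union(state$frozen, "actor")
      }
    }
    if (!is.null(fixed_s)) {
      s <- fixed_s
      si <- which.max(s)
      # fully ambiguous stimulus: either side may be rewarded
      r_side <- if (abs(s[1] - s[2]) < 1e-9) sample.int(2L, 1L) else si
    } else if (!is.null(stimulus_levels)) {
      d <- stimulus_levels[sample.int(length(stimulus_levels), 1L)]
      s <- c(1 - d, d)
      si <- which.max(s)
      # the ambiguous level rewards either side at random
      r_side <- if (abs(d - 0.5) < 1e-9) sample.int(2L, 1L) else si
    } else {
      si <- sample.int(2L, 1L)
      s <- c(0, 0)
      s[si] <- 1
      r_side <- si
    }
    fw <- network_forward(s, state)
    a <- fw$a
    r <- as.numeric(a == r_side)
    delta_rpe <- r - sum(state$W_critic * s)
    delta_ape <- network_ape(a, fw$A_tail, state)
    if (stimulation == "double_ape_contra" && t > stim_onset) {
      triggered <- if (stim_trigger == "choice") {
        a == contra_state
      } else {
        si == contra_state
      }
      if (triggered) delta_ape <- 2 * delta_ape
    }
    network_update(state, s, a, delta_rpe, delta_ape)
    perf <- perf + (r - perf) / params$perf_tau
    out$s[t] <- si; out$a[t] <- a; out$r[t] <- r
    out$delta_rpe[t] <- delta_rpe; out$delta_ape[t] <- delta_ape
    out$performance[t] <- perf
    wt[t, ] <- as.numeric(state$W_tail)
    wa[t, ] <- as.numeric(state$W_actor)
  }
  out$correct <- out$r
  attr(out, "W_tail") <- wt
  attr(out, "W_actor") <- wa
  attr(out, "final_state") <- state
  out
}

#' Run a dual-controller experiment
#'
#' Protocols:
#' * `learning`: the full model; performance is the reward low-pass
#'   filtered with `perf_tau`, starting from `perf_init`.
#' * `value_based_only` / `value_free_only`: the other controller's
#'   weights are clamped at 0 throughout.
#' * `lesion`: at `lesion_time` the named controller's weights are set to
#'   0 and frozen.
#' * `stimulation`: from `stim_onset` on, `delta_APE` is doubled on
#'   triggered trials -- by default trials where the contralateral action
#'   (`contra_state` index) was chosen, mirroring the choice-coupled
#'   optogenetic excitation protocol (a 150-trial unstimulated baseline
#'   followed by stimulation); `stim_trigger = "stimulus"` instead
#'   triggers on contralateral-stimulus trials. The session uses the
#'   seven-level psychometric stimulus set so that ambiguous trials keep
#'   expressing the induced bias.
#' * `psychometric`: sweeps difficulty `d` over `d_grid` with
#'   `s = (1 - d, d)` and reports the proportion of action-2 choices.
#'
#' @param kind Experiment kind (see Details).
#' @param params [network_params()].
#' @param n_agents Independent repeats (seeded `seed + i - 1`).
#' @param seed Base seed.
#' @param n_trials Trials per run (defaults to `params$n_trials`).
#' @param lesion `"tail"` or `"actor"` for `kind = "lesion"`.
#' @param lesion_time Trial after which the lesion applies.
#' @param contra_state Stimulus/action index treated as contralateral.
#' @param d_grid Difficulty grid for `psychometric`.
#' @param stimulus_levels Per-trial difficulty levels for `stimulation`
#'   (`NULL` gives one-hot stimuli).
#' @param stim_onset Trial after which stimulation engages.
#' @param stim_trigger `"choice"` (default) or `"stimulus"`.
#' @return For `psychometric`, a data frame of choice proportions per
#'   difficulty; otherwise a list of per-agent trial data frames (class
#'   `network_experiment`).
#' @export
run_experiment <- function(kind = c("learning", "lesion", "psychometric",
                                    "stimulation", "value_free_only",
                                    "value_based_only"),
                           params = network_params(), n_agents = 1L,
                           seed = 1L, n_trials = NULL, lesion = "tail",
                           lesion_time = 100L, contra_state = 2L,
                           d_grid = seq(0, 1, by = 0.1),
                           stimulus_levels = NULL, stim_onset = 150L,
                           stim_trigger = "choice") {
  kind <- match.arg(kind)
  if (is.null(n_trials)) n_trials <- params$n_trials
  check_count(n_agents, "n_agents")

  if (kind == "psychometric") {
    res <- lapply(d_grid, function(d) {
      props <- vapply(seq_len(n_agents), function(i) {
        with_seed(seed + i - 1L, {
          run <- run_network_trials(params, n_trials,
                                    fixed_s = c(1 - d, d))
          mean(run$a == 2L)
        })
      }, numeric(1))
      data.frame(d = d, prop_action2 = mean(props))
    })
    return(do.call(rbind, res))
  }

  controllers <- switch(kind,
                        value_free_only = "tail",
                        value_based_only = "actor",
                        c("actor", "tail"))
  les <- if (kind == "lesion") lesion else NULL
  les_t <- if (kind == "lesion") lesion_time else NULL
  stim <- if (kind == "stimulation") "double_ape_contra" else "none"
  if (kind == "stimulation" && is.null(stimulus_levels)) {
    stimulus_levels <- seq(0, 1, length.out = 7)
  }
  onset <- if (kind == "stimulation") stim_onset else 0L
  runs <- lapply(seq_len(n_agents), function(i) {
    with_seed(seed + i - 1L, {
      r <- run_network_trials(params, n_trials, controllers = controllers,
                              lesion = les, lesion_time = les_t,
                              stimulation = stim,
                              contra_state = contra_state,
                              stimulus_levels = stimulus_levels,
                              stim_onset = onset,
                              stim_trigger = stim_trigger)
      r$agent <- i
      r
    })
  })
  structure(runs, class = "network_experiment", kind = kind)
}

#' Trials needed to reach a performance criterion
#'
#' With `sustain > 1` the criterion must be reached and then held for
#' `sustain` consecutive trials (the usual trials-to-criterion definition
#' in learning studies, robust to transient threshold crossings of the
#' filtered performance).
#'
#' @param run A per-agent trial data frame from [run_experiment()].
#' @param criterion Performance level to reach.
#' @param sustain Number of consecutive trials the criterion must hold.
#' @return First trial of the qualifying run, or `Inf` if never reached.
#' @export
trials_to_criterion <- function(run, criterion = 0.75, sustain = 1L) {
  ok <- run$performance >= criterion
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values & r$lengths >= sustain)
  if (length(cand)) starts[cand[1]] else Inf
}

#' Paired stimulation versus control bias across a session
#'
#' Runs, for each seed, a matched pair of sessions (identical stimulus and
#' noise streams): one with APE doubling engaged after `stim_onset`
#' (choice-triggered, see [run_experiment()]) and one without. Reports the
#' contralateral-choice bias (stimulated minus control proportion of
#' `contra_state` choices) in an early and a late post-onset window, and
#' their difference (`growth`).
#'
#' @param params [network_params()].
#' @param n_seeds Number of paired seeds.
#' @param n_trials Session length.
#' @param stim_onset Baseline length before stimulation engages.
#' @param window Width (trials) of the early/late comparison windows.
#' @param contra_state Contralateral action index.
#' @param seed Base seed.
#' @return Data frame with one row per seed: `bias_early`, `bias_late`,
#'   `growth`.
#' @export
stimulation_bias_experiment <- function(params = network_params(),
                                        n_seeds = 20L, n_trials = 450L,
                                        stim_onset = 150L, window = 100L,
                                        contra_state = 2L, seed = 1L) {
  levels7 <- seq(0, 1, length.out = 7)
  one <- function(i, stim) {
    with_seed(seed + i - 1L, {
      run_network_trials(params, n_trials,
                         stimulation = if (stim) "double_ape_contra"
                                       else "none",
                         contra_state = contra_state,
                         stimulus_levels = levels7,
                         stim_onset = stim_onset)
    })
  }
  res <- lapply(seq_len(n_seeds), function(i) {
    st <- one(i, TRUE)
    ct <- one(i, FALSE)
    w1 <- (stim_onset + 1L):(stim_onset + window)
    w2 <- (n_trials - window + 1L):n_trials
    b1 <- mean(st$a[w1] == contra_state) - mean(ct$a[w1] == contra_state)
    b2 <- mean(st$a[w2] == contra_state) - mean(ct$a[w2] == contra_state)
    data.frame(seed = seed + i - 1L, bias_early = b1, bias_late = b2,
               growth = b2 - b1)
  })
  do.call(rbind, res)
}

#' Mean performance in the 10 trials after a lesion
#'
#' @param run A per-agent trial data frame.
#' @param lesion_time Lesion trial.
#' @param n_after Number of post-lesion trials to average (default 10).
#' @return Mean filtered performance over those trials.
#' @export
post_lesion_performance <- function(run, lesion_time, n_after = 10L) {
  idx <- (lesion_time + 1L):min(lesion_time + n_after, nrow(run))
  mean(run$performance[idx])
}
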