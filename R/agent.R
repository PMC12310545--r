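# Semi-Markov actor-critic agent with value-free APE learner and the
# novelty / salience / movement candidate dopamine signal models.
#
# The agent tracks state identity plus dwell time and updates only at state
# transitions. Within a trial the state sequence is
#   Start -> cue (HighTone / LowTone / WhiteNoise)
#         -> action state (cue x chosen side)
#         -> Outcome -> Start,
# with actions Left, Right, Centre and Idle.

AGENT_STATES <- c("Start", "HighTone", "LowTone", "WhiteNoise",
                  "High_Left", "High_Right", "Low_Left", "Low_Right",
                  "WN_Left", "WN_Right", "Outcome")
AGENT_ACTIONS <- c("Left", "Right", "Centre", "Idle")

#' Parameters of the semi-Markov agent
#'
#' @param alpha Critic learning rate.
#' @param beta Actor learning rate.
#' @param epsilon Stimulus-action (APE) learning rate; 0.001 is used for the
#'   predicted-value simulation to reflect a slowly updating value-free
#'   controller.
#' @param psi Baseline dopamine constant added before rectification of the
#'   RPE output signal.
#' @param gamma Novelty decay rate with state exposure.
#' @param mu Weight of value in the salience signal (`L = V/mu + N`).
#' @param inverse_temperature Softmax inverse temperature (5 default; 0.5
#'   for the previous-choice simulation, giving more exploratory choices).
#' @param rho_window Number of recent transitions over which the average
#'   reward per unit time is computed.
#' @return An object of class `agent_params`.
#' @export
agent_params <- function(alpha = 0.005, beta = 0.005, epsilon = 0.01,
                         psi = 0.2, gamma = 0.01, mu = 0.5,
                         inverse_temperature = 5, rho_window = 500L) {
  for (r in c(alpha = alpha, beta = beta, epsilon = epsilon)) {
    if (r < 0 || r > 1) stop_domain("learning rates must lie in [0, 1]")
  }
  if (inverse_temperature < 0) {
    stop_domain("inverse_temperature must be >= 0")
  }
  check_count(rho_window, "rho_window")
  structure(list(alpha = alpha, beta = beta, epsilon = epsilon, psi = psi,
                 gamma = gamma, mu = mu,
                 inverse_temperature = inverse_temperature,
                 rho_window = as.integer(rho_window)),
            class = "agent_params")
}

#' Initialize a fresh agent
#'
#' Creates the mutable agent state: critic values `V`, actor strengths `m`,
#' stimulus-action strengths `A`, visit counters and the reward/dwell
#' history buffer behind the average-reward estimate. All values start at
#' zero.
#'
#' @param params An [agent_params()] object.
#' @return An environment of class `agent_state`.
#' @export
agent_init <- function(params = agent_params()) {
  ns <- length(AGENT_STATES)
  na <- length(AGENT_ACTIONS)
  ag <- new.env(parent = emptyenv())
  ag$params <- params
  ag$V <- setNames(numeric(ns), AGENT_STATES)
  ag$m <- matrix(0, ns, na, dimnames = list(AGENT_STATES, AGENT_ACTIONS))
  ag$A <- matrix(0, ns, na, dimnames = list(AGENT_STATES, AGENT_ACTIONS))
  ag$visits <- setNames(integer(ns), AGENT_STATES)
  w <- params$rho_window
  ag$r_buf <- numeric(w)
  ag$d_buf <- numeric(w)
  ag$buf_len <- 0L
  ag$buf_pos <- 0L
  ag$sum_r <- 0
  ag$sum_d <- 0
  class(ag) <- c("agent_state", "environment")
  ag
}

#' Average reward per unit time
#'
#' Computes the average reward rate over the trailing `window` transitions:
#' the sum of rewards divided by the sum of dwell times. For fewer than
#' `window` transitions all available history is used; an empty history
#' returns 0.
#'
#' @param rewards,dwells Per-transition reward and dwell-time vectors.
#' @param window Number of trailing transitions to use.
#' @return The average reward rate (scalar).
#' @export
average_reward <- function(rewards, dwells, window = 500L) {
  stopifnot(length(rewards) == length(dwells))
  if (length(rewards) == 0L) return(0)
  n <- min(length(rewards), window)
  r <- tail(rewards, n)
  d <- tail(dwells, n)
  sd_ <- sum(d)
  if (sd_ <= 0) 0 else sum(r) / sd_
}

#' Dwell-time scaled reward prediction error
#'
#' `delta = r - rho * dwell + V(s') - V(s)`: the semi-Markov RPE in which
#' the opportunity cost of time spent in the departed state (average reward
#' `rho` times dwell time) substitutes for exponential discounting.
#'
#' @param r Reward received on entering the new state.
#' @param dwell Time spent in the departed state.
#' @param v_from,v_to Critic values of the departed and entered states.
#' @param rho Average reward per unit time.
#' @return The raw prediction error (scalar).
#' @export
compute_rpe <- function(r, dwell, v_from, v_to, rho) {
  r - rho * dwell + v_to - v_from
}

#' Rectified RPE output signal
#'
#' The modelled dopamine observation is `max(0, delta + psi)`: the raw
#' prediction error shifted by a baseline dopamine constant and rectified
#' at zero.
#'
#' @param delta Raw prediction error(s).
#' @param psi Baseline constant.
#' @return Non-negative signal value(s).
#' @export
rpe_output <- function(delta, psi = 0.2) {
  pmax(0, delta + psi)
}

#' Action prediction error
#'
#' The APE is the difference between the action taken (one-hot) and the
#' stimulus-action strengths for the current stimulus, rectified so that
#' only the taken action's component (when positive) survives - a scalar
#' value-free teaching signal.
#'
#' @param action Index or name of the taken action among `actions`.
#' @param strengths Stimulus-action strength vector `A(s, .)`.
#' @param actions Action names (defaults to the strength vector's names).
#' @return List with `vector` (rectified APE vector) and `scalar`.
#' @export
compute_ape <- function(action, strengths,
                        actions = names(strengths)) {
  if (is.character(action)) action <- match(action, actions)
  vec <- numeric(length(strengths))
  vec[action] <- max(0, 1 - strengths[[action]])
  list(vector = vec, scalar = vec[action])
}

#' Update stimulus-action strengths from an APE
#'
#' `A(s, a) <- A(s, a) + epsilon * delta_ape` for the taken action only
#' (the rectified APE has a single non-zero component).
#'
#' @param strengths Strength vector `A(s, .)`.
#' @param action Taken action (index or name).
#' @param ape Rectified scalar APE.
#' @param epsilon Stimulus-action learning rate.
#' @return Updated strength vector.
#' @export
update_stimulus_action <- function(strengths, action, ape, epsilon) {
  if (is.character(action)) action <- match(action, names(strengths))
  strengths[action] <- strengths[action] + epsilon * ape
  strengths
}

#' Novelty and salience of a state
#'
#' Novelty decays exponentially with exposure: `N(s) = exp(-gamma * I(s))`
#' where `I(s)` counts visits (already including the current one).
#' Salience combines value and novelty: `L(s) = V(s) / mu + N(s)`.
#'
#' @param v Critic value of the state.
#' @param visits Visit count `I(s)`.
#' @param gamma Novelty decay rate.
#' @param mu Salience value weight.
#' @return List with `novelty` and `salience`.
#' @export
novelty_salience <- function(v, visits, gamma = 0.01, mu = 0.5) {
  n <- exp(-gamma * visits)
  list(novelty = n, salience = v / mu + n)
}

#' Softmax action probabilities
#'
#' `P(a)` proportional to `exp(inverse_temperature * m(s, a))`, computed
#' with the max-subtraction trick for numerical stability.
#'
#' @param strengths Actor strengths for the available actions.
#' @param inverse_temperature Inverse temperature (0 gives uniform).
#' @return Probability vector over the actions.
#' @export
softmax_policy <- function(strengths, inverse_temperature = 5) {
  z <- inverse_temperature * strengths
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Advance the agent through one state transition
#'
#' Computes the average reward, the dwell-scaled RPE and its rectified
#' output, the APE (for Left/Right action transitions), the novelty and
#' salience of the entered state, then applies the critic/actor and
#' stimulus-action updates and pushes the transition into the
#' average-reward history. Mutates `agent` in place.
#'
#' @param agent An [agent_init()] environment.
#' @param from,to State names (see `AGENT_STATES` in the package source).
#' @param action Action name taken to leave `from`.
#' @param reward Reward received on entering `to` (dimensionless; 1 for the
#'   standard 2 ul reward).
#' @param dwell Time spent in `from` (> 0).
#' @return List with `rho`, `delta`, `rpe_signal`, `ape`, `novelty`,
#'   `salience` and the one-hot `movement` vector.
#' @export
agent_step <- function(agent, from, to, action, reward = 0, dwell = 1) {
  stopifnot(inherits(agent, "agent_state"))
  if (dwell <= 0) stop_domain("dwell time must be > 0")
  p <- agent$params
  si <- match(from, AGENT_STATES)
  sj <- match(to, AGENT_STATES)
  ai <- match(action, AGENT_ACTIONS)
  if (is.na(si) || is.na(sj)) stop_domain("unknown state")
  if (is.na(ai)) stop_domain("unknown action")

  rho <- if (agent$sum_d > 0) agent$sum_r / agent$sum_d else 0
  delta <- reward - rho * dwell + agent$V[[sj]] - agent$V[[si]]
  sig <- max(0, delta + p$psi)

  agent$V[[si]] <- agent$V[[si]] + p$alpha * delta
  agent$m[si, ai] <- agent$m[si, ai] + p$beta * delta

  ape <- 0
  if (ai <= 2L) {  # Left / Right: an instrumental action carrying APE
    ape <- max(0, 1 - agent$A[si, ai])
    agent$A[si, ai] <- agent$A[si, ai] + p$epsilon * ape
  }

  agent$visits[[sj]] <- agent$visits[[sj]] + 1L
  nov <- exp(-p$gamma * agent$visits[[sj]])
  sal <- agent$V[[sj]] / p$mu + nov

  # ring buffer backing the average-reward window
  w <- p$rho_window
  pos <- (agent$buf_pos %% w) + 1L
  if (agent$buf_len == w) {
    agent$sum_r <- agent$sum_r - agent$r_buf[pos]
    agent$sum_d <- agent$sum_d - agent$d_buf[pos]
  } else {
    agent$buf_len <- agent$buf_len + 1L
  }
  agent$r_buf[pos] <- reward
  agent$d_buf[pos] <- dwell
  agent$sum_r <- agent$sum_r + reward
  agent$sum_d <- agent$sum_d + dwell
  agent$buf_pos <- pos

  movement <- numeric(length(AGENT_ACTIONS))
  movement[ai] <- 1
  list(rho = rho, delta = delta, rpe_signal = sig, ape = ape,
       novelty = nov, salience = sal, movement = movement)
}

# Median dwell times (s): Start holds only the brief pre-cue centre poke;
# the consume/return interval is spent in the Outcome state.
agent_dwell_defaults <- c(start = 0.2, cue = 0.7, action = 0.68,
                          outcome = 2.5)

run_one_agent <- function(variant, params, n_trials, switch_trial,
                          dwell_medians, dwell_sdlog = 0.3,
                          pretrain_trials = 0L) {
  ag <- agent_init(params)
  nk <- n_trials * 4L
  tr_trial <- integer(nk); tr_phase <- character(nk)
  tr_from <- character(nk); tr_to <- character(nk)
  tr_action <- character(nk); tr_dwell <- numeric(nk)
  tr_reward <- numeric(nk); tr_delta <- numeric(nk)
  tr_sig <- numeric(nk); tr_ape <- numeric(nk)
  tr_nov <- numeric(nk); tr_sal <- numeric(nk)

  t_cue <- character(n_trials); t_choice <- character(n_trials)
  t_correct <- logical(n_trials); t_reward <- numeric(n_trials)
  t_outcome_type <- character(n_trials)

  k <- 0L
  push <- function(trial, phase, from, to, action, reward, dwell) {
    res <- agent_step(ag, from, to, action, reward, dwell)
    k <<- k + 1L
    tr_trial[k] <<- trial; tr_phase[k] <<- phase
    tr_from[k] <<- from; tr_to[k] <<- to; tr_action[k] <<- action
    tr_dwell[k] <<- dwell; tr_reward[k] <<- reward
    tr_delta[k] <<- res$delta; tr_sig[k] <<- res$rpe_signal
    tr_ape[k] <<- res$ape; tr_nov[k] <<- res$novelty
    tr_sal[k] <<- res$salience
    res
  }
  dm <- dwell_medians
  rl <- function(m) rlnorm(1, log(m), dwell_sdlog)

  # unrecorded pretraining on the standard task (manipulation sessions are
  # run in trained animals)
  for (i in seq_len(pretrain_trials)) {
    cue <- if (runif(1) < 0.5) "HighTone" else "LowTone"
    correct_action <- if (cue == "LowTone") "Right" else "Left"
    agent_step(ag, "Start", cue, "Centre", 0, rl(dm[["start"]]))
    pr <- softmax_policy(ag$m[cue, c("Left", "Right")],
                         params$inverse_temperature)
    choice <- if (runif(1) < pr[1]) "Left" else "Right"
    astate <- paste0(if (cue == "HighTone") "High" else "Low", "_", choice)
    agent_step(ag, cue, astate, choice, 0, rl(dm[["cue"]]))
    reward <- as.numeric(choice == correct_action)
    agent_step(ag, astate, "Outcome", "Idle", reward, rl(dm[["action"]]))
    agent_step(ag, "Outcome", "Start", "Idle", 0, rl(dm[["outcome"]]))
  }

  for (i in seq_len(n_trials)) {
    idx0 <- i - 1L
    cue <- if (runif(1) < 0.5) "HighTone" else "LowTone"
    if (variant == "state_change" && idx0 >= switch_trial &&
        cue == "HighTone") {
      cue <- "WhiteNoise"
    }
    correct_action <- if (cue == "LowTone") "Right" else "Left"

    push(idx0, "cue", "Start", cue, "Centre", 0, rl(dm[["start"]]))

    pr <- softmax_policy(ag$m[cue, c("Left", "Right")],
                         params$inverse_temperature)
    choice <- if (runif(1) < pr[1]) "Left" else "Right"
    astate <- paste0(switch(cue, HighTone = "High", LowTone = "Low",
                            WhiteNoise = "WN"), "_", choice)
    push(idx0, "choice", cue, astate, choice, 0, rl(dm[["cue"]]))

    correct <- choice == correct_action
    reward <- if (correct) 1 else 0
    otype <- if (correct) "standard" else "error"
    if (variant == "outcome_value" && correct) {
      u <- runif(1)
      if (u < 0.1) {
        reward <- 0; otype <- "omission"
      } else if (u < 0.2) {
        reward <- 3; otype <- "large"
      }
    } else if (variant == "predicted_value" && correct &&
               idx0 >= switch_trial && choice == "Left") {
      reward <- 3; otype <- "large"
    }
    push(idx0, "outcome", astate, "Outcome", "Idle", reward,
         rl(dm[["action"]]))
    push(idx0, "return", "Outcome", "Start", "Idle", 0, rl(dm[["outcome"]]))

    t_cue[i] <- cue; t_choice[i] <- choice; t_correct[i] <- correct
    t_reward[i] <- reward; t_outcome_type[i] <- otype
  }
  list(transitions = data.frame(trial = tr_trial, phase = tr_phase,
                                from = tr_from, to = tr_to,
                                action = tr_action, dwell = tr_dwell,
                                reward = tr_reward, rpe_raw = tr_delta,
                                rpe_signal = tr_sig, ape = tr_ape,
                                novelty = tr_nov, salience = tr_sal,
                                stringsAsFactors = FALSE),
       trials = data.frame(trial = seq_len(n_trials) - 1L, cue = t_cue,
                           choice = t_choice, correct = t_correct,
                           reward = t_reward,
                           outcome_type = t_outcome_type,
                           stringsAsFactors = FALSE),
       agent_state = ag)
}

#' Simulate learning with the semi-Markov agent
#'
#' Runs `n_agents` independent agents through `n_trials` of the task and
#' returns per-transition traces of all five candidate dopamine signals
#' (raw and rectified RPE, APE, novelty, salience; the movement model is
#' the recorded action itself) together with a trial-level log.
#'
#' Variants: `standard` (also used for the previous-choice simulation with
#' `inverse_temperature = 0.5`), `state_change` (the high-octave cue is
#' replaced by a novel white-noise state from `switch_trial`),
#' `outcome_value` (6 ul rewards and omissions, probability 0.1 each,
#' modelled as rewards 3 and 0 versus the standard 1) and
#' `predicted_value` (the left port pays 3 from `switch_trial`; pass
#' `epsilon = 0.001` via `params` for the slow value-free update used
#' there).
#'
#' @param variant Task variant (see Details).
#' @param params [agent_params()].
#' @param n_trials Trials per agent.
#' @param n_agents Number of agents (each seeded `seed + agent - 1`).
#' @param seed Base seed.
#' @param switch_trial Trial (0-based) of the state/value switch.
#' @param pretrain_trials Unrecorded standard-task trials run before the
#'   logged session (manipulations such as the state change are performed
#'   in trained animals whose critic has converged).
#' @param dwell_medians Median dwell times (s) of the four within-trial
#'   states.
#' @return List with data frames `transitions` and `trials`, each carrying
#'   an `agent` column.
#' @export
simulate_learning <- function(variant = c("standard", "state_change",
                                          "outcome_value",
                                          "predicted_value"),
                              params = agent_params(), n_trials = 300L,
                              n_agents = 1L, seed = 1L,
                              switch_trial = 150L, pretrain_trials = 0L,
                              dwell_medians = agent_dwell_defaults) {
  variant <- match.arg(variant)
  check_count(n_trials, "n_trials")
  check_count(n_agents, "n_agents")
  runs <- lapply(seq_len(n_agents), function(a) {
    with_seed(seed + a - 1L, {
      r <- run_one_agent(variant, params, n_trials, switch_trial,
                         dwell_medians, pretrain_trials = pretrain_trials)
      r$transitions$agent <- a
      r$trials$agent <- a
      r
    })
  })
  list(transitions = do.call(rbind, lapply(runs, `[[`, "transitions")),
       trials = do.call(rbind, lapply(runs, `[[`, "trials")),
       params = params, variant = variant)
}

# Mean of a signal on selected transitions, per agent.
agent_means <- function(tr, rows, col) {
  vapply(split(tr[rows, col], tr$agent[rows]), mean, numeric(1))
}

#' Predicted direction of change for each candidate dopamine model
#'
#' Simulates the battery of manipulations (learning, previous-choice
#' repeat versus switch, state change, outcome value, predicted value) and
#' tabulates the sign of the mean change of each candidate signal (APE,
#' RPE, movement, novelty, salience) under each manipulation. APE and
#' movement are read at the choice transition; RPE, novelty and salience
#' at the cue transition, except for the outcome-value and predicted-value
#' manipulations where the outcome transition is used.
#'
#' A change is reported as `"0"` when the across-agent mean is within two
#' standard errors of zero (or exactly zero for deterministic signals),
#' `"+"`/`"-"` otherwise.
#'
#' @param params Base [agent_params()].
#' @param n_trials,n_agents,seed Simulation size and seeding.
#' @return Character matrix, models by manipulations.
#' @export
condition_battery <- function(params = agent_params(), n_trials = 300L,
                              n_agents = 20L, seed = 1L) {
  models <- c("APE", "RPE", "movement", "novelty", "salience")
  manips <- c("learning", "previous_choice", "state_change",
              "outcome_value", "predicted_value")
  out <- matrix("0", length(models), length(manips),
                dimnames = list(models, manips))

  sign_of <- function(changes) {
    changes <- changes[!is.na(changes)]
    if (length(changes) == 0L) return("0")
    m <- mean(changes)
    s <- sd(changes)
    if (is.na(s) || s == 0) {
      if (m == 0) "0" else if (m > 0) "+" else "-"
    } else if (abs(m) < 2 * s / sqrt(length(changes))) {
      "0"
    } else if (m > 0) "+" else "-"
  }
  movement_signal <- function(tr, rows) {
    # one-hot action vector: magnitude of the taken-action component
    as.numeric(tr$action[rows] %in% c("Left", "Right"))
  }
  per_agent_change <- function(tr, rows_a, rows_b, col) {
    agents <- sort(unique(tr$agent))
    va <- if (identical(col, "movement")) {
      tapply(movement_signal(tr, rows_a), tr$agent[rows_a], mean)
    } else {
      tapply(tr[rows_a, col], tr$agent[rows_a], mean)
    }
    vb <- if (identical(col, "movement")) {
      tapply(movement_signal(tr, rows_b), tr$agent[rows_b], mean)
    } else {
      tapply(tr[rows_b, col], tr$agent[rows_b], mean)
    }
    vb[as.character(agents)] - va[as.character(agents)]
  }
  col_for <- function(model) switch(model, APE = "ape", RPE = "rpe_signal",
                                    movement = "movement",
                                    novelty = "novelty",
                                    salience = "salience")
  phase_for <- function(model, manip) {
    if (model %in% c("APE", "movement")) return("choice")
    if (manip %in% c("outcome_value", "predicted_value")) return("outcome")
    "cue"
  }

  # learning: first versus last decile of correct contralateral trials
  sim <- simulate_learning("standard", params, n_trials, n_agents, seed)
  tr <- sim$transitions
  contra <- sim$trials$correct & sim$trials$choice == "Left"
  key <- paste(tr$agent, tr$trial)
  ckey <- paste(sim$trials$agent, sim$trials$trial)
  on_contra <- key %in% ckey[contra]
  dec <- n_trials %/% 10L
  for (mdl in models) {
    ph <- phase_for(mdl, "learning")
    ra <- which(on_contra & tr$phase == ph & tr$trial < dec)
    rb <- which(on_contra & tr$phase == ph & tr$trial >= n_trials - dec)
    out[mdl, "learning"] <- sign_of(per_agent_change(tr, ra, rb,
                                                     col_for(mdl)))
  }

  # previous choice: repeat versus switch under exploratory softmax
  pexp <- params; pexp$inverse_temperature <- 0.5
  sim <- simulate_learning("standard", pexp, n_trials, n_agents, seed + 101L)
  tr <- sim$transitions
  tl <- sim$trials
  rep_flag <- rep(NA, nrow(tl))
  for (a in unique(tl$agent)) {
    ix <- which(tl$agent == a)
    for (j in seq_along(ix)[-1]) {
      prev <- ix[j - 1L]
      cur <- ix[j]
      if (tl$cue[cur] == tl$cue[prev]) {
        rep_flag[cur] <- tl$choice[cur] == tl$choice[prev]
      }
    }
  }
  key <- paste(tr$agent, tr$trial)
  ckey <- paste(tl$agent, tl$trial)
  for (mdl in models) {
    ph <- phase_for(mdl, "previous_choice")
    rs <- which(key %in% ckey[!is.na(rep_flag) & !rep_flag] & tr$phase == ph)
    rr <- which(key %in% ckey[!is.na(rep_flag) & rep_flag] & tr$phase == ph)
    out[mdl, "previous_choice"] <-
      sign_of(per_agent_change(tr, rs, rr, col_for(mdl)))
  }

  # state change: 50 trials before versus after the switched stimulus,
  # in trained agents
  st <- 150L
  sim <- simulate_learning("state_change", params, st + 50L, n_agents,
                           seed + 202L, switch_trial = st,
                           pretrain_trials = 1000L)
  tr <- sim$transitions
  tl <- sim$trials
  switched_pre <- tl$cue == "HighTone" & tl$trial >= st - 50L
  switched_post <- tl$cue == "WhiteNoise"
  key <- paste(tr$agent, tr$trial)
  ckey <- paste(tl$agent, tl$trial)
  for (mdl in models) {
    ph <- phase_for(mdl, "state_change")
    ra <- which(key %in% ckey[switched_pre] & tr$phase == ph)
    rb <- which(key %in% ckey[switched_post] & tr$phase == ph)
    out[mdl, "state_change"] <- sign_of(per_agent_change(tr, ra, rb,
                                                         col_for(mdl)))
  }

  # outcome value: large (3) versus standard (1) rewards
  sim <- simulate_learning("outcome_value", params, n_trials, n_agents,
                           seed + 303L)
  tr <- sim$transitions
  tl <- sim$trials
  key <- paste(tr$agent, tr$trial)
  ckey <- paste(tl$agent, tl$trial)
  for (mdl in models) {
    ph <- phase_for(mdl, "outcome_value")
    ra <- which(key %in% ckey[tl$outcome_type == "standard"] &
                  tr$phase == ph)
    rb <- which(key %in% ckey[tl$outcome_type == "large"] & tr$phase == ph)
    out[mdl, "outcome_value"] <- sign_of(per_agent_change(tr, ra, rb,
                                                          col_for(mdl)))
  }

  # predicted value: before versus after one port's reward is tripled
  ppv <- params; ppv$epsilon <- 0.001
  pv <- 100L
  sim <- simulate_learning("predicted_value", ppv, pv + 100L, n_agents,
                           seed + 404L, switch_trial = pv)
  tr <- sim$transitions
  tl <- sim$trials
  big <- tl$correct & tl$choice == "Left"
  key <- paste(tr$agent, tr$trial)
  ckey <- paste(tl$agent, tl$trial)
  for (mdl in models) {
    ph <- phase_for(mdl, "predicted_value")
    ra <- which(key %in% ckey[big & tl$trial < pv] & tr$phase == ph)
    rb <- which(key %in% ckey[big & tl$trial >= pv] & tr$phase == ph)
    out[mdl, "predicted_value"] <- sign_of(per_agent_change(tr, ra, rb,
                                                            col_for(mdl)))
  }
  out
}
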