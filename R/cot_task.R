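#' Tone-cloud stimulus specification
#'
#' Describes the auditory cloud-of-tones stimulus used to cue choices: a
#' stream of short pure tones (default 50 slots at 100 Hz, i.e. a 500 ms
#' cloud) where each slot independently contains a tone from the high octave
#' with probability `p_high` and a tone from the low octave with probability
#' `1 - p_high`. Because the draws are independent, both tones may sound in
#' the same slot.
#'
#' @param p_high Probability in \[0, 1\] that a slot contains a high-octave
#'   tone.
#' @param n_slots Number of 10 ms tone slots (50 = 500 ms at 100 Hz).
#' @param low_octave,high_octave Frequency ranges in Hz for the two octaves.
#' @param n_freqs_per_octave Number of log-spaced frequencies per octave.
#' @param amplitude_db Range of the overall cloud amplitude in dB SPL.
#' @return An object of class `tone_cloud_spec`.
#' @export
tone_cloud_spec <- function(p_high, n_slots = 50L,
                            low_octave = c(5000, 10000),
                            high_octave = c(20000, 40000),
                            n_freqs_per_octave = 16L,
                            amplitude_db = c(60, 80)) {
  check_prob(p_high, "p_high")
  check_count(n_slots, "n_slots")
  check_count(n_freqs_per_octave, "n_freqs_per_octave")
  structure(list(p_high = p_high, n_slots = as.integer(n_slots),
                 low_octave = low_octave, high_octave = high_octave,
                 n_freqs_per_octave = as.integer(n_freqs_per_octave),
                 amplitude_db = amplitude_db),
            class = "tone_cloud_spec")
}

#' Sample a tone cloud
#'
#' Draws one stimulus realisation from a [tone_cloud_spec()]. Per slot, the
#' presence of high- and low-octave tones is drawn independently and the tone
#' frequency is picked from the octave's log-spaced frequency set. The cloud
#' amplitude is drawn uniformly from the spec's dB range.
#'
#' @param spec A [tone_cloud_spec()].
#' @param seed Optional integer seed for reproducible draws.
#' @return A list with `slots` (data frame: `slot`, `has_high`, `has_low`,
#'   `freq_high`, `freq_low` in Hz, `NA` where absent) and `amplitude_db`.
#' @export
sample_tone_cloud <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "tone_cloud_spec"))
  with_seed(seed, {
    n <- spec$n_slots
    freqs_of <- function(range) {
      f <- exp(seq(log(range[1]), log(range[2]),
                   length.out = spec$n_freqs_per_octave))
      # pin the endpoints, which exp(log(.)) can miss by an ulp
      f[1] <- range[1]
      f[length(f)] <- range[2]
      f
    }
    high_set <- freqs_of(spec$high_octave)
    low_set <- freqs_of(spec$low_octave)
    has_high <- runif(n) < spec$p_high
    has_low <- runif(n) < (1 - spec$p_high)
    freq_high <- ifelse(has_high, sample(high_set, n, replace = TRUE), NA)
    freq_low <- ifelse(has_low, sample(low_set, n, replace = TRUE), NA)
    list(slots = data.frame(slot = seq_len(n), has_high = has_high,
                            has_low = has_low, freq_high = freq_high,
                            freq_low = freq_low),
         amplitude_db = runif(1, spec$amplitude_db[1], spec$amplitude_db[2]))
  })
}

#' Task configuration for the cloud-of-tones task
#'
#' Bundles the parameters of one behavioural session of the two-alternative
#' choice task, including the variant-specific manipulations used in the
#' photometry experiments.
#'
#' Variants:
#' * `standard`: easiest stimuli only (98/2% high tones), 2 ul reward.
#' * `psychometric`: seven equally spaced tone-ratio levels.
#' * `silence`: cue omitted on a random subset of trials (`silence_prob`).
#' * `state_change`: from `switch_trial` on, the cue for the contralateral
#'   side is replaced by a white-noise stimulus (flag `white_noise_cue`).
#' * `outcome_value`: unexpected 6 ul rewards and omissions, each with
#'   probability 0.1, on otherwise correct trials.
#' * `predicted_value`: from `switch_trial` on, one port pays 6 ul.
#' * `sound_on_return`: cue moved to the return period (flag
#'   `sound_on_return`).
#'
#' @param variant One of the variant names above.
#' @param stimulus_set Vector of `p_high` levels; defaults to `c(0.98, 0.02)`
#'   for the simple task and 7 equally spaced levels for `psychometric`.
#' @param switch_trial 0-based trial index at which `state_change` (default
#'   150) or `predicted_value` (default 100) engages.
#' @param hold_range Centre-port hold requirement in seconds (uniform).
#' @param cue_duration Cue length in seconds.
#' @param antibias_enabled Engage the anti-bias target-side protocol.
#' @param antibias_window Trials per anti-bias evaluation block.
#' @param antibias_gain Gain `k` of the anti-bias correction.
#' @param dwell_medians Named medians (s) of the log-normal dwell times for
#'   `hold`, `movement` and `return`.
#' @param dwell_sdlog Log-scale SD shared by the dwell distributions.
#' @param opto_prob Probability a trial is flagged `opto_stim`.
#' @param silence_prob Probability of a silence trial (silence variant).
#' @param high_side Side rewarded for high-octave stimuli.
#' @param big_reward_port Port paying 6 ul in `predicted_value`.
#' @return An object of class `task_config`.
#' @export
task_config <- function(variant = c("standard", "psychometric", "silence",
                                    "state_change", "outcome_value",
                                    "predicted_value", "sound_on_return"),
                        stimulus_set = NULL, switch_trial = NULL,
                        hold_range = c(0.1, 0.3), cue_duration = 0.5,
                        antibias_enabled = FALSE, antibias_window = 10L,
                        antibias_gain = 1,
                        dwell_medians = c(hold = 0.2, movement = 0.68,
                                          return = 1.5),
                        dwell_sdlog = 0.3, opto_prob = 0,
                        silence_prob = 0.1,
                        high_side = c("right", "left"),
                        big_reward_port = "right") {
  variant <- match.arg(variant)
  high_side <- match.arg(high_side)
  if (is.null(stimulus_set)) {
    stimulus_set <- if (variant == "psychometric") {
      seq(0, 1, length.out = 7)
    } else {
      c(0.98, 0.02)
    }
  }
  if (variant == "psychometric") {
    if (length(stimulus_set) != 7 ||
        max(abs(diff(diff(stimulus_set)))) > 1e-9) {
      stop_domain("psychometric variant requires exactly 7 equally spaced ",
                  "stimulus levels")
    }
  }
  if (is.null(switch_trial)) {
    switch_trial <- if (variant == "predicted_value") 100L else 150L
  }
  structure(list(variant = variant, stimulus_set = stimulus_set,
                 switch_trial = as.integer(switch_trial),
                 hold_range = hold_range, cue_duration = cue_duration,
                 antibias_enabled = antibias_enabled,
                 antibias_window = as.integer(antibias_window),
                 antibias_gain = antibias_gain,
                 dwell_medians = dwell_medians, dwell_sdlog = dwell_sdlog,
                 opto_prob = opto_prob, silence_prob = silence_prob,
                 high_side = high_side, big_reward_port = big_reward_port),
            class = "task_config")
}

correct_side_for <- function(p_high, high_side) {
  other <- if (high_side == "right") "left" else "right"
  if (p_high > 0.5) high_side
  else if (p_high < 0.5) other
  else sample(c("left", "right"), 1)
}

#' Simulate a behavioural session
#'
#' Runs `n_trials` of the cloud-of-tones task under a caller-supplied choice
#' policy and returns a session log with one row per trial. Event times are
#' in seconds from session start and drawn from log-normal dwell
#' distributions; reward contingencies follow the configured variant.
#'
#' The policy is called as `policy(p_high, trial_info)` where `trial_info`
#' is a list with the current trial's `flags`, the running `history` data
#' frame of completed trials, and the trial index; it must return `"left"`
#' or `"right"`.
#'
#' @param config A [task_config()].
#' @param policy Choice-making function (see Details).
#' @param n_trials Number of trials (>= 1).
#' @param seed Optional integer seed.
#' @return A `data.frame` session log with columns `trial_idx`,
#'   `session_idx`, `p_high`, `correct_side`, `choice`, `rewarded`,
#'   `reward_ul`, the event times `t_trial_start`, `t_cue_on`,
#'   `t_center_out`, `t_side_in`, `t_outcome`, `flags` (semicolon-joined
#'   tokens) and `inter_trial_interval`. The `task_config` is attached as
#'   attribute `config`.
#' @export
run_session <- function(config, policy, n_trials, seed = NULL) {
  stopifnot(inherits(config, "task_config"), is.function(policy))
  check_count(n_trials, "n_trials")
  with_seed(seed, run_session_impl(config, policy, n_trials))
}

run_session_impl <- function(config, policy, n_trials) {
  n <- n_trials
  md <- config$dwell_medians
  sdl <- config$dwell_sdlog
  out <- data.frame(trial_idx = seq_len(n) - 1L, session_idx = 0L,
                    p_high = NA_real_, correct_side = NA_character_,
                    choice = NA_character_, rewarded = FALSE,
                    reward_ul = 0, t_trial_start = NA_real_,
                    t_cue_on = NA_real_, t_center_out = NA_real_,
                    t_side_in = NA_real_, t_outcome = NA_real_,
                    flags = "", inter_trial_interval = NA_real_,
                    stringsAsFactors = FALSE)
  t_now <- rlnorm(1, log(md[["return"]]), sdl)
  # target-side probability, steered by the anti-bias protocol
  p_target_high_side <- 0.5
  low_levels <- config$stimulus_set[config$stimulus_set < 0.5]
  high_levels <- config$stimulus_set[config$stimulus_set > 0.5]
  mid_levels <- config$stimulus_set[config$stimulus_set == 0.5]
  for (i in seq_len(n)) {
    idx0 <- i - 1L
    flags <- character(0)
    # pick the rewarded target side, then a stimulus level consistent with it
    target_high <- runif(1) < p_target_high_side
    pool <- if (target_high) high_levels else low_levels
    if (length(mid_levels) && runif(1) < 1 / (length(pool) * 2 + 1)) {
      p_high <- 0.5
    } else {
      p_high <- pool[sample.int(length(pool), 1)]
    }
    correct <- correct_side_for(p_high, config$high_side)

    if (config$opto_prob > 0 && runif(1) < config$opto_prob) {
      flags <- c(flags, "opto_stim")
    }
    if (config$variant == "silence" && runif(1) < config$silence_prob) {
      flags <- c(flags, "silence")
    }
    if (config$variant == "sound_on_return") {
      flags <- c(flags, "sound_on_return")
    }
    contra_side <- config$high_side  # contra cue = the high-octave cue
    if (config$variant == "state_change" && idx0 >= config$switch_trial &&
        correct == contra_side) {
      flags <- c(flags, "white_noise_cue")
    }

    t_start <- t_now
    t_cue <- t_start + runif(1, 0, 0.05)
    hold <- runif(1, config$hold_range[1], config$hold_range[2])
    t_center_out <- t_cue + hold + rlnorm(1, log(md[["hold"]]), sdl)
    t_side_in <- t_center_out + rlnorm(1, log(md[["movement"]]), sdl)
    t_outcome <- t_side_in + 0.01

    info <- list(flags = flags, trial_idx = idx0,
                 history = out[seq_len(i - 1L), , drop = FALSE])
    choice <- policy(p_high, info)
    if (!choice %in% c("left", "right", "none")) {
      stop_domain("policy must return 'left', 'right' or 'none'")
    }

    rewarded <- FALSE
    reward_ul <- 0
    if (choice == correct) {
      rewarded <- TRUE
      reward_ul <- 2
      if (config$variant == "outcome_value") {
        u <- runif(1)
        if (u < 0.1) {          # unexpected large reward
          reward_ul <- 6
        } else if (u < 0.2) {   # unexpected omission
          reward_ul <- 0
          rewarded <- FALSE
        }
      } else if (config$variant == "predicted_value" &&
                 idx0 >= config$switch_trial &&
                 choice == config$big_reward_port) {
        reward_ul <- 6
      }
    }

    iti <- rlnorm(1, log(md[["return"]]), sdl)
    out$p_high[i] <- p_high
    out$correct_side[i] <- correct
    out$choice[i] <- choice
    out$rewarded[i] <- rewarded
    out$reward_ul[i] <- reward_ul
    out$t_trial_start[i] <- t_start
    out$t_cue_on[i] <- t_cue
    out$t_center_out[i] <- t_center_out
    out$t_side_in[i] <- t_side_in
    out$t_outcome[i] <- t_outcome
    out$flags[i] <- paste(flags, collapse = ";")
    out$inter_trial_interval[i] <- iti
    t_now <- t_outcome + iti

    # anti-bias: every `antibias_window` trials, steer the target side
    # against an error-weighted choice bias
    if (config$antibias_enabled && i %% config$antibias_window == 0L) {
      recent <- out[(i - config$antibias_window + 1L):i, ]
      err_rate <- mean(!recent$rewarded)
      bias <- mean(recent$choice == "left") - mean(recent$choice == "right")
      # biased left -> raise probability that the target is right
      p_right_target <- min(0.9, max(0.1,
        0.5 + config$antibias_gain * err_rate * bias / 2))
      p_target_high_side <- if (config$high_side == "right") {
        p_right_target
      } else {
        1 - p_right_target
      }
    }
  }
  attr(out, "config") <- config
  out
}

#' Write / read a session log
#'
#' Session logs round-trip as CSV (one row per trial, flags as
#' semicolon-joined tokens) with the task configuration in a JSON sidecar
#' (`<path>.json`).
#'
#' @param log A session log from [run_session()].
#' @param path CSV file path.
#' @return `read_session_log` returns the session log with the config
#'   re-attached when the sidecar exists.
#' @export
write_session_log <- function(log, path) {
  write.csv(log, path, row.names = FALSE)
  cfg <- attr(log, "config")
  if (!is.null(cfg)) {
    jsonlite::write_json(unclass(cfg), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(path) {
  log <- read.csv(path, stringsAsFactors = FALSE)
  log$flags[is.na(log$flags)] <- ""
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    cfg <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(log, "config") <- structure(cfg, class = "task_config")
  }
  log
}
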