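# Behavioural and trial-linked statistics: Weibull learning curves,
# shuffle-null optogenetic bias tests, dopamine-history and repeat/switch
# regressions, kinematic residual-trend regression and discrete Frechet
# trajectory similarity.

#' Modified Weibull learning curve
#'
#' `performance = 50 + a * (1 - 2^(-(trials / l)^s))`: chance (50%) at
#' trial 0, rising towards `50 + a` with scale `l` (trials) and shape `s`.
#'
#' @param trials Trial numbers (>= 0).
#' @param a Asymptotic amplitude above 50, in percent.
#' @param l Scale in trials.
#' @param s Shape (dimensionless).
#' @return Performance in percent.
#' @export
weibull_curve <- function(trials, a, l, s) {
  50 + a * (1 - 2^(-(trials / l)^s))
}

weibull_derivative <- function(trials, a, l, s) {
  a * log(2) * (s / l) * (trials / l)^(s - 1) * 2^(-(trials / l)^s)
}

#' Clean a trial table for learning-curve analysis
#'
#' Drops sessions with fewer than `min_session_trials` trials, the first
#' `drop_first` trials of each session, and disengaged trials whose
#' inter-trial interval exceeds `iti_factor` times the session median.
#'
#' @param trials Data frame with columns `session_idx`, `correct` and
#'   (optionally) `inter_trial_interval`.
#' @param min_session_trials,drop_first,iti_factor Filter settings.
#' @return The filtered data frame, in chronological order.
#' @export
clean_learning_trials <- function(trials, min_session_trials = 60L,
                                  drop_first = 5L, iti_factor = 3) {
  keep <- rep(TRUE, nrow(trials))
  for (s in unique(trials$session_idx)) {
    ix <- which(trials$session_idx == s)
    if (length(ix) < min_session_trials) {
      keep[ix] <- FALSE
      next
    }
    keep[ix[seq_len(min(drop_first, length(ix)))]] <- FALSE
    if ("inter_trial_interval" %in% names(trials)) {
      iti <- trials$inter_trial_interval[ix]
      keep[ix[iti > iti_factor * median(iti)]] <- FALSE
    }
  }
  trials[keep, , drop = FALSE]
}

#' Fit the modified Weibull learning curve
#'
#' Least-squares fit of [weibull_curve()] to per-trial performance, with
#' multi-start over log-spaced scale values. Also reports the maximum
#' performance (maximum of 200-trial-binned medians of the trailing
#' 100-trial running performance) and the maximum learning rate (the
#' analytic maximum of the fitted curve's derivative over the observed
#' trial range, in percent per trial).
#'
#' @param correct Per-trial outcomes: 0/1 (or percentages 0-100).
#' @param n_starts Number of multi-start scale values.
#' @param running_window Window of the running-performance estimate.
#' @param bin_width Bin width for the maximum-performance estimate.
#' @return List of class `weibull_fit`: `a`, `l`, `s`, `max_performance`,
#'   `max_learning_rate`, `fitted`, `converged`.
#' @export
fit_weibull <- function(correct, n_starts = 5L, running_window = 100L,
                        bin_width = 200L) {
  perf <- as.numeric(correct)
  if (max(perf, na.rm = TRUE) <= 1) perf <- perf * 100
  n <- length(perf)
  trials <- seq_len(n)
  a0 <- max(1, mean(tail(perf, max(10, n %/% 10))) - 50)
  starts <- exp(seq(log(max(5, n / 100)), log(max(10, n)),
                    length.out = n_starts))
  best <- NULL
  best_rss <- Inf
  for (l0 in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        perf ~ 50 + a * (1 - 2^(-(trials / l)^s)),
        start = list(a = a0, l = l0, s = 1),
        lower = c(a = 0, l = 1e-2, s = 0.05),
        upper = c(a = 50, l = 1e7, s = 10),
        control = minpack.lm::nls.lm.control(maxiter = 200,
                                             ftol = 1e-8)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(resid(fit)^2)
      if (rss < best_rss) {
        best <- fit
        best_rss <- rss
      }
    }
  }
  cf <- if (!is.null(best)) {
    coef(best)
  } else {
    # flat or degenerate data can defeat the LM starts; fall back to a
    # bounded quasi-Newton search on the same residual sum of squares
    rss <- function(par) {
      sum((perf - weibull_curve(trials, par[1], par[2], par[3]))^2)
    }
    op <- optim(c(a0, starts[ceiling(n_starts / 2)], 1), rss,
                method = "L-BFGS-B", lower = c(0, 1e-2, 0.05),
                upper = c(50, 1e7, 10))
    c(a = op$par[1], l = op$par[2], s = op$par[3])
  }
  run_perf <- vapply(trials, function(i) {
    mean(perf[max(1, i - running_window + 1):i])
  }, numeric(1))
  bins <- split(run_perf, (trials - 1L) %/% bin_width)
  max_perf <- max(vapply(bins, median, numeric(1)))
  opt <- optimize(function(t) weibull_derivative(t, cf[["a"]], cf[["l"]],
                                                 cf[["s"]]),
                  interval = c(1, n), maximum = TRUE)
  structure(list(a = cf[["a"]], l = cf[["l"]], s = cf[["s"]],
                 max_performance = max_perf,
                 max_learning_rate = opt$objective, fitted = best,
                 converged = !is.null(best)),
            class = "weibull_fit")
}

#' Shuffle-null test of an optogenetic choice bias
#'
#' For each trial type, compares the proportion of reference-port choices
#' on stimulated trials against a null distribution built by shuffling
#' which trials carry the stimulated label (matched count per type); the
#' session bias is the average over trial types of (stimulated minus
#' unstimulated) choice proportion, and the two-sided p-value is taken
#' from the shuffle distribution of session biases with add-one
#' smoothing. `scheme = "subsample"` instead draws the null from
#' same-sized subsets of the unstimulated trials only; this leaves the
#' stimulated trials out of the null and is anticonservative when they
#' are a sizeable fraction of the session, so label permutation is the
#' default.
#'
#' @param trials Data frame with columns `type` (trial type), `choice`
#'   (`"left"`/`"right"`) and `stimulated` (logical).
#' @param n_shuffles Number of shuffles.
#' @param seed Optional seed.
#' @param reference_side Port whose choice proportion defines the bias.
#' @param scheme Null-construction scheme (see Details).
#' @return List of class `bias_test_result`: `per_type` (data frame),
#'   `session_bias`, `null_distribution`, `p_value`, `excluded_types`.
#' @export
shuffle_bias_test <- function(trials, n_shuffles = 1000L, seed = NULL,
                              reference_side = "left",
                              scheme = c("permutation", "subsample")) {
  scheme <- match.arg(scheme)
  check_count(n_shuffles, "n_shuffles")
  with_seed(seed, {
    types <- unique(trials$type)
    per_type <- list()
    nulls <- matrix(NA_real_, n_shuffles, 0)
    excluded <- character(0)
    for (ty in types) {
      sub <- trials[trials$type == ty, ]
      is_ref <- sub$choice == reference_side
      m <- sum(sub$stimulated)
      n_un <- sum(!sub$stimulated)
      if (m == 0L || n_un == 0L) {
        excluded <- c(excluded, as.character(ty))
        next
      }
      p_stim <- mean(is_ref[sub$stimulated])
      p_unstim <- mean(is_ref[!sub$stimulated])
      obs <- p_stim - p_unstim
      if (scheme == "permutation") {
        k_pool <- sum(is_ref)
        n_pool <- nrow(sub)
        draws <- rhyper(n_shuffles, k_pool, n_pool - k_pool, m)
        null <- draws / m - (k_pool - draws) / (n_pool - m)
      } else {
        k_un <- sum(is_ref[!sub$stimulated])
        draws <- rhyper(n_shuffles, k_un, n_un - k_un, m)
        null <- draws / m - k_un / n_un
      }
      per_type[[as.character(ty)]] <- data.frame(type = ty, n_stim = m,
                                                 n_unstim = n_un,
                                                 bias = obs)
      nulls <- cbind(nulls, null)
    }
    if (length(per_type) == 0L) {
      stop_domain("no trial type has both stimulated and unstimulated ",
                  "trials")
    }
    per_type <- do.call(rbind, per_type)
    session_bias <- mean(per_type$bias)
    null_session <- rowMeans(nulls)
    p <- (1 + sum(abs(null_session) >= abs(session_bias) - 1e-12)) /
      (n_shuffles + 1)
    structure(list(per_type = per_type, session_bias = session_bias,
                   null_distribution = null_session, p_value = p,
                   excluded_types = excluded, n_shuffles = n_shuffles),
              class = "bias_test_result")
  })
}

# Ridge-penalized logistic IRLS, used as the separation fallback.
logistic_ridge <- function(X, y, lambda = 1e-2, maxit = 50L) {
  beta <- numeric(ncol(X))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-8)
    z <- eta + (y - mu) / w
    H <- crossprod(X * w, X) + diag(lambda, ncol(X))
    new_beta <- solve(H, crossprod(X * w, z))
    if (max(abs(new_beta - beta)) < 1e-8) {
      beta <- new_beta
      break
    }
    beta <- new_beta
  }
  drop(beta)
}

#' Log perceptual uncertainty of a stimulus level
#'
#' `-log(2 * |p_high - 0.5| + eps_floor)`: 0 near the category boundary
#' where discrimination is hardest, increasingly negative for easy
#' stimuli. The floor keeps the ambiguous (50/50) stimulus finite.
#'
#' @param p_high Stimulus high-tone probability.
#' @param eps_floor Floor inside the logarithm.
#' @return Log uncertainty values.
#' @export
log_uncertainty <- function(p_high, eps_floor = 1e-3) {
  -log(2 * abs(p_high - 0.5) + eps_floor)
}

#' Repeat/switch logistic regression on previous-trial dopamine
#'
#' Models whether the current choice repeats the previous one as a
#' function of the previous trial's dopamine response size and the
#' current trial's log perceptual uncertainty. Only correct trials enter,
#' except for the ambiguous (50/50) stimulus where all trials are used
#' (the movement-aligned tail response precedes the outcome). Also
#' returns the large/small summary split at the 65th percentile of the
#' response distribution. On separation or non-convergence the model is
#' refitted with a small ridge penalty and flagged.
#'
#' @param trials Data frame with columns `p_high`, `choice`, `correct`
#'   and `response` (per-trial dopamine response).
#' @param large_quantile Percentile defining "large" responses.
#' @return List of class `repeat_choice_fit`: `coefficients` (intercept,
#'   `prev_response`, `log_uncertainty`), `binned` summary data frame,
#'   `regularized` flag, `n`.
#' @export
repeat_choice_logistic <- function(trials, large_quantile = 0.65) {
  n <- nrow(trials)
  if (n < 3L) stop_domain("need at least 3 trials")
  idx <- 2:n
  prev_resp <- trials$response[idx - 1L]
  repeats <- trials$choice[idx] == trials$choice[idx - 1L]
  unc <- log_uncertainty(trials$p_high[idx])
  ambiguous <- abs(trials$p_high[idx] - 0.5) < 1e-9
  include <- trials$correct[idx] | ambiguous
  ok <- include & !is.na(prev_resp)
  df <- data.frame(repeats = repeats[ok], prev_response = prev_resp[ok],
                   log_uncertainty = unc[ok],
                   p_high = trials$p_high[idx][ok])
  thr <- quantile(trials$response, large_quantile, na.rm = TRUE)
  df$prev_large <- df$prev_response > thr

  fit <- suppressWarnings(glm(repeats ~ prev_response + log_uncertainty,
                              family = binomial(), data = df))
  regularized <- FALSE
  cf <- coef(fit)
  if (!fit$converged || any(abs(cf[-1]) > 20, na.rm = TRUE) ||
      anyNA(cf)) {
    warning("separation detected: refitting with ridge penalty",
            call. = FALSE)
    X <- cbind(1, df$prev_response, df$log_uncertainty)
    cf <- logistic_ridge(X, as.numeric(df$repeats))
    names(cf) <- c("(Intercept)", "prev_response", "log_uncertainty")
    regularized <- TRUE
  }
  binned <- do.call(rbind, lapply(split(df, list(df$p_high,
                                                 df$prev_large),
                                        drop = TRUE), function(g) {
    data.frame(p_high = g$p_high[1], prev_large = g$prev_large[1],
               repeat_rate = mean(g$repeats), n = nrow(g))
  }))
  rownames(binned) <- NULL
  structure(list(coefficients = cf, binned = binned,
                 regularized = regularized, n = nrow(df)),
            class = "repeat_choice_fit")
}

#' Per-lag regression of dopamine response on past choices
#'
#' For each lag, regresses the dopamine response on included trials
#' against whether the same side was chosen on the lag-th most recent
#' earlier trial with the same stimulus. A negative coefficient means a
#' smaller response when the action was recently repeated for that
#' stimulus.
#'
#' @param stimulus Per-trial stimulus identifiers.
#' @param choice Per-trial choices.
#' @param response Per-trial dopamine responses.
#' @param include Logical: trials entering the regression as outcomes
#'   (e.g. correct contralateral trials). Predictors use all trials.
#' @param max_lag Largest lag.
#' @return Data frame with `lag`, `coefficient`, `n`.
#' @export
dopamine_history_regression <- function(stimulus, choice, response,
                                        include = rep(TRUE,
                                                      length(choice)),
                                        max_lag = 5L) {
  n <- length(choice)
  stopifnot(length(stimulus) == n, length(response) == n,
            length(include) == n)
  out <- data.frame(lag = seq_len(max_lag), coefficient = NA_real_,
                    n = NA_integer_)
  for (lag in seq_len(max_lag)) {
    same <- rep(NA, n)
    for (t in which(include)) {
      prev <- which(stimulus[seq_len(t - 1L)] == stimulus[t])
      if (length(prev) >= lag) {
        same[t] <- choice[prev[length(prev) - lag + 1L]] == choice[t]
      }
    }
    ok <- include & !is.na(same)
    if (sum(ok) >= 3L && length(unique(same[ok])) > 1L) {
      fit <- lm(response[ok] ~ as.numeric(same[ok]))
      out$coefficient[lag] <- coef(fit)[2]
    }
    out$n[lag] <- sum(ok)
  }
  out
}

#' Discrete Frechet distance between two trajectories
#'
#' The minimum over monotone couplings of the maximal pointwise Euclidean
#' distance, computed by the standard recursive coupling recurrence with
#' memoization (dynamic programming over the full coupling table).
#'
#' @param p,q Trajectories: numeric matrices with one row per point and
#'   two columns (x, y), or data frames coercible to such.
#' @return The discrete Frechet distance (scalar, >= 0).
#' @export
frechet_distance <- function(p, q) {
  p <- as.matrix(p)
  q <- as.matrix(q)
  n <- nrow(p)
  m <- nrow(q)
  if (n < 1L || m < 1L) stop_domain("trajectories must be non-empty")
  # pairwise Euclidean distances
  d <- sqrt(outer(p[, 1], q[, 1], "-")^2 + outer(p[, 2], q[, 2], "-")^2)
  ca <- matrix(0, n, m)
  ca[1, 1] <- d[1, 1]
  if (n >= 2) {
    for (i in 2:n) ca[i, 1] <- max(ca[i - 1, 1], d[i, 1])
  }
  if (m >= 2) {
    for (j in 2:m) ca[1, j] <- max(ca[1, j - 1], d[1, j])
  }
  if (n >= 2 && m >= 2) {
    for (i in 2:n) {
      for (j in 2:m) {
        ca[i, j] <- max(min(ca[i - 1, j], ca[i - 1, j - 1], ca[i, j - 1]),
                        d[i, j])
      }
    }
  }
  ca[n, m]
}

#' Regression of movement similarity on dopamine response
#'
#' Regresses the Frechet distance between each trial's trajectory and the
#' next trial's trajectory on the current trial's dopamine response; a
#' negative slope means larger responses precede more similar (more
#' repeated) movements.
#'
#' @param responses Per-trial dopamine responses (length n).
#' @param trajectories List of n trajectories (two-column matrices).
#' @return List with `slope`, `intercept`, `distances` and the `lm` fit.
#' @export
similarity_regression <- function(responses, trajectories) {
  n <- length(trajectories)
  stopifnot(length(responses) == n, n >= 3L)
  dists <- vapply(seq_len(n - 1L), function(i) {
    frechet_distance(trajectories[[i]], trajectories[[i + 1L]])
  }, numeric(1))
  fit <- lm(dists ~ responses[seq_len(n - 1L)])
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       distances = dists, fit = fit)
}

#' Movement-residual trend regression
#'
#' Predicts the dopamine response from speed and turn angle, regresses
#' the residuals against log trial number, and decomposes explained
#' variance across the three predictors via drop-one differences in R^2
#' from the full model. Collinear kinematic designs are solved by the
#' minimum-norm solution (with a warning).
#'
#' @param response,speed,turn_angle,trial_number Per-trial vectors.
#' @return List with `movement_fit` coefficients, `residual_slope` (on
#'   log trial number), `r2_full`, and `ev_decomposition` (named vector
#'   of drop-one R^2 differences).
#' @export
residual_trend_regression <- function(response, speed, turn_angle,
                                      trial_number) {
  n <- length(response)
  stopifnot(length(speed) == n, length(turn_angle) == n,
            length(trial_number) == n)
  Xm <- cbind(intercept = 1, speed = speed, turn_angle = turn_angle)
  bm <- least_squares_solve(Xm, response, warn_label = "kinematic design")
  residuals <- response - drop(Xm %*% bm)
  lt <- log(trial_number)
  trend <- lm(residuals ~ lt)
  r2_of <- function(X) {
    b <- least_squares_solve(X, response, warn_label = "design")
    pred <- drop(X %*% b)
    1 - sum((response - pred)^2) / sum((response - mean(response))^2)
  }
  Xf <- cbind(Xm, log_trial = lt)
  r2_full <- r2_of(Xf)
  ev <- c(speed = r2_full - r2_of(Xf[, -2, drop = FALSE]),
          turn_angle = r2_full - r2_of(Xf[, -3, drop = FALSE]),
          log_trial = r2_full - r2_of(Xf[, -4, drop = FALSE]))
  list(movement_fit = bm, residual_slope = unname(coef(trend)[2]),
       r2_full = r2_full, ev_decomposition = ev)
}
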