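# Fiber-photometry processing: lock-in demodulation, denoising and
# bleaching correction, isosbestic motion regression, dF/F, z-scoring,
# event-locked response extraction and the event-kernel linear regression
# with per-regressor explained variance.

#' Lock-in demodulation of a carrier-modulated photometry trace
#'
#' Recovers the signal (465 nm excitation) and background (isosbestic,
#' 405 nm) envelopes from a single trace in which the two channels are
#' amplitude-modulated on sinusoidal carriers. Quadrature demodulation:
#' multiply by sine and cosine at each carrier, low-pass both products,
#' and take `2 * sqrt(I^2 + Q^2)` so a pure carrier of amplitude A
#' recovers an envelope of A.
#'
#' @param x Modulated trace.
#' @param carrier_freqs Carrier frequencies in Hz, signal channel first
#'   (default `c(211, 531)`).
#' @param rate Sampling rate in Hz; must exceed twice the largest carrier.
#' @param lp_cutoff Demodulation low-pass cutoff in Hz (below the carrier
#'   spacing).
#' @return List with `signal` and `background` envelope traces.
#' @export
demodulate <- function(x, carrier_freqs = c(211, 531), rate,
                       lp_cutoff = 20) {
  if (max(carrier_freqs) * 2 >= rate) {
    stop_domain("carrier frequency above Nyquist: rate must exceed twice ",
                "the largest carrier")
  }
  t <- (seq_along(x) - 1) / rate
  demod_one <- function(f) {
    i <- butter_lowpass(x * sin(2 * pi * f * t), lp_cutoff, rate)
    q <- butter_lowpass(x * cos(2 * pi * f * t), lp_cutoff, rate)
    2 * sqrt(i^2 + q^2)
  }
  list(signal = demod_one(carrier_freqs[1]),
       background = demod_one(carrier_freqs[2]))
}

#' Preprocess a two-channel photometry session
#'
#' Applies, in order: a width-5 median filter and a zero-phase order-2
#' Butterworth low-pass at 10 Hz (both channels); a 0.001 Hz high-pass to
#' remove photo-bleaching; a linear regression of the background channel
#' onto the signal channel whose fitted component is subtracted (motion
#' correction); division by the 0.001 Hz low-pass baseline of the
#' denoised signal channel (dF/F); and z-scoring. The very-low-frequency
#' filters are bidirectional single-pole exponential filters, which remain
#' numerically stable at cutoffs this far below the sampling rate.
#'
#' @param signal,background The two fluorescence channels (equal length).
#' @param rate Sampling rate in Hz.
#' @param lp_cutoff Denoising low-pass cutoff (Hz).
#' @param hp_cutoff Bleaching high-pass / baseline cutoff (Hz).
#' @param baseline_pre_highpass Use the denoised, pre-high-pass signal
#'   channel for the dF/F baseline (default) or the high-passed one.
#' @return List of class `processed_trace` with `dff_z` (z-scored dF/F),
#'   `rate`, and the intermediate `dff`, `baseline` and `motion_fit`
#'   coefficients.
#' @export
preprocess_photometry <- function(signal, background, rate,
                                  lp_cutoff = 10, hp_cutoff = 0.001,
                                  baseline_pre_highpass = TRUE) {
  if (length(signal) != length(background)) {
    stop_domain("signal and background channels must have equal length")
  }
  if (length(signal) < 30L) {
    stop_domain("trace shorter than filter warm-up (need >= 30 samples)")
  }
  denoise <- function(x) {
    butter_lowpass(stats::runmed(x, 5), lp_cutoff, rate)
  }
  sig_dn <- denoise(signal)
  bg_dn <- denoise(background)
  sig_base <- lowpass_exp(sig_dn, hp_cutoff, rate)
  bg_base <- lowpass_exp(bg_dn, hp_cutoff, rate)
  sig_hp <- sig_dn - sig_base
  bg_hp <- bg_dn - bg_base
  fit <- lm(sig_hp ~ bg_hp)
  corrected <- sig_hp - predict(fit)
  baseline <- if (baseline_pre_highpass) sig_base else {
    lowpass_exp(sig_hp, hp_cutoff, rate)
  }
  dff <- corrected / baseline
  s <- sd(dff)
  if (!is.finite(s) || s < 1e-10) {
    warning("degenerate trace: zero variance after preprocessing; ",
            "returning zeros", call. = FALSE)
    dff_z <- numeric(length(dff))
  } else {
    dff_z <- (dff - mean(dff)) / s
  }
  structure(list(dff_z = dff_z, rate = rate, dff = dff,
                 baseline = baseline, motion_fit = coef(fit)),
            class = "processed_trace")
}

#' Event-locked response of a trace
#'
#' `method = "peak"` returns the largest interior local maximum within the
#' window, falling back to the window maximum when no local peak exists
#' (e.g. a monotone segment); `"mean"` averages the window (used for
#' ventral-striatum omission responses, which dip rather than peak).
#'
#' @param trace Numeric trace (e.g. `dff_z`).
#' @param rate Sampling rate in Hz.
#' @param window `c(t_start, t_end)` in seconds.
#' @param method `"peak"` or `"mean"`.
#' @return Scalar response.
#' @export
extract_response <- function(trace, rate, window, method = c("peak",
                                                             "mean")) {
  method <- match.arg(method)
  i0 <- max(1L, floor(window[1] * rate) + 1L)
  i1 <- min(length(trace), ceiling(window[2] * rate) + 1L)
  if (i1 < i0) stop_domain("empty response window")
  seg <- trace[i0:i1]
  if (method == "mean") return(mean(seg))
  n <- length(seg)
  if (n >= 3) {
    interior <- 2:(n - 1)
    is_peak <- seg[interior] > seg[interior - 1] &
      seg[interior] >= seg[interior + 1]
    if (any(is_peak)) return(max(seg[interior][is_peak]))
  }
  max(seg)
}

#' Kernel window specification
#'
#' Pre/post windows (seconds) of the event response kernels. Defaults:
#' choice movement 0.5 s pre / 1.5 s post (movement may begin before the
#' centre-port exit is detected and outlasts the cue), cue and outcome
#' 0 s pre / 1 s post, return 0.2 s pre / 1.5 s post.
#'
#' @param windows Named list of `c(pre, post)` pairs.
#' @return Object of class `kernel_spec`.
#' @export
kernel_spec <- function(windows = list(cue = c(0, 1),
                                       movement = c(0.5, 1.5),
                                       outcome = c(0, 1),
                                       return_mv = c(0.2, 1.5))) {
  for (w in windows) {
    if (w[1] < 0 || w[2] <= 0) stop_domain("kernel windows must be positive")
  }
  structure(windows, class = "kernel_spec")
}

# Lagged-indicator design matrix: one column per (event type, lag).
kernel_design <- function(n, rate, events, spec) {
  types <- intersect(names(spec), names(events))
  cols <- list()
  map <- list()
  for (ev in types) {
    w <- spec[[ev]]
    lags <- seq(-round(w[1] * rate), round(w[2] * rate))
    idx <- round(events[[ev]] * rate) + 1L  # nearest-sample event times
    idx <- idx[idx >= 1L & idx <= n]
    block <- matrix(0, n, length(lags))
    for (j in seq_along(lags)) {
      at <- idx + lags[j]
      at <- at[at >= 1L & at <= n]
      block[at, j] <- block[at, j] + 1
    }
    cols[[ev]] <- block
    map[[ev]] <- lags / rate
  }
  list(X = do.call(cbind, cols), lags = map, types = types)
}

#' Fit event response kernels by linear regression
#'
#' Predicts the photometry signal at each sample as an intercept plus the
#' sum over event types of the event indicator convolved with an unknown
#' kernel, and solves the resulting lagged-indicator ordinary least
#' squares problem. Rank-deficient designs fall back to the minimum-norm
#' solution with a warning.
#'
#' @param trace Processed (z-scored dF/F) trace.
#' @param rate Sampling rate in Hz.
#' @param events Named list of event-time vectors (seconds); names must
#'   match the spec's.
#' @param spec A [kernel_spec()].
#' @return Object of class `kernel_fit`: `g0` (intercept), `kernels` (per
#'   event, data frame of `lag_s` and `weight`), `v_full` (% explained
#'   variance), plus the fitted values and design metadata.
#' @export
fit_kernels <- function(trace, rate, events, spec = kernel_spec()) {
  n <- length(trace)
  for (ev in intersect(names(spec), names(events))) {
    tms <- events[[ev]]
    if (any(tms < 0 | tms > n / rate)) {
      stop_domain("event times outside the trace span")
    }
  }
  des <- kernel_design(n, rate, events, spec)
  X <- cbind(1, des$X)
  beta <- least_squares_solve(X, trace, warn_label = "kernel design")
  fitted <- drop(X %*% beta)
  v_full <- explained_variance_pct(trace, fitted)
  kernels <- list()
  off <- 1L
  for (ev in des$types) {
    nl <- length(des$lags[[ev]])
    kernels[[ev]] <- data.frame(lag_s = des$lags[[ev]],
                                weight = beta[(off + 1L):(off + nl)])
    off <- off + nl
  }
  structure(list(g0 = beta[1], kernels = kernels, v_full = v_full,
                 fitted = fitted, rate = rate, events = events,
                 spec = spec, trace = trace),
            class = "kernel_fit")
}

explained_variance_pct <- function(y, pred) {
  100 * (1 - sum((y - pred)^2) / sum((y - mean(y))^2))
}

# Sample indices inside any kernel window around any event ("trimming").
event_epoch_index <- function(n, rate, events, spec) {
  keep <- logical(n)
  for (ev in intersect(names(spec), names(events))) {
    w <- spec[[ev]]
    for (tm in events[[ev]]) {
      i0 <- max(1L, round((tm - w[1]) * rate) + 1L)
      i1 <- min(n, round((tm + w[2]) * rate) + 1L)
      if (i1 >= i0) keep[i0:i1] <- TRUE
    }
  }
  which(keep)
}

#' Percentage of explained variance attributable to one regressor
#'
#' Recomputes the model prediction with the named event type's kernel
#' contribution removed (coefficients are not refitted) and returns
#' `(v_full - v_partial) / v_full * 100`. Values can exceed 100 when the
#' partial prediction explains the data worse than the intercept alone.
#' With `trim = TRUE` both explained variances are evaluated only on
#' samples inside some kernel window around an event.
#'
#' @param fit A [fit_kernels()] object.
#' @param regressor Event-type name to remove.
#' @param trim Restrict scoring to event epochs.
#' @return Percentage (scalar); `NA` with a warning when `v_full <= 0`.
#' @export
partial_explained_variance <- function(fit, regressor, trim = FALSE) {
  stopifnot(inherits(fit, "kernel_fit"))
  if (!regressor %in% names(fit$kernels)) {
    stop_domain("unknown regressor: ", regressor)
  }
  n <- length(fit$trace)
  des <- kernel_design(n, fit$rate, fit$events[regressor],
                       fit$spec[regressor])
  contribution <- drop(des$X %*% fit$kernels[[regressor]]$weight)
  pred_partial <- fit$fitted - contribution
  idx <- if (trim) {
    event_epoch_index(n, fit$rate, fit$events, fit$spec)
  } else {
    seq_len(n)
  }
  v_full <- explained_variance_pct(fit$trace[idx], fit$fitted[idx])
  v_partial <- explained_variance_pct(fit$trace[idx], pred_partial[idx])
  if (v_full <= 0) {
    warning("v_full <= 0: per-regressor percentage undefined",
            call. = FALSE)
    return(NA_real_)
  }
  (v_full - v_partial) / v_full * 100
}

#' Export fitted kernels as a long data frame
#'
#' @param fit A [fit_kernels()] object.
#' @return Data frame with columns `event`, `lag_s`, `weight` (suitable
#'   for CSV export).
#' @export
kernels_as_df <- function(fit) {
  do.call(rbind, lapply(names(fit$kernels), function(ev) {
    cbind(event = ev, fit$kernels[[ev]])
  }))
}
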