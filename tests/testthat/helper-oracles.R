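# Independent oracles used across the suite. These deliberately do not
# share code with the package implementation.

# Naive memo-free recursive discrete Frechet distance (exponential; only
# for tiny trajectories).
frechet_naive <- function(p, q) {
  f <- function(i, j) {
    d <- sqrt(sum((p[i, ] - q[j, ])^2))
    if (i == 1 && j == 1) {
      d
    } else if (i == 1) {
      max(f(1, j - 1), d)
    } else if (j == 1) {
      max(f(i - 1, 1), d)
    } else {
      max(min(f(i - 1, j), f(i - 1, j - 1), f(i, j - 1)), d)
    }
  }
  f(nrow(p), nrow(q))
}

# Scalar first-order exponential filter, forward Euler with dt = 1.
exp_filter_oracle <- function(inputs, tau, init = 0) {
  out <- numeric(length(inputs))
  x <- init
  for (i in seq_along(inputs)) {
    x <- x + (inputs[i] - x) / tau
    out[i] <- x
  }
  out
}

# Always-correct choice policy for the cloud-of-tones task
# (high octave -> right under the default contingency).
policy_always_correct <- function(p_high, info) {
  if (p_high > 0.5) "right" else "left"
}

policy_random <- function(p_high, info) {
  c("left", "right")[sample.int(2L, 1L)]
}

# Per-trial choice-locked APE table for one agent of a simulate_learning()
# result, aligned with its trial log.
choice_locked_ape <- function(sim, agent) {
  tl <- sim$trials[sim$trials$agent == agent, ]
  tr <- sim$transitions
  tra <- tr[tr$agent == agent & tr$phase == "choice", ]
  tl$ape <- tra$ape[match(tl$trial, tra$trial)]
  tl
}
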