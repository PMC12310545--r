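#' @keywords internal
"_PACKAGE"

#' @importFrom stats lm coef rbinom rnorm runif rlnorm quantile median sd
#'   var predict glm binomial optimize rhyper resid fft setNames complete.cases
#' @importFrom utils head tail read.csv write.csv
NULL

# Scoped RNG: run `expr` under a local seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

stop_domain <- function(...) stop(..., call. = FALSE)

check_prob <- function(p, name = "probability") {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop_domain(name, " must be a single number in [0, 1], got ",
                deparse(substitute(p)))
  }
  invisible(p)
}

check_count <- function(n, name, min = 1L) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < min ||
      n != floor(n)) {
    stop_domain(name, " must be an integer >= ", min)
  }
  invisible(as.integer(n))
}

# Least-squares solve that tolerates rank deficiency: QR when full rank,
# otherwise the minimum-norm SVD solution with a warning.
least_squares_solve <- function(X, y, warn_label = "design") {
  qrX <- qr(X)
  if (qrX$rank == ncol(X)) {
    return(qr.coef(qrX, y))
  }
  warning("rank-deficient ", warn_label,
          ": returning minimum-norm least-squares solution", call. = FALSE)
  sv <- svd(X)
  tol <- max(dim(X)) * .Machine$double.eps * sv$d[1]
  keep <- sv$d > tol
  drop(sv$v[, keep, drop = FALSE] %*%
         ((crossprod(sv$u[, keep, drop = FALSE], y)) / sv$d[keep]))
}

# Bidirectional single-pole exponential low-pass; numerically stable at
# cutoffs far below those representable by a discretized Butterworth.
lowpass_exp <- function(x, cutoff_hz, rate) {
  a <- exp(-2 * pi * cutoff_hz / rate)
  one_pass <- function(v) {
    as.numeric(stats::filter(v * (1 - a), filter = a, method = "recursive",
                             init = v[1]))
  }
  rev(one_pass(rev(one_pass(x))))
}

# Zero-phase order-2 Butterworth low-pass.
butter_lowpass <- function(x, cutoff_hz, rate, order = 2) {
  bf <- signal::butter(order, 2 * cutoff_hz / rate, type = "low")
  signal::filtfilt(bf, x)
}
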