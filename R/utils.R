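#' Wrap angles into (-pi, pi]
#'
#' The package-wide wrapping convention for phases and phase differences.
#'
#' @param x Numeric vector/array of angles in radians.
#' @return Angles wrapped into the half-open interval (-pi, pi].
#' @export
wrap_pi <- function(x) {
  x - 2 * pi * ceiling((x - pi) / (2 * pi))
}

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded helpers do not disturb
#' the caller's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Fourier-domain resampling of a single series to n_out samples
# (band-limited interpolation; anti-aliased on downsampling because
# frequencies above the new Nyquist are dropped).
fft_resample <- function(x, n_out) {
  n_in <- length(x)
  if (n_out == n_in) return(x)
  X <- stats::fft(x)
  Y <- complex(n_out)
  nh <- min(n_in, n_out)
  keep <- floor(nh / 2)
  Y[1] <- X[1]
  if (keep >= 1) {
    Y[2:(keep + 1)] <- X[2:(keep + 1)]
    Y[(n_out - keep + 1):n_out] <- X[(n_in - keep + 1):n_in]
  }
  if (nh %% 2 == 0 && keep >= 1) {
    # split the shared Nyquist bin to keep the result real-valued
    if (n_out < n_in) {
      nyq <- (X[keep + 1] + X[n_in - keep + 1]) / 2
      Y[keep + 1] <- nyq
      Y[n_out - keep + 1] <- Conj(nyq)
    } else {
      Y[keep + 1] <- X[keep + 1] / 2
      Y[n_out - keep + 1] <- Conj(X[keep + 1] / 2)
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) / n_in
}

# Zero-phase band-pass via the frequency domain with raised-cosine
# transition bands.  `x` is a channels x samples matrix.
fft_bandpass_matrix <- function(x, fs, low, high,
                                trans_low = low / 2,
                                trans_high = min(high * 0.1, fs / 2 - high)) {
  n <- ncol(x)
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f)           # two-sided frequency axis
  h <- numeric(n)
  h[f >= low & f <= high] <- 1
  lo0 <- low - trans_low
  ramp <- f > lo0 & f < low
  h[ramp] <- 0.5 * (1 - cos(pi * (f[ramp] - lo0) / trans_low))
  hi1 <- high + trans_high
  fall <- f > high & f < hi1
  h[fall] <- 0.5 * (1 + cos(pi * (f[fall] - high) / trans_high))
  t(apply(x, 1, function(row) {
    Re(stats::fft(stats::fft(row) * h, inverse = TRUE)) / n
  }))
}

# Run-length cleaning of a coded vector: zero out maximal same-sign nonzero
# runs shorter than min_run points.
clean_run_vector <- function(codes, min_run) {
  if (min_run <= 1L || length(codes) == 0L) return(codes)
  r <- rle(codes)
  kill <- r$values != 0L & r$lengths < min_run
  if (any(kill)) {
    r$values[kill] <- 0L
    codes <- inverse.rle(r)
  }
  codes
}

stopifnot_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  invisible(x)
}
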