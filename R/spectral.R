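#' Morlet wavelet analysis parameters
#'
#' @param fois Frequencies of interest in Hz, strictly increasing.  Default:
#'   the 17 components 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 14, 16, 18, 20,
#'   24, 28 Hz used throughout the analysis.
#' @param cycles Number of oscillation cycles in the Gaussian envelope; the
#'   envelope standard deviation at frequency f is `cycles / (2 * pi * f)`.
#'   Default 7.
#' @param step Samples between evaluated wavelet coefficients (default 5; at
#'   250 Hz this gives a 20-ms coefficient interval).
#' @return An object of class `wavelet_params`.
#' @export
wavelet_params <- function(fois = c(2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12,
                                    14, 16, 18, 20, 24, 28),
                           cycles = 7, step = 5) {
  if (any(fois <= 0) || is.unsorted(fois, strictly = TRUE))
    stop("`fois` must be strictly positive and increasing", call. = FALSE)
  stopifnot_scalar(cycles, "cycles", positive = TRUE)
  if (!is.numeric(step) || step < 1)
    stop("`step` must be >= 1", call. = FALSE)
  structure(list(fois = as.numeric(fois), cycles = cycles,
                 step = as.integer(step)),
            class = "wavelet_params")
}

#' Instantaneous phase via complex Morlet wavelet transform
#'
#' Convolves every channel of every epoch with an analytic (complex) Morlet
#' kernel at each frequency of interest and takes the argument of the
#' complex coefficient as the instantaneous phase.  Coefficients are
#' evaluated every `params$step` samples.  Coefficients closer than
#' `cycles/(2*f)` seconds to an epoch boundary are flagged invalid (edge
#' artifacts of the convolution) and are excluded from all downstream
#' coupling statistics.
#'
#' @param epochs An [epoched_signals()] object.
#' @param params A [wavelet_params()] object.
#' @return An object of class `phase_tensor`: fields `phase` (array channel
#'   x coefficient-time x FOI x epoch, radians in (-pi, pi]), `fois`,
#'   `interval` (coefficient spacing in s), `valid` (coefficient-time x FOI
#'   logical), `labels`, `brain`.
#' @export
morlet_phase <- function(epochs, params = wavelet_params()) {
  if (!inherits(epochs, "epoched_signals"))
    stop("`epochs` must be epoched_signals", call. = FALSE)
  fs <- epochs$sampling_rate
  d <- dim(epochs$data)
  n <- d[2]
  dur <- n / fs
  if (any(params$fois >= fs / 2))
    stop("FOI at or above Nyquist frequency (", fs / 2, " Hz)", call. = FALSE)
  short <- params$fois[dur * params$fois < params$cycles]
  if (length(short))
    stop("epoch too short to resolve FOI(s) ",
         paste(short, collapse = ", "),
         " Hz with ", params$cycles, " cycles", call. = FALSE)
  sigma <- params$cycles / (2 * pi * params$fois)
  half <- ceiling(4 * sigma * fs)
  nfft <- stats::nextn(n + 2L * max(half) + 1L, 2)
  kfft <- vector("list", length(params$fois))
  for (fi in seq_along(params$fois)) {
    tt <- seq(-half[fi], half[fi]) / fs
    ker <- exp(1i * 2 * pi * params$fois[fi] * tt) * exp(-tt^2 / (2 * sigma[fi]^2))
    kfft[[fi]] <- stats::fft(c(ker, rep(0, nfft - length(ker))))
  }
  idx <- seq(1L, n, by = params$step)
  nt <- length(idx)
  nf <- length(params$fois)
  phase <- array(NA_real_, c(d[1], nt, nf, d[3]))
  for (e in seq_len(d[3])) {
    for (ch in seq_len(d[1])) {
      x <- epochs$data[ch, , e]
      xf <- stats::fft(c(x, rep(0, nfft - n)))
      for (fi in seq_len(nf)) {
        y <- stats::fft(xf * kfft[[fi]], inverse = TRUE)[idx + half[fi]]
        phase[ch, , fi, e] <- Arg(y)
      }
    }
  }
  times <- (idx - 1) / fs
  valid <- matrix(TRUE, nt, nf)
  edge <- params$cycles / (2 * params$fois)
  for (fi in seq_len(nf))
    valid[, fi] <- times >= edge[fi] & times <= (n - 1) / fs - edge[fi]
  structure(list(phase = phase, fois = params$fois,
                 interval = params$step / fs, times = times, valid = valid,
                 labels = epochs$labels, brain = epochs$brain,
                 sampling_rate = fs, cycles = params$cycles),
            class = "phase_tensor")
}

#' Construct a phase-difference series directly
#'
#' Wraps a user-supplied array of pairwise phase differences into the
#' `phase_diff` container consumed by [psi()], [code_phase_difference()]
#' and friends — useful for feeding phase estimates obtained outside the
#' Morlet path, and for constructing analytic test cases.
#'
#' @param delta Array pair x time x FOI x epoch (lower dimensionality is
#'   promoted: a vector is one pair/FOI/epoch, a matrix is pair x time).
#'   Values are wrapped into (-pi, pi].
#' @param fois Frequencies of interest (Hz), one per FOI slice.
#' @param interval Coefficient spacing in seconds.
#' @param valid Optional time x FOI logical mask (default: all valid).
#' @param pairs Optional two-column matrix of channel indices.
#' @return A `phase_diff` object.
#' @export
phase_diff_series <- function(delta, fois, interval, valid = NULL,
                              pairs = NULL) {
  if (is.vector(delta)) delta <- matrix(delta, nrow = 1)
  if (length(dim(delta)) == 2) delta <- array(delta, c(dim(delta), 1, 1))
  if (length(dim(delta)) == 3) delta <- array(delta, c(dim(delta), 1))
  if (length(dim(delta)) != 4) stop("`delta` must be at most 4-d", call. = FALSE)
  if (dim(delta)[3] != length(fois))
    stop("third dimension must match length(fois)", call. = FALSE)
  stopifnot_scalar(interval, "interval", positive = TRUE)
  if (is.null(valid)) valid <- matrix(TRUE, dim(delta)[2], dim(delta)[3])
  if (is.null(pairs)) pairs <- cbind(seq_len(dim(delta)[1]), 0L)
  storage.mode(pairs) <- "integer"
  structure(list(delta = wrap_pi(delta), pairs = pairs,
                 fois = as.numeric(fois), interval = interval, valid = valid,
                 labels = NULL, brain = NULL),
            class = "phase_diff")
}

#' Pairwise wrapped phase differences
#'
#' For each ordered channel pair (m, n), computes
#' `wrap(phase_m - phase_n)` into (-pi, pi] at every coefficient time and
#' FOI.  A positive difference means channel m leads channel n.
#'
#' @param phases A [morlet_phase()] result.
#' @param pairs Two-column matrix or data.frame of ordered pairs, given as
#'   channel labels or indices.  Default: all ordered pairs m != n.
#' @return An object of class `phase_diff`: fields `delta` (pair x time x
#'   FOI x epoch), `pairs` (integer matrix with label attributes), plus the
#'   `fois`/`interval`/`valid` metadata of the input.
#' @export
phase_difference <- function(phases, pairs = NULL) {
  if (!inherits(phases, "phase_tensor"))
    stop("`phases` must be a phase_tensor", call. = FALSE)
  nc <- dim(phases$phase)[1]
  if (is.null(pairs)) {
    g <- expand.grid(n = seq_len(nc), m = seq_len(nc))
    g <- g[g$m != g$n, ]
    pairs <- cbind(g$m, g$n)
  } else {
    pairs <- as.matrix(pairs)
    if (ncol(pairs) != 2) stop("`pairs` must have two columns", call. = FALSE)
    if (is.character(pairs)) {
      ids <- match(pairs, phases$labels)
      if (anyNA(ids))
        stop("unknown channel(s): ",
             paste(unique(pairs[is.na(ids)]), collapse = ", "), call. = FALSE)
      pairs <- matrix(ids, ncol = 2)
    }
    if (any(pairs < 1 | pairs > nc))
      stop("pair index out of range", call. = FALSE)
  }
  storage.mode(pairs) <- "integer"
  dd <- dim(phases$phase)
  delta <- array(NA_real_, c(nrow(pairs), dd[2], dd[3], dd[4]))
  for (p in seq_len(nrow(pairs))) {
    delta[p, , , ] <- wrap_pi(phases$phase[pairs[p, 1], , , , drop = FALSE] -
                              phases$phase[pairs[p, 2], , , , drop = FALSE])
  }
  rownames(pairs) <- paste(phases$labels[pairs[, 1]],
                           phases$labels[pairs[, 2]], sep = "->")
  structure(list(delta = delta, pairs = pairs, fois = phases$fois,
                 interval = phases$interval, valid = phases$valid,
                 labels = phases$labels, brain = phases$brain),
            class = "phase_diff")
}
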