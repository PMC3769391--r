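#' Specification of a coupled oscillator pair
#'
#' Describes a two-channel validation dataset: channel A carries a unit
#' amplitude sinusoid at `frequency`; channel B carries the same oscillation
#' shifted back by a per-epoch phase shift (positive shift: channel A leads)
#' and delayed by `lag` seconds, each
#' channel with an independent additive white Gaussian noise realization.
#' With `phase_shift = "uniform"` the shift is drawn once per epoch from the
#' uniform distribution on (-pi, pi], reproducing the validation design of
#' band-limited oscillations with random per-epoch phase offsets.
#'
#' @param frequency Oscillation frequency in Hz (> 0).
#' @param duration Epoch length in seconds (> 0); default 3 s.
#' @param sampling_rate Hz; default 250.
#' @param phase_shift Either a fixed radian value or the string "uniform"
#'   (per-epoch draw from (-pi, pi]).
#' @param lag Delay of channel B relative to channel A in seconds.
#' @param noise_sd Standard deviation of the additive Gaussian noise
#'   (oscillation amplitude is fixed at 1); default 0.5.
#' @param n_epochs Number of epochs (>= 1).
#' @param seed Integer seed; the generator is a pure function of (spec, seed).
#' @return An object of class `oscillator_pair_spec`.
#' @export
oscillator_pair_spec <- function(frequency, duration = 3, sampling_rate = 250,
                                 phase_shift = "uniform", lag = 0,
                                 noise_sd = 0.5, n_epochs = 1, seed = 1) {
  stopifnot_scalar(frequency, "frequency", positive = TRUE)
  stopifnot_scalar(duration, "duration", positive = TRUE)
  stopifnot_scalar(sampling_rate, "sampling_rate", positive = TRUE)
  stopifnot_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  stopifnot_scalar(lag, "lag")
  if (!is.numeric(n_epochs) || n_epochs < 1)
    stop("`n_epochs` must be >= 1", call. = FALSE)
  if (!(identical(phase_shift, "uniform") ||
        (is.numeric(phase_shift) && length(phase_shift) == 1L)))
    stop("`phase_shift` must be a radian scalar or \"uniform\"", call. = FALSE)
  structure(list(frequency = frequency, duration = duration,
                 sampling_rate = sampling_rate, phase_shift = phase_shift,
                 lag = lag, noise_sd = noise_sd,
                 n_epochs = as.integer(n_epochs), seed = as.integer(seed)),
            class = "oscillator_pair_spec")
}

#' Generate a coupled oscillator pair
#'
#' @param spec An [oscillator_pair_spec()].
#' @return An [epoched_signals()] object with channels "A" and "B" and brain
#'   membership A/B.  The drawn per-epoch phase shifts are attached as
#'   attribute `"phase_shifts"`.
#' @export
generate_oscillator_pair <- function(spec) {
  if (!inherits(spec, "oscillator_pair_spec"))
    stop("`spec` must be an oscillator_pair_spec", call. = FALSE)
  n <- round(spec$duration * spec$sampling_rate)
  t <- (seq_len(n) - 1) / spec$sampling_rate
  with_seed(spec$seed, {
    shifts <- if (identical(spec$phase_shift, "uniform")) {
      # uniform on (-pi, pi]: negate a draw from [-pi, pi)
      -(stats::runif(spec$n_epochs, -pi, pi))
    } else rep(spec$phase_shift, spec$n_epochs)
    dat <- array(0, c(2L, n, spec$n_epochs))
    w <- 2 * pi * spec$frequency
    for (e in seq_len(spec$n_epochs)) {
      a <- sin(w * t)
      b <- sin(w * (t - spec$lag) - shifts[e])   # positive shift: B delayed, A leads
      if (spec$noise_sd > 0) {
        a <- a + stats::rnorm(n, 0, spec$noise_sd)
        b <- b + stats::rnorm(n, 0, spec$noise_sd)
      }
      dat[1, , e] <- a
      dat[2, , e] <- b
    }
    out <- epoched_signals(dat, spec$sampling_rate, c("A", "B"), c("A", "B"))
    attr(out, "phase_shifts") <- shifts
    out
  })
}

#' Specification of a two-brain oscillator dataset
#'
#' Stand-in for an (undeposited) dual-EEG recording: two "brains" of
#' `channels_per_brain` channels each, all carrying independent Gaussian
#' background noise, with selected channel pairs additionally carrying a
#' shared oscillation.  Each coupling entry injects a sinusoid at `frequency`
#' Hz (random per-epoch starting phase) into the source channel and the same
#' sinusoid delayed by `lag` seconds, scaled by `strength`, into the target.
#'
#' @param channels_per_brain Channels per brain (default 21, labelled with
#'   the 10-20 montage; other counts get labels "ch01", ...).
#' @param couplings A data.frame with columns `source`, `target` (channel
#'   names like "A:Fz", "B:Cz"), `frequency` (Hz), `lag` (s), `strength`
#'   (amplitude of the injected oscillation); may be empty/NULL.
#' @param noise_sd Background noise standard deviation (default 1).
#' @param seed Integer seed.
#' @return An object of class `hyper_brain_spec`.
#' @export
hyper_brain_spec <- function(channels_per_brain = 21, couplings = NULL,
                             noise_sd = 1, seed = 1) {
  if (!is.numeric(channels_per_brain) || channels_per_brain < 1)
    stop("`channels_per_brain` must be >= 1", call. = FALSE)
  channels_per_brain <- as.integer(channels_per_brain)
  stopifnot_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  elec <- if (channels_per_brain == 21L) montage_1020()$label
          else sprintf("ch%02d", seq_len(channels_per_brain))
  labels <- c(paste0("A:", elec), paste0("B:", elec))
  if (is.null(couplings)) {
    couplings <- data.frame(source = character(), target = character(),
                            frequency = numeric(), lag = numeric(),
                            strength = numeric(), stringsAsFactors = FALSE)
  }
  need <- c("source", "target", "frequency", "lag", "strength")
  if (!all(need %in% names(couplings)))
    stop("`couplings` needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(c(couplings$source, couplings$target)), labels)
  if (length(bad))
    stop("coupling entry references missing channel(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(list(channels_per_brain = channels_per_brain, labels = labels,
                 couplings = couplings, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "hyper_brain_spec")
}

#' Generate a two-brain oscillator dataset
#'
#' @param spec A [hyper_brain_spec()].
#' @param epoch_length Epoch length in seconds (default 10).
#' @param n_epochs Number of epochs (default 1).
#' @param sampling_rate Hz (default 250).
#' @return An [epoched_signals()] object with `2 * channels_per_brain`
#'   channels labelled "A:<electrode>" / "B:<electrode>".
#' @export
generate_hyper_brain_dataset <- function(spec, epoch_length = 10, n_epochs = 1,
                                         sampling_rate = 250) {
  if (!inherits(spec, "hyper_brain_spec"))
    stop("`spec` must be a hyper_brain_spec", call. = FALSE)
  stopifnot_scalar(epoch_length, "epoch_length", positive = TRUE)
  n <- round(epoch_length * sampling_rate)
  nc <- 2L * spec$channels_per_brain
  t <- (seq_len(n) - 1) / sampling_rate
  with_seed(spec$seed, {
    dat <- array(stats::rnorm(nc * n * n_epochs, 0, spec$noise_sd),
                 c(nc, n, n_epochs))
    if (nrow(spec$couplings)) {
      for (e in seq_len(n_epochs)) {
        for (ci in seq_len(nrow(spec$couplings))) {
          cp <- spec$couplings[ci, ]
          phi0 <- stats::runif(1, -pi, pi)
          si <- match(cp$source, spec$labels)
          ti <- match(cp$target, spec$labels)
          w <- 2 * pi * cp$frequency
          dat[si, , e] <- dat[si, , e] + cp$strength * sin(w * t + phi0)
          dat[ti, , e] <- dat[ti, , e] + cp$strength * sin(w * (t - cp$lag) + phi0)
        }
      }
    }
    brain <- rep(c("A", "B"), each = spec$channels_per_brain)
    epoched_signals(dat, sampling_rate, spec$labels, brain)
  })
}

#' Shuffle surrogate of epoched signals
#'
#' Independently permutes the samples of every channel within every epoch.
#' This destroys all temporal (and hence phase) structure while preserving
#' each channel's amplitude histogram exactly — the surrogate construction
#' used for significance thresholding of the coupling measures.
#'
#' @param signals An [epoched_signals()] object.
#' @param seed Integer seed; identical seed gives the identical permutation.
#' @return An [epoched_signals()] object of identical shape.
#' @export
shuffle_surrogate <- function(signals, seed = 1) {
  if (!inherits(signals, "epoched_signals"))
    stop("`signals` must be epoched_signals", call. = FALSE)
  d <- dim(signals$data)
  if (any(d == 0)) stop("empty input", call. = FALSE)
  with_seed(seed, {
    out <- signals
    for (e in seq_len(d[3]))
      for (ch in seq_len(d[1]))
        out$data[ch, , e] <- signals$data[ch, sample.int(d[2]), e]
    out
  })
}
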