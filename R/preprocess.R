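#' Artifact rejection criteria
#'
#' Two deterministic criteria applied per channel within each epoch: a
#' gradient criterion (maximum admissible voltage step between consecutive
#' samples) and a difference criterion (maximum admissible max-minus-min
#' range within the epoch).  Thresholds are in recording units and
#' configurable; the defaults are 50 and 200.
#'
#' @param max_step Maximum |x[t+1] - x[t]| (default 50).
#' @param max_range Maximum (max - min) within an epoch (default 200).
#' @return An object of class `artifact_criteria`.
#' @export
artifact_criteria <- function(max_step = 50, max_range = 200) {
  stopifnot_scalar(max_step, "max_step", positive = TRUE)
  stopifnot_scalar(max_range, "max_range", positive = TRUE)
  structure(list(max_step = max_step, max_range = max_range),
            class = "artifact_criteria")
}

#' Re-reference to linked mastoids
#'
#' Subtracts the average of the left and right mastoid channels from every
#' non-EOG channel.
#'
#' @param raw A [raw_recording()].
#' @param left_label,right_label Mastoid channel labels.
#' @return A re-referenced [raw_recording()].
#' @export
rereference_linked_mastoids <- function(raw, left_label = "M1",
                                        right_label = "M2") {
  for (lab in c(left_label, right_label))
    if (!lab %in% raw$labels)
      stop("mastoid channel not found: ", lab, call. = FALSE)
  ref <- (raw$samples[left_label, ] + raw$samples[right_label, ]) / 2
  eeg <- setdiff(raw$labels, raw$eog)
  raw$samples[eeg, ] <- sweep(raw$samples[eeg, , drop = FALSE], 2, ref)
  raw$reference <- sprintf("linked(%s,%s)", left_label, right_label)
  raw
}

#' Zero-phase band-pass filter
#'
#' Frequency-domain (hence exactly zero-phase) band-pass with raised-cosine
#' transition bands; the DC component is removed.  Zero-phase filtering is
#' essential here because any filter phase distortion would bias the
#' downstream phase-coupling measures.
#'
#' @param raw A [raw_recording()].
#' @param low,high Band edges in Hz (defaults 0.5 and 70).
#' @return A filtered [raw_recording()].
#' @export
bandpass <- function(raw, low = 0.5, high = 70) {
  fs <- raw$sampling_rate
  if (!(low > 0 && low < high && high < fs / 2))
    stop("invalid band: need 0 < low < high < sampling_rate/2", call. = FALSE)
  raw$samples <- fft_bandpass_matrix(raw$samples, fs, low, high)
  rownames(raw$samples) <- raw$labels
  raw
}

#' Regression-based EOG artifact correction
#'
#' Per EEG channel, propagation factors onto the EOG channels are estimated
#' by ordinary least squares (EOG as independent variables, intercept
#' included) and the scaled EOG voltages are subtracted, so that the
#' corrected channel is uncorrelated with the EOG on the fit data.
#'
#' @param raw A [raw_recording()].
#' @param eog_labels EOG channel labels (default `raw$eog`).
#' @return A corrected [raw_recording()]; estimated propagation factors are
#'   attached as attribute `"propagation_factors"` (EEG channel x EOG).
#' @export
correct_eog_regression <- function(raw, eog_labels = raw$eog) {
  if (!length(eog_labels)) stop("no EOG channels given", call. = FALSE)
  missing <- setdiff(eog_labels, raw$labels)
  if (length(missing))
    stop("EOG channel not found: ", paste(missing, collapse = ", "), call. = FALSE)
  X <- t(raw$samples[eog_labels, , drop = FALSE])
  if (any(apply(X, 2, stats::var) == 0))
    stop("EOG channel has zero variance; cannot estimate propagation factors",
         call. = FALSE)
  eeg <- setdiff(raw$labels, eog_labels)
  Xc <- cbind(1, X)
  coefs <- qr.solve(Xc, t(raw$samples[eeg, , drop = FALSE]))
  beta <- coefs[-1, , drop = FALSE]                # drop intercept
  raw$samples[eeg, ] <- raw$samples[eeg, , drop = FALSE] - t(X %*% beta)
  attr(raw, "propagation_factors") <-
    matrix(t(beta), nrow = length(eeg),
           dimnames = list(eeg, eog_labels))
  raw
}

#' Resample and cut into epochs
#'
#' Band-limited (Fourier) resampling to `target_rate`, then segmentation
#' into consecutive non-overlapping epochs; a trailing partial epoch is
#' discarded.
#'
#' @param raw A [raw_recording()].
#' @param target_rate Target sampling rate in Hz (default 250).
#' @param epoch_length Epoch length in seconds (default 10).
#' @return An [epoched_signals()] object.
#' @export
resample_and_epoch <- function(raw, target_rate = 250, epoch_length = 10) {
  stopifnot_scalar(target_rate, "target_rate", positive = TRUE)
  stopifnot_scalar(epoch_length, "epoch_length", positive = TRUE)
  if (target_rate > raw$sampling_rate)
    stop("`target_rate` must not exceed the recording rate", call. = FALSE)
  n_in <- ncol(raw$samples)
  n_out <- round(n_in * target_rate / raw$sampling_rate)
  n_per <- round(target_rate * epoch_length)
  ne <- floor(n_out / n_per)
  if (ne < 1)
    stop(sprintf("recording (%.2f s) shorter than one epoch (%g s)",
                 n_in / raw$sampling_rate, epoch_length), call. = FALSE)
  res <- t(apply(raw$samples, 1, fft_resample, n_out = n_out))
  dat <- array(0, c(nrow(res), n_per, ne))
  for (e in seq_len(ne))
    dat[, , e] <- res[, ((e - 1) * n_per + 1):(e * n_per), drop = FALSE]
  epoched_signals(dat, target_rate, raw$labels, raw$brain)
}

#' Reject artifact epochs
#'
#' Drops every epoch in which any channel violates the gradient criterion
#' (consecutive-sample step above `max_step`) or the difference criterion
#' (within-epoch max-minus-min above `max_range`).
#'
#' @param epochs An [epoched_signals()] object.
#' @param criteria An [artifact_criteria()] object.
#' @return The surviving epochs, with a data.frame attribute
#'   `"rejection_log"` (columns epoch, channel, criterion, value); retrieve
#'   it with [rejection_log()].  If everything is rejected an empty set is
#'   returned with a warning.
#' @export
reject_artifacts <- function(epochs, criteria = artifact_criteria()) {
  d <- dim(epochs$data)
  log <- list()
  bad <- logical(d[3])
  for (e in seq_len(d[3])) {
    for (ch in seq_len(d[1])) {
      x <- epochs$data[ch, , e]
      step <- max(abs(diff(x)))
      rng <- max(x) - min(x)
      if (step > criteria$max_step)
        log[[length(log) + 1L]] <- data.frame(
          epoch = e, channel = epochs$labels[ch],
          criterion = "gradient", value = step, stringsAsFactors = FALSE)
      if (rng > criteria$max_range)
        log[[length(log) + 1L]] <- data.frame(
          epoch = e, channel = epochs$labels[ch],
          criterion = "difference", value = rng, stringsAsFactors = FALSE)
      if (step > criteria$max_step || rng > criteria$max_range) bad[e] <- TRUE
    }
  }
  log <- if (length(log)) do.call(rbind, log) else
    data.frame(epoch = integer(), channel = character(),
               criterion = character(), value = numeric(),
               stringsAsFactors = FALSE)
  if (all(bad)) warning("all epochs rejected", call. = FALSE)
  out <- epochs
  out$data <- epochs$data[, , !bad, drop = FALSE]
  attr(out, "rejection_log") <- log
  out
}

#' @rdname reject_artifacts
#' @param x Output of [reject_artifacts()].
#' @export
rejection_log <- function(x) attr(x, "rejection_log")

#' Restrict and order channels to a montage
#'
#' Selects, per brain, the montage electrodes in montage order (so a dyad
#' yields `2 * nrow(montage)` channels) and attaches region metadata.
#' Channel labels may carry an "A:"/"B:" brain prefix.
#'
#' @param epochs An [epoched_signals()] object.
#' @param montage A [montage_spec()]; default [montage_1020()].
#' @return An [epoched_signals()] object with attribute `"region"` (per
#'   channel).
#' @export
select_montage <- function(epochs, montage = montage_1020()) {
  keep <- integer()
  for (b in unique(epochs$brain)) {
    idx_b <- which(epochs$brain == b)
    elec <- electrode_of(epochs$labels[idx_b])
    pos <- match(montage$label, elec)
    if (anyNA(pos))
      stop("montage label(s) missing for brain ", b, ": ",
           paste(montage$label[is.na(pos)], collapse = ", "), call. = FALSE)
    keep <- c(keep, idx_b[pos])
  }
  out <- epochs
  out$data <- epochs$data[keep, , , drop = FALSE]
  out$labels <- epochs$labels[keep]
  out$brain <- epochs$brain[keep]
  dimnames(out$data)[[1]] <- out$labels
  attr(out, "region") <- montage$region[match(electrode_of(out$labels),
                                              montage$label)]
  out
}
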