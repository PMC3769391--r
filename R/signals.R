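#' Raw multichannel recording
#'
#' Container for an unsegmented EEG recording: a channels x samples amplitude
#' matrix plus sampling rate and channel metadata.  For dual-subject
#' (hyperscanning) recordings the `brain` vector assigns each channel to
#' subject "A" or "B".
#'
#' @param samples Numeric matrix, channels x samples.
#' @param sampling_rate Sampling rate in Hz.
#' @param labels Character vector of unique channel labels.
#' @param brain Character vector ("A"/"B") per channel; default all "A".
#' @param reference Label of the recording reference (informational).
#' @param eog Labels of EOG channels.
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(samples, sampling_rate, labels,
                          brain = rep("A", nrow(samples)),
                          reference = NULL, eog = character()) {
  samples <- as.matrix(samples)
  stopifnot_scalar(sampling_rate, "sampling_rate", positive = TRUE)
  if (length(labels) != nrow(samples))
    stop("`labels` must have one entry per channel", call. = FALSE)
  if (anyDuplicated(labels))
    stop("channel labels must be unique", call. = FALSE)
  if (length(brain) != nrow(samples))
    stop("`brain` must have one entry per channel", call. = FALSE)
  bad <- setdiff(eog, labels)
  if (length(bad))
    stop("EOG label(s) not present: ", paste(bad, collapse = ", "), call. = FALSE)
  rownames(samples) <- labels
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 labels = as.character(labels), brain = as.character(brain),
                 reference = reference, eog = as.character(eog)),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$sampling_rate,
              ncol(x$samples) / x$sampling_rate))
  invisible(x)
}

#' Epoched multichannel signals
#'
#' Channels x samples x epochs array with sampling rate, channel labels and
#' brain membership — the common currency between the generator, the
#' preprocessing chain and the spectral stage.
#'
#' @param data Numeric array channels x samples x epochs (a matrix is treated
#'   as a single epoch).
#' @param sampling_rate Hz.
#' @param labels Character channel labels (unique).
#' @param brain "A"/"B" membership per channel.
#' @return An object of class `epoched_signals`.
#' @export
epoched_signals <- function(data, sampling_rate, labels,
                            brain = rep("A", dim(data)[1])) {
  if (is.matrix(data)) data <- array(data, c(nrow(data), ncol(data), 1L))
  if (length(dim(data)) != 3L)
    stop("`data` must be a channels x samples x epochs array", call. = FALSE)
  stopifnot_scalar(sampling_rate, "sampling_rate", positive = TRUE)
  if (length(labels) != dim(data)[1])
    stop("`labels` must have one entry per channel", call. = FALSE)
  if (anyDuplicated(labels))
    stop("channel labels must be unique", call. = FALSE)
  if (length(brain) != dim(data)[1])
    stop("`brain` must have one entry per channel", call. = FALSE)
  dimnames(data) <- list(labels, NULL, NULL)
  structure(list(data = data, sampling_rate = sampling_rate,
                 labels = as.character(labels), brain = as.character(brain)),
            class = "epoched_signals")
}

#' @export
print.epoched_signals <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoched_signals> %d channels x %d samples x %d epochs @ %g Hz\n",
              d[1], d[2], d[3], x$sampling_rate))
  cat(sprintf("  brains: %s\n",
              paste(sprintf("%s (%d)", names(table(x$brain)), table(x$brain)),
                    collapse = ", ")))
  invisible(x)
}

#' @export
dim.epoched_signals <- function(x) dim(x$data)

#' Number of epochs
#' @param x An `epoched_signals` object.
#' @return Integer epoch count.
#' @export
n_epochs <- function(x) dim(x$data)[3]

#' Standard 21-electrode 10-20 montage
#'
#' The 21 scalp positions of the international 10-20 system together with
#' their assignment to three anterior-posterior regions (frontal, central,
#' parieto-occipital) used when collapsing node-level statistics.
#'
#' @return A data.frame with columns `label` and `region` (21 rows).
#' @export
montage_1020 <- function() {
  labels <- c("Fp1", "Fpz", "Fp2", "F7", "F3", "Fz", "F4", "F8",
              "T7", "C3", "Cz", "C4", "T8",
              "P7", "P3", "Pz", "P4", "P8", "O1", "Oz", "O2")
  region <- c(rep("frontal", 8), rep("central", 5), rep("parieto-occipital", 8))
  montage_spec(labels, stats::setNames(region, labels))
}

#' Montage specification
#'
#' @param labels Ordered electrode labels.
#' @param region_map Named character vector mapping each label to one of
#'   "frontal", "central", "parieto-occipital".
#' @return A data.frame of class `montage_spec` with columns label, region.
#' @export
montage_spec <- function(labels, region_map) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("montage labels must be unique", call. = FALSE)
  missing <- setdiff(labels, names(region_map))
  if (length(missing))
    stop("no region for label(s): ", paste(missing, collapse = ", "), call. = FALSE)
  out <- data.frame(label = labels,
                    region = unname(region_map[labels]),
                    stringsAsFactors = FALSE)
  class(out) <- c("montage_spec", "data.frame")
  out
}

# strip an optional "A:"/"B:"/"a:"/"b:" brain prefix from channel labels
electrode_of <- function(labels) sub("^[AaBb]:", "", labels)
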