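#' Read a raw recording
#'
#' Dispatches on `format` (or the file extension for "auto"): BrainVision
#' (`.vhdr` + `.eeg`/`.vmrk`), EDF, or the delimited-text fallback (header
#' row of channel labels, one row per sample, JSON sidecar `<path>.json`
#' with `sampling_rate` and optional `brain`/`eog`/`reference`).  Channel
#' labels with an "A:"/"B:" (or "a:"/"b:") prefix are assigned to the
#' corresponding brain, supporting merged dual-subject files.
#'
#' @param path File path.
#' @param format One of "auto", "delimited", "brainvision", "edf".
#' @return A [raw_recording()].
#' @export
read_raw <- function(path, format = c("auto", "delimited", "brainvision", "edf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, vhdr = "brainvision", edf = "edf", "delimited")
  }
  switch(format,
         delimited = read_raw_delimited(path),
         brainvision = read_brainvision(path),
         edf = read_edf(path))
}

brain_from_labels <- function(labels) {
  ifelse(grepl("^[Bb]:", labels), "B",
         ifelse(grepl("^[Aa]:", labels), "A", "A"))
}

#' @rdname read_raw
#' @export
read_raw_delimited <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("missing sidecar: ", sidecar, call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  labels <- colnames(tab)
  raw_recording(t(as.matrix(tab)), meta$sampling_rate, labels,
                brain = if (!is.null(meta$brain)) meta$brain
                        else brain_from_labels(labels),
                reference = meta$reference,
                eog = if (!is.null(meta$eog)) meta$eog else character())
}

#' Write a recording as delimited text
#'
#' @param raw A [raw_recording()].
#' @param path Output path; the JSON sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_raw_delimited <- function(raw, path) {
  tab <- as.data.frame(t(raw$samples))
  colnames(tab) <- raw$labels
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(sampling_rate = raw$sampling_rate, brain = raw$brain,
         eog = raw$eog, reference = raw$reference),
    paste0(path, ".json"), auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

parse_vhdr <- function(path) {
  lines <- readLines(path, warn = FALSE)
  section <- ""
  kv <- list()
  channels <- list()
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[", ln)) {
      section <- gsub("\\[|\\]", "", ln)
      next
    }
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) next
    key <- trimws(substr(ln, 1, eq - 1))
    val <- trimws(substr(ln, eq + 1, nchar(ln)))
    if (section == "Channel Infos") channels[[key]] <- val
    else kv[[paste(section, key, sep = ".")]] <- val
  }
  list(kv = kv, channels = channels)
}

#' @rdname read_raw
#' @export
read_brainvision <- function(path) {
  h <- parse_vhdr(path)
  kv <- h$kv
  dir <- dirname(path)
  datafile <- file.path(dir, kv[["Common Infos.DataFile"]])
  if (!file.exists(datafile)) stop("data file not found: ", datafile, call. = FALSE)
  nchan <- as.integer(kv[["Common Infos.NumberOfChannels"]])
  srate <- 1e6 / as.numeric(kv[["Common Infos.SamplingInterval"]])
  orient <- toupper(kv[["Common Infos.DataOrientation"]] %||% "MULTIPLEXED")
  fmt <- toupper(kv[["Common Infos.DataFormat"]] %||% "BINARY")
  chinfo <- lapply(h$channels, function(v) strsplit(v, ",")[[1]])
  labels <- vapply(chinfo, `[`, "", 1)
  res <- vapply(chinfo, function(v)
    if (length(v) >= 3 && nzchar(v[3])) as.numeric(v[3]) else 1, 0)
  if (length(labels) != nchan)
    stop("channel count mismatch in ", path, call. = FALSE)
  if (fmt == "ASCII") {
    tab <- utils::read.table(datafile, header = FALSE)
    x <- t(as.matrix(tab))                     # lines are samples
  } else {
    bfmt <- toupper(kv[["Binary Infos.BinaryFormat"]] %||% "IEEE_FLOAT_32")
    sz <- file.info(datafile)$size
    if (bfmt == "IEEE_FLOAT_32") {
      v <- readBin(datafile, "numeric", n = sz / 4, size = 4, endian = "little")
    } else if (bfmt == "INT_16") {
      v <- readBin(datafile, "integer", n = sz / 2, size = 2, signed = TRUE,
                   endian = "little")
    } else stop("unsupported BinaryFormat: ", bfmt, call. = FALSE)
    ns <- length(v) %/% nchan
    v <- v[seq_len(ns * nchan)]
    x <- if (orient == "VECTORIZED") matrix(v, nrow = nchan, byrow = TRUE)
         else matrix(v, nrow = nchan)
    x <- x * res
  }
  if (anyDuplicated(labels))
    stop("label collision in ", path, call. = FALSE)
  raw_recording(x, srate, labels, brain = brain_from_labels(labels))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a recording in BrainVision format
#'
#' Writes the `.vhdr` header, a minimal `.vmrk` marker file and the data
#' file (multiplexed IEEE float32 binary, or ASCII when
#' `ascii = TRUE`).
#'
#' @param raw A [raw_recording()].
#' @param vhdr_path Path for the header file (`.vhdr`).
#' @param ascii Write ASCII data instead of binary float32.
#' @return `vhdr_path`, invisibly.
#' @export
write_brainvision <- function(raw, vhdr_path, ascii = FALSE) {
  stem <- sub("\\.vhdr$", "", vhdr_path)
  base <- basename(stem)
  datafile <- paste0(stem, ".eeg")
  vmrk <- paste0(stem, ".vmrk")
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", basename(datafile)),
    paste0("MarkerFile=", basename(vmrk)),
    paste0("DataFormat=", if (ascii) "ASCII" else "BINARY"),
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nrow(raw$samples)),
    paste0("SamplingInterval=", format(1e6 / raw$sampling_rate, scientific = FALSE)),
    if (ascii) c("[ASCII Infos]", "DecimalSymbol=.")
    else c("[Binary Infos]", "BinaryFormat=IEEE_FLOAT_32"),
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(nrow(raw$samples)), raw$labels))
  writeLines(hdr, vhdr_path, useBytes = TRUE)
  writeLines(c("Brain Vision Data Exchange Marker File, Version 1.0",
               "[Common Infos]", paste0("DataFile=", basename(datafile)),
               "[Marker Infos]",
               "Mk1=New Segment,,1,1,0,0"), vmrk)
  if (ascii) {
    utils::write.table(t(raw$samples), datafile, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
  } else {
    con <- file(datafile, "wb")
    on.exit(close(con))
    writeBin(as.numeric(raw$samples), con, size = 4, endian = "little")
  }
  invisible(vhdr_path)
}

#' @rdname read_raw
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  rd(8)                                   # version
  rd(80); rd(80); rd(8); rd(8)            # patient, recording, date, time
  as.integer(rd(8))                       # header bytes
  rd(44)                                  # reserved
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)           # transducer
  for (i in seq_len(ns)) rd(8)            # physical dimension
  pmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)           # prefiltering
  nspr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)           # reserved
  x <- matrix(0, ns, n_rec * nspr[1])
  if (length(unique(nspr)) != 1)
    stop("per-channel sampling rates unsupported", call. = FALSE)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = nspr[ch], size = 2, signed = TRUE,
                     endian = "little")
      phys <- (dig - dmin[ch]) / (dmax[ch] - dmin[ch]) *
        (pmax[ch] - pmin[ch]) + pmin[ch]
      x[ch, ((r - 1) * nspr[ch] + 1):(r * nspr[ch])] <- phys
    }
  }
  srate <- nspr[1] / dur
  if (anyDuplicated(labels)) stop("label collision in ", path, call. = FALSE)
  raw_recording(x, srate, labels, brain = brain_from_labels(labels))
}

#' Write a recording as EDF
#'
#' Minimal continuous EDF writer (16-bit, identical sampling rate on all
#' channels, 1-s data records; a trailing partial second is dropped).
#'
#' @param raw A [raw_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(raw, path) {
  fs <- raw$sampling_rate
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF writer needs an integer sampling rate", call. = FALSE)
  fs <- as.integer(round(fs))
  ns <- nrow(raw$samples)
  n_rec <- floor(ncol(raw$samples) / fs)
  if (n_rec < 1) stop("recording shorter than one EDF record (1 s)", call. = FALSE)
  x <- raw$samples[, seq_len(n_rec * fs), drop = FALSE]
  pmin <- apply(x, 1, min)
  pmax <- apply(x, 1, max)
  pmax <- ifelse(pmax > pmin, pmax, pmin + 1)
  dmin <- -32768
  dmax <- 32767
  pad <- function(s, n) {
    s <- substr(as.character(s), 1, n)
    formatC(s, width = n, flag = "-")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, n) writeBin(charToRaw(pad(s, n)), con)
  wr("0", 8); wr("X", 80); wr("X", 80)
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(256 + 256 * ns, 8); wr("", 44)
  wr(n_rec, 8); wr("1", 8); wr(ns, 4)
  for (l in raw$labels) wr(l, 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(formatC(pmin[i], digits = 5, format = "g"), 8)
  for (i in seq_len(ns)) wr(formatC(pmax[i], digits = 5, format = "g"), 8)
  for (i in seq_len(ns)) wr(dmin, 8)
  for (i in seq_len(ns)) wr(dmax, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(fs, 8)
  for (i in seq_len(ns)) wr("", 32)
  # re-read the header's physical min/max (printed precision) for scaling
  pmin_p <- as.numeric(formatC(pmin, digits = 5, format = "g"))
  pmax_p <- as.numeric(formatC(pmax, digits = 5, format = "g"))
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      seg <- x[ch, ((r - 1) * fs + 1):(r * fs)]
      dig <- round((seg - pmin_p[ch]) / (pmax_p[ch] - pmin_p[ch]) *
                     (dmax - dmin) + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Export a hyper-brain graph as GraphML
#'
#' Vertex attributes: label, brain and (when present) region; edge
#' attribute: weight.
#'
#' @param g A [hyper_brain_graph()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(g, path) {
  ig <- igraph::graph_from_adjacency_matrix(
    g$W, mode = if (g$directed) "directed" else "undirected",
    weighted = TRUE)
  igraph::V(ig)$brain <- g$nodes$brain
  if (!is.null(g$nodes$region)) igraph::V(ig)$region <- g$nodes$region
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' Write coupling matrices as delimited text
#'
#' One TSV per measure and FOI (`<measure>_<foi>Hz.tsv`) plus a
#' `nodes.tsv` metadata sidecar, and a single structured binary container
#' (`coupling_matrices.rds`).
#'
#' @param mats A [connectivity_matrices()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_coupling_matrices <- function(mats, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fois <- attr(mats, "fois")
  for (m in names(mats)) {
    for (fi in seq_along(fois)) {
      utils::write.table(
        mats[[m]][, , fi],
        file.path(dir, sprintf("%s_%gHz.tsv", m, fois[fi])),
        sep = "\t", quote = FALSE)
    }
  }
  utils::write.table(attr(mats, "nodes"), file.path(dir, "nodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  saveRDS(mats, file.path(dir, "coupling_matrices.rds"))
  invisible(dir)
}
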