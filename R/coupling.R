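# Internal cores operate on plain pair x time matrices so that the
# user-facing operations and the all-pairs matrix assembly share one code
# path.

psi_core <- function(dmat) {
  if (ncol(dmat) < 2) stop("PSI needs k >= 2 coefficient times", call. = FALSE)
  Mod(rowMeans(exp(1i * dmat)))
}

code_core <- function(dmat) {
  codes <- matrix(0L, nrow(dmat), ncol(dmat))
  codes[dmat >= 0 & dmat < pi / 4] <- 1L
  codes[dmat > -pi / 4 & dmat < 0] <- -1L
  codes
}

clean_core <- function(cmat, min_run) {
  if (min_run <= 1L) return(cmat)
  t(apply(cmat, 1, clean_run_vector, min_run = min_run))
}

min_run_points <- function(foi, interval) {
  # a run of r points spans r * interval seconds of locking; runs shorter
  # than one oscillation period T = 1/f are discarded
  as.integer(ceiling(1 / (foi * interval) - 1e-9))
}

indices_core <- function(cmat, k) {
  if (k < 1) stop("k = 0 valid coefficient times", call. = FALSE)
  pci <- rowSums(cmat == 1L) / k
  nci <- rowSums(cmat == -1L) / k
  # ICI = PCI * 1/(1+NCI); the factor 1/(1+NCI) lies in [0.5, 1] and
  # approaches 0.5 when all locked points are negative, driving ICI to 0
  list(pci = pci, nci = nci, aci = pci + nci, ici = pci / (1 + nci))
}

#' Phase Synchronization Index (PSI)
#'
#' Mean resultant length of the phase-difference angles across the valid
#' (non-edge) coefficient times of each epoch.  PSI measures phase stability
#' across time irrespective of the preferred phase angle; it is 1 for a
#' perfectly constant phase difference and tends to 0 for uniformly
#' distributed differences.
#'
#' @param delta_phi A [phase_difference()] result.
#' @return Numeric array pair x FOI x epoch in `[0, 1]`.
#' @export
psi <- function(delta_phi) {
  if (!inherits(delta_phi, "phase_diff"))
    stop("`delta_phi` must be a phase_diff", call. = FALSE)
  dd <- dim(delta_phi$delta)
  out <- array(NA_real_, c(dd[1], dd[3], dd[4]),
               dimnames = list(rownames(delta_phi$pairs), delta_phi$fois, NULL))
  for (fi in seq_len(dd[3])) {
    tv <- delta_phi$valid[, fi]
    for (e in seq_len(dd[4])) {
      sub <- delta_phi$delta[, tv, fi, e, drop = FALSE]
      dim(sub) <- c(dd[1], sum(tv))
      out[, fi, e] <- psi_core(sub)
    }
  }
  out
}

#' Code phase differences into {-1, 0, +1}
#'
#' Applies the in-phase synchronization coding: +1 for differences in
#' `[0, +pi/4)` (first channel leads), -1 for `(-pi/4, 0)` (first channel
#' lags), 0 otherwise (non-synchronization).  The boundary 0 is assigned to
#' the positive bin and the outer boundaries +/-pi/4 code 0.
#'
#' @param delta_phi A [phase_difference()] result.
#' @return An object of class `coded_series` (field `codes`, pair x time x
#'   FOI x epoch integer array; `cleaned = FALSE`).
#' @export
code_phase_difference <- function(delta_phi) {
  if (!inherits(delta_phi, "phase_diff"))
    stop("`delta_phi` must be a phase_diff", call. = FALSE)
  codes <- array(0L, dim(delta_phi$delta))
  codes[delta_phi$delta >= 0 & delta_phi$delta < pi / 4] <- 1L
  codes[delta_phi$delta > -pi / 4 & delta_phi$delta < 0] <- -1L
  structure(list(codes = codes, pairs = delta_phi$pairs,
                 fois = delta_phi$fois, interval = delta_phi$interval,
                 valid = delta_phi$valid, cleaned = FALSE),
            class = "coded_series")
}

#' Remove accidental-synchronization runs
#'
#' Recodes to 0 every maximal run of consecutive same-sign nonzero codes
#' whose duration is shorter than one period `T = 1/f` of the corresponding
#' frequency of interest (a sign flip ends a run).  Longer runs are left
#' untouched.  Only valid (non-edge) coefficient times are considered.
#'
#' @param codes A [code_phase_difference()] result.
#' @return The cleaned `coded_series` (`cleaned = TRUE`).
#' @export
clean_codes <- function(codes) {
  if (!inherits(codes, "coded_series"))
    stop("`codes` must be a coded_series", call. = FALSE)
  if (codes$cleaned) return(codes)
  dd <- dim(codes$codes)
  for (fi in seq_along(codes$fois)) {
    mr <- min_run_points(codes$fois[fi], codes$interval)
    if (mr <= 1L) next
    tv <- which(codes$valid[, fi])
    if (!length(tv)) next
    for (e in seq_len(dd[4])) {
      sub <- codes$codes[, tv, fi, e, drop = FALSE]
      dim(sub) <- c(dd[1], length(tv))
      codes$codes[, tv, fi, e] <- clean_core(sub, mr)
    }
  }
  codes$cleaned <- TRUE
  codes
}

#' Coupling indices from coded phase differences
#'
#' Computes, per ordered pair, FOI and epoch: the Positive Coupling Index
#' (PCI, fraction of +1 codes), the Negative Coupling Index (NCI, fraction
#' of -1 codes), the Absolute Coupling Index (ACI = PCI + NCI) and the
#' directed Integrative Coupling Index `ICI = PCI / (1 + NCI)`.  The
#' normalizing count k is the number of valid coefficient times of the
#' epoch.  ICI equals 1 when all k points are positive-locked; when all
#' locked points are negative the term `1/(1+NCI)` approaches 0.5 and ICI
#' approaches 0.
#'
#' @param codes A (preferably cleaned, see [clean_codes()]) `coded_series`.
#' @return An object of class `coupling_result`: fields `pci`, `nci`, `aci`,
#'   `ici` (pair x FOI x epoch arrays in `[0, 1]`) and `k` (valid count per
#'   FOI).
#' @export
coupling_indices <- function(codes) {
  if (!inherits(codes, "coded_series"))
    stop("`codes` must be a coded_series", call. = FALSE)
  dd <- dim(codes$codes)
  dn <- list(rownames(codes$pairs), codes$fois, NULL)
  res <- list(pci = array(NA_real_, c(dd[1], dd[3], dd[4]), dn),
              nci = array(NA_real_, c(dd[1], dd[3], dd[4]), dn),
              aci = array(NA_real_, c(dd[1], dd[3], dd[4]), dn),
              ici = array(NA_real_, c(dd[1], dd[3], dd[4]), dn))
  k <- colSums(codes$valid)
  if (any(k < 1)) stop("k = 0 valid coefficient times at some FOI", call. = FALSE)
  for (fi in seq_len(dd[3])) {
    tv <- codes$valid[, fi]
    for (e in seq_len(dd[4])) {
      sub <- codes$codes[, tv, fi, e, drop = FALSE]
      dim(sub) <- c(dd[1], sum(tv))
      v <- indices_core(sub, k[fi])
      res$pci[, fi, e] <- v$pci
      res$nci[, fi, e] <- v$nci
      res$aci[, fi, e] <- v$aci
      res$ici[, fi, e] <- v$ici
    }
  }
  structure(c(res, list(k = k, pairs = codes$pairs, fois = codes$fois,
                        cleaned = codes$cleaned,
                        notes = paste("ICI = PCI/(1+NCI); intermediate term",
                                      "1/(1+NCI) in [0.5, 1], -> 0.5 when",
                                      "all locked points are negative"))),
            class = "coupling_result")
}

#' Hyper-brain connectivity matrices
#'
#' Runs the full phase / coding / cleaning / index chain for every ordered
#' channel pair within and between the brains and assembles node x node
#' matrices per measure and FOI.  Entry (m, n) of a directed measure (pci,
#' nci, ici) is the value of the ordered pair m -> n; psi and aci are
#' symmetric.
#'
#' @param epochs Montage-selected [epoched_signals()] (a dyad gives a 42 x
#'   42 node set).
#' @param params A [wavelet_params()] object.
#' @param measures Subset of c("psi", "pci", "nci", "aci", "ici").
#' @param average If TRUE (default) matrices are averaged across epochs;
#'   otherwise a node x node x FOI x epoch array per measure is returned.
#' @return A named list of class `coupling_matrix`: one array (node x node
#'   x FOI, or x epoch when `average = FALSE`) per measure, with node
#'   metadata in attribute `"nodes"` (label, brain, region when known).
#' @export
connectivity_matrices <- function(epochs, params = wavelet_params(),
                                  measures = c("psi", "pci", "nci", "aci", "ici"),
                                  average = TRUE) {
  measures <- match.arg(measures, several.ok = TRUE)
  ph <- morlet_phase(epochs, params)
  nc <- dim(ph$phase)[1]
  ne <- dim(ph$phase)[4]
  nf <- length(ph$fois)
  g <- expand.grid(n = seq_len(nc), m = seq_len(nc))
  g <- g[g$m != g$n, ]
  pm <- g$m
  pn <- g$n
  store <- lapply(measures, function(m)
    array(0, c(nc, nc, nf, ne),
          dimnames = list(ph$labels, ph$labels, ph$fois, NULL)))
  names(store) <- measures
  need_codes <- any(measures != "psi")
  for (e in seq_len(ne)) {
    for (fi in seq_len(nf)) {
      tv <- ph$valid[, fi]
      k <- sum(tv)
      if (k < 2) stop("fewer than 2 valid coefficient times at FOI ",
                      ph$fois[fi], call. = FALSE)
      P <- ph$phase[, tv, fi, e, drop = FALSE]
      dim(P) <- c(nc, k)
      dmat <- wrap_pi(P[pm, , drop = FALSE] - P[pn, , drop = FALSE])
      if ("psi" %in% measures) {
        v <- psi_core(dmat)
        store$psi[, , fi, e][cbind(pm, pn)] <- v
      }
      if (need_codes) {
        cmat <- clean_core(code_core(dmat),
                           min_run_points(ph$fois[fi], ph$interval))
        v <- indices_core(cmat, k)
        for (m in intersect(measures, c("pci", "nci", "aci", "ici")))
          store[[m]][, , fi, e][cbind(pm, pn)] <- v[[m]]
      }
    }
  }
  if (average) store <- lapply(store, function(a) {
    out <- array(0, dim(a)[1:3], dimnames = dimnames(a)[1:3])
    for (fi in seq_len(dim(a)[3]))
      out[, , fi] <- apply(a[, , fi, , drop = FALSE], c(1, 2), mean)
    out
  })
  nodes <- data.frame(label = ph$labels, brain = ph$brain,
                      stringsAsFactors = FALSE)
  reg <- attr(epochs, "region")
  if (!is.null(reg)) nodes$region <- reg
  structure(store, class = "coupling_matrix", nodes = nodes,
            fois = ph$fois, averaged = average)
}
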