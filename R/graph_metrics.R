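#' Hyper-brain graph
#'
#' Thresholded weighted adjacency over the joint two-brain node set, with a
#' binarized twin and node metadata.  Undirected graphs must have a
#' symmetric weight matrix; self-loops are removed.
#'
#' @param W Nonnegative weighted adjacency matrix (node x node).
#' @param directed Logical; TRUE for the asymmetric measures.
#' @param nodes Optional data.frame with columns `label`, `brain` (and
#'   optionally `region`), one row per node.
#' @param measure,foi,threshold Provenance metadata.
#' @return An object of class `hyper_brain_graph` with fields `W`, `A`
#'   (binary), `directed`, `nodes`, `measure`, `foi`, `threshold`.
#' @export
hyper_brain_graph <- function(W, directed = FALSE, nodes = NULL,
                              measure = NA_character_, foi = NA_real_,
                              threshold = NA_real_) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("`W` must be square", call. = FALSE)
  if (any(W < 0)) stop("`W` must be nonnegative", call. = FALSE)
  diag(W) <- 0
  if (!directed && !isTRUE(all.equal(W, t(W), tolerance = 1e-12)))
    stop("undirected graph needs a symmetric `W`", call. = FALSE)
  n <- nrow(W)
  if (is.null(nodes)) {
    labs <- rownames(W)
    if (is.null(labs)) labs <- sprintf("n%02d", seq_len(n))
    nodes <- data.frame(label = labs, brain = rep("A", n),
                        stringsAsFactors = FALSE)
  }
  if (nrow(nodes) != n) stop("`nodes` must have one row per node", call. = FALSE)
  dimnames(W) <- list(nodes$label, nodes$label)
  structure(list(W = W, A = (W > 0) * 1, directed = isTRUE(directed),
                 nodes = nodes, measure = measure, foi = foi,
                 threshold = threshold),
            class = "hyper_brain_graph")
}

#' @export
print.hyper_brain_graph <- function(x, ...) {
  m <- sum(x$A) / if (x$directed) 1 else 2
  cat(sprintf("<hyper_brain_graph> %d nodes, %d %s edges%s\n",
              nrow(x$W), m, if (x$directed) "directed" else "undirected",
              if (!is.na(x$measure))
                sprintf(" [%s @ %g Hz]", x$measure, x$foi) else ""))
  invisible(x)
}

#' Number of edges
#' @param g A [hyper_brain_graph()].
#' @return Edge count (each undirected edge counted once).
#' @export
n_edges <- function(g) as.integer(sum(g$A) / if (g$directed) 1 else 2)

#' Node degrees and strengths with intra/inter-brain decomposition
#'
#' In-/out-degrees are row/column sums of the binary adjacency, strengths
#' the corresponding weighted sums.  The intra-brain component is computed
#' on the within-brain blocks of the matrix; the inter-brain component is
#' the total minus the intra component, per node (the subtraction used to
#' isolate between-brain links).
#'
#' @param g A [hyper_brain_graph()].
#' @return A data.frame, one row per node: label, brain, in/out/total
#'   degree and strength plus `intra_*` and `inter_*` strength columns.
#' @export
strengths <- function(g) {
  W <- g$W
  A <- g$A
  same <- outer(g$nodes$brain, g$nodes$brain, "==")
  Wi <- W * same
  out <- data.frame(
    label = g$nodes$label, brain = g$nodes$brain,
    in_degree = colSums(A), out_degree = rowSums(A),
    degree = colSums(A) + rowSums(A),
    in_strength = colSums(W), out_strength = rowSums(W),
    strength = colSums(W) + rowSums(W),
    intra_in_strength = colSums(Wi), intra_out_strength = rowSums(Wi),
    stringsAsFactors = FALSE)
  out$intra_strength <- out$intra_in_strength + out$intra_out_strength
  out$inter_in_strength <- out$in_strength - out$intra_in_strength
  out$inter_out_strength <- out$out_strength - out$intra_out_strength
  out$inter_strength <- out$strength - out$intra_strength
  rownames(out) <- NULL
  out
}

#' Clustering coefficient
#'
#' Per-node clustering and its mean.  For binary undirected graphs,
#' `C_i = 2 t_i / (k_i (k_i - 1))` with `t_i` the triangle count around i;
#' the weighted variant uses the geometric-mean triangle intensity of the
#' max-normalized weights; directed graphs use the directed triangle
#' formula with `t_i = ((W^(1/3) + (W')^(1/3))^3)_ii / 2` and denominator
#' `k_tot (k_tot - 1) - 2 k_bi`.  Nodes with fewer than two neighbours get
#' `C_i = 0`.
#'
#' @param g A [hyper_brain_graph()].
#' @param mode "binary" (default), "weighted", or "directed" (forces the
#'   directed formula).  Directed graphs always use the directed formula;
#'   binary/weighted then only choose the input matrix.
#' @return A list with `ci` (per node) and `cc` (mean).
#' @export
clustering_coefficient <- function(g, mode = c("binary", "weighted", "directed")) {
  mode <- match.arg(mode)
  n <- nrow(g$W)
  if (n < 3) stop("clustering needs >= 3 nodes", call. = FALSE)
  use_w <- mode %in% c("weighted", "directed") && any(g$W != g$A)
  M <- if (use_w) {
    mx <- max(g$W)
    if (mx > 0) g$W / mx else g$W
  } else g$A
  directed <- g$directed || mode == "directed"
  if (!directed) {
    A <- g$A
    k <- rowSums(A)
    t3 <- diag((M^(1 / 3)) %*% (M^(1 / 3)) %*% (M^(1 / 3))) / 2
    denom <- k * (k - 1) / 2
    ci <- ifelse(denom > 0, t3 / denom, 0)
  } else {
    A <- g$A
    S <- M^(1 / 3) + t(M)^(1 / 3)
    t3 <- diag(S %*% S %*% S) / 2
    ktot <- rowSums(A) + colSums(A)
    kbi <- diag(A %*% A)
    denom <- ktot * (ktot - 1) - 2 * kbi
    ci <- ifelse(denom > 0, t3 / denom, 0)
  }
  names(ci) <- g$nodes$label
  list(ci = ci, cc = mean(ci))
}

#' Characteristic path length
#'
#' Mean shortest-path length over all ordered pairs of distinct nodes,
#' computed on the binary adjacency or on lengths `1/weight` for weighted
#' graphs (strong coupling = short distance), respecting edge direction for
#' directed graphs.  Unreachable pairs are excluded from the mean by
#' default (their count is reported in attribute `"n_unreachable"`); the
#' `"harmonic"` method instead returns the inverse of the mean inverse
#' distance, which penalizes disconnection smoothly.
#'
#' @param g A [hyper_brain_graph()].
#' @param weighted Use `1/weight` edge lengths (default FALSE = binary hops).
#' @param method "exclude" (default) or "harmonic".
#' @return CPL scalar (NA with a warning for an empty graph), with
#'   attribute `n_unreachable`.
#' @export
characteristic_path_length <- function(g, weighted = FALSE,
                                       method = c("exclude", "harmonic")) {
  method <- match.arg(method)
  if (sum(g$A) == 0) {
    warning("graph has no edges; CPL undefined", call. = FALSE)
    return(structure(NA_real_, n_unreachable = nrow(g$W) * (nrow(g$W) - 1)))
  }
  M <- if (weighted) g$W else g$A
  ig <- igraph::graph_from_adjacency_matrix(
    M, mode = if (g$directed) "directed" else "undirected",
    weighted = if (weighted) TRUE else NULL)
  wts <- if (weighted) 1 / igraph::E(ig)$weight else NULL
  D <- igraph::distances(ig, mode = "out", weights = wts)
  offdiag <- row(D) != col(D)
  d <- D[offdiag]
  unreach <- sum(!is.finite(d))
  cpl <- if (method == "exclude") {
    if (all(!is.finite(d))) NA_real_ else mean(d[is.finite(d)])
  } else {
    1 / mean(ifelse(is.finite(d), 1 / d, 0))
  }
  structure(cpl, n_unreachable = unreach)
}

edge_list_of <- function(W, directed) {
  if (directed) which(W > 0, arr.ind = TRUE)
  else which(W > 0 & upper.tri(W), arr.ind = TRUE)
}

# Maslov-Sneppen degree-preserving double-edge swaps; returns the new W
# (weights travel with the rewired edges)
rewire_random <- function(W, directed, n_attempts = NULL) {
  idx <- edge_list_of(W, directed)
  m <- nrow(idx)
  if (m < 2) {
    warning("too few edges to rewire; returning graph unchanged", call. = FALSE)
    return(W)
  }
  if (is.null(n_attempts)) n_attempts <- 30L * m
  edges <- idx
  wts <- W[idx]
  B <- W > 0
  for (it in seq_len(n_attempts)) {
    pick <- sample.int(m, 2)
    a <- edges[pick[1], 1]; b <- edges[pick[1], 2]
    c_ <- edges[pick[2], 1]; d <- edges[pick[2], 2]
    if (!directed && stats::runif(1) < 0.5) { tmp <- c_; c_ <- d; d <- tmp }
    if (a == d || c_ == b) next
    if (directed) {
      if (B[a, d] || B[c_, b]) next
    } else {
      if (B[a, d] || B[d, a] || B[c_, b] || B[b, c_]) next
    }
    B[a, b] <- FALSE; B[c_, d] <- FALSE
    if (!directed) { B[b, a] <- FALSE; B[d, c_] <- FALSE }
    B[a, d] <- TRUE; B[c_, b] <- TRUE
    if (!directed) { B[d, a] <- TRUE; B[b, c_] <- TRUE }
    edges[pick[1], ] <- c(a, d)
    edges[pick[2], ] <- c(c_, b)
  }
  Wn <- matrix(0, nrow(W), ncol(W), dimnames = dimnames(W))
  Wn[edges] <- wts
  if (!directed) Wn[edges[, c(2, 1)]] <- wts
  Wn
}

# greedy latticization: degree-preserving swaps accepted only when they
# reduce the total |i - j| edge distance, with proposals targeted at the
# longest edges so the configuration settles near the main diagonal
latticize <- function(W, directed, passes = 20L, tries_per_edge = 60L) {
  idx <- edge_list_of(W, directed)
  m <- nrow(idx)
  if (m < 2) {
    warning("too few edges to latticize; returning graph unchanged",
            call. = FALSE)
    return(W)
  }
  edges <- idx
  wts <- W[idx]
  B <- W > 0
  len <- abs(edges[, 1] - edges[, 2])
  for (pass in seq_len(passes)) {
    improved <- FALSE
    ord <- order(len, decreasing = TRUE)
    for (e1 in ord[seq_len(min(m, max(50L, m %/% 2L)))]) {
      done <- FALSE
      for (e2 in sample.int(m, min(m - 1L, tries_per_edge))) {
        if (e2 == e1) next
        a <- edges[e1, 1]; b <- edges[e1, 2]
        c_ <- edges[e2, 1]; d <- edges[e2, 2]
        for (flip in 0:1) {
          if (flip == 1L) {
            if (directed) break
            tmp <- c_; c_ <- d; d <- tmp
          }
          if (a == d || c_ == b) next
          if (directed) {
            if (B[a, d] || B[c_, b]) next
          } else {
            if (B[a, d] || B[d, a] || B[c_, b] || B[b, c_]) next
          }
          if (abs(a - d) + abs(c_ - b) >= abs(a - b) + abs(c_ - d)) next
          B[a, b] <- FALSE; B[c_, d] <- FALSE
          if (!directed) { B[b, a] <- FALSE; B[d, c_] <- FALSE }
          B[a, d] <- TRUE; B[c_, b] <- TRUE
          if (!directed) { B[d, a] <- TRUE; B[b, c_] <- TRUE }
          edges[e1, ] <- c(a, d)
          edges[e2, ] <- c(c_, b)
          len[e1] <- abs(a - d)
          len[e2] <- abs(c_ - b)
          improved <- TRUE
          done <- TRUE
          break
        }
        if (done) break
      }
    }
    if (!improved) break
  }
  Wn <- matrix(0, nrow(W), ncol(W), dimnames = dimnames(W))
  Wn[edges] <- wts
  if (!directed) Wn[edges[, c(2, 1)]] <- wts
  Wn
}

#' Null-model graph ensembles
#'
#' Random nulls are built by degree-preserving double-edge swaps
#' (Maslov-Sneppen rewiring); lattice nulls start from a randomized copy
#' and then accept only swaps that move edges closer to the main diagonal,
#' yielding a degree-matched lattice-like graph.  Edge weights travel with
#' the rewired edges, so node count and the full degree sequence are
#' preserved exactly in every realization.
#'
#' @param g A [hyper_brain_graph()] with at least one edge.
#' @param kind "random" or "lattice".
#' @param n Number of realizations (default 20).
#' @param seed Integer seed (deterministic ensembles).
#' @return A list of `n` hyper_brain_graph objects.
#' @export
null_models <- function(g, kind = c("random", "lattice"), n = 20, seed = 1) {
  kind <- match.arg(kind)
  if (sum(g$A) == 0) stop("graph has no edges", call. = FALSE)
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      W <- rewire_random(g$W, g$directed)
      if (kind == "lattice") W <- latticize(W, g$directed)
      hyper_brain_graph(W, directed = g$directed, nodes = g$nodes,
                        measure = g$measure, foi = g$foi)
    })
  })
}

#' Small-worldness coefficients sigma and omega
#'
#' Compares the graph's clustering coefficient and characteristic path
#' length to degree-matched random and lattice null ensembles:
#' `gamma = CC/CC_rand`, `lambda = CPL/CPL_rand`, `sigma = gamma/lambda`
#' (sigma > 1 indicates small-world structure) and
#' `omega = CPL_rand/CPL - CC/CC_latt` (near 0 small-world, negative more
#' lattice-like, positive more random; clamped to `[-1, 1]` with a warning
#' if estimation noise pushes it outside).
#'
#' @param g A [hyper_brain_graph()].
#' @param n_null Null realizations per kind (default 20).
#' @param seed Integer seed.
#' @param mode Clustering mode passed to [clustering_coefficient()].
#' @param weighted Use weighted path lengths (default FALSE).
#' @return An object of class `small_world_stats`.
#' @export
small_worldness <- function(g, n_null = 20, seed = 1, mode = "binary",
                            weighted = FALSE) {
  cc <- clustering_coefficient(g, mode)$cc
  cpl <- as.numeric(characteristic_path_length(g, weighted))
  rand <- null_models(g, "random", n_null, seed)
  latt <- null_models(g, "lattice", n_null, seed + 1L)
  cc_rand <- mean(vapply(rand, function(x) clustering_coefficient(x, mode)$cc, 0))
  cpl_rand <- mean(vapply(rand, function(x)
    as.numeric(characteristic_path_length(x, weighted)), 0))
  cc_latt <- mean(vapply(latt, function(x) clustering_coefficient(x, mode)$cc, 0))
  cpl_latt <- mean(vapply(latt, function(x)
    as.numeric(characteristic_path_length(x, weighted)), 0))
  if (cc_rand == 0 || cc_latt == 0)
    stop("degenerate null ensemble (zero clustering); ",
         "graph too sparse for sigma/omega", call. = FALSE)
  gamma <- cc / cc_rand
  lambda <- cpl / cpl_rand
  omega <- cpl_rand / cpl - cc / cc_latt
  if (omega < -1 || omega > 1) {
    warning("omega outside [-1, 1]; clamped", call. = FALSE)
    omega <- max(-1, min(1, omega))
  }
  structure(list(cc = cc, cpl = cpl, cc_rand = cc_rand, cpl_rand = cpl_rand,
                 cc_latt = cc_latt, cpl_latt = cpl_latt,
                 gamma = gamma, lambda = lambda, sigma = gamma / lambda,
                 omega = omega, n_null = n_null, seed = seed),
            class = "small_world_stats")
}

#' @export
print.small_world_stats <- function(x, ...) {
  cat(sprintf(paste0("<small_world_stats> CC=%.4f CPL=%.4f | ",
                     "gamma=%.3f lambda=%.3f sigma=%.3f omega=%.3f\n"),
              x$cc, x$cpl, x$gamma, x$lambda, x$sigma, x$omega))
  invisible(x)
}

#' Standard frequency bands
#'
#' @return Named list mapping band to its FOIs (Hz): delta 2-3, theta 4-7,
#'   alpha 8-12, beta1 14-20, beta2 24-28.
#' @export
default_bands <- function() {
  list(delta = c(2, 3), theta = c(4, 5, 6, 7), alpha = c(8, 9, 10, 11, 12),
       beta1 = c(14, 16, 18, 20), beta2 = c(24, 28))
}

#' Collapse metric tables over frequency bands and scalp regions
#'
#' Arithmetic means of a node/FOI-level metric over each band's FOIs and
#' (when electrode labels are present) each region's electrodes.
#'
#' @param df A data.frame with columns `foi`, `value`, and optionally
#'   `label` (electrode, possibly "A:"/"B:"-prefixed) or `region`.
#' @param bands Band definition, default [default_bands()].
#' @param montage Montage supplying the label-to-region map.
#' @return A data.frame of band (x region) means.  FOIs outside all bands
#'   are dropped with a warning.
#' @export
collapse_bands_and_regions <- function(df, bands = default_bands(),
                                       montage = montage_1020()) {
  if (!all(c("foi", "value") %in% names(df)))
    stop("`df` needs columns `foi` and `value`", call. = FALSE)
  band_of <- rep(NA_character_, nrow(df))
  for (b in names(bands)) band_of[df$foi %in% bands[[b]]] <- b
  if (anyNA(band_of)) {
    warning("FOI(s) outside all bands dropped: ",
            paste(unique(df$foi[is.na(band_of)]), collapse = ", "),
            call. = FALSE)
    df <- df[!is.na(band_of), , drop = FALSE]
    band_of <- band_of[!is.na(band_of)]
  }
  df$band <- factor(band_of, levels = names(bands))
  if (!"region" %in% names(df) && "label" %in% names(df))
    df$region <- montage$region[match(electrode_of(df$label), montage$label)]
  groups <- if ("region" %in% names(df)) list(band = df$band, region = df$region)
            else list(band = df$band)
  out <- stats::aggregate(df["value"], by = groups, FUN = mean)
  out[order(out$band), , drop = FALSE]
}
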