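# Shared fixtures and independent oracles (brute-force implementations kept
# deliberately naive and loop-based, so they do not share code paths with
# the package).

toy_undirected <- function(n, p = 0.4, weighted = FALSE, seed = 1) {
  set.seed(seed)
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- as.numeric(stats::runif(n * (n - 1) / 2) < p)
  if (weighted) A[upper.tri(A)] <- A[upper.tri(A)] * stats::runif(n * (n - 1) / 2, 0.1, 1)
  A <- A + t(A)
  hyper_brain_graph(A, directed = FALSE)
}

toy_directed <- function(n, p = 0.4, weighted = FALSE, seed = 1) {
  set.seed(seed)
  A <- matrix(as.numeric(stats::runif(n * n) < p), n, n)
  diag(A) <- 0
  if (weighted) A <- A * matrix(stats::runif(n * n, 0.1, 1), n, n)
  hyper_brain_graph(A, directed = TRUE)
}

ring_lattice <- function(n, k_half) {
  A <- matrix(0, n, n)
  for (i in seq_len(n)) for (d in seq_len(k_half)) {
    j <- ((i - 1 + d) %% n) + 1
    A[i, j] <- A[j, i] <- 1
  }
  hyper_brain_graph(A)
}

two_cliques <- function(k = 5) {
  n <- 2 * k
  W <- matrix(0, n, n)
  W[1:k, 1:k] <- 1
  W[(k + 1):n, (k + 1):n] <- 1
  diag(W) <- 0
  W[k, k + 1] <- W[k + 1, k] <- 1
  hyper_brain_graph(W)
}

# Floyd-Warshall all-pairs shortest paths (weighted lengths already given)
oracle_distances <- function(L) {
  n <- nrow(L)
  D <- L
  D[D == 0] <- Inf
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

oracle_cpl <- function(g, weighted = FALSE) {
  L <- if (weighted) ifelse(g$W > 0, 1 / g$W, 0) else g$A
  D <- oracle_distances(L)
  d <- D[row(D) != col(D)]
  mean(d[is.finite(d)])
}

# triangle-enumeration clustering oracles (ordered-triple loops)
oracle_cc_undirected <- function(g, weighted = FALSE) {
  M <- if (weighted) g$W / max(g$W) else g$A
  A <- g$A
  n <- nrow(A)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(A[i, ])
    if (k < 2) next
    t3 <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j == i || h == i || j == h) next
      t3 <- t3 + (M[i, j] * M[i, h] * M[j, h])^(1 / 3)
    }
    ci[i] <- t3 / (k * (k - 1))
  }
  mean(ci)
}

oracle_cc_directed <- function(g, weighted = FALSE) {
  M <- if (weighted) g$W / max(g$W) else g$A
  A <- g$A
  n <- nrow(A)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    ktot <- sum(A[i, ]) + sum(A[, i])
    kbi <- sum(A[i, ] * A[, i])
    denom <- ktot * (ktot - 1) - 2 * kbi
    if (denom <= 0) next
    t3 <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j == i || h == i || j == h) next
      t3 <- t3 + (M[i, j]^(1 / 3) + M[j, i]^(1 / 3)) *
        (M[i, h]^(1 / 3) + M[h, i]^(1 / 3)) *
        (M[j, h]^(1 / 3) + M[h, j]^(1 / 3))
    }
    ci[i] <- (t3 / 2) / denom   # t_i = (S^3)_ii / 2 with S symmetric
  }
  mean(ci)
}

# exhaustive modularity maximum over all assignments into <= n_mod modules
oracle_best_modularity <- function(g, n_mod = 3, variant = "auto") {
  n <- nrow(g$W)
  best <- -Inf
  memb <- rep(1L, n)
  repeat {
    best <- max(best, modularity_value(g, memb, variant))
    i <- 1L
    while (i <= n && memb[i] == n_mod) {
      memb[i] <- 1L
      i <- i + 1L
    }
    if (i > n) break
    memb[i] <- memb[i] + 1L
  }
  best
}

# quick 2-channel dataset with an imposed lead of channel A
lagged_pair <- function(f = 6, lag = 0.01, noise_sd = 0.5, n_epochs = 10,
                        duration = 3, seed = 1) {
  generate_oscillator_pair(oscillator_pair_spec(
    f, duration = duration, phase_shift = 0, lag = lag, noise_sd = noise_sd,
    n_epochs = n_epochs, seed = seed))
}
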