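#' Modularity of a partition
#'
#' Evaluates the modularity quality function for a given module assignment:
#' the weighted Newman form for undirected graphs,
#' `M = sum_c [ w_cc/m - (S_c/m)^2 ]` with `m` the total weight and `S_c`
#' module strength, and the Leicht-Newman form for directed graphs using
#' in- and out-strengths, `M = sum_c [ w_cc/m - S_c^out S_c^in / m^2 ]`.
#' `M = 0` when all nodes share one module.
#'
#' @param g A [hyper_brain_graph()].
#' @param membership Integer module id per node.
#' @param variant "auto" (follow the graph's directedness), "weighted"
#'   (undirected Newman) or "directed" (Leicht-Newman).
#' @return Modularity value (<= 1).
#' @export
modularity_value <- function(g, membership,
                             variant = c("auto", "weighted", "directed")) {
  variant <- match.arg(variant)
  W <- g$W
  if (variant == "auto") variant <- if (g$directed) "directed" else "weighted"
  if (variant == "weighted" && g$directed) W <- (W + t(W)) / 2
  if (length(membership) != nrow(W))
    stop("`membership` must cover all nodes", call. = FALSE)
  m <- sum(W)
  if (m == 0) stop("graph has no edges", call. = FALSE)
  s_out <- rowSums(W)
  s_in <- colSums(W)
  q <- 0
  for (c_ in unique(membership)) {
    idx <- membership == c_
    q <- q + sum(W[idx, idx]) / m -
      sum(s_out[idx]) * sum(s_in[idx]) / m^2
  }
  q
}

# one local-moving pass; returns membership (possibly improved)
local_moves <- function(W, membership, m, order_) {
  s_out <- rowSums(W)
  s_in <- colSums(W)
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (i in order_) {
      ci <- membership[i]
      cand <- unique(membership[W[i, ] > 0 | W[, i] > 0])
      cand <- unique(c(cand, ci))
      best_gain <- 0
      best_c <- ci
      others <- membership
      others[i] <- 0L                       # exclude i from its community
      for (cc in cand) {
        if (cc == ci) next
        idx_new <- others == cc
        idx_old <- others == ci
        gain_new <- (sum(W[i, idx_new]) + sum(W[idx_new, i])) / m -
          (s_out[i] * sum(s_in[idx_new]) + s_in[i] * sum(s_out[idx_new])) / m^2
        gain_old <- (sum(W[i, idx_old]) + sum(W[idx_old, i])) / m -
          (s_out[i] * sum(s_in[idx_old]) + s_in[i] * sum(s_out[idx_old])) / m^2
        gain <- gain_new - gain_old
        if (gain > best_gain + 1e-13) {
          best_gain <- gain
          best_c <- cc
        }
      }
      if (best_c != ci) {
        membership[i] <- best_c
        improved <- TRUE
      }
    }
  }
  membership
}

#' Optimize a modularity partition
#'
#' Seeded multi-restart greedy optimization of the modularity quality
#' function ([modularity_value()]): repeated local node moves from a
#' singleton start (random node order per restart), interleaved with greedy
#' module merges, until no single move or merge improves M.  The best of
#' `restarts` runs is returned; ties are broken towards the partition found
#' first, and module ids are relabelled in order of first node appearance,
#' so results are a pure function of (graph, seed, restarts).
#'
#' @param g A [hyper_brain_graph()] with at least one edge.
#' @param variant Quality-function variant, see [modularity_value()].
#' @param restarts Number of seeded restarts (default 20).
#' @param seed Integer seed.
#' @return An object of class `partition`: fields `membership` (integer per
#'   node), `modularity`, `variant`, `restarts`, `seed`.
#' @export
optimize_partition <- function(g, variant = c("auto", "weighted", "directed"),
                               restarts = 20, seed = 1) {
  variant <- match.arg(variant)
  W <- g$W
  if (variant == "auto") variant <- if (g$directed) "directed" else "weighted"
  if (variant == "weighted" && g$directed) W <- (W + t(W)) / 2
  if (sum(W) == 0) stop("graph has no edges", call. = FALSE)
  n <- nrow(W)
  m <- sum(W)
  gfix <- g
  gfix$W <- W
  gfix$directed <- variant == "directed"
  best_q <- -Inf
  best <- seq_len(n)
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      memb <- seq_len(n)
      order_ <- sample.int(n)
      repeat {
        memb <- local_moves(W, memb, m, order_)
        # greedy module merges
        q_now <- modularity_value(gfix, memb, variant)
        mods <- unique(memb)
        merged <- FALSE
        if (length(mods) > 1) {
          best_gain <- 1e-13
          best_pair <- NULL
          for (a in seq_along(mods)) for (b in seq_len(a - 1L)) {
            trial <- memb
            trial[trial == mods[a]] <- mods[b]
            gq <- modularity_value(gfix, trial, variant) - q_now
            if (gq > best_gain) {
              best_gain <- gq
              best_pair <- c(mods[a], mods[b])
            }
          }
          if (!is.null(best_pair)) {
            memb[memb == best_pair[1]] <- best_pair[2]
            merged <- TRUE
          }
        }
        if (!merged) break
      }
      q <- modularity_value(gfix, memb, variant)
      if (q > best_q + 1e-13) {
        best_q <- q
        best <- memb
      }
    }
  })
  # canonical relabelling: modules numbered by first appearance
  best <- as.integer(factor(best, levels = unique(best)))
  structure(list(membership = best, modularity = best_q, variant = variant,
                 restarts = restarts, seed = seed,
                 labels = g$nodes$label),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition> %d nodes in %d modules, M = %.4f (%s)\n",
              length(x$membership), length(unique(x$membership)),
              x$modularity, x$variant))
  invisible(x)
}

# links between node i and members of each module (counting both directions
# for directed graphs)
module_degrees <- function(g, membership, weighted = FALSE) {
  M <- if (weighted) g$W else g$A
  K <- M + t(M)
  if (!g$directed) K <- K / 2
  mods <- sort(unique(membership))
  km <- sapply(mods, function(c_) rowSums(K[, membership == c_, drop = FALSE]))
  km <- matrix(km, nrow = nrow(K), dimnames = list(g$nodes$label, mods))
  km
}

#' Within-module degree z-score
#'
#' `Z_i = (k_i(m_i) - mean_m) / sd_m`, where `k_i(m_i)` is node i's degree
#' restricted to its own module and mean/sd are taken over that module's
#' within-module degree distribution (population sd).  If the sd is 0 (all
#' module nodes equally connected, e.g. a fully interconnected module) all
#' its nodes get Z = 0.
#'
#' @param g A [hyper_brain_graph()].
#' @param partition A [optimize_partition()] result or membership vector.
#' @param weighted Use strengths instead of binary degrees (default FALSE).
#' @return Numeric Z per node.
#' @export
within_module_degree <- function(g, partition, weighted = FALSE) {
  membership <- if (inherits(partition, "partition")) partition$membership
                else partition
  if (length(membership) != nrow(g$W))
    stop("partition must cover all nodes", call. = FALSE)
  km <- module_degrees(g, membership, weighted)
  z <- numeric(length(membership))
  for (c_ in unique(membership)) {
    idx <- membership == c_
    kwm <- km[idx, as.character(c_)]
    mu <- mean(kwm)
    sdv <- sqrt(mean((kwm - mu)^2))
    z[idx] <- if (sdv > 0) (kwm - mu) / sdv else 0
  }
  names(z) <- g$nodes$label
  z
}

#' Participation coefficient
#'
#' `P_i = 1 - sum_m (k_i(m) / k_i)^2` over all modules m; close to 1 when
#' node i's links are spread uniformly over modules, 0 when they all stay
#' inside its own module.  Isolated nodes get P = 0.
#'
#' @inheritParams within_module_degree
#' @return Numeric P per node, in `[0, 1]`.
#' @export
participation_coefficient <- function(g, partition, weighted = FALSE) {
  membership <- if (inherits(partition, "partition")) partition$membership
                else partition
  if (length(membership) != nrow(g$W))
    stop("partition must cover all nodes", call. = FALSE)
  km <- module_degrees(g, membership, weighted)
  k <- rowSums(km)
  p <- ifelse(k > 0, 1 - rowSums((km / pmax(k, 1))^2), 0)
  names(p) <- g$nodes$label
  p
}

#' Classify nodes into the eight Z-P roles
#'
#' Hubs are nodes with `Z >= 1.4`.  Participation bins are
#' `P <= 0.05` (ultra-peripheral), `0.05 < P <= 0.5` (peripheral),
#' `0.5 < P <= 0.8` (connector), `P > 0.8` (kinless), giving roles R1-R4
#' for non-hubs and R5-R8 for hubs.
#'
#' @param z,p Numeric vectors of within-module degree z-scores and
#'   participation coefficients.
#' @return Factor with levels R1..R8.
#' @export
classify_roles <- function(z, p) {
  if (length(z) != length(p)) stop("z and p lengths differ", call. = FALSE)
  pbin <- findInterval(p, c(0.05, 0.5, 0.8), left.open = TRUE) + 1L
  role <- ifelse(z >= 1.4, pbin + 4L, pbin)
  factor(paste0("R", role), levels = paste0("R", 1:8))
}

#' Node role table
#'
#' Convenience wrapper computing Z, P and the R1-R8 role for every node of
#' a partitioned graph.
#'
#' @inheritParams within_module_degree
#' @return A data.frame: label, brain, module, Z, P, role.
#' @export
node_roles <- function(g, partition, weighted = FALSE) {
  membership <- if (inherits(partition, "partition")) partition$membership
                else partition
  z <- within_module_degree(g, membership, weighted)
  p <- participation_coefficient(g, membership, weighted)
  data.frame(label = g$nodes$label, brain = g$nodes$brain,
             module = membership, Z = unname(z), P = unname(p),
             role = classify_roles(z, p), stringsAsFactors = FALSE)
}

#' Modules spanning both brains
#'
#' @param partition A [optimize_partition()] result or membership vector.
#' @param nodes Node metadata data.frame with columns `label`, `brain`.
#' @return A named list, one entry per module containing nodes from both
#'   brain A and brain B, giving the member labels; empty if the partition
#'   splits exactly along the brain boundary.
#' @export
hyper_brain_modules <- function(partition, nodes) {
  membership <- if (inherits(partition, "partition")) partition$membership
                else partition
  if (length(membership) != nrow(nodes))
    stop("partition and node metadata disagree", call. = FALSE)
  out <- list()
  for (c_ in sort(unique(membership))) {
    idx <- membership == c_
    if (length(unique(nodes$brain[idx])) > 1)
      out[[as.character(c_)]] <- nodes$label[idx]
  }
  out
}

#' Role census
#'
#' Pools node-role tables (e.g. across trials) and returns the percentage
#' of nodes per role; percentages sum to 100.
#'
#' @param tables A data.frame from [node_roles()] or a list of them.
#' @return A data.frame with columns role, n, percent.
#' @export
role_census <- function(tables) {
  if (is.data.frame(tables)) tables <- list(tables)
  if (!length(tables)) stop("need at least one role table", call. = FALSE)
  roles <- factor(unlist(lapply(tables, function(t) as.character(t$role))),
                  levels = paste0("R", 1:8))
  tab <- table(roles)
  data.frame(role = names(tab), n = as.integer(tab),
             percent = 100 * as.numeric(tab) / sum(tab),
             stringsAsFactors = FALSE)
}
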