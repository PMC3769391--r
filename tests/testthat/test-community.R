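test_that("modularity identities: single module = 0, M <= 1", {
  g <- toy_undirected(8, p = 0.5, weighted = TRUE, seed = 2)
  expect_equal(modularity_value(g, rep(1, 8)), 0)
  gd <- toy_directed(8, p = 0.4, seed = 3)
  expect_equal(modularity_value(gd, rep(1, 8)), 0)
  expect_lte(optimize_partition(g, restarts = 5, seed = 1)$modularity, 1)
})

test_that("random module assignment has expected modularity ~ 0", {
  # finite-size bias is -(1 - 1/K) * sum(s^2)/m^2, so use a graph large
  # enough for it to vanish below the 0.02 tolerance
  g <- toy_undirected(50, p = 0.5, seed = 4)
  set.seed(40)
  ms <- replicate(100, modularity_value(g, sample.int(2, 50, replace = TRUE)))
  expect_lt(abs(mean(ms)), 0.02)
})

test_that("two joined cliques are recovered; M matches exhaustive search", {
  g <- two_cliques(5)
  part <- optimize_partition(g, restarts = 10, seed = 1)
  expect_equal(part$membership, rep(1:2, each = 5))
  best <- oracle_best_modularity(g, n_mod = 3)
  expect_equal(part$modularity, best, tolerance = 1e-9)
})

test_that("optimizer is deterministic and >= exhaustive optimum on random toys", {
  for (i in 1:4) {
    g <- if (i %% 2 == 0) toy_directed(8, p = 0.35, seed = 50 + i)
         else toy_undirected(8, p = 0.35, weighted = TRUE, seed = 50 + i)
    if (sum(g$A) == 0) next
    p1 <- optimize_partition(g, restarts = 10, seed = 9)
    p2 <- optimize_partition(g, restarts = 10, seed = 9)
    expect_identical(p1$membership, p2$membership)
    best3 <- oracle_best_modularity(g, n_mod = 3)
    expect_gte(p1$modularity, best3 - 1e-9)
  }
})

test_that("within-module degree Z: equal degrees give 0, hand case checks", {
  # two disconnected K4s: every node same within-module degree -> Z = 0
  W <- matrix(0, 8, 8)
  W[1:4, 1:4] <- 1
  W[5:8, 5:8] <- 1
  diag(W) <- 0
  g <- hyper_brain_graph(W)
  memb <- rep(1:2, each = 4)
  expect_equal(unname(within_module_degree(g, memb)), rep(0, 8))

  # module with degrees (3,1,1,1): Z1 = (3-1.5)/sd_pop
  Ws <- matrix(0, 4, 4)
  Ws[1, 2:4] <- 1
  Ws <- Ws + t(Ws)
  gs <- hyper_brain_graph(Ws)
  z <- within_module_degree(gs, rep(1, 4))
  sd_pop <- sqrt(mean((c(3, 1, 1, 1) - 1.5)^2))
  expect_equal(unname(z[1]), (3 - 1.5) / sd_pop)

  # singleton module -> Z = 0
  z2 <- within_module_degree(gs, c(1, 1, 1, 2))
  expect_equal(unname(z2[4]), 0)
})

test_that("participation coefficient: formula cases and bounds", {
  W <- matrix(0, 8, 8)
  W[1:4, 1:4] <- 1
  W[5:8, 5:8] <- 1
  diag(W) <- 0
  g <- hyper_brain_graph(W)
  memb <- rep(1:2, each = 4)
  expect_equal(unname(participation_coefficient(g, memb)), rep(0, 8))

  # degree-4 node with 2 links into each of two modules -> P = 0.5
  W2 <- matrix(0, 5, 5)
  W2[1, 2:5] <- 1
  W2 <- W2 + t(W2)
  g2 <- hyper_brain_graph(W2)
  p <- participation_coefficient(g2, c(1, 1, 1, 2, 2))
  expect_equal(unname(p[1]), 0.5)

  # isolated node -> 0; P always in [0, 1]
  W3 <- matrix(0, 3, 3)
  W3[1, 2] <- W3[2, 1] <- 1
  p3 <- participation_coefficient(hyper_brain_graph(W3), c(1, 1, 2))
  expect_equal(unname(p3[3]), 0)
  set.seed(60)
  gr <- toy_directed(10, p = 0.4, seed = 61)
  pr <- participation_coefficient(gr, sample.int(3, 10, replace = TRUE))
  expect_true(all(pr >= 0 & pr <= 1))
})

test_that("role classification covers the eight Z-P regions", {
  z <- c(0.0, 1.0, 1.0, 1.0, 2.0, 2.0, 2.0, 2.0, 1.4, 1.39)
  p <- c(0.0, 0.3, 0.7, 0.9, 0.01, 0.3, 0.6, 0.95, 0.0, 0.0)
  roles <- classify_roles(z, p)
  expect_equal(as.character(roles),
               c("R1", "R2", "R3", "R4", "R5", "R6", "R7", "R8", "R5", "R1"))
  # boundary conventions: P = 0.05 -> ultra-peripheral, P = 0.5 -> peripheral
  expect_equal(as.character(classify_roles(c(0, 0), c(0.05, 0.5))),
               c("R1", "R2"))
})

test_that("hyper-brain modules are detected across the brain boundary", {
  nodes <- data.frame(label = paste0(rep(c("A:", "B:"), each = 3), 1:3),
                      brain = rep(c("A", "B"), each = 3))
  expect_length(hyper_brain_modules(rep(1:2, each = 3), nodes), 0)
  memb <- c(1, 1, 1, 1, 2, 2)          # one B node joins module 1
  hm <- hyper_brain_modules(memb, nodes)
  expect_length(hm, 1)
  expect_true("B:1" %in% hm[["1"]])
})

test_that("role census pools tables into percentages summing to 100", {
  t1 <- data.frame(role = factor(rep("R1", 4), levels = paste0("R", 1:8)))
  cen <- role_census(t1)
  expect_equal(cen$percent[cen$role == "R1"], 100)
  t2 <- data.frame(role = factor(c("R1", "R2"), levels = paste0("R", 1:8)))
  cen2 <- role_census(list(t1, t2))
  expect_equal(sum(cen2$percent), 100, tolerance = 1e-9)
  expect_equal(cen2$n[cen2$role == "R1"], 5)
})

test_that("end-to-end: strong inter-brain coupling lands in one module", {
  spec <- hyper_brain_spec(
    channels_per_brain = 3,
    couplings = data.frame(source = "A:ch01", target = "B:ch01",
                           frequency = 6, lag = 0.02, strength = 3),
    noise_sd = 0.5, seed = 19)
  ep <- generate_hyper_brain_dataset(spec, epoch_length = 3, n_epochs = 3)
  mats <- connectivity_matrices(ep, wavelet_params(fois = 6), measures = "aci")
  W <- mats$aci[, , 1]
  W[W < 0.5] <- 0                       # crude sparsification for the test
  g <- hyper_brain_graph(W, nodes = attr(mats, "nodes"))
  part <- optimize_partition(g, restarts = 10, seed = 2)
  expect_equal(part$membership[1], part$membership[4])  # A:ch01 with B:ch01
})
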