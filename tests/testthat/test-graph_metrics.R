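test_that("strengths: toy arithmetic and decomposition identity", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- 0.5
  W[2, 3] <- 0.2
  g <- hyper_brain_graph(W, directed = TRUE,
                         nodes = data.frame(label = c("a", "b", "c"),
                                            brain = c("A", "A", "B")))
  st <- strengths(g)
  expect_equal(st$out_strength, c(0.5, 0.2, 0))
  expect_equal(st$in_strength, c(0, 0.5, 0.2))
  expect_equal(st$intra_out_strength, c(0.5, 0, 0))
  expect_equal(st$inter_out_strength, c(0, 0.2, 0))
  expect_equal(st$intra_strength + st$inter_strength, st$strength)

  g0 <- hyper_brain_graph(matrix(0, 3, 3))
  expect_true(all(strengths(g0)$strength == 0))

  set.seed(5)
  gr <- toy_directed(10, weighted = TRUE, seed = 5)
  str <- strengths(gr)
  expect_equal(str$intra_strength + str$inter_strength, str$strength)
})

test_that("clustering: K4, star, and brute-force oracle agreement", {
  K4 <- hyper_brain_graph(matrix(1, 4, 4) - diag(4))
  expect_equal(clustering_coefficient(K4)$cc, 1)
  star <- matrix(0, 4, 4)
  star[1, 2:4] <- 1
  star <- star + t(star)
  expect_equal(clustering_coefficient(hyper_brain_graph(star))$cc, 0)

  g <- toy_directed(8, weighted = TRUE, seed = 7)
  expect_equal(clustering_coefficient(g, "weighted")$cc,
               oracle_cc_directed(g, weighted = TRUE), tolerance = 1e-12)
  gu <- toy_undirected(8, weighted = TRUE, seed = 8)
  expect_equal(clustering_coefficient(gu, "weighted")$cc,
               oracle_cc_undirected(gu, weighted = TRUE), tolerance = 1e-12)
})

test_that("CPL: K4, 4-cycle, Floyd-Warshall oracle, empty graph", {
  K4 <- hyper_brain_graph(matrix(1, 4, 4) - diag(4))
  expect_equal(as.numeric(characteristic_path_length(K4)), 1)
  C4 <- ring_lattice(4, 1)
  expect_equal(as.numeric(characteristic_path_length(C4)), 4 / 3)
  g <- toy_directed(8, weighted = TRUE, seed = 9)
  expect_equal(as.numeric(characteristic_path_length(g, weighted = TRUE)),
               oracle_cpl(g, weighted = TRUE), tolerance = 1e-12)
  expect_warning(cpl0 <- characteristic_path_length(
    hyper_brain_graph(matrix(0, 3, 3))), "no edges")
  expect_true(is.na(cpl0))
})

test_that("CC and CPL match oracles over a randomized battery (<= 8 nodes)", {
  set.seed(77)
  for (i in 1:25) {
    n <- sample(4:8, 1)
    directed <- i %% 2 == 0
    weighted <- i %% 3 == 0
    g <- if (directed) toy_directed(n, p = 0.5, weighted = weighted, seed = 1000 + i)
         else toy_undirected(n, p = 0.5, weighted = weighted, seed = 1000 + i)
    if (sum(g$A) == 0) next
    mode <- if (weighted) "weighted" else "binary"
    cc_o <- if (directed) oracle_cc_directed(g, weighted)
            else oracle_cc_undirected(g, weighted)
    expect_equal(clustering_coefficient(g, mode)$cc, cc_o, tolerance = 1e-10)
    expect_equal(as.numeric(characteristic_path_length(g, weighted)),
                 oracle_cpl(g, weighted), tolerance = 1e-10)
  }
})

test_that("adding an edge never increases binary CPL", {
  set.seed(13)
  for (i in 1:10) {
    g <- toy_undirected(8, p = 0.4, seed = 300 + i)
    holes <- which(g$A == 0 & upper.tri(g$A), arr.ind = TRUE)
    if (!nrow(holes) || sum(g$A) == 0) next
    pick <- holes[sample.int(nrow(holes), 1), ]
    W2 <- g$W
    W2[pick[1], pick[2]] <- W2[pick[2], pick[1]] <- 1
    g2 <- hyper_brain_graph(W2)
    d1 <- characteristic_path_length(g, method = "harmonic")
    d2 <- characteristic_path_length(g2, method = "harmonic")
    expect_lte(as.numeric(d2), as.numeric(d1) + 1e-12)
  }
})

test_that("directed CC/CPL differ from symmetrized values on asymmetric toys", {
  A <- matrix(0, 4, 4)
  A[1, 2] <- A[2, 3] <- A[3, 1] <- A[3, 4] <- 1
  gd <- hyper_brain_graph(A, directed = TRUE)
  gs <- hyper_brain_graph(pmax(A, t(A)), directed = FALSE)
  expect_false(isTRUE(all.equal(as.numeric(characteristic_path_length(gd)),
                                as.numeric(characteristic_path_length(gs)))))
  expect_false(isTRUE(all.equal(clustering_coefficient(gd)$cc,
                                clustering_coefficient(gs)$cc)))
})

test_that("null models preserve node count and degree sequence exactly", {
  g <- toy_undirected(20, p = 0.3, seed = 17)
  gd <- toy_directed(15, p = 0.25, seed = 18)
  for (kind in c("random", "lattice")) {
    for (nm in null_models(g, kind, n = 3, seed = 2)) {
      expect_equal(rowSums(nm$A), rowSums(g$A))
      expect_equal(nrow(nm$W), nrow(g$W))
    }
    for (nm in null_models(gd, kind, n = 3, seed = 2)) {
      expect_equal(rowSums(nm$A), rowSums(gd$A))
      expect_equal(colSums(nm$A), colSums(gd$A))
    }
  }
  expect_identical(
    null_models(g, "random", n = 2, seed = 4)[[1]]$W,
    null_models(g, "random", n = 2, seed = 4)[[1]]$W)
  expect_error(null_models(hyper_brain_graph(matrix(0, 3, 3)), "random"),
               "no edges")
})

test_that("lattice null of a ring lattice keeps CC; random null shortens CPL", {
  rl <- ring_lattice(100, 3)
  cc0 <- clustering_coefficient(rl)$cc
  lat <- null_models(rl, "lattice", n = 3, seed = 5)
  for (nm in lat)
    expect_lt(abs(clustering_coefficient(nm)$cc - cc0) / cc0, 0.05)
  cpl0 <- as.numeric(characteristic_path_length(rl))
  rnd <- null_models(rl, "random", n = 10, seed = 6)
  shorter <- sum(vapply(rnd, function(nm)
    as.numeric(characteristic_path_length(nm)) < cpl0, TRUE))
  expect_gte(shorter, 9)
})

test_that("small-worldness: sigma/omega behave on canonical graphs", {
  set.seed(100)
  ws <- hyper_brain_graph(igraph::as_adjacency_matrix(
    igraph::sample_smallworld(1, 42, 4, 0.1), sparse = FALSE))
  sw <- small_worldness(ws, n_null = 10, seed = 1)
  expect_gt(sw$sigma, 1)

  rl <- ring_lattice(42, 4)
  swr <- small_worldness(rl, n_null = 10, seed = 2)
  expect_lt(swr$omega, 0)

  set.seed(101)
  gr <- hyper_brain_graph(igraph::as_adjacency_matrix(
    igraph::sample_gnm(42, 168), sparse = FALSE))
  swg <- small_worldness(gr, n_null = 10, seed = 3)
  expect_gt(swg$omega, 0)
  expect_lt(abs(swg$sigma - 1), 0.15)
})

test_that("band/region collapsing averages correctly", {
  df <- data.frame(foi = c(2, 3, 8, 10, 40), value = c(1, 3, 2, 4, 99))
  expect_warning(out <- collapse_bands_and_regions(df), "40")
  expect_equal(out$value[out$band == "delta"], 2)
  expect_equal(out$value[out$band == "alpha"], 3)

  mont <- montage_1020()
  df2 <- expand.grid(foi = c(2, 3), label = paste0("A:", mont$label))
  df2$value <- 1
  out2 <- collapse_bands_and_regions(df2)
  expect_equal(nrow(out2), 3)           # 3 regions x 1 band
  expect_true(all(out2$value == 1))
  expect_setequal(unique(out2$region),
                  c("frontal", "central", "parieto-occipital"))
})
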