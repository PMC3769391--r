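pd_of <- function(delta, foi = 10, interval = 0.02)
  phase_diff_series(delta, fois = foi, interval = interval)

test_that("PSI: constant angle 1, cancelling vectors 0, uniform ~ sqrt(pi)/(2 sqrt(k))", {
  expect_equal(as.numeric(psi(pd_of(rep(0.7, 100)))), 1)
  expect_equal(as.numeric(psi(pd_of(c(0, pi)))), 0, tolerance = 1e-12)
  expect_error(psi(pd_of(0.5)), "k >= 2")

  set.seed(10)
  reps <- replicate(200, as.numeric(psi(pd_of(stats::runif(750, -pi, pi)))))
  # Monte-Carlo oracle: E[mean resultant length] ~= sqrt(pi)/2/sqrt(750) = 0.0323
  expect_lt(abs(mean(reps) - sqrt(pi) / 2 / sqrt(750)), 0.003)
})

test_that("coding rule: bins, boundaries, antisymmetry", {
  d <- c(pi / 8, -pi / 8, pi / 2, -pi / 2, 0, pi / 4, -pi / 4, pi)
  codes <- code_phase_difference(pd_of(d))$codes[1, , 1, 1]
  expect_equal(codes, c(1L, -1L, 0L, 0L, 1L, 0L, 0L, 0L))
})

test_that("cleaning removes sub-period runs only", {
  # foi 10 Hz, interval 0.02 s -> period T = 5 points
  # encode +1 as pi/8, -1 as -pi/8 and 0 as pi/2 (non-synchronization)
  run4 <- c(rep(0, 3), rep(1, 4), rep(0, 13))
  run6 <- c(rep(0, 3), rep(1, 6), rep(0, 11))
  mk <- function(v) {
    d <- ifelse(v == 0, pi / 2, v * pi / 8)
    clean_codes(code_phase_difference(pd_of(d)))
  }
  expect_equal(mk(run4)$codes[1, , 1, 1], rep(0L, 20))
  expect_equal(mk(run6)$codes[1, , 1, 1], as.integer(run6))
  # sign flip ends a run: 3 pos + 3 neg both removed at T = 5
  flip <- c(rep(1, 3), rep(-1, 3), rep(0, 14))
  expect_equal(mk(flip)$codes[1, , 1, 1], rep(0L, 20))
  # all-zero unchanged, cleaned flag set
  z <- mk(rep(0, 20))
  expect_true(z$cleaned)
  expect_true(all(z$codes == 0L))
})

test_that("coupling indices: boundary identities and the ICI formula", {
  all_pos <- coupling_indices(clean_codes(code_phase_difference(
    pd_of(rep(pi / 8, 100)))))
  expect_equal(as.numeric(all_pos$pci), 1)
  expect_equal(as.numeric(all_pos$nci), 0)
  expect_equal(as.numeric(all_pos$aci), 1)
  expect_equal(as.numeric(all_pos$ici), 1)

  all_neg <- coupling_indices(clean_codes(code_phase_difference(
    pd_of(rep(-pi / 8, 100)))))
  expect_equal(as.numeric(all_neg$pci), 0)
  expect_equal(as.numeric(all_neg$nci), 1)
  expect_equal(as.numeric(all_neg$aci), 1)
  expect_equal(as.numeric(all_neg$ici), 0)

  # 50 locked-positive + 50 non-synchronized points
  half <- coupling_indices(clean_codes(code_phase_difference(
    pd_of(c(rep(pi / 8, 50), rep(pi / 2, 50))))))
  expect_equal(as.numeric(half$pci), 0.5)
  expect_equal(as.numeric(half$nci), 0)
  expect_equal(as.numeric(half$aci), 0.5)
  expect_equal(as.numeric(half$ici), 0.5 / (1 + 0))
})

test_that("ACI symmetry and PCI/NCI mirror identity hold exactly on random input", {
  set.seed(11)
  for (rep_i in 1:20) {
    d <- stats::runif(80, -pi, pi)
    fwd <- coupling_indices(clean_codes(code_phase_difference(pd_of(d))))
    rev <- coupling_indices(clean_codes(code_phase_difference(pd_of(-d))))
    expect_identical(as.numeric(fwd$aci), as.numeric(rev$aci))
    expect_identical(as.numeric(fwd$pci), as.numeric(rev$nci))
    expect_identical(as.numeric(fwd$nci), as.numeric(rev$pci))
    # bounds
    for (m in c("psi")) expect_true(all(psi(pd_of(d)) >= 0 & psi(pd_of(d)) <= 1))
    for (m in c("pci", "nci", "aci", "ici"))
      expect_true(all(fwd[[m]] >= 0 & fwd[[m]] <= 1))
  }
})

test_that("cleaning never increases pci, nci or aci", {
  set.seed(12)
  for (rep_i in 1:20) {
    d <- stats::runif(60, -pi / 3, pi / 3)
    cod <- code_phase_difference(pd_of(d))
    raw <- coupling_indices(cod)
    cl <- coupling_indices(clean_codes(cod))
    expect_lte(as.numeric(cl$pci), as.numeric(raw$pci))
    expect_lte(as.numeric(cl$nci), as.numeric(raw$nci))
    expect_lte(as.numeric(cl$aci), as.numeric(raw$aci))
  }
})

test_that("connectivity matrices: shape, symmetry, mirror structure", {
  spec <- hyper_brain_spec(
    channels_per_brain = 3,
    couplings = data.frame(source = "A:ch01", target = "B:ch02",
                           frequency = 6, lag = 0.02, strength = 2),
    noise_sd = 0.8, seed = 3)
  ep <- generate_hyper_brain_dataset(spec, epoch_length = 3, n_epochs = 2)
  mats <- connectivity_matrices(ep, wavelet_params(fois = c(6, 10)))
  expect_named(mats, c("psi", "pci", "nci", "aci", "ici"))
  expect_equal(dim(mats$ici), c(6, 6, 2))
  expect_equal(mats$aci[, , 1], t(mats$aci[, , 1]), tolerance = 1e-12)
  expect_equal(mats$psi[, , 2], t(mats$psi[, , 2]), tolerance = 1e-12)
  expect_equal(mats$pci[, , 1], t(mats$nci[, , 1]), tolerance = 1e-12)
  expect_true(all(diag(mats$ici[, , 1]) == 0))
  nodes <- attr(mats, "nodes")
  expect_equal(nodes$brain, rep(c("A", "B"), each = 3))
})

test_that("independent-noise dyad: inter-brain PSI at surrogate level", {
  spec <- hyper_brain_spec(channels_per_brain = 2, noise_sd = 1, seed = 21)
  ep <- generate_hyper_brain_dataset(spec, epoch_length = 3, n_epochs = 3)
  wp <- wavelet_params(fois = 8)
  mats <- connectivity_matrices(ep, wp, measures = "psi")
  inter <- mats$psi[1:2, 3:4, 1]
  sur <- connectivity_matrices(shuffle_surrogate(ep, 5), wp,
                               measures = "psi")$psi[1:2, 3:4, 1]
  expect_lt(abs(mean(inter) - mean(sur)), 0.1)
})
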