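make_raw <- function(x, fs = 100, eog = character()) {
  raw_recording(x, fs, rownames(x), eog = eog)
}

test_that("linked-mastoid re-referencing subtracts the mastoid mean", {
  x <- rbind(ch1 = c(1, 2, 3), ch2 = c(0, 0, 0),
             M1 = c(2, 2, 2), M2 = c(4, 4, 4))
  raw <- make_raw(x)
  out <- rereference_linked_mastoids(raw, "M1", "M2")
  expect_equal(out$samples["ch1", ], c(-2, -1, 0))
  expect_equal(out$samples["ch2", ], c(-3, -3, -3))

  # zero mastoids leave data unchanged
  x0 <- x
  x0["M1", ] <- 0
  x0["M2", ] <- 0
  expect_equal(rereference_linked_mastoids(make_raw(x0), "M1", "M2")$samples,
               x0)
  expect_error(rereference_linked_mastoids(raw, "M1", "M9"), "M9")
})

test_that("band-pass: passband preserved, DC and out-of-band removed", {
  fs <- 1000
  t <- (0:(4 * fs - 1)) / fs
  x <- rbind(s10 = sin(2 * pi * 10 * t),
             dc = rep(3, length(t)),
             s100 = sin(2 * pi * 100 * t))
  out <- bandpass(make_raw(x, fs), 0.5, 70)
  amp <- function(v) sqrt(2 * mean(v^2))
  expect_gt(amp(out$samples["s10", ]), 0.95)          # < 5% attenuation
  expect_lt(abs(mean(out$samples["dc", ])), 1e-6 * 3) # DC removed
  expect_lt(amp(out$samples["s100", ]), 0.1)          # > 90% attenuation
  expect_error(bandpass(make_raw(x, fs), 70, 0.5), "invalid band")
})

test_that("EOG regression recovers the propagation factor", {
  set.seed(4)
  n <- 2000
  clean <- sin(2 * pi * 7 * (1:n) / 250)
  eog <- stats::rnorm(n)
  eog <- stats::residuals(stats::lm(eog ~ clean))  # independent of clean
  x <- rbind(eeg = clean + 0.2 * eog, EOG = eog)
  raw <- raw_recording(x, 250, c("eeg", "EOG"), eog = "EOG")
  out <- correct_eog_regression(raw)
  expect_lt(abs(attr(out, "propagation_factors")["eeg", "EOG"] - 0.2), 1e-6)
  expect_lt(max(abs(out$samples["eeg", ] - clean)), 1e-6)
  expect_lt(abs(stats::cor(out$samples["eeg", ], eog)), 1e-8)

  # uncorrelated EEG: factor ~ 0, output ~ input
  x2 <- rbind(eeg = clean, EOG = eog)
  raw2 <- raw_recording(x2, 250, c("eeg", "EOG"), eog = "EOG")
  out2 <- correct_eog_regression(raw2)
  expect_lt(abs(attr(out2, "propagation_factors")["eeg", "EOG"]), 0.01)
  expect_lt(max(abs(out2$samples["eeg", ] - clean)), 0.05)

  # zero-variance EOG errors
  x3 <- rbind(eeg = clean, EOG = rep(1, n))
  expect_error(correct_eog_regression(
    raw_recording(x3, 250, c("eeg", "EOG"), eog = "EOG")), "variance")
})

test_that("resample_and_epoch: counts, waveform fidelity, short input", {
  fs <- 250
  x <- matrix(stats::rnorm(65 * fs), 1)
  rownames(x) <- "a"
  ep <- resample_and_epoch(make_raw(x, fs), 250, 10)
  expect_equal(dim(ep$data), c(1, 2500, 6))

  fs2 <- 5000
  t <- (0:(4 * fs2 - 1)) / fs2
  x2 <- matrix(sin(2 * pi * 10 * t), 1)
  rownames(x2) <- "s"
  ep2 <- resample_and_epoch(make_raw(x2, fs2), 250, 2)
  t250 <- (0:(250 * 2 - 1)) / 250
  expect_gt(stats::cor(ep2$data[1, , 1], sin(2 * pi * 10 * t250)), 0.999)

  x3 <- matrix(stats::rnorm(5 * fs), 1)
  rownames(x3) <- "a"
  expect_error(resample_and_epoch(make_raw(x3, fs), 250, 10), "shorter")
})

test_that("artifact rejection applies gradient and difference rules", {
  dat <- array(0, c(1, 100, 3))
  dat[1, 50, 2] <- 60                       # single 60-unit jump in epoch 2
  dat[1, , 3] <- seq(0, 250, length.out = 100)  # slow ramp, steps ~2.5
  ep <- epoched_signals(dat, 100, "ch")
  out <- reject_artifacts(ep, artifact_criteria(50, 200))
  log <- rejection_log(out)
  expect_equal(dim(out$data)[3], 1)
  expect_setequal(log$epoch, c(2, 3))
  # epoch 2 trips gradient (and range 60 < 200 passes difference)
  expect_true(all(log$criterion[log$epoch == 2] == "gradient"))
  expect_true(all(log$criterion[log$epoch == 3] == "difference"))

  # flat data: nothing rejected
  flat <- epoched_signals(array(0, c(2, 50, 4)), 100, c("a", "b"))
  expect_equal(dim(reject_artifacts(flat)$data)[3], 4)

  # all rejected warns
  hot <- epoched_signals(array(rep(c(0, 500), 50), c(1, 100, 1)), 100, "x")
  expect_warning(reject_artifacts(hot), "all epochs rejected")
})

test_that("rejection is monotone in the criteria", {
  set.seed(9)
  dat <- array(stats::rnorm(2 * 200 * 20, sd = 12), c(2, 200, 20))
  ep <- epoched_signals(dat, 100, c("a", "b"))
  n_strict <- dim(reject_artifacts(ep, artifact_criteria(55, 80))$data)[3]
  n_loose1 <- dim(reject_artifacts(ep, artifact_criteria(65, 80))$data)[3]
  n_loose2 <- dim(reject_artifacts(ep, artifact_criteria(55, 95))$data)[3]
  expect_lt(n_strict, 20)               # the strict criteria actually bite
  expect_gte(n_loose1, n_strict)
  expect_gte(n_loose2, n_strict)
})

test_that("montage selection restricts, orders, and is idempotent", {
  mont <- montage_1020()
  extra <- c(mont$label, "AF3", "AF4")
  labels <- c(paste0("A:", extra), paste0("B:", extra))
  set.seed(2)
  dat <- array(stats::rnorm(length(labels) * 50), c(length(labels), 50, 1))
  ep <- epoched_signals(dat, 250, labels,
                        rep(c("A", "B"), each = length(extra)))
  sel <- select_montage(ep)
  expect_equal(dim(sel$data)[1], 42)
  expect_equal(electrode_of <- sub("^[AB]:", "", sel$labels),
               rep(mont$label, 2))
  expect_equal(attr(sel, "region")[1:8], rep("frontal", 8))
  # idempotent
  sel2 <- select_montage(sel)
  expect_equal(sel2$data, sel$data)
  # missing label errors by name
  bad <- montage_spec(c("Fz", "XX"), c(Fz = "frontal", XX = "central"))
  expect_error(select_montage(ep, bad), "XX")
})
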