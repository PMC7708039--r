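test_that("noiseless mono-exponential decay matches the closed form", {
  acq <- acquisition()
  tr <- simulate_decay(donor_components(4.9), acq, noiseless = TRUE)

  expect_equal(nrow(tr), 4096)
  expect_equal(max(tr$counts), 10000)
  expect_equal(which.max(tr$counts), 1L)

  # channel whose elapsed time is nearest one lifetime holds ~ peak/e
  elapsed <- tr$time_ns - tr$time_ns[1]
  k <- which.min(abs(elapsed - 4.9))
  expect_equal(tr$counts[k], 10000 * exp(-elapsed[k] / 4.9), tolerance = 1e-12)
  expect_equal(tr$counts[k], 10000 * exp(-1), tolerance = 2e-3)

  # whole curve equals the closed form to high relative accuracy
  expect_equal(tr$counts, 10000 * exp(-elapsed / 4.9), tolerance = 1e-10)
})

test_that("noiseless multi-exponential decay equals the hand-computed sum", {
  comps <- ccc_components()
  acq <- acquisition()
  tr <- simulate_decay(comps, acq, noiseless = TRUE)
  elapsed <- tr$time_ns - tr$time_ns[1]

  # independent evaluation of the three-exponential model at spot channels
  shape <- function(t) {
    0.39 * exp(-t / 0.40) + 0.33 * exp(-t / 1.7) + 0.28 * exp(-t / 5.2)
  }
  scale <- 10000 / shape(0)
  for (k in c(1, 2, 10, 50, 100, 409, 1000, 2000, 3000, 4096)) {
    expect_equal(tr$counts[k], scale * shape(elapsed[k]), tolerance = 1e-12)
  }
})

test_that("seeded noisy traces are reproducible and unbiased", {
  acq <- small_acq(seed = 42L)
  comps <- ccc_components()
  t1 <- simulate_decay(comps, acq)
  t2 <- simulate_decay(comps, acq)
  expect_identical(t1$counts, t2$counts)

  # a different seed gives a different realization
  t3 <- simulate_decay(comps, small_acq(seed = 43L))
  expect_false(identical(t1$counts, t3$counts))

  # empirical mean over replicates approaches the noiseless expectation
  mu <- simulate_decay(comps, acq, noiseless = TRUE)$counts
  n_rep <- 40
  avg <- colMeans(do.call(rbind, lapply(seq_len(n_rep), function(s) {
    simulate_decay(comps, small_acq(seed = 1000L + s))$counts
  })))
  picked <- which(mu > 20)
  z <- (avg[picked] - mu[picked]) / sqrt(mu[picked] / n_rep)
  expect_gt(mean(abs(z) < 3), 0.98)
})

test_that("expected total counts scale linearly with peak counts", {
  comps <- ccc_components()
  tot <- vapply(c(1000, 2000, 4000), function(pc) {
    sum(simulate_decay(comps,
      acquisition(n_channels = 1024, peak_counts = pc),
      noiseless = TRUE
    )$counts)
  }, numeric(1))
  expect_equal(tot[2] / tot[1], 2, tolerance = 1e-9)
  expect_equal(tot[3] / tot[1], 4, tolerance = 1e-9)
})

test_that("a Gaussian IRF shifts the peak off channel one and conserves shape", {
  acq <- acquisition(n_channels = 1024, irf_fwhm = 0.5, seed = 5L)
  tr <- simulate_decay(donor_components(4.9), acq, noiseless = TRUE)
  expect_equal(max(tr$counts), 10000, tolerance = 1e-9)
  # the rising edge before the IRF peak is represented
  expect_gt(which.max(tr$counts), 1L)
})

test_that("simulate_decay validates inputs", {
  expect_error(
    simulate_decay(
      data.frame(tau = c(1, 2), amplitude = c(0.5, 0.4)),
      acquisition()
    ),
    "sum to 1"
  )
  expect_error(lifetime_components(c(1, -2), c(0.5, 0.5)), "positive")
  expect_warning(
    simulate_decay(
      lifetime_components(2000, 1),
      acquisition(n_channels = 64)
    ),
    "cannot be resolved"
  )
})
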