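test_that("noiseless mono-exponential inversion concentrates on the true lifetime", {
  tr <- simulate_decay(
    donor_components(1.0),
    acquisition(window = 50, n_channels = 1024),
    noiseless = TRUE
  )
  fit <- mem_fit(tr, lifetime_grid(n = 80))
  td <- tidy(fit)
  spacing <- diff(log10(td$tau_ns[1:2]))
  near <- abs(log10(td$tau_ns / 1.0)) <= 1.01 * spacing
  expect_gte(sum(td$fractional_amplitude[near]), 0.95)
  expect_true(all(td$amplitude >= 0))
})

test_that("two well-separated components are recovered within tolerance", {
  comps <- lifetime_components(c(0.4, 5.2), c(0.5, 0.5))
  fit <- mem_fit(simulate_decay(comps, acquisition(seed = 7L)))
  expect_equal(count_peaks(fit), 2)
  td <- tidy(fit)
  # amplitude-weighted mean lifetime of each mode within 15% of truth
  for (tau_true in c(0.4, 5.2)) {
    sel <- abs(log10(td$tau_ns / tau_true)) < 0.3
    wmean <- sum(td$amplitude[sel] * td$tau_ns[sel]) / sum(td$amplitude[sel])
    expect_equal(wmean, tau_true, tolerance = 0.15)
  }
})

test_that("degenerate and low-count traces are reported", {
  acq <- small_acq()
  zero <- structure(
    tibble::tibble(time_ns = channel_seq <- seq(0.05, 50, length.out = 512), counts = rep(0, 512)),
    class = c("decay_trace", class(tibble::tibble())), acq = acq
  )
  expect_error(mem_fit(zero), "all zeros")

  tiny <- simulate_decay(
    donor_components(2),
    acquisition(window = 20, n_channels = 64, peak_counts = 20, seed = 2L)
  )
  expect_warning(mem_fit(tiny, lifetime_grid(n = 20)), "below 1000")
})

test_that("fit diagnostics report flux conservation and convergence", {
  fit <- mem_fit(simulate_decay(ccc_components(), acquisition(seed = 3L)))
  d <- glance(fit)
  expect_true(d$converged)
  expect_equal(d$flux_ratio, 1, tolerance = 0.02)
  expect_lte(d$reduced_chisq, 1.10)
})

test_that("vanishing regularization matches a non-negative least-squares oracle", {
  acq <- acquisition(
    window = 20, n_channels = 512, peak_counts = 5000,
    background_rate = 50, seed = 21L
  )
  tr <- simulate_decay(lifetime_components(c(0.5, 3.0), c(0.5, 0.5)), acq)
  grid <- lifetime_grid(0.05, 10, 32)
  fit <- suppressWarnings(
    mem_fit(tr, grid, chi2_target = 1e-9, background = "fixed")
  )
  d <- attr(fit, "diagnostics")
  chi2_mem <- d$reduced_chisq * d$n_channels_fit

  # oracle: weighted NNLS on the same tail-fit system, known background
  y <- tr$counts
  peak <- which.max(y)
  idx <- peak:length(y)
  tt <- tr$time_ns[idx] - tr$time_ns[peak]
  K <- exp(-outer(tt, as.numeric(grid), `/`))
  yy <- y[idx]
  w <- 1 / pmax(yy, 1)
  A <- K * sqrt(w)
  b <- (yy - 50) * sqrt(w)
  nn <- pracma::lsqnonneg(A, b)
  chi2_nnls <- sum((b - A %*% nn$x)^2)

  expect_equal(chi2_mem / chi2_nnls, 1, tolerance = 0.01)
})

test_that("replicate measurements reproduce the same peak structure", {
  comps <- ccc_components()
  spacing <- diff(log10(as.numeric(lifetime_grid())[1:2]))
  mode_taus <- lapply(c(501L, 502L, 503L), function(s) {
    fit <- mem_fit(simulate_decay(comps, acquisition(seed = s)))
    td <- tidy(fit)
    idx <- fretscape:::find_peaks(td$amplitude)
    sort(td$tau_ns[idx])
  })
  expect_true(all(lengths(mode_taus) == 3))
  for (rep in mode_taus[-1]) {
    expect_true(all(abs(log10(rep / mode_taus[[1]])) <= 1.01 * spacing))
  }
})

test_that("an IRF-declared trace is fitted by reconvolution", {
  acq <- acquisition(n_channels = 2048, irf_fwhm = 0.4, seed = 9L)
  tr <- simulate_decay(ccc_components(), acq)
  fit <- mem_fit(tr)
  expect_true(glance(fit)$converged)
  expect_equal(count_peaks(fit), 3)
})
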