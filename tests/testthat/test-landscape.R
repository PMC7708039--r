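test_that("FRET efficiency follows E = 1 - tau_DA/tau_D", {
  expect_equal(fret_efficiency(0.32, 4.9), 1 - 0.32 / 4.9)
  expect_equal(fret_efficiency(4.9, 4.9), 0)
  e <- fret_efficiency(5.2, 4.9, clamp = TRUE)
  expect_equal(as.numeric(e), 0)
  expect_equal(attr(e, "raw"), 1 - 5.2 / 4.9)
  expect_error(fret_efficiency(-1, 4.9), "positive")
  expect_error(fret_efficiency(1, 0), "positive")
})

test_that("FRET efficiency is monotone in tau_DA and scale invariant", {
  taus <- seq(0.1, 6, by = 0.1)
  e <- fret_efficiency(taus, 4.9)
  expect_true(all(diff(e) < 0))
  expect_equal(
    fret_efficiency(0.7, 4.9),
    fret_efficiency(0.7 * 3.1, 4.9 * 3.1)
  )
})

test_that("average FRET matches the normalized-amplitude formula", {
  # single component reduces to the per-peak efficiency
  expect_equal(
    average_fret(2.2, 4.9, amplitudes = 1),
    fret_efficiency(2.2, 4.9),
    ignore_attr = TRUE
  )
  # three-peak hand arithmetic: <tau> = 0.39*0.40 + 0.33*1.7 + 0.28*5.2
  expect_equal(
    as.numeric(average_fret(c(0.40, 1.7, 5.2), 4.9,
      amplitudes = c(0.39, 0.33, 0.28)
    )),
    1 - 2.173 / 4.9,
    tolerance = 1e-12
  )
  # weights need not be normalized
  expect_equal(
    as.numeric(average_fret(c(1, 3), 4.9, amplitudes = c(2, 6))),
    as.numeric(average_fret(c(1, 3), 4.9, amplitudes = c(0.25, 0.75)))
  )
  # all amplitude at vanishing lifetime drives <E> toward 1
  expect_equal(as.numeric(average_fret(1e-9, 4.9, amplitudes = 1)), 1,
    tolerance = 1e-6
  )
  expect_error(average_fret(numeric(0), 4.9, amplitudes = numeric(0)), "no lifetime")
})

test_that("a single log-Gaussian distribution is recovered by self-fit", {
  grid <- lifetime_grid()
  x <- log10(as.numeric(grid))
  amp <- 120 * exp(-(x - log10(1.5))^2 / (2 * 0.12^2))
  dist <- fretscape:::new_lifetime_distribution(
    tibble::tibble(tau_ns = as.numeric(grid), amplitude = amp),
    grid = grid, diagnostics = list(reduced_chisq = 1)
  )
  pk <- fit_gaussians(dist)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$center_ns, 1.5, tolerance = 0.01)
  expect_equal(pk$width_log10, 0.12, tolerance = 0.01)
  expect_equal(pk$fractional_population, 1)
})

test_that("two modes closer than a half-width merge into one component", {
  grid <- lifetime_grid()
  x <- log10(as.numeric(grid))
  w <- 0.2
  amp <- exp(-(x - 0.0)^2 / (2 * w^2)) + exp(-(x - 0.08)^2 / (2 * w^2))
  dist <- fretscape:::new_lifetime_distribution(
    tibble::tibble(tau_ns = as.numeric(grid), amplitude = amp),
    grid = grid, diagnostics = list(reduced_chisq = 1)
  )
  pk <- fit_gaussians(dist)
  expect_equal(nrow(pk), 1)
})

test_that("fractional populations always sum to one", {
  for (s in c(2L, 3L)) {
    fit <- mem_fit(simulate_decay(ccc_components(), acquisition(seed = s)))
    pk <- fit_gaussians(fit)
    expect_equal(sum(pk$fractional_population), 1, tolerance = 1e-6)
    expect_true(all(pk$area >= 0))
  }
})

test_that("count_peaks classifies mono- and tri-modal distributions", {
  fit3 <- mem_fit(simulate_decay(ccc_components(), acquisition(seed = 2L)))
  expect_equal(count_peaks(fit3), 3)
  fit1 <- mem_fit(simulate_decay(donor_components(), acquisition(seed = 102L)))
  expect_equal(count_peaks(fit1), 1)
  zero <- fretscape:::new_lifetime_distribution(
    tibble::tibble(tau_ns = as.numeric(lifetime_grid()), amplitude = 0),
    grid = lifetime_grid(), diagnostics = list()
  )
  expect_equal(count_peaks(zero), 0)
  expect_error(fit_gaussians(zero), "degenerate")
  expect_error(fit_gaussians(fit3, max_components = 0), "max_components")
})

test_that("landscape assembly attaches efficiencies and mean FRET", {
  pk <- tibble::tibble(
    center_ns = c(0.40, 1.7, 5.2), width_log10 = 0.1, height = 1,
    area = c(0.39, 0.33, 0.28),
    fractional_population = c(0.39, 0.33, 0.28)
  )
  ls <- conformational_landscape(pk, tau_D = 4.9)
  expect_equal(ls$E_peak, pmax(1 - c(0.40, 1.7, 5.2) / 4.9, 0))
  expect_equal(ls$E_raw[3], 1 - 5.2 / 4.9)
  expect_equal(attr(ls, "mean_E"), 1 - 2.173 / 4.9, tolerance = 1e-12)
  g <- glance(ls)
  expect_equal(g$n_peaks, 3)
  expect_equal(g$tau_D, 4.9)
})

test_that("mean FRET from peaks agrees with mean FRET from grid amplitudes", {
  fit <- mem_fit(simulate_decay(ccc_components(), acquisition(seed = 6L)))
  pk <- fit_gaussians(fit)
  e_grid <- as.numeric(average_fret(fit, 4.9))
  e_peaks <- as.numeric(average_fret(pk, 4.9))
  expect_equal(e_peaks, e_grid, tolerance = 0.02)
})
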