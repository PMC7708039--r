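test_that("tidiers and autoplot methods produce well-formed output", {
  fit <- suppressWarnings(mem_fit(
    simulate_decay(donor_components(2), small_acq(seed = 8L)),
    lifetime_grid(n = 40)
  ))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(sum(td$fractional_amplitude), 1, tolerance = 1e-9)
  expect_s3_class(glance(fit), "tbl_df")

  pk <- fit_gaussians(fit)
  ls <- conformational_landscape(pk, 4.9)
  expect_s3_class(tidy(ls), "tbl_df")
  expect_equal(nrow(glance(ls)), 1)

  tr <- simulate_decay(donor_components(2), small_acq(seed = 8L))
  expect_s3_class(autoplot(tr), "ggplot")
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(autoplot(ls), "ggplot")
  expect_s3_class(autoplot(descriptor_series("untwist", rnorm(20))), "ggplot")
})
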