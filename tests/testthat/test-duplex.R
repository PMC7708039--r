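test_that("an unperturbed duplex is a straight helix with the set twist", {
  dx <- straight_duplex(24)
  fr <- basepair_frames(dx)
  expect_equal(length(fr), 24)
  for (k in c(1, 5, 11, 23)) {
    expect_equal(step_twist(fr, k), 36, tolerance = 0.1)
  }
  expect_lt(bend_angle(dx, 12, 5), 0.5)
  # frames are orthonormal
  for (f in fr) {
    B <- rbind(f$x, f$y, f$z)
    expect_equal(B %*% t(B), diag(3), tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("cumulative twist is additive over the span", {
  dx <- straight_duplex(24, twist = 30)
  fr <- basepair_frames(dx)
  expect_equal(cumulative_twist(fr, 14, 19), 150, tolerance = 0.5)
  steps <- vapply(14:18, function(k) step_twist(fr, k), numeric(1))
  expect_equal(cumulative_twist(fr, 14, 19), sum(steps), tolerance = 1e-9)
})

test_that("injected untwist is recovered at the right step only", {
  dx <- build_duplex(duplex_spec(strrep("GC", 12),
    untwist = data.frame(step = 8, degrees = 15)
  ))
  fr <- basepair_frames(dx)
  expect_equal(step_twist(fr, 8), 21, tolerance = 0.5)
  for (k in c(3, 9, 15)) expect_equal(step_twist(fr, k), 36, tolerance = 0.1)
})

test_that("complementary strand and pairing map are generated", {
  dx <- build_duplex(duplex_spec("GATC"))
  expect_equal(nrow(dx$pairing), 4)
  bases_w <- vapply(1:4, function(i) {
    dx$atoms$base[dx$atoms$chain == "W" & dx$atoms$resno == i][1]
  }, character(1))
  bases_y <- vapply(1:4, function(i) {
    dx$atoms$base[dx$atoms$chain == "Y" & dx$atoms$resno == i][1]
  }, character(1))
  expect_equal(bases_w, c("G", "A", "T", "C"))
  expect_equal(bases_y, c("C", "T", "A", "G"))
})

test_that("duplex_spec validates sequence and perturbation indices", {
  expect_error(duplex_spec("GXTC"), "A/C/G/T")
  expect_error(
    duplex_spec("GATC", untwist = data.frame(step = 4, degrees = 5)),
    "outside"
  )
  expect_error(
    duplex_spec("GATCGA", bend = data.frame(hinge = 6, degrees = 10, direction = 0)),
    "outside"
  )
  expect_error(
    duplex_spec("GATC", extrude = data.frame(nucleotide = 4, degrees = 90)),
    "3' neighbor"
  )
})

test_that("ensembles stack structurally identical models", {
  m1 <- straight_duplex(10)
  m2 <- straight_duplex(10, twist = 34)
  ens <- structure_ensemble(list(m1, m2))
  expect_equal(length(ens$coords), 2)
  tw <- twist_series(ens, 2, 8)
  expect_equal(tw, c(6 * 36, 6 * 34), tolerance = 0.1)
  m3 <- straight_duplex(12)
  expect_error(structure_ensemble(list(m1, m3)), "identical atom table")
})
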