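test_that("bend angle round-trips generator hinge bends", {
  for (beta in c(20, 40)) {
    dx <- build_duplex(duplex_spec(strrep("GC", 12),
      bend = data.frame(hinge = 12, degrees = beta, direction = 0)
    ))
    tol <- if (beta <= 20) 1 else 1.5
    expect_equal(bend_angle(dx, 12, 5), beta, tolerance = tol / beta)
  }
  expect_error(bend_angle(straight_duplex(8), 4, 5), "insufficient arm")
})

test_that("bend direction is negative toward the minor groove and flips when mirrored", {
  minor <- build_duplex(duplex_spec(strrep("GC", 12),
    bend = data.frame(hinge = 12, degrees = 20, direction = 0)
  ))
  major <- build_duplex(duplex_spec(strrep("GC", 12),
    bend = data.frame(hinge = 12, degrees = 20, direction = 180)
  ))
  d_minor <- bend_direction_dihedral(minor, 12, 5)
  d_major <- bend_direction_dihedral(major, 12, 5)
  expect_lt(d_minor, 0)
  expect_gt(d_major, 0)
  # straight helix: direction undefined
  expect_true(is.na(bend_direction_dihedral(straight_duplex(24), 12, 5)))
})

test_that("base-extrusion dihedral round-trips generator base rotations", {
  dx0 <- straight_duplex(24, sequence = strrep("C", 24))
  theta0 <- base_extrusion_dihedral(dx0, 16)
  # homogeneous duplex: identical baseline for interior pyrimidines
  for (i in c(5, 10, 20)) {
    expect_equal(base_extrusion_dihedral(dx0, i), theta0, tolerance = 0.5 / abs(theta0))
  }
  for (rho in c(90, -90)) {
    dx <- build_duplex(duplex_spec(strrep("C", 24),
      extrude = data.frame(nucleotide = 16, degrees = rho)
    ))
    th <- base_extrusion_dihedral(dx, 16)
    delta <- (th - theta0 + 180) %% 360 - 180
    expect_equal(delta, rho, tolerance = 2 / 90)
  }
  expect_error(base_extrusion_dihedral(dx0, 24), "3' neighbor")
})

test_that("untwist angle uses the caller-supplied reference with the stated sign", {
  s <- untwist_angle(c(165, 172), twist_initial = 180)
  expect_equal(s$value, c(15, 8))
  expect_equal(untwist_angle(170, twist_initial = 170)$value, 0)
  expect_error(untwist_angle(165, twist_initial = numeric(0)), "empty reference")

  # drifting synthetic ensemble: the recovered trend matches the injection
  drift <- -0.02
  models <- lapply(0:39, function(i) straight_duplex(12, twist = 34 + drift * i))
  ens <- structure_ensemble(models)
  tw <- twist_series(ens, 3, 9)
  ref <- tw[1:10] # first-quarter reference sub-ensemble
  u <- untwist_angle(tw, ref)
  slope <- coef(lm(u$value ~ seq_along(u$value)))[2]
  expect_equal(as.numeric(slope), -drift * 6, tolerance = 0.05)
  # drift toward lower twist means positive untwist later in the series
  expect_gt(mean(u$value[31:40]), 0)
})

test_that("all angle descriptors are invariant under rigid motion", {
  dx <- build_duplex(duplex_spec(strrep("GC", 12),
    bend = data.frame(hinge = 12, degrees = 20, direction = 0),
    extrude = data.frame(nucleotide = 16, degrees = 45)
  ))
  R <- random_rotation(11)
  moved <- transform_structure(dx, R, c(13.2, -8.1, 4.4))
  expect_equal(
    cumulative_twist(basepair_frames(moved), 2, 8),
    cumulative_twist(basepair_frames(dx), 2, 8),
    tolerance = 1e-9
  )
  expect_equal(bend_angle(moved, 12, 5), bend_angle(dx, 12, 5), tolerance = 1e-9)
  expect_equal(
    bend_direction_dihedral(moved, 12, 5),
    bend_direction_dihedral(dx, 12, 5),
    tolerance = 1e-9
  )
  expect_equal(
    base_extrusion_dihedral(moved, 16),
    base_extrusion_dihedral(dx, 16),
    tolerance = 1e-9
  )
})

test_that("traversing the frames in reverse order flips the step-twist sign", {
  dx <- straight_duplex(12)
  fr <- basepair_frames(dx)
  n <- length(fr)
  for (k in c(2, 5, 9)) {
    expect_equal(
      step_twist(rev(fr), k),
      -step_twist(fr, n - k),
      tolerance = 1e-6
    )
  }
})

test_that("Watson-Crick hydrogen bonds are detected with the expected geometry", {
  gc <- build_duplex(duplex_spec("G"))
  hb <- hydrogen_bonds(gc)
  expect_equal(nrow(hb), 3)
  expect_setequal(
    paste(hb$donor_atom, hb$acceptor_atom, sep = "-"),
    c("N4-O6", "N1-N3", "N2-O2")
  )
  expect_true(all(hb$distance <= 3.5))

  at <- build_duplex(duplex_spec("A"))
  expect_equal(nrow(hydrogen_bonds(at)), 2)

  # strands translated 2 A apart: no bonds; tighter cutoff: no bonds
  apart <- gc
  sel <- gc$atoms$chain == "Y"
  apart$coords[[1]][sel, 2] <- apart$coords[[1]][sel, 2] + 2
  expect_equal(nrow(hydrogen_bonds(apart)), 0)
  expect_equal(nrow(hydrogen_bonds(gc, d_max = 2.5)), 0)
})

test_that("missing atoms are reported by name", {
  dx <- straight_duplex(6)
  drop <- which(dx$atoms$chain == "W" & dx$atoms$resno == 3 & dx$atoms$atom == "C1'")
  dx$atoms <- dx$atoms[-drop, ]
  dx$coords[[1]] <- dx$coords[[1]][-drop, ]
  expect_error(basepair_frames(dx), "W3:C1'")
})

test_that("block averaging matches the iid closed form and flags correlation", {
  expect_equal(block_average(rep(3.7, 100), 10)$block_sd, 0)

  set.seed(99)
  sigma <- 2.5
  x <- rnorm(1e4, sd = sigma)
  nb <- 50
  ba <- block_average(x, nb)
  expect_equal(ba$block_sd, sigma / sqrt(ba$block_length), tolerance = 0.2)
  expect_equal(ba$mean, 0, tolerance = 4 * sigma / sqrt(1e4))

  # AR(1) with positive autocorrelation inflates the block-mean SD
  phi <- 0.9
  ar <- as.numeric(stats::arima.sim(list(ar = phi), 1e4, sd = sigma))
  ba_ar <- block_average(ar, nb)
  iid_pred <- sd(ar) / sqrt(ba_ar$block_length)
  expect_gt(ba_ar$block_sd, 1.5 * iid_pred)

  expect_error(block_average(1:3, 5), "shorter")
  # trailing remainder is discarded and reported
  ba2 <- block_average(1:103, 10)
  expect_equal(ba2$n_discarded, 3)
  expect_equal(ba2$block_length, 10)
})
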