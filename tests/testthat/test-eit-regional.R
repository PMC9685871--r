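# ROI reduction, tidal impedance change, proportional distribution, DFV,
# PEEP titration.

test_that("band means reduce frames as expected", {
  fr <- array(5, dim = c(32, 32, 3))
  eit <- eit_sequence(frames = fr)
  roi <- roi_mean_series(eit)
  expect_true(all(roi == 5))
  fr2 <- array(0, dim = c(32, 32, 2))
  fr2[17:32, , ] <- 1
  roi2 <- roi_mean_series(eit_sequence(frames = fr2))
  expect_equal(unname(roi2[1, ]), c(0, 0, 1, 1))
  # empty band after masking is refused, naming the band
  mask <- matrix(TRUE, 32, 32); mask[1:8, ] <- FALSE
  expect_error(roi_mean_series(eit_sequence(frames = fr),
                               roi_partition(lung_mask = mask)),
               "anterior")
})

test_that("partition must be 4 disjoint ordered bands", {
  expect_error(roi_partition(bands = list(1:8, 9:16, 17:24)), "4 bands")
  expect_error(roi_partition(bands = list(1:8, 8:16, 17:24, 25:32)), "disjoint")
  expect_error(roi_partition(bands = list(9:16, 1:8, 17:24, 25:32)), "ordered")
})

test_that("tidal frames are the global-Z extrema of the breath", {
  z <- -cos(2 * pi * seq(0, 1, length.out = 51)) # trough at ends, peak mid
  tf <- tidal_frames(z, onset_frame = 3, end_frame = 51, frame_rate = 50)
  expect_equal(tf$end_insp_frame, 26)
  expect_lte(abs(tf$end_exp_frame - 1), 10) # trough inside the search window
  expect_lt(tf$end_exp_frame, tf$end_insp_frame)
  expect_error(tidal_frames(z, 50, 51, 50), "3 frames")
  expect_error(tidal_frames(z, 40, 60, 50), "coverage")
})

test_that("printed regional impedance changes reproduce the published proportions", {
  # mean regional dz at PEEP 0 and PEEP 15
  rt0 <- regional_tidal(rbind(c(0, 0, 0, 0), c(1.8, 13.0, 6.3, 0.07)), 1, 2)
  expect_equal(unname(round_half_up(rt0$proportions)), c(9, 61, 30, 0))
  expect_equal(round_half_up(rt0$nondependent_pct), 70)
  expect_equal(round_half_up(rt0$dfv), 30)
  rt15 <- regional_tidal(rbind(c(0, 0, 0, 0), c(0.31, 10.4, 14.7, 0.54)), 1, 2)
  expect_equal(unname(round_half_up(rt15$proportions)), c(1, 40, 57, 2))
  expect_equal(round_half_up(rt15$nondependent_pct), 41)
  expect_equal(round_half_up(rt15$dfv), 59)
})

test_that("proportions sum to 100 and DFV is scale invariant", {
  set.seed(9)
  for (i in 1:50) {
    dz <- runif(4, 0.01, 20)
    rt <- regional_tidal(rbind(0 * dz, dz), 1, 2)
    expect_equal(sum(rt$proportions), 100, tolerance = 1e-6)
    expect_equal(rt$nondependent_pct + rt$dependent_pct, 100, tolerance = 1e-6)
    expect_equal(rt$dfv, dependent_fraction(dz), tolerance = 1e-9)
    k <- runif(1, 0.1, 500)
    expect_equal(dependent_fraction(k * dz), dependent_fraction(dz),
                 tolerance = 1e-9)
    expect_gte(rt$dfv, 0); expect_lte(rt$dfv, 100)
  }
})

test_that("symmetric and degenerate dz behave as defined", {
  expect_equal(dependent_fraction(c(1, 1, 1, 1)), 50)
  expect_equal(dependent_fraction(c(0, 0, 2, 3)), 100)
  expect_error(dependent_fraction(c(0, 0, 0, 0)), "degenerate")
  expect_error(dependent_fraction(c(1, 1)), "4 regional")
  rt <- regional_tidal(rbind(c(0, 0, 0, 0), c(-0.5, 6, 4, 0.5)), 1, 2)
  expect_true(rt$paradoxical)
  expect_lt(rt$proportions[[1]], 0) # negative dz reported, not clamped
  expect_equal(sum(rt$proportions), 100, tolerance = 1e-6)
})

test_that("DFV-guided titration picks the level nearest 50% with low-PEEP ties", {
  expect_equal(titrate_peep(c(`0` = 30, `3` = 36, `6` = 42, `9` = 47,
                              `12` = 55, `15` = 59)), 9)
  expect_equal(titrate_peep(c(`5` = 48, `10` = 52)), 5)
  expect_equal(titrate_peep(c(`4` = 43, `8` = 50, `12` = 61)), 8)
  expect_error(titrate_peep(c(`5` = 48)), "at least 2")
  expect_error(titrate_peep(setNames(c(48, 52), c("a", "b"))), "named by PEEP")
})

test_that("dependent minus non-dependent difference marks the homogeneity point", {
  expect_equal(distribution_difference(59, 41), 18)
  expect_equal(distribution_difference(50, 50), 0)
  # monotone recruitment produces exactly one sign change
  peep <- seq(0, 15, by = 3)
  dfv <- 100 * regional_partition_model(peep)
  diffc <- distribution_difference(dfv, 100 - dfv)
  expect_equal(sum(diff(sign(diffc)) != 0), 1)
  expect_error(distribution_difference(c(1, 2), 1), "equal length")
})

test_that("DFV rises monotonically with the recruitment parameter and PEEP", {
  peep <- seq(0, 15, by = 1)
  f <- regional_partition_model(peep)
  expect_true(all(diff(f) > 0))
  # and through the full synthesis + reduction path
  cfg <- sim_config(seed = 4, duration = 6)
  dfv <- sapply(c(0, 6, 12, 15), function(p) {
    acq <- simulate_breath_dynamics(cfg, p, duration = 6, noisy = FALSE)
    eit <- synthesize_eit(acq$truth$volume, cfg, p, duration = 6, noisy = FALSE)
    roi <- roi_mean_series(eit$eit)
    gz <- rowMeans(roi)
    s <- select_breaths(detect_breaths(acq$waveforms$flow, 200), 1)[[1]]
    tf <- tidal_frames(gz, frame_of(acq$waveforms$time[s$insp_start], eit$eit),
                       frame_of(acq$waveforms$time[s$exp_end], eit$eit), 50)
    regional_tidal(roi, tf$end_exp_frame, tf$end_insp_frame)$dfv
  })
  expect_true(all(diff(dfv) > 0))
})
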