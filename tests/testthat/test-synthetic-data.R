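# The NAVA breathing + EIT generator: drive, dynamics, recruitment model,
# calibration and determinism.

test_that("Edi bursts have the configured count, peak and period", {
  edi <- simulate_edi(rr = 60, amplitude = 3, ti_fraction = 0.4,
                      duration = 10, rate = 100)
  onsets <- which(edi > 0 & c(0, head(edi, -1)) == 0)
  expect_length(onsets, 10)
  expect_equal(max(edi), 3, tolerance = 1e-3)
  expect_true(all(edi >= 0))
  expect_identical(simulate_edi(60, 0, 0.4, 5), rep(0, 500))
  # default baseline rate: 75 breaths/min -> 0.8 s between bursts
  edi75 <- simulate_edi(rr = 75, amplitude = 3, ti_fraction = 0.4,
                        duration = 8, rate = 200)
  on75 <- which(edi75 > 0 & c(0, head(edi75, -1)) == 0)
  expect_equal(mean(diff(on75)) / 200, 0.8, tolerance = 1e-2)
  expect_error(simulate_edi(-1, 3, 0.4, 5), "rr")
})

test_that("the recruitment logistic hits its calibration anchors", {
  expect_equal(regional_partition_model(0), 0.30, tolerance = 0.005)
  expect_equal(regional_partition_model(9), 0.47, tolerance = 0.01)
  expect_equal(regional_partition_model(15), 0.59, tolerance = 0.005)
  # infinite width limit: constant midpoint
  rec <- list(f_min = 0.2, f_max = 0.6, p50 = 8, width = 1e9)
  expect_equal(regional_partition_model(c(0, 7, 15), rec),
               rep(0.4, 3), tolerance = 1e-6)
})

test_that("a passive pressure-driven breath recovers the mechanical truth", {
  cfg <- sim_config(seed = 2)
  # no muscle pressure: the ventilator drive alone inflates the lung, so
  # the transpulmonary fit must recover C_lung and R_aw
  acq <- simulate_breath_dynamics(cfg, 6, duration = 8, k_edi = 0,
                                  noisy = FALSE)
  wf <- acq$waveforms
  segs <- select_breaths(detect_breaths(wf$flow, wf$sample_rate), 3)
  p_tp <- transpulmonary(wf$p_ao, wf$p_eso)
  for (s in segs) {
    span <- s$insp_start:s$exp_end
    vol <- integrate_volume(wf$flow, s, wf$sample_rate)$volume_series
    fit <- fit_eom(p_tp[span], wf$flow[span], vol)
    expect_lt(abs(coef(fit)[["compliance"]] - acq$truth$params$c_lung) /
                acq$truth$params$c_lung, 0.01)
    expect_lt(abs(coef(fit)[["resistance"]] - acq$truth$params$r_aw) /
                acq$truth$params$r_aw, 0.01)
  }
})

test_that("population calibration meets the study-condition endpoints", {
  cfg <- sim_config(seed = 6)
  acq0 <- simulate_breath_dynamics(cfg, 0, duration = 10, noisy = FALSE)
  acq15 <- simulate_breath_dynamics(cfg, 15, duration = 10, noisy = FALSE)
  expect_equal(mean(acq0$truth$vt_breaths), 153, tolerance = 0.02)
  expect_equal(mean(acq15$truth$vt_breaths), 297, tolerance = 0.02)
  m0 <- breath_metrics(acq0$waveforms,
                       detect_breaths(acq0$waveforms$flow, 200)[[2]])
  m15 <- breath_metrics(acq15$waveforms,
                        detect_breaths(acq15$waveforms$flow, 200)[[2]])
  expect_equal(m0$peak_p_ao, 6.6, tolerance = 0.01)
  expect_equal(m15$peak_p_ao, 23.5, tolerance = 0.01)
  expect_equal(m0$rr_inst, 75, tolerance = 0.02)
  expect_equal(m15$rr_inst, 38, tolerance = 0.02)
})

test_that("noise-free EIT synthesis reproduces the dependent fraction exactly", {
  cfg <- sim_config(seed = 3, eit_gain = 1, eit_baseline = rep(0, 4))
  acq <- simulate_breath_dynamics(cfg, 12, duration = 6, noisy = FALSE)
  eit <- synthesize_eit(acq$truth$volume, cfg, 12, duration = 6, noisy = FALSE)
  roi <- roi_mean_series(eit$eit)
  i0 <- which.min(rowSums(roi)[10:100]) + 9; i1 <- which.max(rowSums(roi))
  rt <- regional_tidal(roi, i0, i1)
  f_true <- regional_partition_model(12, cfg$recruitment)
  expect_equal(rt$dfv / 100, f_true, tolerance = 1e-9)
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- sim_config(seed = 99, n_animals = 1, peep_ladder = c(0, 9),
                    duration = 5)
  d1 <- generate_protocol_dataset(cfg)
  d2 <- generate_protocol_dataset(cfg)
  expect_identical(d1, d2)
  d3 <- generate_protocol_dataset(sim_config(seed = 100, n_animals = 1,
                                             peep_ladder = c(0, 9),
                                             duration = 5))
  expect_false(identical(d1, d3))
})

test_that("protocol datasets have the ladder structure and phase labels", {
  cfg <- sim_config(seed = 1, n_animals = 2, duration = 5)
  ds <- generate_protocol_dataset(cfg)
  expect_length(ds, 2 * 11)
  phases <- sapply(ds, function(a) a$meta$phase)
  peeps <- sapply(ds, function(a) a$meta$peep)
  expect_equal(unname(table(phases)[["incremental"]]), 2 * 6)
  expect_equal(unname(table(phases)[["decremental"]]), 2 * 5)
  expect_equal(peeps[1:11], c(0, 3, 6, 9, 12, 15, 12, 9, 6, 3, 0))
  one <- generate_protocol_dataset(sim_config(seed = 1, n_animals = 1,
                                              peep_ladder = 5, duration = 5))
  expect_length(one, 1)
})

test_that("simulator rejects non-physical configurations", {
  expect_error(sim_config(r_aw = -1))
  expect_error(sim_config(ti_frac = 1.2))
  expect_error(sim_config(recruitment = list(f_min = 0.7, f_max = 0.3,
                                             p50 = 8, width = 5)))
})
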