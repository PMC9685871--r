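# Containers, file round-trips and stream alignment.

test_that("waveform record validates lengths, rates and time uniformity", {
  n <- 12000
  rec <- waveform_record(p_ao = rnorm(n), p_eso = rnorm(n), flow = rnorm(n),
                         sample_rate = 200)
  expect_s3_class(rec, "waveform_record")
  expect_equal(rec$time[n] - rec$time[1], (n - 1) / 200) # 60 s at 200 Hz
  expect_error(waveform_record(p_ao = 1, p_eso = 1, flow = 1), "2 samples")
  expect_error(waveform_record(p_ao = rnorm(5), p_eso = rnorm(4),
                               flow = rnorm(5)), "same length")
  bad_time <- c(0, 1, 1, 2, 3) / 200
  expect_error(waveform_record(p_ao = rnorm(5), p_eso = rnorm(5),
                               flow = rnorm(5), time = bad_time),
               "sampling error")
  expect_error(waveform_record(p_ao = rnorm(5), p_eso = rnorm(5),
                               flow = rnorm(5), time = c(0, 1, 2, 3, 4.5) / 200),
               "sampling error")
})

test_that("waveform CSV round-trip is lossless and schema errors name the column", {
  set.seed(1)
  n <- 400
  rec <- waveform_record(p_ao = rnorm(n, 10), p_eso = rnorm(n, -3),
                         flow = rnorm(n), p_ga = rnorm(n, 5),
                         sample_rate = 200, edi = runif(200), edi_rate = 100,
                         meta = list(animal = 3, peep = 9,
                                     phase = "incremental"))
  path <- file.path(tempdir(), "wf_roundtrip.csv")
  write_waveforms(rec, path)
  back <- read_waveforms(path)
  for (ch in c("p_ao", "p_eso", "p_ga", "flow", "edi"))
    expect_lt(max(abs(back[[ch]] - rec[[ch]])), 1e-9)
  expect_equal(back$meta$peep, 9)
  expect_equal(back$meta$phase, "incremental")
  expect_equal(back$sample_rate, 200)
  expect_error(read_waveforms(path, schema = c(time = "time", p_ao = "Paw",
                                               p_eso = "p_eso", flow = "flow")),
               "Paw")
  expect_error(read_waveforms(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("unit and sign declarations are normalized on load", {
  n <- 300
  rec <- waveform_record(p_ao = seq_len(n) / 50, p_eso = rep(-2, n),
                         flow = sin(seq_len(n) / 20), sample_rate = 100)
  path <- file.path(tempdir(), "wf_units.csv")
  write_waveforms(rec, path)
  # interpret the stored numbers as mbar and L/min with expiration positive
  conv <- read_waveforms(path, pressure_units = "mbar", flow_units = "L/min",
                         flow_sign = "insp_neg")
  expect_equal(conv$p_ao, rec$p_ao * 1.0197162, tolerance = 1e-8)
  expect_equal(conv$flow, -rec$flow / 60, tolerance = 1e-8)
})

test_that("EIT containers accept exactly one representation and check the grid", {
  tr <- matrix(rnorm(40), 10, 4)
  e1 <- eit_sequence(roi_traces = tr, frame_rate = 50)
  expect_null(e1$frames)
  expect_equal(colnames(e1$roi_traces),
               c("anterior", "mid_anterior", "mid_posterior", "posterior"))
  fr <- array(rnorm(32 * 32 * 5), dim = c(32, 32, 5))
  e2 <- eit_sequence(frames = fr)
  expect_equal(length(e2$time), 5)
  expect_error(eit_sequence(frames = array(0, dim = c(31, 32, 5))),
               "expected 32x32")
  expect_error(eit_sequence(frames = fr, roi_traces = tr), "exactly one")
  expect_error(eit_sequence(), "exactly one")
})

test_that("EIT CSV round-trips preserve traces and frames", {
  tr <- matrix(rnorm(200), 50, 4)
  e1 <- eit_sequence(roi_traces = tr, frame_rate = 50)
  p1 <- file.path(tempdir(), "eit_traces.csv")
  write_eit(e1, p1)
  b1 <- read_eit(p1)
  expect_null(b1$frames)
  expect_lt(max(abs(b1$roi_traces - e1$roi_traces)), 1e-9)
  expect_equal(b1$frame_rate, 50, tolerance = 1e-6)

  fr <- array(rnorm(32 * 32 * 6), dim = c(32, 32, 6))
  e2 <- eit_sequence(frames = fr, frame_rate = 50)
  p2 <- file.path(tempdir(), "eit_frames.csv")
  write_eit(e2, p2)
  b2 <- read_eit(p2)
  expect_lt(max(abs(b2$frames - fr)), 1e-9)
})

test_that("frame-stack reduction and direct traces give identical downstream dz", {
  cfg <- sim_config(seed = 5, duration = 10)
  acq <- simulate_breath_dynamics(cfg, 6, duration = 10, noisy = FALSE)
  s_fr <- synthesize_eit(acq$truth$volume, cfg, 6, duration = 10,
                         emit_frames = TRUE, noisy = FALSE)
  s_tr <- synthesize_eit(acq$truth$volume, cfg, 6, duration = 10,
                         emit_frames = FALSE, noisy = FALSE)
  roi_fr <- roi_mean_series(s_fr$eit)
  roi_tr <- roi_mean_series(s_tr$eit)
  expect_lt(max(abs(roi_fr - roi_tr)), 1e-9)
  gz <- rowMeans(roi_fr)
  i1 <- which.max(gz)
  i0 <- which.min(gz[1:i1])
  rt_fr <- regional_tidal(roi_fr, i0, i1)
  rt_tr <- regional_tidal(roi_tr, i0, i1)
  expect_equal(rt_fr$dz, rt_tr$dz, tolerance = 1e-12)
  expect_equal(rt_fr$dfv, rt_tr$dfv, tolerance = 1e-12)
})

test_that("cross-correlation alignment recovers embedded EIT clock lags", {
  for (lag in c(0, 0.2, 37 / 50, -1.5, 2)) {
    cfg <- sim_config(seed = 8, eit_lag = lag)
    acq <- simulate_breath_dynamics(cfg, 6, duration = 20, noisy = FALSE)
    eit <- synthesize_eit(acq$truth$volume, cfg, 6, duration = 20,
                          noisy = FALSE)
    al <- align_acquisition(acq$waveforms, eit$eit,
                            method = "cross-correlation", max_lag = 2)
    expect_lt(abs(al$offset - lag), 1 / 50 + 1e-9)
  }
})

test_that("declared-offset alignment defaults to simultaneous clocks", {
  cfg <- sim_config(seed = 8)
  acq <- simulate_breath_dynamics(cfg, 3, duration = 6, noisy = FALSE)
  eit <- synthesize_eit(acq$truth$volume, cfg, 3, duration = 6, noisy = FALSE)
  al <- align_acquisition(acq$waveforms, eit$eit)
  expect_identical(al$offset, 0)
  expect_error(align_acquisition(acq$waveforms, eit$eit, offset = 100),
               "alignment error")
})
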