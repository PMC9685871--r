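# Calibrated generator of NAVA-assisted spontaneous breathing and EIT
# data over an incremental/decremental PEEP ladder.
#
# Breathing follows a single-compartment equation of motion integrated
# with fixed-step RK4 at the waveform rate. Neural drive is a half-sine
# Edi burst; the ventilator delivers PEEP plus nava_level * Edi above the
# trigger, the inspiratory muscles add k_edi * Edi, and esophageal
# pressure combines chest-wall elastic recoil with muscle pressure:
#
#   P_ao  = PEEP + P_vent,   P_eso = eso_offset + V/C_cw - P_mus,
#   1/C_rs = 1/C_lung(PEEP) + 1/C_cw.
#
# Calibration is closed-form against the study-condition endpoints:
# respiratory rate falls linearly 75 -> 38 /min and tidal volume rises
# 153 -> 297 ml as PEEP goes 0 -> 15 cmH2O (rapid-shallow to slow-deep
# post-lavage breathing); peak airway pressure 6.6 -> 23.5 cmH2O fixes
# the Edi amplitude per PEEP through the NAVA gain (2.3 cmH2O/uV); lung
# compliance rises linearly 14.5 -> 26.9 ml/cmH2O. Because the ODE is
# linear in the drive, the muscle gain that meets the tidal volume
# target is solved exactly from two unit-drive simulations.
#
# Regional distribution: a logistic recruitment model in PEEP sets the
# dependent (dorsal) volume fraction, calibrated to 0.30 at PEEP 0, 0.47
# at PEEP 9 and 0.59 at PEEP 15; EIT ROI traces are linear in regional
# volume (gain in AU/ml) with additive Gaussian noise, and frames paint
# each band uniformly so frame and trace paths agree exactly.

#' Simulator configuration
#'
#' All study conditions in one list. Endpoints are linearly interpolated
#' in PEEP between the 0 and 15 cmH2O values.
#'
#' @param seed integer RNG seed.
#' @param n_animals cohort size (default 10).
#' @param peep_ladder PEEP sequence, cmH2O (default 0,3,...,15,...,3,0).
#' @param duration acquisition length per step, seconds (default 60).
#' @param nava_level NAVA gain, cmH2O/uV (default 2.3).
#' @param rr_endpoints respiratory rate at PEEP 0 and 15, /min.
#' @param vt_endpoints tidal volume target at PEEP 0 and 15, ml.
#' @param peak_paw_endpoints peak airway pressure at PEEP 0 and 15,
#'   cmH2O; with the NAVA gain these set the Edi amplitude.
#' @param c_lung_endpoints lung compliance at PEEP 0 and 15, ml/cmH2O.
#' @param r_aw airway resistance, cmH2O.s/L (default 8).
#' @param c_cw chest-wall compliance, ml/cmH2O (default 100).
#' @param eso_offset end-expiratory esophageal pressure, cmH2O
#'   (default -2.5).
#' @param ti_frac neural inspiratory fraction of the cycle (default 0.4).
#' @param trigger Edi assist trigger, uV (default 0.5).
#' @param recruitment logistic dependent-fraction model: list
#'   `f_min`, `f_max`, `p50` (cmH2O), `width` (cmH2O).
#' @param subsplit_ant anterior share of non-dependent volume at PEEP 0
#'   and 15 (linearly interpolated).
#' @param subsplit_post posterior share of dependent volume at PEEP 0
#'   and 15.
#' @param eit_gain AU/ml, scalar (all ROIs) or length 4.
#' @param eit_baseline per-ROI Z baseline, AU.
#' @param eit_lag EIT clock lag, seconds: frame at EIT time t shows the
#'   lung at waveform time t + lag (default 0, simultaneous clocks).
#' @param noise per-channel Gaussian SDs: list `p_ao`, `p_eso`, `p_ga`
#'   (cmH2O), `flow` (L/s), `edi` (uV), `eit` (AU, per ROI trace sample).
#' @param animal_sd between-animal variability: lognormal sdlog for
#'   `c_lung`, `vt`, `rr`, `r_aw`, `edi`; additive SD for `dfv`
#'   (fraction) and `eso` (cmH2O).
#' @param sample_rate,edi_rate,frame_rate sampling rates, Hz.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_animals = 10L,
                       peep_ladder = c(0, 3, 6, 9, 12, 15, 12, 9, 6, 3, 0),
                       duration = 60,
                       nava_level = 2.3,
                       rr_endpoints = c(75, 38),
                       vt_endpoints = c(153, 297),
                       peak_paw_endpoints = c(6.6, 23.5),
                       c_lung_endpoints = c(14.5, 26.9),
                       r_aw = 8, c_cw = 100, eso_offset = -2.5,
                       ti_frac = 0.4, trigger = 0.5,
                       recruitment = list(f_min = 0.23, f_max = 0.69,
                                          p50 = 8.5, width = 5),
                       subsplit_ant = c(0.122, 0.029),
                       subsplit_post = c(0.011, 0.035),
                       eit_gain = 0.1,
                       eit_baseline = c(5, 10, 10, 5),
                       eit_lag = 0,
                       noise = list(p_ao = 0.1, p_eso = 0.1, p_ga = 0.05,
                                    flow = 0.005, edi = 0.02, eit = 0.02),
                       animal_sd = list(c_lung = 0.15, vt = 0.2, rr = 0.17,
                                        r_aw = 0.15, edi = 0.15,
                                        dfv = 0.07, eso = 1.5),
                       sample_rate = 200, edi_rate = 100, frame_rate = 50) {
  stopifnot(all(peep_ladder >= 0), n_animals >= 1, duration > 0,
            r_aw > 0, c_cw > 0, all(c_lung_endpoints > 0),
            all(rr_endpoints > 0), ti_frac > 0, ti_frac < 1)
  with(recruitment, stopifnot(f_min >= 0, f_min <= f_max, f_max <= 1,
                              width > 0))
  if (length(eit_gain) == 1L) eit_gain <- rep(eit_gain, 4)
  cfg <- list(seed = as.integer(seed), n_animals = as.integer(n_animals),
              peep_ladder = peep_ladder, duration = duration,
              nava_level = nava_level, rr_endpoints = rr_endpoints,
              vt_endpoints = vt_endpoints,
              peak_paw_endpoints = peak_paw_endpoints,
              c_lung_endpoints = c_lung_endpoints,
              r_aw = r_aw, c_cw = c_cw, eso_offset = eso_offset,
              ti_frac = ti_frac, trigger = trigger,
              recruitment = recruitment,
              subsplit_ant = subsplit_ant, subsplit_post = subsplit_post,
              eit_gain = eit_gain, eit_baseline = eit_baseline,
              eit_lag = eit_lag, noise = noise, animal_sd = animal_sd,
              sample_rate = sample_rate, edi_rate = edi_rate,
              frame_rate = frame_rate)
  class(cfg) <- "sim_config"
  cfg
}

# linear interpolation between the PEEP-0 and PEEP-15 endpoint values
peep_interp <- function(endpoints, peep) {
  endpoints[1] + (endpoints[2] - endpoints[1]) * peep / 15
}

#' Half-sine diaphragm electrical activity bursts
#'
#' @param rr respiratory rate, breaths/min.
#' @param amplitude burst peak, uV.
#' @param ti_fraction inspiratory fraction of the cycle, in (0, 1).
#' @param duration seconds.
#' @param rate sampling rate, Hz (default 100).
#' @return numeric Edi series (baseline 0) sampled at `rate`.
#' @export
simulate_edi <- function(rr, amplitude, ti_fraction, duration, rate = 100) {
  stopifnot(rr > 0, amplitude >= 0, duration > 0,
            ti_fraction > 0, ti_fraction < 1)
  t <- seq(0, duration, by = 1 / rate)
  t <- t[t < duration]
  edi_at(t, rr, amplitude, ti_fraction)
}

edi_at <- function(t, rr, amplitude, ti_fraction) {
  cyc <- 60 / rr
  ti <- ti_fraction * cyc
  ph <- t %% cyc
  ifelse(ph < ti, amplitude * sin(pi * ph / ti), 0)
}

#' Dependent volume fraction as a logistic function of PEEP
#'
#' Recruitment model of the generator: the fraction of tidal volume
#' reaching the dependent (dorsal) half of the lung rises with PEEP as
#' `f_min + (f_max - f_min) / (1 + exp(-(PEEP - p50)/width))`, calibrated
#' so the defaults give 0.30 at PEEP 0, ~0.47 at PEEP 9 and ~0.59 at
#' PEEP 15.
#'
#' @param peep cmH2O (vectorised).
#' @param recruitment list with `f_min`, `f_max`, `p50`, `width` (see
#'   [sim_config()]).
#' @return dependent volume fraction in `[0, 1]`.
#' @export
regional_partition_model <- function(peep,
                                     recruitment = sim_config()$recruitment) {
  with(recruitment,
       f_min + (f_max - f_min) / (1 + exp(-(peep - p50) / width)))
}

# realized parameter set for one animal at one PEEP step
step_params <- function(config, peep, re = NULL) {
  if (is.null(re))
    re <- list(c_lung = 1, vt = 1, rr = 1, r_aw = 1, edi = 1,
               dfv = 0, eso = 0)
  p <- list(
    peep = peep,
    rr = peep_interp(config$rr_endpoints, peep) * re$rr,
    vt_target = peep_interp(config$vt_endpoints, peep) * re$vt,
    edi_amp = pmax(0.1, (peep_interp(config$peak_paw_endpoints, peep) - peep) /
                     config$nava_level * re$edi),
    c_lung = peep_interp(config$c_lung_endpoints, peep) * re$c_lung,
    r_aw = config$r_aw * re$r_aw,
    c_cw = config$c_cw,
    eso_offset = config$eso_offset + re$eso,
    f_dep = min(0.95, max(0.05,
                regional_partition_model(peep, config$recruitment) + re$dfv)),
    nava_level = config$nava_level,
    ti_frac = config$ti_frac, trigger = config$trigger)
  p$c_rs_l <- 1 / (1000 / p$c_lung + 1000 / p$c_cw) # L/cmH2O
  p
}

# integrate the compartment for `duration` seconds; drive gains explicit
run_compartment <- function(p, duration, rate, nava_level, k_edi) {
  n <- round(duration * rate)
  t_half <- seq(0, by = 1 / (2 * rate), length.out = 2L * n - 1L)
  edi_half <- edi_at(t_half, p$rr, p$edi_amp, p$ti_frac)
  rk4_lung(edi_half, 1 / rate, nava_level, k_edi, p$r_aw, p$c_rs_l,
           p$trigger, 0)
}

# tidal excursion (L) of the second simulated cycle under given gains
unit_vt <- function(p, rate, nava_level, k_edi) {
  cyc <- 60 / p$rr
  sim <- run_compartment(p, 3 * cyc, rate, nava_level, k_edi)
  n <- length(sim$v)
  i <- seq.int(ceiling(n / 3) + 1L, min(n, ceiling(2 * n / 3)))
  max(sim$v[i]) - min(sim$v[i])
}

# muscle gain meeting the tidal volume target: the ODE is linear in the
# drive, so Vt = nava * Vt_assist_unit + k * Vt_mus_unit solves exactly
solve_k_edi <- function(p, rate) {
  vt_a <- unit_vt(p, rate, 1, 0) # tidal excursion per unit assist gain
  vt_m <- unit_vt(p, rate, 0, 1) # ... per unit muscle gain

  k <- (p$vt_target / 1000 - p$nava_level * vt_a) / vt_m
  max(0, k)
}

#' Simulate one NAVA acquisition at a given PEEP
#'
#' Integrates the single-compartment model (fixed-step RK4 at the
#' waveform rate) under half-sine neural drive and returns the full
#' waveform record plus the generator's ground truth. The muscle
#' pressure gain is solved so the noise-free tidal volume equals the
#' configured target unless `k_edi` is given.
#'
#' @param config a [sim_config()].
#' @param peep PEEP level, cmH2O.
#' @param edi optional externally supplied Edi series at the waveform
#'   rate (overrides the internal half-sine; half-step values are
#'   interpolated linearly).
#' @param duration seconds (default `config$duration`).
#' @param params realized parameter list (internal use; defaults to the
#'   population parameters at `peep`).
#' @param k_edi muscle gain, cmH2O/uV; `NULL` (default) solves it from
#'   the tidal volume target.
#' @param noisy add measurement noise to the emitted channels (default
#'   TRUE; the truth is always noise-free).
#' @return list with `waveforms` (a [waveform_record()]) and `truth`
#'   (list: `volume` ml above end-expiration, `params`, `k_edi`,
#'   `vt_breaths` ml per cycle, `n_breaths`).
#' @export
simulate_breath_dynamics <- function(config, peep, edi = NULL,
                                     duration = config$duration,
                                     params = NULL, k_edi = NULL,
                                     noisy = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  rate <- config$sample_rate
  p <- if (is.null(params)) step_params(config, peep) else params
  if (is.null(k_edi)) k_edi <- solve_k_edi(p, rate)
  n <- round(duration * rate)
  if (is.null(edi)) {
    sim <- run_compartment(p, duration, rate, p$nava_level, k_edi)
  } else {
    if (length(edi) != n)
      stop_arg("edi must be sampled at the waveform rate (%d samples)", n)
    t_half <- seq(0, by = 1 / (2 * rate), length.out = 2L * n - 1L)
    t_full <- seq(0, by = 1 / rate, length.out = n)
    edi_half <- approx(t_full, edi, xout = t_half, rule = 2)$y
    sim <- rk4_lung(edi_half, 1 / rate, p$nava_level, k_edi, p$r_aw,
                    p$c_rs_l, p$trigger, 0)
  }
  v_ml <- sim$v * 1000
  p_ao <- p$peep + sim$p_vent
  p_eso <- p$eso_offset + v_ml / p$c_cw - sim$p_mus
  p_ga <- rep(5, n) # gastric pressure carried but unused by the analysis
  flow <- sim$flow
  edi_t <- seq(0, by = 1 / config$edi_rate,
               length.out = floor(duration * config$edi_rate))
  edi_out <- if (is.null(edi)) edi_at(edi_t, p$rr, p$edi_amp, p$ti_frac)
             else approx(seq(0, by = 1 / rate, length.out = n), edi,
                         xout = edi_t, rule = 2)$y
  nz <- config$noise
  if (noisy) {
    p_ao <- p_ao + rnorm(n, 0, nz$p_ao)
    p_eso <- p_eso + rnorm(n, 0, nz$p_eso)
    p_ga <- p_ga + rnorm(n, 0, nz$p_ga)
    flow <- flow + rnorm(n, 0, nz$flow)
    edi_out <- pmax(0, edi_out + rnorm(length(edi_out), 0, nz$edi))
  }
  # per-cycle tidal excursions of the true volume state
  cyc <- 60 / p$rr
  nb <- floor(duration / cyc)
  vt_breaths <- vapply(seq_len(nb), function(b) {
    lo <- round((b - 1) * cyc * rate) + 1L
    hi <- min(n, round(b * cyc * rate))
    max(v_ml[lo:hi]) - min(v_ml[lo:hi])
  }, numeric(1))
  wf <- waveform_record(p_ao = p_ao, p_eso = p_eso, flow = flow, p_ga = p_ga,
                        sample_rate = rate, edi = edi_out, edi_time = edi_t,
                        edi_rate = config$edi_rate,
                        meta = list(peep = peep))
  list(waveforms = wf,
       truth = list(volume = v_ml, params = p, k_edi = k_edi,
                    vt_breaths = vt_breaths, n_breaths = nb))
}

#' Synthesize an EIT sequence from the true volume state
#'
#' Regional volumes are fixed fractions of the compartment volume (the
#' dependent fraction from the recruitment model, extreme-band shares
#' from the subsplit rule); each ROI trace is `gain * volume + baseline`
#' plus Gaussian noise, sampled at the frame rate. Optionally paints
#' 32 x 32 frames with uniform band values, so the frame-stack and
#' trace paths are exactly equivalent downstream.
#'
#' @param volume true volume above end-expiration, ml, at the waveform
#'   rate.
#' @param config a [sim_config()].
#' @param peep PEEP level, cmH2O (sets the subsplit shares).
#' @param f_dep dependent volume fraction (default from the recruitment
#'   model at `peep`).
#' @param duration seconds.
#' @param emit_frames also build the frame stack (default FALSE; traces
#'   only).
#' @param noisy add trace noise (default TRUE).
#' @return list with `eit` (an [eit_sequence()]) and `regional_volumes`
#'   (`T x 4` ml at frame times, the truth).
#' @export
synthesize_eit <- function(volume, config, peep,
                           f_dep = regional_partition_model(peep, config$recruitment),
                           duration = config$duration,
                           emit_frames = FALSE, noisy = TRUE) {
  rate <- config$sample_rate
  t_wave <- seq(0, by = 1 / rate, length.out = length(volume))
  nt <- floor(duration * config$frame_rate)
  t_frame <- seq(0, by = 1 / config$frame_rate, length.out = nt)
  v_f <- approx(t_wave, volume, xout = t_frame + config$eit_lag, rule = 2)$y
  a_s <- peep_interp(config$subsplit_ant, peep)
  p_s <- peep_interp(config$subsplit_post, peep)
  shares <- c(a_s * (1 - f_dep), (1 - a_s) * (1 - f_dep),
              (1 - p_s) * f_dep, p_s * f_dep)
  vols <- outer(v_f, shares)
  colnames(vols) <- ROI_NAMES
  traces <- sweep(sweep(vols, 2, config$eit_gain, "*"), 2,
                  config$eit_baseline, "+")
  if (noisy) traces <- traces + matrix(rnorm(length(traces), 0, config$noise$eit),
                                       nrow = nt)
  frames <- NULL
  if (emit_frames) {
    frames <- array(0, dim = c(32, 32, nt))
    bands <- list(1:8, 9:16, 17:24, 25:32)
    for (r in 1:4)
      frames[bands[[r]], , ] <- rep(traces[, r], each = 8L * 32L)
  }
  eit <- if (emit_frames)
    eit_sequence(frames = frames, time = t_frame,
                 frame_rate = config$frame_rate)
  else
    eit_sequence(roi_traces = traces, time = t_frame,
                 frame_rate = config$frame_rate)
  list(eit = eit, regional_volumes = vols)
}

#' Generate a full PEEP-ladder protocol dataset
#'
#' One acquisition per animal per ladder step, with animal-level random
#' effects (multiplicative lognormal on compliance, resistance, tidal
#' volume target, respiratory rate and Edi amplitude; additive on the
#' dependent fraction and esophageal offset). Deterministic given the
#' config seed.
#'
#' @param config a [sim_config()].
#' @param emit_frames build 32 x 32 frame stacks instead of ROI traces
#'   (memory-heavy; default FALSE).
#' @return list of acquisitions, each a list with `waveforms`, `eit`,
#'   `truth` and `meta` (`animal`, `peep`, `phase`, `step`).
#' @export
generate_protocol_dataset <- function(config = sim_config(),
                                      emit_frames = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ladder <- config$peep_ladder
  peak_at <- which.max(ladder)
  phases <- ifelse(seq_along(ladder) <= peak_at, "incremental", "decremental")
  sdv <- config$animal_sd
  out <- vector("list", config$n_animals * length(ladder))
  idx <- 0L
  for (a in seq_len(config$n_animals)) {
    re <- list(c_lung = rlnorm(1, 0, sdv$c_lung),
               vt = rlnorm(1, 0, sdv$vt),
               rr = rlnorm(1, 0, sdv$rr),
               r_aw = rlnorm(1, 0, sdv$r_aw),
               edi = rlnorm(1, 0, sdv$edi),
               dfv = rnorm(1, 0, sdv$dfv),
               eso = rnorm(1, 0, sdv$eso))
    for (s in seq_along(ladder)) {
      p <- step_params(config, ladder[s], re)
      acq <- simulate_breath_dynamics(config, ladder[s], params = p)
      eit <- synthesize_eit(acq$truth$volume, config, ladder[s],
                            f_dep = p$f_dep, emit_frames = emit_frames)
      meta <- list(animal = a, peep = ladder[s], phase = phases[s], step = s)
      acq$waveforms$meta <- meta
      acq$truth$f_dep <- p$f_dep
      acq$truth$regional_volumes <- eit$regional_volumes
      idx <- idx + 1L
      out[[idx]] <- list(waveforms = acq$waveforms, eit = eit$eit,
                         truth = acq$truth, meta = meta)
    }
  }
  out
}
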