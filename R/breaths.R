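# Breath segmentation from the flow signal and tidal volume by flow
# integration. Spontaneous breaths are delimited on flow alone:
# inspiration starts at a positive-going crossing of a small flow
# threshold sustained for a minimum duration (hysteresis against sensor
# noise at rapid rates), expiration starts at the subsequent
# negative-going zero crossing, and the breath ends where the next
# inspiration begins. Incomplete leading/trailing breaths are discarded.

#' Breath segment
#'
#' @param insp_start sample index of inspiration onset.
#' @param insp_end sample index of the start of expiration.
#' @param exp_end sample index of the end of the breath (= onset of the
#'   next inspiration).
#' @param sample_rate Hz.
#' @return object of class `breath_segment` with a `duration` in seconds.
#' @export
breath_segment <- function(insp_start, insp_end, exp_end, sample_rate) {
  if (!(insp_start < insp_end && insp_end < exp_end))
    stop_arg("invalid breath segment: need insp_start < insp_end < exp_end")
  structure(list(insp_start = as.integer(insp_start),
                 insp_end = as.integer(insp_end),
                 exp_end = as.integer(exp_end),
                 duration = (exp_end - insp_start) / sample_rate,
                 sample_rate = sample_rate),
            class = "breath_segment")
}

#' Detect breaths in a continuous flow signal
#'
#' @param flow airway flow, L/s, inspiration positive.
#' @param sample_rate Hz.
#' @param flow_threshold onset threshold, L/s (default 0.02).
#' @param min_insp_duration minimum time flow must stay above threshold
#'   for a crossing to count as an inspiration onset, seconds
#'   (default 0.08).
#' @return list of [breath_segment()]s, time ordered and non-overlapping;
#'   empty list when no complete breath is found.
#' @export
detect_breaths <- function(flow, sample_rate, flow_threshold = 0.02,
                           min_insp_duration = 0.08) {
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop_arg("sample_rate must be a positive scalar")
  n <- length(flow)
  if (n / sample_rate < 2) stop_arg("flow series must cover at least 2 s")
  above <- flow >= flow_threshold
  onset_cand <- which(above & !c(TRUE, above[-n])) # positive-going crossings
  min_run <- max(1L, ceiling(min_insp_duration * sample_rate))
  sustained <- vapply(onset_cand, function(i) {
    j <- min(n, i + min_run - 1L)
    all(above[i:j]) && (i + min_run - 1L) <= n
  }, logical(1))
  onsets <- onset_cand[sustained]
  segs <- list()
  prev_end <- 0L
  for (k in seq_along(onsets)) {
    i0 <- onsets[k]
    if (i0 <= prev_end) next
    nxt <- onsets[onsets > i0 + min_run]
    if (length(nxt) == 0L) break # trailing incomplete breath discarded
    i2 <- nxt[1]
    neg <- which(flow[(i0 + 1L):(i2 - 1L)] < 0)
    if (length(neg) == 0L) next # no expiratory phase before next onset
    i1 <- i0 + neg[1]
    segs[[length(segs) + 1L]] <- breath_segment(i0, i1, i2, sample_rate)
    prev_end <- i2 - 1L
  }
  segs
}

#' Tidal volumes by trapezoidal flow integration
#'
#' Integrates flow over one breath: the positive lobe gives the inspired
#' volume, the magnitude of the negative lobe the expired volume, and the
#' running integral (zeroed at inspiration onset) gives the volume
#' waveform used by the mechanics fit.
#'
#' @param flow full flow series, L/s.
#' @param segment a [breath_segment()].
#' @param sample_rate Hz.
#' @return list with `vt_insp` (ml), `vt_exp` (ml) and `volume_series`
#'   (ml, one value per sample from `insp_start` to `exp_end`).
#' @export
integrate_volume <- function(flow, segment, sample_rate) {
  i0 <- segment$insp_start; i2 <- segment$exp_end
  if (i0 < 1L || i2 > length(flow))
    stop_arg("index error: segment [%d, %d] outside flow series of length %d",
             i0, i2, length(flow))
  dt <- 1 / sample_rate
  f <- flow[i0:i2]
  list(vt_insp = 1000 * trapz(pmax(f, 0), dt),
       vt_exp  = 1000 * trapz(-pmin(f, 0), dt),
       volume_series = 1000 * cumtrapz(f, dt))
}

#' Per-breath flow and pressure summary
#'
#' Maximum airway flow and maximum airway pressure over the inspiratory
#' phase, plus the instantaneous respiratory rate from the full cycle
#' duration.
#'
#' @param record a [waveform_record()].
#' @param segment a [breath_segment()].
#' @return list with `vt_insp`, `vt_exp` (ml), `peak_flow` (L/s),
#'   `peak_p_ao` (cmH2O) and `rr_inst` (breaths/min).
#' @export
breath_metrics <- function(record, segment) {
  insp <- segment$insp_start:segment$insp_end
  vols <- integrate_volume(record$flow, segment, record$sample_rate)
  list(vt_insp = vols$vt_insp, vt_exp = vols$vt_exp,
       peak_flow = max(record$flow[insp]),
       peak_p_ao = max(record$p_ao[insp]),
       rr_inst = 60 / segment$duration)
}

#' Select the analyzed breaths of an acquisition
#'
#' Keeps the first `n` complete breaths of the recording window (the
#' convention used for 1-minute steady-state acquisitions); warns when
#' fewer are available.
#'
#' @param segments list of [breath_segment()]s from [detect_breaths()].
#' @param n number of breaths to keep (default 3).
#' @return list of at most `n` segments.
#' @export
select_breaths <- function(segments, n = 3) {
  if (n < 1) stop_arg("n must be >= 1")
  if (length(segments) < n)
    warning(sprintf("only %d complete breaths available (requested %d)",
                    length(segments), n), call. = FALSE)
  segments[seq_len(min(n, length(segments)))]
}
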