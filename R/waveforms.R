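# Containers and I/O for ventilator waveforms and EIT sequences.
#
# Waveforms live in a `waveform_record`: airway-opening, esophageal and
# gastric pressure (cmH2O) plus airway flow (L/s, inspiration positive),
# uniformly sampled (default 200 Hz). Diaphragm electrical activity (Edi)
# is carried at its native rate (default 100 Hz) with its own timestamps
# and is never resampled implicitly. EIT sequences carry either a 32 x 32
# relative-impedance frame stack or pre-reduced 4-ROI mean-Z traces at a
# default 50 Hz.

ROI_NAMES <- c("anterior", "mid_anterior", "mid_posterior", "posterior")

#' Multichannel respiratory waveform record
#'
#' Validated container for one acquisition of synchronized airway
#' pressure, esophageal pressure, gastric pressure and airway flow,
#' with optional Edi at its own (typically lower) sampling rate.
#'
#' @param p_ao airway-opening pressure, cmH2O.
#' @param p_eso esophageal pressure, cmH2O.
#' @param flow airway flow, L/s, inspiratory positive.
#' @param p_ga gastric pressure, cmH2O (carried, not used by the
#'   analysis); defaults to zeros.
#' @param time sample times in seconds; defaults to a uniform grid at
#'   `sample_rate` starting at 0.
#' @param sample_rate sampling frequency, Hz (default 200).
#' @param edi optional diaphragm electrical activity, uV.
#' @param edi_time timestamps for `edi`, seconds; defaults to a uniform
#'   grid at `edi_rate`.
#' @param edi_rate Edi sampling frequency, Hz (default 100).
#' @param meta named list of pass-through metadata (animal id, PEEP in
#'   cmH2O, protocol phase "incremental"/"decremental", FiO2, blood gas
#'   annotations, ...).
#' @return an object of class `waveform_record`.
#' @export
waveform_record <- function(p_ao, p_eso, flow, p_ga = NULL, time = NULL,
                            sample_rate = 200, edi = NULL, edi_time = NULL,
                            edi_rate = 100, meta = list()) {
  n <- length(p_ao)
  if (n < 2L) stop_arg("waveform record needs at least 2 samples, got %d", n)
  if (!is.numeric(sample_rate) || sample_rate <= 0)
    stop_arg("sample_rate must be > 0")
  if (is.null(time)) time <- (seq_len(n) - 1L) / sample_rate
  if (is.null(p_ga)) p_ga <- numeric(n)
  for (ch in list(p_eso = p_eso, p_ga = p_ga, flow = flow, time = time)) {
    if (length(ch) != n)
      stop_arg("all channels must have the same length as p_ao (%d)", n)
  }
  check_uniform_time(time)
  if (!is.null(edi)) {
    if (is.null(edi_time)) edi_time <- (seq_along(edi) - 1L) / edi_rate
    if (length(edi_time) != length(edi))
      stop_arg("edi and edi_time must have the same length")
  }
  structure(
    list(time = as.numeric(time), p_ao = as.numeric(p_ao),
         p_eso = as.numeric(p_eso), p_ga = as.numeric(p_ga),
         flow = as.numeric(flow), edi = edi, edi_time = edi_time,
         sample_rate = sample_rate, edi_rate = edi_rate, meta = meta),
    class = "waveform_record")
}

# time must be strictly increasing and uniform to 1 part in 1e6
check_uniform_time <- function(time) {
  dt <- diff(time)
  if (any(dt <= 0))
    stop_arg("sampling error: time is not strictly increasing (first violation at sample %d)",
             which(dt <= 0)[1] + 1L)
  dev <- max(abs(dt - dt[1])) / dt[1]
  if (dev > 1e-6)
    stop_arg("sampling error: non-uniform time grid, max relative deviation %.3g", dev)
  invisible(TRUE)
}

#' @export
print.waveform_record <- function(x, ...) {
  dur <- x$time[length(x$time)] - x$time[1]
  cat(sprintf("<waveform_record> %d samples @ %g Hz (%.1f s)%s\n",
              length(x$time), x$sample_rate, dur,
              if (is.null(x$edi)) "" else sprintf(", Edi @ %g Hz", x$edi_rate)))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# unit conversion factors to cmH2O and L/s
.pressure_factor <- c(cmH2O = 1, mbar = 1.0197162, hPa = 1.0197162,
                      kPa = 10.197162)
.flow_factor <- c("L/s" = 1, "L/min" = 1 / 60, "mL/s" = 1e-3)

#' Read a waveform CSV with a named-column schema
#'
#' Reads a delimited text file of synchronized waveform channels. The
#' schema maps the record's field names to the file's column names so
#' arbitrary acquisition-software exports can be ingested. A JSON sidecar
#' (same path with extension `.json`) holding metadata (animal id, PEEP,
#' phase, sample rate) is read if present; an Edi file `<stem>_edi.csv`
#' (columns `time,edi`) is read if present.
#'
#' @param path CSV file path.
#' @param schema named character vector mapping fields `time`, `p_ao`,
#'   `p_eso`, `flow` (and optionally `p_ga`) to column names in the file.
#' @param pressure_units units of the pressure columns in the file:
#'   `"cmH2O"` (default), `"mbar"`, `"hPa"` or `"kPa"`; converted on load.
#' @param flow_units units of the flow column: `"L/s"` (default),
#'   `"L/min"` or `"mL/s"`.
#' @param flow_sign `"insp_pos"` (default) or `"insp_neg"`; flow is
#'   normalized to inspiration-positive on load.
#' @param sample_rate sampling frequency if no sidecar declares one;
#'   `NULL` (default) infers it from the time column.
#' @param meta extra metadata merged over the sidecar's.
#' @return a [waveform_record()].
#' @export
read_waveforms <- function(path,
                           schema = c(time = "time", p_ao = "p_ao",
                                      p_eso = "p_eso", p_ga = "p_ga",
                                      flow = "flow"),
                           pressure_units = "cmH2O", flow_units = "L/s",
                           flow_sign = c("insp_pos", "insp_neg"),
                           sample_rate = NULL, meta = list()) {
  if (!file.exists(path)) stop_arg("file not found: %s", path)
  flow_sign <- match.arg(flow_sign)
  dat <- read.csv(path, check.names = FALSE)
  if (nrow(dat) < 2L) stop_arg("waveform file must contain at least 2 samples")
  required <- c("time", "p_ao", "p_eso", "flow")
  for (f in required) {
    if (is.na(schema[f]) || is.null(schema[f]))
      stop_arg("schema error: no column declared for field '%s'", f)
    if (!schema[[f]] %in% names(dat))
      stop_arg("schema error: declared column '%s' (field '%s') missing from %s",
               schema[[f]], f, basename(path))
  }
  pf <- .pressure_factor[[match.arg(pressure_units, names(.pressure_factor))]]
  ff <- .flow_factor[[match.arg(flow_units, names(.flow_factor))]]
  time <- dat[[schema[["time"]]]]
  p_ga <- if (!is.na(schema["p_ga"]) && schema[["p_ga"]] %in% names(dat))
    dat[[schema[["p_ga"]]]] * pf else NULL
  flow <- dat[[schema[["flow"]]]] * ff
  if (flow_sign == "insp_neg") flow <- -flow

  side <- paste0(tools::file_path_sans_ext(path), ".json")
  smeta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
           else list()
  sr <- sample_rate
  if (is.null(sr)) sr <- smeta$sample_rate
  if (is.null(sr)) sr <- 1 / stats::median(diff(time))
  smeta$sample_rate <- NULL
  edi <- edi_time <- NULL
  edi_path <- paste0(tools::file_path_sans_ext(path), "_edi.csv")
  edi_rate <- 100
  if (file.exists(edi_path)) {
    ed <- read.csv(edi_path)
    edi <- ed$edi; edi_time <- ed$time
    if (length(edi_time) > 1L) edi_rate <- 1 / stats::median(diff(edi_time))
  }
  m <- utils::modifyList(as.list(smeta), as.list(meta))
  waveform_record(p_ao = dat[[schema[["p_ao"]]]] * pf,
                  p_eso = dat[[schema[["p_eso"]]]] * pf,
                  flow = flow, p_ga = p_ga, time = time, sample_rate = sr,
                  edi = edi, edi_time = edi_time, edi_rate = edi_rate,
                  meta = m)
}

#' Write a waveform record as CSV plus JSON sidecar
#'
#' Inverse of [read_waveforms()]: channels to `<path>`, metadata and
#' sample rate to `<stem>.json`, Edi (if present) to `<stem>_edi.csv`.
#'
#' @param record a [waveform_record()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_waveforms <- function(record, path) {
  stopifnot(inherits(record, "waveform_record"))
  dat <- data.frame(time = record$time, p_ao = record$p_ao,
                    p_eso = record$p_eso, p_ga = record$p_ga,
                    flow = record$flow)
  write.csv(format(dat, digits = 15, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  side <- c(list(sample_rate = record$sample_rate), record$meta)
  jsonlite::write_json(side, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(record$edi)) {
    ed <- data.frame(time = record$edi_time, edi = record$edi)
    write.csv(format(ed, digits = 15, trim = TRUE, scientific = FALSE),
              paste0(tools::file_path_sans_ext(path), "_edi.csv"),
              row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' EIT sequence container
#'
#' Holds either a stack of 32 x 32 relative-impedance frames (`frames`,
#' array `[32, 32, T]`, image row 1 = anterior/ventral) or pre-reduced
#' 4-ROI mean-Z traces (`roi_traces`, `T x 4` matrix with columns
#' anterior, mid_anterior, mid_posterior, posterior). Exactly one of the
#' two must be supplied; ROI traces are always derivable from frames via
#' [roi_mean_series()].
#'
#' @param frames numeric array `[32, 32, T]` of relative impedance
#'   (arbitrary units, relative to a device-set zero), or `NULL`.
#' @param roi_traces `T x 4` numeric matrix of per-ROI mean Z, or `NULL`.
#' @param time frame times in seconds; defaults to a uniform grid at
#'   `frame_rate`.
#' @param frame_rate frames per second (default 50).
#' @param lung_mask optional logical 32 x 32 pixel-inclusion mask applied
#'   before ROI means.
#' @return an object of class `eit_sequence`.
#' @export
eit_sequence <- function(frames = NULL, roi_traces = NULL, time = NULL,
                         frame_rate = 50, lung_mask = NULL) {
  if (is.null(frames) == is.null(roi_traces))
    stop_arg("exactly one of frames/roi_traces must be supplied")
  if (!is.numeric(frame_rate) || frame_rate <= 0)
    stop_arg("frame_rate must be > 0")
  if (!is.null(frames)) {
    d <- dim(frames)
    if (length(d) != 3L || d[1] != 32L || d[2] != 32L)
      stop_arg("format error: expected 32x32 frame grid, got %s",
               paste(d, collapse = "x"))
    nt <- d[3]
  } else {
    roi_traces <- as.matrix(roi_traces)
    if (ncol(roi_traces) != 4L)
      stop_arg("format error: roi_traces must have 4 columns (got %d)",
               ncol(roi_traces))
    colnames(roi_traces) <- ROI_NAMES
    nt <- nrow(roi_traces)
  }
  if (is.null(time)) time <- (seq_len(nt) - 1L) / frame_rate
  if (length(time) != nt)
    stop_arg("time must have one entry per frame (%d != %d)", length(time), nt)
  if (!is.null(lung_mask)) {
    lung_mask <- matrix(as.logical(lung_mask), 32, 32)
  }
  structure(list(frames = frames, roi_traces = roi_traces,
                 time = as.numeric(time), frame_rate = frame_rate,
                 lung_mask = lung_mask),
            class = "eit_sequence")
}

#' @export
print.eit_sequence <- function(x, ...) {
  nt <- length(x$time)
  cat(sprintf("<eit_sequence> %d frames @ %g Hz (%.1f s), %s%s\n",
              nt, x$frame_rate, nt / x$frame_rate,
              if (is.null(x$frames)) "4-ROI traces" else "32x32 frame stack",
              if (is.null(x$lung_mask)) "" else ", masked"))
  invisible(x)
}

#' Read an EIT sequence from delimited text
#'
#' Two layouts are recognised by the header: a 4-ROI trace table
#' (columns `time, anterior, mid_anterior, mid_posterior, posterior`)
#' or a wide frame table (`time` plus 1024 pixel columns `px0001` ...
#' `px1024`, row-major from the anterior image row). Frame stacks of any
#' other grid size are rejected.
#'
#' @param path CSV path.
#' @param frame_rate declared frame rate used when the file has no time
#'   column; default 50 Hz.
#' @return an [eit_sequence()].
#' @export
read_eit <- function(path, frame_rate = 50) {
  if (!file.exists(path)) stop_arg("file not found: %s", path)
  dat <- read.csv(path, check.names = FALSE)
  cols <- setdiff(names(dat), "time")
  time <- if ("time" %in% names(dat)) dat$time else NULL
  if (!is.null(time) && length(time) > 1L)
    frame_rate <- 1 / stats::median(diff(time))
  if (all(ROI_NAMES %in% cols)) {
    return(eit_sequence(roi_traces = as.matrix(dat[ROI_NAMES]), time = time,
                        frame_rate = frame_rate))
  }
  px <- grep("^px[0-9]+$", cols, value = TRUE)
  if (length(px) == 0L)
    stop_arg("format error: %s has neither 4-ROI trace columns nor pixel columns",
             basename(path))
  if (length(px) != 1024L)
    stop_arg("format error: expected 32x32 grid (1024 pixel columns), got %d",
             length(px))
  px <- px[order(as.integer(sub("^px", "", px)))]
  nt <- nrow(dat)
  frames <- aperm(array(t(as.matrix(dat[px])), dim = c(32L, 32L, nt)),
                  c(2L, 1L, 3L)) # file is row-major per frame
  eit_sequence(frames = frames, time = time, frame_rate = frame_rate)
}

#' Write an EIT sequence as delimited text
#'
#' @param eit an [eit_sequence()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_eit <- function(eit, path) {
  stopifnot(inherits(eit, "eit_sequence"))
  if (!is.null(eit$roi_traces)) {
    dat <- data.frame(time = eit$time, eit$roi_traces, check.names = FALSE)
  } else {
    nt <- length(eit$time)
    flat <- t(apply(eit$frames, 3L, function(fr) as.vector(t(fr))))
    colnames(flat) <- sprintf("px%04d", 1:1024)
    dat <- data.frame(time = eit$time, flat, check.names = FALSE)
  }
  write.csv(format(dat, digits = 15, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Place waveforms and EIT on a common timeline
#'
#' Either applies a declared clock offset (default 0 s: simultaneous
#' acquisition) or estimates the offset by scanning frame-period lags for
#' the maximum Pearson correlation between the global EIT signal (mean Z
#' over ROIs or pixels) and the tidal volume obtained by integrating the
#' flow signal.
#'
#' @param waveforms a [waveform_record()].
#' @param eit an [eit_sequence()].
#' @param method `"declared-offset"` (default) or `"cross-correlation"`.
#' @param offset declared offset in seconds added to the EIT clock
#'   (ignored for cross-correlation).
#' @param max_lag half-width of the lag scan, seconds (default 2).
#' @return an object of class `aligned_acquisition`: list with elements
#'   `waveforms`, `eit` and `offset` (seconds added to the EIT clock).
#' @export
align_acquisition <- function(waveforms, eit,
                              method = c("declared-offset", "cross-correlation"),
                              offset = 0, max_lag = 2) {
  stopifnot(inherits(waveforms, "waveform_record"), inherits(eit, "eit_sequence"))
  method <- match.arg(method)
  dur_w <- diff(range(waveforms$time))
  dur_e <- diff(range(eit$time))
  if (dur_w < 5 || dur_e < 5)
    stop_arg("alignment requires at least 5 s of both streams")
  if (method == "cross-correlation") {
    z <- global_z(eit)
    vol <- cumtrapz(waveforms$flow, 1 / waveforms$sample_rate) * 1000
    lags <- seq(-max_lag, max_lag, by = 1 / eit$frame_rate)
    score <- vapply(lags, function(l) {
      tw <- eit$time + l
      keep <- tw >= waveforms$time[1] & tw <= waveforms$time[length(waveforms$time)]
      if (sum(keep) < 10L) return(NA_real_)
      v <- approx(waveforms$time, vol, xout = tw[keep])$y
      suppressWarnings(cor(z[keep], v))
    }, numeric(1))
    if (all(is.na(score))) stop_arg("alignment error: no usable overlap in lag scan")
    offset <- lags[which.max(score)]
  }
  span <- min(waveforms$time[length(waveforms$time)],
              max(eit$time) + offset) -
          max(waveforms$time[1], min(eit$time) + offset)
  if (span <= 0)
    stop_arg("alignment error: no overlap between streams at offset %.3f s", offset)
  structure(list(waveforms = waveforms, eit = eit, offset = offset),
            class = "aligned_acquisition")
}

# mean Z over the whole (masked) image / over ROIs
global_z <- function(eit) {
  if (!is.null(eit$roi_traces)) return(rowMeans(eit$roi_traces))
  if (is.null(eit$lung_mask)) {
    apply(eit$frames, 3L, mean)
  } else {
    apply(eit$frames, 3L, function(fr) mean(fr[eit$lung_mask]))
  }
}

#' @export
print.aligned_acquisition <- function(x, ...) {
  cat(sprintf("<aligned_acquisition> offset %.3f s\n", x$offset))
  print(x$waveforms); print(x$eit)
  invisible(x)
}
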