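# Four-ROI reduction of EIT sequences, tidal impedance change, the
# proportional distribution of tidal volume and the dependent fraction of
# ventilation (DFV).
#
# The 32 x 32 image is split into four equal horizontal bands ordered
# anterior (ventral) to posterior (dorsal): anterior, mid-anterior,
# mid-posterior, posterior. Per breath, the end-expiratory and
# end-inspiratory frames are located on the global Z signal; the tidal
# impedance change dZ of each ROI is the difference of its mean Z between
# those two frames, and the proportional distribution is each ROI's dZ as
# a percentage of the total. DFV is the share of the two posterior
# (dependent, in supine) ROIs: 100 * dZ_dependent / dZ_total. DFV = 50%
# marks an antero-posteriorly homogeneous distribution, which is the PEEP
# selection criterion.

#' ROI partition of the EIT image
#'
#' @param bands list of 4 integer vectors of image rows (1 = anterior),
#'   ordered anterior to posterior; default four equal bands 1-8, 9-16,
#'   17-24, 25-32.
#' @param lung_mask optional logical 32 x 32 pixel mask applied before
#'   band means.
#' @return object of class `roi_partition`.
#' @export
roi_partition <- function(bands = list(1:8, 9:16, 17:24, 25:32),
                          lung_mask = NULL) {
  if (length(bands) != 4L) stop_arg("partition needs exactly 4 bands")
  rows <- unlist(bands)
  if (anyDuplicated(rows)) stop_arg("partition bands must be disjoint")
  if (is.unsorted(rows)) stop_arg("bands must be ordered anterior to posterior")
  if (!is.null(lung_mask)) lung_mask <- matrix(as.logical(lung_mask), 32, 32)
  structure(list(bands = bands, lung_mask = lung_mask),
            class = "roi_partition")
}

#' Per-ROI mean-Z time series
#'
#' Reduces a frame stack to the four ROI mean-Z traces (mean over the
#' masked pixels of each band, per frame). A sequence already holding ROI
#' traces is passed through unchanged.
#'
#' @param eit an [eit_sequence()].
#' @param partition a [roi_partition()]; the sequence's own `lung_mask`
#'   is used when the partition declares none.
#' @return `T x 4` matrix with columns anterior, mid_anterior,
#'   mid_posterior, posterior.
#' @export
roi_mean_series <- function(eit, partition = roi_partition()) {
  stopifnot(inherits(eit, "eit_sequence"))
  if (!is.null(eit$roi_traces)) return(eit$roi_traces)
  mask <- partition$lung_mask
  if (is.null(mask)) mask <- eit$lung_mask
  if (is.null(mask)) mask <- matrix(TRUE, 32, 32)
  nt <- dim(eit$frames)[3]
  out <- matrix(NA_real_, nt, 4, dimnames = list(NULL, ROI_NAMES))
  for (r in 1:4) {
    band_mask <- matrix(FALSE, 32, 32)
    band_mask[partition$bands[[r]], ] <- TRUE
    band_mask <- band_mask & mask
    if (!any(band_mask))
      stop_arg("partition error: band '%s' is empty after masking", ROI_NAMES[r])
    idx <- which(band_mask)
    out[, r] <- apply(eit$frames, 3L, function(fr) mean(fr[idx]))
  }
  out
}

#' Locate the end-expiratory and end-inspiratory frames of a breath
#'
#' End-expiration is the global-Z minimum within a +/- `search_window`
#' second window around the (flow-defined) inspiration-onset frame; end-
#' inspiration is the global-Z maximum within the breath.
#'
#' @param global_z global mean-Z series (one value per frame).
#' @param onset_frame frame index of inspiration onset.
#' @param end_frame frame index of the end of the breath.
#' @param frame_rate Hz.
#' @param search_window seconds (default 0.2), reconciling the 50 Hz EIT
#'   clock with the 200 Hz flow timing.
#' @return list with `end_exp_frame` and `end_insp_frame`.
#' @export
tidal_frames <- function(global_z, onset_frame, end_frame, frame_rate,
                         search_window = 0.2) {
  nt <- length(global_z)
  if (onset_frame < 1L || end_frame > nt || end_frame <= onset_frame)
    stop_arg("coverage error: breath frames [%d, %d] not covered by EIT (%d frames)",
             onset_frame, end_frame, nt)
  if (end_frame - onset_frame + 1L < 3L)
    stop_arg("coverage error: breath window shorter than 3 frames")
  hw <- max(1L, round(search_window * frame_rate))
  w0 <- max(1L, onset_frame - hw):min(nt, onset_frame + hw)
  end_exp <- w0[which.min(global_z[w0])]
  w1 <- max(end_exp + 1L, onset_frame):end_frame
  end_insp <- w1[which.max(global_z[w1])]
  list(end_exp_frame = end_exp, end_insp_frame = end_insp)
}

#' Tidal impedance change and proportional distribution for one breath
#'
#' @param roi_series `T x 4` ROI mean-Z matrix (see [roi_mean_series()]).
#' @param end_exp_frame,end_insp_frame frame indices from
#'   [tidal_frames()]; end-expiration must precede end-inspiration.
#' @return object of class `regional_tidal`: `dz` (4 values, AU),
#'   `dz_total`, `proportions` (% of total, 4 values), `nondependent_pct`
#'   (anterior + mid-anterior), `dependent_pct` (mid-posterior +
#'   posterior), `dfv` (%), the two frame indices, and `paradoxical`
#'   (TRUE when any regional dz is negative; values are reported, not
#'   clamped).
#' @export
regional_tidal <- function(roi_series, end_exp_frame, end_insp_frame) {
  if (end_exp_frame >= end_insp_frame)
    stop_arg("end_exp_frame must precede end_insp_frame")
  roi_series <- as.matrix(roi_series)
  dz <- roi_series[end_insp_frame, ] - roi_series[end_exp_frame, ]
  names(dz) <- ROI_NAMES
  total <- sum(dz)
  if (total <= 0)
    stop_arg("degenerate-breath error: total tidal impedance change %.4g <= 0",
             total)
  prop <- 100 * dz / total
  structure(list(dz = dz, dz_total = total, proportions = prop,
                 nondependent_pct = sum(prop[1:2]),
                 dependent_pct = sum(prop[3:4]),
                 dfv = sum(prop[3:4]),
                 end_exp_frame = end_exp_frame,
                 end_insp_frame = end_insp_frame,
                 paradoxical = any(dz < 0)),
            class = "regional_tidal")
}

#' @export
print.regional_tidal <- function(x, ...) {
  cat("<regional_tidal>\n")
  tab <- rbind(dz = x$dz, `% of total` = round_half_up(x$proportions))
  print(tab)
  cat(sprintf("  non-dependent %g%%, dependent %g%% (DFV %.1f%%)%s\n",
              round_half_up(x$nondependent_pct),
              round_half_up(x$dependent_pct), x$dfv,
              if (x$paradoxical) " [paradoxical regional dz]" else ""))
  invisible(x)
}

#' Dependent fraction of ventilation
#'
#' `DFV (%) = 100 * dZ(dependent region) / dZ(whole lung)`, the share of
#' the tidal impedance change occurring in the two most posterior ROIs.
#'
#' @param dz numeric vector of 4 regional tidal impedance changes,
#'   ordered anterior to posterior.
#' @return DFV in percent.
#' @export
dependent_fraction <- function(dz) {
  if (length(dz) != 4L) stop_arg("dz must have 4 regional values")
  total <- sum(dz)
  if (total <= 0)
    stop_arg("degenerate-breath error: total tidal impedance change %.4g <= 0",
             total)
  100 * (dz[3] + dz[4]) / total
}

#' DFV-guided PEEP selection
#'
#' Selects the PEEP level whose dependent fraction of ventilation is
#' nearest 50% (antero-posterior homogeneity); ties go to the lower PEEP.
#'
#' @param dfv_by_peep named numeric vector or list mapping PEEP (cmH2O)
#'   to DFV (%); names are the PEEP levels.
#' @return selected PEEP, cmH2O.
#' @export
titrate_peep <- function(dfv_by_peep) {
  dfv <- unlist(dfv_by_peep)
  if (length(dfv) < 2L)
    stop_arg("titration needs at least 2 PEEP levels (got %d)", length(dfv))
  peep <- suppressWarnings(as.numeric(names(dfv)))
  if (anyNA(peep)) stop_arg("dfv_by_peep must be named by PEEP level")
  o <- order(peep)
  peep <- peep[o]; dfv <- dfv[o]
  dist <- abs(dfv - 50)
  peep[which.min(dist)] # which.min takes the first minimum = lowest PEEP
}

#' Dependent minus non-dependent distribution difference
#'
#' Signed difference in percentage points between dependent and
#' non-dependent proportional tidal volume distribution per PEEP step.
#' Negative values mean predominantly non-dependent ventilation, zero
#' marks antero-posterior homogeneity, positive values predominantly
#' dependent ventilation.
#'
#' @param dependent_pct,nondependent_pct numeric vectors (one value per
#'   PEEP step).
#' @return `dependent_pct - nondependent_pct`, percentage points.
#' @export
distribution_difference <- function(dependent_pct, nondependent_pct) {
  if (length(dependent_pct) != length(nondependent_pct))
    stop_arg("dependent and non-dependent vectors must have equal length")
  dependent_pct - nondependent_pct
}
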