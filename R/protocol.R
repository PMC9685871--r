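# Orchestration of a full PEEP-ladder experiment:
# acquisition -> breath segmentation -> mechanics -> EIT reduction ->
# per-step aggregation -> statistics -> DFV-guided PEEP selection.
#
# Per acquisition the first `n_breaths` complete breaths are analyzed.
# A breath failing any stage (rejected mechanics fit, degenerate tidal
# impedance change, missing EIT coverage) is excluded from all per-step
# aggregates with a logged reason; incremental and decremental phases
# are never pooled.

#' Write one acquisition (waveforms + EIT) to a directory
#'
#' Emits `<id>_waveforms.csv` (+ `.json` sidecar, `_edi.csv`) and
#' `<id>_eit.csv`, the pair layout consumed by [run_protocol()].
#'
#' @param waveforms a [waveform_record()] (its `meta` is written to the
#'   sidecar).
#' @param eit an [eit_sequence()].
#' @param dir output directory (created if needed).
#' @param id acquisition identifier used as the file stem.
#' @return the file stem, invisibly.
#' @export
write_acquisition <- function(waveforms, eit, dir, id) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_waveforms(waveforms, file.path(dir, paste0(id, "_waveforms.csv")))
  write_eit(eit, file.path(dir, paste0(id, "_eit.csv")))
  invisible(file.path(dir, id))
}

# discover matched waveform/EIT pairs in a directory
acquisition_manifest <- function(dir) {
  wf <- list.files(dir, pattern = "_waveforms\\.csv$")
  et <- list.files(dir, pattern = "_eit\\.csv$")
  ids_w <- sub("_waveforms\\.csv$", "", wf)
  ids_e <- sub("_eit\\.csv$", "", et)
  orphans <- c(setdiff(ids_w, ids_e), setdiff(ids_e, ids_w))
  if (length(union(ids_w, ids_e)) == 0L)
    stop_arg("manifest error: no acquisitions found in %s", dir)
  if (length(orphans) > 0L)
    stop_arg("manifest error: unmatched acquisitions: %s",
             paste(sort(orphans), collapse = ", "))
  sort(ids_w)
}

#' Run the full protocol analysis
#'
#' `x` is either a directory of matched `<id>_waveforms.csv` /
#' `<id>_eit.csv` pairs (see [write_acquisition()]) or a list of
#' in-memory acquisitions as produced by [generate_protocol_dataset()]
#' (elements with `waveforms`, `eit` and a `meta` holding `animal`,
#' `peep`, `phase`).
#'
#' @param x directory path or acquisition list.
#' @param n_breaths breaths analyzed per acquisition (default 3, the
#'   first three complete breaths).
#' @param flow_threshold,min_insp_duration breath-detection settings
#'   (see [detect_breaths()]).
#' @param partition a [roi_partition()].
#' @param alpha family-wise significance level (default 0.05).
#' @param family_size Bonferroni family size; default `NULL` uses the
#'   number of unordered PEEP-level pairs.
#' @param fit_window `"breath"` or `"inspiration"` (see [fit_eom()]).
#' @return object of class `protocol_result`: `per_breath` data frame,
#'   `per_step` mean/SD aggregates by PEEP and phase, `comparisons`
#'   (routed paired tests of DFV between incremental PEEP levels, with
#'   Bonferroni threshold), `titration` (selected PEEP and the DFV
#'   table), `exclusions` data frame, and `counts`.
#' @export
run_protocol <- function(x, n_breaths = 3, flow_threshold = 0.02,
                         min_insp_duration = 0.08,
                         partition = roi_partition(), alpha = 0.05,
                         family_size = NULL, fit_window = "breath") {
  acqs <- if (is.character(x)) {
    ids <- acquisition_manifest(x)
    lapply(ids, function(id) {
      wf <- read_waveforms(file.path(x, paste0(id, "_waveforms.csv")))
      et <- read_eit(file.path(x, paste0(id, "_eit.csv")))
      list(waveforms = wf, eit = et, meta = wf$meta, id = id)
    })
  } else x
  rows <- list(); excl <- list()
  detected_total <- 0L
  for (k in seq_along(acqs)) {
    acq <- acqs[[k]]
    meta <- acq$meta
    if (is.null(meta)) meta <- acq$waveforms$meta
    id <- if (!is.null(acq$id)) acq$id
          else sprintf("a%02d_s%02d", meta$animal,
                       if (!is.null(meta$step)) meta$step else k)
    res <- analyze_acquisition(acq$waveforms, acq$eit, meta, id,
                               n_breaths = n_breaths,
                               flow_threshold = flow_threshold,
                               min_insp_duration = min_insp_duration,
                               partition = partition,
                               fit_window = fit_window)
    detected_total <- detected_total + res$n_detected
    rows <- c(rows, res$rows)
    excl <- c(excl, res$exclusions)
  }
  per_breath <- do.call(rbind, lapply(rows, as.data.frame))
  exclusions <- if (length(excl)) do.call(rbind, lapply(excl, as.data.frame))
                else data.frame(id = character(), breath = integer(),
                                stage = character(), reason = character())
  if (is.null(per_breath) || nrow(per_breath) == 0L)
    stop_arg("no analyzable breaths in the input")
  per_step <- summarize_steps(per_breath)
  peeps <- sort(unique(per_breath$peep))
  m <- if (is.null(family_size)) choose(length(peeps), 2) else family_size
  thr <- bonferroni_threshold(alpha, max(1, m))
  comparisons <- dfv_comparisons(per_breath, thr)
  inc <- per_step[per_step$phase == "incremental", ]
  if (nrow(inc) == 0L) inc <- per_step
  titr_tab <- stats::setNames(inc$dfv_mean, inc$peep)
  titration <- list(
    selected_peep = if (length(titr_tab) >= 2L) titrate_peep(titr_tab)
                    else NA_real_,
    dfv_by_peep = titr_tab)
  structure(list(per_breath = per_breath, per_step = per_step,
                 comparisons = comparisons, titration = titration,
                 exclusions = exclusions,
                 counts = list(detected = detected_total,
                               analyzed = nrow(per_breath),
                               selected = nrow(per_breath) + nrow(exclusions),
                               excluded = nrow(exclusions),
                               eit_scans = 2L * nrow(per_breath)),
                 alpha = alpha, family_size = m,
                 alpha_adjusted = thr),
            class = "protocol_result")
}

# one acquisition: segment, select, per-breath mechanics + EIT reduction
analyze_acquisition <- function(wf, eit, meta, id, n_breaths, flow_threshold,
                                min_insp_duration, partition, fit_window) {
  segs <- detect_breaths(wf$flow, wf$sample_rate, flow_threshold,
                         min_insp_duration)
  n_detected <- length(segs)
  segs <- suppressWarnings(select_breaths(segs, n_breaths))
  roi <- roi_mean_series(eit, partition)
  gz <- rowMeans(roi)
  rows <- list(); excl <- list()
  add_excl <- function(b, stage, msg)
    excl[[length(excl) + 1L]] <<- list(id = id, breath = b, stage = stage,
                                       reason = msg)
  for (b in seq_along(segs)) {
    seg <- segs[[b]]
    met <- breath_metrics(wf, seg)
    vols <- integrate_volume(wf$flow, seg, wf$sample_rate)
    p_tp <- transpulmonary(wf$p_ao, wf$p_eso)
    span <- seg$insp_start:seg$exp_end
    fit <- tryCatch(
      fit_eom(p_tp[span], wf$flow[span], vols$volume_series,
              window = fit_window,
              insp_end = seg$insp_end - seg$insp_start + 1L),
      error = function(e) e)
    if (inherits(fit, "error")) { add_excl(b, "mechanics", conditionMessage(fit)); next }
    if (fit$rejected) { add_excl(b, "mechanics", "non-positive compliance coefficient"); next }
    ptp <- ptp_max_summary(wf$p_ao, wf$p_eso, p_tp, wf$flow, seg,
                           resistance_rrs = coef(fit)[["resistance"]])
    # map sample indices to frame indices on the common timeline
    onset_f <- nearest_frame(wf$time[seg$insp_start], eit)
    end_f <- nearest_frame(wf$time[seg$exp_end], eit)
    reg <- tryCatch({
      tf <- tidal_frames(gz, onset_f, end_f, eit$frame_rate)
      regional_tidal(roi, tf$end_exp_frame, tf$end_insp_frame)
    }, error = function(e) e)
    if (inherits(reg, "error")) { add_excl(b, "eit", conditionMessage(reg)); next }
    rows[[length(rows) + 1L]] <- list(
      id = id,
      animal = meta$animal %||% NA_integer_,
      peep = meta$peep %||% NA_real_,
      phase = meta$phase %||% NA_character_,
      breath = b,
      vt_insp = met$vt_insp, vt_exp = met$vt_exp,
      peak_flow = met$peak_flow, peak_p_ao = met$peak_p_ao,
      rr_inst = met$rr_inst,
      compliance = coef(fit)[["compliance"]],
      resistance = coef(fit)[["resistance"]],
      p0 = coef(fit)[["p0"]], fit_r2 = fit$r.squared,
      delta_peso = ptp$delta_peso, p_tp_max = ptp$p_tp_max,
      p_tp_true_max = ptp$p_tp_true_max,
      prop_anterior = reg$proportions[[1]],
      prop_mid_anterior = reg$proportions[[2]],
      prop_mid_posterior = reg$proportions[[3]],
      prop_posterior = reg$proportions[[4]],
      nondependent_pct = reg$nondependent_pct,
      dependent_pct = reg$dependent_pct,
      dfv = reg$dfv,
      dz_total = reg$dz_total,
      paradoxical = reg$paradoxical)
  }
  list(rows = rows, exclusions = excl, n_detected = n_detected)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

nearest_frame <- function(t, eit, offset = 0) {
  f <- which.min(abs(eit$time + offset - t))
  as.integer(f)
}

# per-breath proportions averaged per PEEP x phase (mean-of-ratios)
summarize_steps <- function(pb) {
  key <- interaction(pb$peep, pb$phase, drop = TRUE)
  vars <- c("vt_insp", "rr_inst", "peak_p_ao", "p_tp_true_max", "compliance",
            "prop_anterior", "prop_mid_anterior", "prop_mid_posterior",
            "prop_posterior", "nondependent_pct", "dependent_pct", "dfv")
  agg <- lapply(split(pb, key), function(d) {
    row <- data.frame(peep = d$peep[1], phase = d$phase[1],
                      n_breaths = nrow(d), n_animals = length(unique(d$animal)))
    for (v in vars) {
      row[[paste0(v, "_mean")]] <- mean(d[[v]])
      row[[paste0(v, "_sd")]] <- sd(d[[v]])
    }
    row
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$phase, out$peep), ]
  rownames(out) <- NULL
  out
}

# routed paired comparisons of DFV between incremental PEEP levels,
# paired by animal (animal means)
dfv_comparisons <- function(pb, alpha_adjusted) {
  inc <- pb[pb$phase %in% c(NA, "incremental") | is.na(pb$phase), ]
  if (nrow(inc) == 0L) inc <- pb
  am <- stats::aggregate(dfv ~ animal + peep, data = inc, FUN = mean)
  peeps <- sort(unique(am$peep))
  out <- list()
  for (i in seq_along(peeps)) for (j in seq_along(peeps)) {
    if (j <= i) next
    a <- am[am$peep == peeps[i], c("animal", "dfv")]
    b <- am[am$peep == peeps[j], c("animal", "dfv")]
    m <- merge(a, b, by = "animal")
    if (nrow(m) < 3L) next
    cmp <- tryCatch(
      compare_samples(m$dfv.x, m$dfv.y, paired = TRUE,
                      alpha_adjusted = alpha_adjusted,
                      on_constant = "nonparametric"),
      error = function(e) NULL)
    if (is.null(cmp)) next
    out[[length(out) + 1L]] <- data.frame(
      peep_a = peeps[i], peep_b = peeps[j], test = cmp$test_name,
      statistic = cmp$statistic, p_value = cmp$p_value, n = cmp$n,
      alpha_adjusted = cmp$alpha_adjusted, significant = cmp$significant)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(peep_a = numeric(), peep_b = numeric(), test = character(),
               statistic = numeric(), p_value = numeric(), n = integer(),
               alpha_adjusted = numeric(), significant = logical())
}

#' @export
print.protocol_result <- function(x, ...) {
  cat("<protocol_result>\n")
  cat(sprintf("  breaths: %d detected, %d analyzed, %d excluded; %d EIT scans\n",
              x$counts$detected, x$counts$analyzed, x$counts$excluded,
              x$counts$eit_scans))
  cat(sprintf("  Bonferroni: alpha %.3g / %d comparisons -> threshold %.4g\n",
              x$alpha, x$family_size, x$alpha_adjusted))
  cat(sprintf("  DFV-guided PEEP selection: %g cmH2O\n",
              x$titration$selected_peep))
  invisible(x)
}

#' @export
summary.protocol_result <- function(object, ...) {
  print(object)
  inc <- object$per_step[object$per_step$phase == "incremental", ]
  cat("\nIncremental ladder (mean per step):\n")
  print(data.frame(peep = inc$peep,
                   vt_ml = round(inc$vt_insp_mean, 1),
                   rr = round(inc$rr_inst_mean, 1),
                   c_ml_cmH2O = round(inc$compliance_mean, 1),
                   ptp_true_max = round(inc$p_tp_true_max_mean, 1),
                   dfv_pct = round(inc$dfv_mean, 1)),
        row.names = FALSE)
  invisible(object)
}

#' Write the report files of a protocol analysis
#'
#' Emits CSV tables: per-breath values, per-step summaries, pairwise
#' comparisons, the DFV titration table (with the selected PEEP), the
#' exclusion ledger, plot-ready distribution data (proportions per ROI
#' and dependent/non-dependent difference per PEEP step), and a JSON
#' manifest of counts and settings.
#'
#' @param result a `protocol_result` from [run_protocol()].
#' @param out_dir output directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
write_report <- function(result, out_dir) {
  stopifnot(inherits(result, "protocol_result"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- c(
    per_breath = file.path(out_dir, "per_breath.csv"),
    per_step = file.path(out_dir, "per_step.csv"),
    comparisons = file.path(out_dir, "comparisons.csv"),
    titration = file.path(out_dir, "titration.csv"),
    exclusions = file.path(out_dir, "exclusions.csv"),
    distribution = file.path(out_dir, "distribution_by_peep.csv"),
    manifest = file.path(out_dir, "manifest.json"))
  write.csv(result$per_breath, paths["per_breath"], row.names = FALSE)
  write.csv(result$per_step, paths["per_step"], row.names = FALSE)
  write.csv(result$comparisons, paths["comparisons"], row.names = FALSE)
  titr <- data.frame(peep = as.numeric(names(result$titration$dfv_by_peep)),
                     dfv = unname(result$titration$dfv_by_peep))
  titr$selected <- titr$peep == result$titration$selected_peep
  write.csv(titr, paths["titration"], row.names = FALSE)
  write.csv(result$exclusions, paths["exclusions"], row.names = FALSE)
  ps <- result$per_step
  dist <- data.frame(peep = ps$peep, phase = ps$phase,
                     anterior = ps$prop_anterior_mean,
                     mid_anterior = ps$prop_mid_anterior_mean,
                     mid_posterior = ps$prop_mid_posterior_mean,
                     posterior = ps$prop_posterior_mean,
                     nondependent = ps$nondependent_pct_mean,
                     dependent = ps$dependent_pct_mean,
                     dfv = ps$dfv_mean,
                     dep_minus_nondep = distribution_difference(
                       ps$dependent_pct_mean, ps$nondependent_pct_mean))
  write.csv(dist, paths["distribution"], row.names = FALSE)
  jsonlite::write_json(
    c(result$counts,
      list(alpha = result$alpha, family_size = result$family_size,
           alpha_adjusted = result$alpha_adjusted,
           selected_peep = result$titration$selected_peep)),
    paths["manifest"], auto_unbox = TRUE, digits = NA)
  invisible(unname(paths))
}
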