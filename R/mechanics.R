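# Per-breath respiratory mechanics.
#
# Transpulmonary pressure is the elementwise difference between airway
# and esophageal pressure. Compliance and resistance are estimated per
# breath by ordinary least squares on the single-compartment equation of
# motion,
#
#   P_TP(t) = V(t)/C + R * V'(t) + P0,
#
# fitted over the whole breath (no inspiratory hold is assumed anywhere:
# the animals breathe continuously). The maximum transpulmonary pressure
# is corrected for the resistive pressure drop to yield the "true"
# maximum distending pressure at the alveoli:
#
#   P_TP,true max = (P_AO - dP_ESO)_at TP max - R * V'_at TP max
#
# where dP_ESO is esophageal pressure at the moment of maximum P_TP minus
# esophageal pressure at end-expiration.

#' Transpulmonary pressure series
#'
#' @param p_ao airway-opening pressure, cmH2O.
#' @param p_eso esophageal pressure, cmH2O.
#' @return `p_ao - p_eso`, elementwise.
#' @export
transpulmonary <- function(p_ao, p_eso) {
  if (length(p_ao) != length(p_eso))
    stop_arg("p_ao and p_eso must have the same length (%d vs %d)",
             length(p_ao), length(p_eso))
  p_ao - p_eso
}

#' Fit the equation of motion to one breath
#'
#' Multilinear (ordinary least squares) fit of transpulmonary pressure on
#' volume and flow over one breath, returning compliance, resistance and
#' the end-expiratory pressure intercept as a classed model object.
#' Volume enters the regression in litres so the resistance coefficient
#' is in cmH2O.s/L; compliance is reported in ml/cmH2O.
#'
#' @param p_tp transpulmonary pressure over the breath, cmH2O.
#' @param flow airway flow over the breath, L/s.
#' @param volume volume above end-expiration over the breath, ml, zeroed
#'   at inspiration onset (from [integrate_volume()]).
#' @param window `"breath"` (default) fits the full cycle; the samples
#'   passed in are used as-is, so pass inspiration-only slices for
#'   `"inspiration"` semantics via `insp_end`.
#' @param insp_end optional index (within the breath vectors) of the end
#'   of inspiration; used when `window = "inspiration"`.
#' @return an object of class `eom_fit` with components `coefficients`
#'   (`compliance` ml/cmH2O, `resistance` cmH2O.s/L, `p0` cmH2O),
#'   `r.squared`, `fitted.values`, `residuals`, `rejected` (TRUE when the
#'   volume coefficient is not positive), `data` and `n`.
#' @export
fit_eom <- function(p_tp, flow, volume, window = c("breath", "inspiration"),
                    insp_end = NULL) {
  window <- match.arg(window)
  n <- length(p_tp)
  if (length(flow) != n || length(volume) != n)
    stop_arg("p_tp, flow and volume must have equal length")
  if (window == "inspiration") {
    if (is.null(insp_end)) stop_arg("window = 'inspiration' needs insp_end")
    keep <- seq_len(insp_end)
  } else keep <- seq_len(n)
  if (length(keep) < 10L)
    stop_arg("breath too short for mechanics fit (%d samples, need >= 10)",
             length(keep))
  y <- p_tp[keep]
  X <- cbind(intercept = 1, v_l = volume[keep] / 1000, flow = flow[keep])
  qrX <- qr(X)
  if (qrX$rank < 3L)
    stop_arg("conditioning error: rank-deficient design (flow and volume are collinear)")
  beta <- qr.coef(qrX, y)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_
  rejected <- beta[["v_l"]] <= 0
  cf <- c(compliance = if (beta[["v_l"]] > 0) 1000 / beta[["v_l"]] else NA_real_,
          resistance = beta[["flow"]],
          p0 = beta[["intercept"]])
  structure(list(coefficients = cf, elastance_l = beta[["v_l"]],
                 r.squared = r2, fitted.values = fitted, residuals = res,
                 rejected = rejected, n = length(keep), window = window,
                 data = list(p_tp = y, flow = flow[keep], volume = volume[keep])),
            class = "eom_fit")
}

#' @export
print.eom_fit <- function(x, digits = 4, ...) {
  cat("Equation-of-motion fit (P_TP = V/C + R*V' + P0)\n")
  cat(sprintf("  C  = %s ml/cmH2O\n  R  = %s cmH2O.s/L\n  P0 = %s cmH2O\n",
              format(x$coefficients[["compliance"]], digits = digits),
              format(x$coefficients[["resistance"]], digits = digits),
              format(x$coefficients[["p0"]], digits = digits)))
  cat(sprintf("  R^2 = %s on %d samples (%s window)%s\n",
              format(x$r.squared, digits = digits), x$n, x$window,
              if (x$rejected) " [REJECTED: non-positive compliance]" else ""))
  invisible(x)
}

#' @export
coef.eom_fit <- function(object, ...) object$coefficients

#' @export
residuals.eom_fit <- function(object, ...) object$residuals

#' @export
fitted.eom_fit <- function(object, ...) object$fitted.values

#' @export
predict.eom_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  cf <- object$coefficients
  cf[["p0"]] + object$elastance_l * newdata$volume / 1000 +
    cf[["resistance"]] * newdata$flow
}

#' @export
summary.eom_fit <- function(object, ...) {
  out <- list(coefficients = object$coefficients,
              r.squared = object$r.squared,
              sigma = sqrt(sum(object$residuals^2) / max(1, object$n - 3)),
              n = object$n, rejected = object$rejected)
  class(out) <- "summary.eom_fit"
  out
}

#' @export
print.summary.eom_fit <- function(x, digits = 4, ...) {
  cat("Equation-of-motion fit summary\n")
  print(round(x$coefficients, digits))
  cat(sprintf("R^2 = %s, residual SD = %s cmH2O, n = %d%s\n",
              format(x$r.squared, digits = digits),
              format(x$sigma, digits = digits), x$n,
              if (x$rejected) " [REJECTED]" else ""))
  invisible(x)
}

#' @export
plot.eom_fit <- function(x, ...) {
  op <- par(mfrow = c(1, 2)); on.exit(par(op))
  t_idx <- seq_along(x$data$p_tp)
  plot(t_idx, x$data$p_tp, type = "l", xlab = "sample",
       ylab = "P_TP (cmH2O)", main = "observed vs fitted", ...)
  lines(t_idx, x$fitted.values, lty = 2)
  legend("topright", legend = c("observed", "fitted"), lty = 1:2, bty = "n")
  plot(x$fitted.values, x$residuals, xlab = "fitted (cmH2O)",
       ylab = "residual (cmH2O)", main = "residuals")
  abline(h = 0, lty = 3)
  invisible(x)
}

#' Maximum transpulmonary pressure, esophageal swing, and resistive
#' correction
#'
#' Locates the maximum of transpulmonary pressure within a breath,
#' computes the esophageal pressure swing relative to end-expiration, the
#' maximum transpulmonary pressure referenced to end-expiratory
#' esophageal pressure, and its resistive-corrected value.
#'
#' @param p_ao,p_eso,p_tp,flow full-length channel series (cmH2O, cmH2O,
#'   cmH2O, L/s).
#' @param segment a [breath_segment()].
#' @param end_exp_idx sample index taken as end-expiration for this
#'   breath; defaults to the last sample before inspiration onset (or the
#'   onset itself for the first breath of a record).
#' @param resistance_rrs resistance from the same breath's [fit_eom()],
#'   cmH2O.s/L.
#' @return list with `delta_peso`, `p_tp_max`, `p_tp_true_max` (cmH2O),
#'   `idx_tp_max` (sample index) and `flow_at_tp_max` (L/s).
#' @export
ptp_max_summary <- function(p_ao, p_eso, p_tp, flow, segment,
                            end_exp_idx = NULL, resistance_rrs) {
  i0 <- segment$insp_start; i2 <- segment$exp_end
  if (is.null(end_exp_idx)) end_exp_idx <- max(1L, i0 - 1L)
  if (end_exp_idx < i0 - ceiling(segment$duration * segment$sample_rate) ||
      end_exp_idx > i2)
    stop_arg("end_exp_idx %d outside the neighborhood of breath [%d, %d]",
             end_exp_idx, i0, i2)
  win <- i0:i2
  idx <- win[which.max(p_tp[win])]
  delta_peso <- p_eso[idx] - p_eso[end_exp_idx]
  p_tp_max <- p_ao[idx] - delta_peso
  f_at <- flow[idx]
  list(delta_peso = delta_peso,
       p_tp_max = p_tp_max,
       p_tp_true_max = p_tp_max - resistance_rrs * f_at,
       idx_tp_max = idx,
       flow_at_tp_max = f_at)
}
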