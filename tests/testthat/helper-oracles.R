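# Independent oracles and small fixture builders used across the suite.

# Explicit normal-equation least squares for P = V/C + R*flow + P0:
# the brute-force reference the package's QR-based fit is checked against.
oracle_eom_fit <- function(p_tp, flow, volume_ml) {
  X <- cbind(1, volume_ml / 1000, flow)
  beta <- solve(t(X) %*% X, t(X) %*% p_tp)
  c(p0 = beta[1], compliance = 1000 / beta[2], resistance = beta[3])
}

# Exhaustive sign-enumeration two-sided p for the Wilcoxon signed-rank
# statistic: loops over all 2^n sign assignments of the ranked |d|.
oracle_wilcoxon_exact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  lo <- mean(w_all <= w_obs + 1e-9)
  hi <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(lo, hi))
}

# A noise-free synthetic breath obeying the equation of motion exactly:
# half-sine inspiratory flow, exponential expiratory flow scaled so the
# breath returns to baseline volume.
make_eom_breath <- function(c_ml = 20, r = 10, p0 = 2, ti = 0.8, te = 1.2,
                            amp = 0.5, rate = 200, noise_sd = 0) {
  t_i <- seq(0, ti, by = 1 / rate)
  t_e <- seq(1 / rate, te, by = 1 / rate)
  insp <- amp * sin(pi * t_i / ti)
  vt <- sum((insp[-1] + insp[-length(insp)]) / 2) / rate
  exp_shape <- exp(-(t_e - t_e[1]) / 0.25)
  exp_int <- sum((exp_shape[-1] + exp_shape[-length(exp_shape)]) / 2) / rate
  flow <- c(insp, -vt / exp_int * exp_shape)
  n <- length(flow)
  volume <- c(0, cumsum((flow[-1] + flow[-n]) / 2 / rate)) * 1000
  p_tp <- volume / c_ml + r * flow + p0
  if (noise_sd > 0) p_tp <- p_tp + rnorm(n, 0, noise_sd)
  list(p_tp = p_tp, flow = flow, volume = volume, rate = rate)
}

# Map a waveform time to the nearest EIT frame index.
frame_of <- function(t, eit) which.min(abs(eit$time - t))

# Small simulated cohort shared by pipeline tests.
small_cohort <- function(seed = 42, n_animals = 2, duration = 20) {
  generate_protocol_dataset(sim_config(seed = seed, n_animals = n_animals,
                                       duration = duration))
}
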