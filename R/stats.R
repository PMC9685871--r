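# Statistical battery for the PEEP protocol: Shapiro-Wilk normality
# routing between parametric and nonparametric tests, an exact Wilcoxon
# signed-rank test (full sign-enumeration distribution for small n,
# tie-corrected normal approximation for large n), Mann-Whitney and
# t-tests via stats, Bonferroni alpha adjustment, and ordinary linear
# regression of a response on PEEP.

#' Choose the test for a comparison by normality routing
#'
#' Runs Shapiro-Wilk on each sample (on the paired differences for
#' paired data). Any rejection at `alpha_normality` routes to the
#' nonparametric test (Wilcoxon signed-rank when paired, Mann-Whitney
#' otherwise); otherwise the t-test is used.
#'
#' @param sample_a,sample_b numeric vectors (equal length when paired).
#' @param paired logical.
#' @param alpha_normality significance level of the normality screen
#'   (default 0.05).
#' @param on_constant `"error"` (default) or `"nonparametric"`: policy
#'   for zero-variance input, on which Shapiro-Wilk is undefined.
#' @return one of `"t-paired"`, `"t-unpaired"`, `"wilcoxon-signed-rank"`,
#'   `"mann-whitney"`.
#' @export
route_test <- function(sample_a, sample_b, paired = TRUE,
                       alpha_normality = 0.05,
                       on_constant = c("error", "nonparametric")) {
  on_constant <- match.arg(on_constant)
  if (length(sample_a) < 3L || length(sample_b) < 3L)
    stop_arg("routing error: need at least 3 observations per sample")
  if (paired && length(sample_a) != length(sample_b))
    stop_arg("paired samples must have equal length")
  mats <- if (paired) list(sample_a - sample_b) else list(sample_a, sample_b)
  normal <- TRUE
  for (m in mats) {
    if (sd(m) == 0) {
      if (on_constant == "error")
        stop_arg("routing error: constant sample, normality test undefined")
      normal <- FALSE
      next
    }
    if (shapiro.test(m)$p.value <= alpha_normality) normal <- FALSE
  }
  if (normal) {
    if (paired) "t-paired" else "t-unpaired"
  } else {
    if (paired) "wilcoxon-signed-rank" else "mann-whitney"
  }
}

# Exact two-sided signed-rank p-value by convolution over all 2^n sign
# assignments. Ranks may be midranks (ties): work on the integer grid of
# doubled ranks. Returns P(W+ as or more extreme than w, two-sided).
signed_rank_exact_p <- function(ranks, w_plus) {
  r2 <- as.integer(round(2 * ranks))
  tot <- sum(r2)
  # distribution of 2*W+ over independent fair sign flips
  pmf <- numeric(tot + 1L) # support 0..tot
  pmf[1] <- 1
  for (r in r2) {
    shifted <- c(rep(0, r), pmf[seq_len(tot + 1L - r)])
    pmf <- (pmf + shifted) / 2
  }
  w2 <- as.integer(round(2 * w_plus))
  lo <- sum(pmf[seq_len(w2 + 1L)])              # P(2W <= w2)
  hi <- sum(pmf[(w2 + 1L):(tot + 1L)])          # P(2W >= w2)
  min(1, 2 * min(lo, hi))
}

#' Exact Wilcoxon signed-rank test
#'
#' Paired two-sided signed-rank test. Zero differences are dropped
#' (Wilcoxon's original treatment). The p-value is exact — computed from
#' the full sign-flip distribution of the rank sum, valid with tied
#' ranks — for `n <= exact_limit` non-zero differences, and a normal
#' approximation with tie correction and continuity correction otherwise.
#'
#' @param x,y paired numeric vectors.
#' @param mode `"auto"` (default; exact for n <= `exact_limit`),
#'   `"exact"`, or `"normal-approx"`.
#' @param exact_limit largest n for the exact distribution (default 25).
#' @param alpha nominal significance level before adjustment (default
#'   0.05).
#' @param alpha_adjusted significance threshold after multiplicity
#'   correction (default `alpha`; see [bonferroni_threshold()]).
#' @return object of class `comparison_result`: `test_name`, `statistic`
#'   (W+, the positive-rank sum), `p_value`, `n` (non-zero pairs),
#'   `alpha_adjusted`, `significant`.
#' @export
wilcoxon_signed_rank <- function(x, y, mode = c("auto", "exact", "normal-approx"),
                                 exact_limit = 25, alpha = 0.05,
                                 alpha_adjusted = alpha) {
  mode <- match.arg(mode)
  if (length(x) != length(y)) stop_arg("x and y must be paired (equal length)")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n < 1L)
    stop_arg("undefined-test error: all paired differences are zero")
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  use_exact <- mode == "exact" || (mode == "auto" && n <= exact_limit)
  if (use_exact) {
    p <- signed_rank_exact_p(r, w_plus)
    test <- "wilcoxon-signed-rank"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w_plus - mu - sign(w_plus - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    test <- "wilcoxon-signed-rank"
  }
  comparison_result(test, statistic = w_plus, p_value = p, n = n,
                    alpha_adjusted = alpha_adjusted)
}

#' Comparison result container
#'
#' @param test_name one of `"wilcoxon-signed-rank"`, `"mann-whitney"`,
#'   `"t-paired"`, `"t-unpaired"`.
#' @param statistic test statistic (W+, U, or t).
#' @param p_value two-sided p-value.
#' @param n number of pairs (paired tests) or total observations.
#' @param alpha_adjusted significance threshold after correction.
#' @return classed list; `significant` is `p_value <= alpha_adjusted`.
#' @export
comparison_result <- function(test_name, statistic, p_value, n,
                              alpha_adjusted = 0.05) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(list(test_name = test_name, statistic = unname(statistic),
                 p_value = p_value, n = n, alpha_adjusted = alpha_adjusted,
                 significant = p_value <= alpha_adjusted),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (threshold %.4g) -> %s, n = %d\n",
              x$test_name, x$statistic, x$p_value, x$alpha_adjusted,
              if (x$significant) "significant" else "not significant", x$n))
  invisible(x)
}

#' Run one routed comparison
#'
#' Applies [route_test()] and then the chosen test: [wilcoxon_signed_rank()]
#' for paired nonparametric, [stats::wilcox.test()] (Mann-Whitney) for
#' unpaired nonparametric, or [stats::t.test()].
#'
#' @inheritParams route_test
#' @param alpha_adjusted significance threshold after multiplicity
#'   correction.
#' @param force optional test name to bypass routing.
#' @return a [comparison_result()].
#' @export
compare_samples <- function(sample_a, sample_b, paired = TRUE,
                            alpha_normality = 0.05, alpha_adjusted = 0.05,
                            force = NULL,
                            on_constant = c("error", "nonparametric")) {
  test <- if (is.null(force))
    route_test(sample_a, sample_b, paired, alpha_normality,
               on_constant = match.arg(on_constant))
  else force
  switch(test,
    "wilcoxon-signed-rank" =
      wilcoxon_signed_rank(sample_a, sample_b, alpha_adjusted = alpha_adjusted),
    "mann-whitney" = {
      ht <- suppressWarnings(wilcox.test(sample_a, sample_b, paired = FALSE))
      comparison_result("mann-whitney", ht$statistic, ht$p.value,
                        length(sample_a) + length(sample_b), alpha_adjusted)
    },
    "t-paired" = {
      ht <- t.test(sample_a, sample_b, paired = TRUE)
      comparison_result("t-paired", ht$statistic, ht$p.value,
                        length(sample_a), alpha_adjusted)
    },
    "t-unpaired" = {
      ht <- t.test(sample_a, sample_b, paired = FALSE)
      comparison_result("t-unpaired", ht$statistic, ht$p.value,
                        length(sample_a) + length(sample_b), alpha_adjusted)
    },
    stop_arg("unknown test '%s'", test))
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha family-wise level (default 0.05).
#' @param m number of comparisons in the family. The PEEP-ladder default
#'   family is the 15 unordered pairs among six PEEP levels, giving the
#'   0.0033 threshold.
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (m < 1) stop_arg("m must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop_arg("alpha must be in (0, 1)")
  alpha / m
}

#' Linear regression of a response on PEEP
#'
#' Ordinary least squares of a response (e.g. regional tidal impedance
#' change or DFV) on PEEP level.
#'
#' @param peep PEEP levels, cmH2O.
#' @param response numeric response, same length.
#' @return list with `slope` (per cmH2O), `intercept`, `r_squared`.
#' @export
regress_on_peep <- function(peep, response) {
  if (length(peep) != length(response))
    stop_arg("peep and response must have equal length")
  if (length(unique(peep)) < 2L)
    stop_arg("degenerate-design error: need at least 2 distinct PEEP values")
  fit <- lm(response ~ peep)
  ss_tot <- sum((response - mean(response))^2)
  r2 <- if (ss_tot > 0) 1 - sum(residuals(fit)^2) / ss_tot else 0
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2)
}
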