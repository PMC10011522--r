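# Shared fixtures and independent oracles used across test files.

# Exact sign-flip (permutation) p-value for a paired test: enumerates all
# 2^n assignments of signs to the differences and compares |t| tails.
signflip_p <- function(d) {
  n <- length(d)
  stopifnot(n <= 16)
  tstat <- function(x) mean(x) / (sd(x) / sqrt(length(x)))
  t_obs <- abs(tstat(d))
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  t_all <- apply(signs, 1, function(s) tstat(d * s))
  mean(abs(t_all) >= t_obs - 1e-12)
}

# One-way ANOVA from first principles (sums of squares written out).
anova_bruteforce <- function(groups) {
  all_v <- unlist(groups)
  gm <- mean(all_v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 1))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  df1 <- length(groups) - 1
  df2 <- length(all_v) - length(groups)
  F <- (ssb / df1) / (ssw / df2)
  list(F = F, p = pf(F, df1, df2, lower.tail = FALSE))
}

# RM-ANOVA from first principles on a subjects x conditions matrix.
rm_anova_bruteforce <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  gm <- mean(mat)
  ss_cond <- n * sum((colMeans(mat) - gm)^2)
  ss_subj <- k * sum((rowMeans(mat) - gm)^2)
  ss_tot <- sum((mat - gm)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  F <- (ss_cond / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
  list(F = F, df1 = k - 1, df2 = (k - 1) * (n - 1))
}

# Numerical ellipsoid surface area by trapezoid quadrature of the exact
# area element in spherical parametrization.
ellipsoid_area_quadrature <- function(a, b, c0, n = 400) {
  th <- seq(0, pi, length.out = n + 1)
  ph <- seq(0, 2 * pi, length.out = 2 * n + 1)
  g <- outer(th, ph, function(th, ph) {
    st <- sin(th); ct <- cos(th)
    sqrt((b * c0 * st^2 * cos(ph))^2 + (a * c0 * st^2 * sin(ph))^2 +
         (a * b * st * ct)^2)
  })
  w1 <- rep(1, n + 1); w1[c(1, n + 1)] <- 0.5
  w2 <- rep(1, 2 * n + 1); w2[c(1, 2 * n + 1)] <- 0.5
  sum((w1 %o% w2) * g) * (pi / n) * (2 * pi / (2 * n))
}

# Small cohort whose sessions hold a good number of events: used for the
# detection-performance checks. Returns pooled match statistics.
detection_batch <- function(seed, n_per_group = 6, session_hours = 0.2,
                            det = detector_config()) {
  cfg <- cohort_config(
    session_hours = session_hours, sessions_per_period = 1,
    n_per_group = n_per_group,
    event_rate_mean = c("PHT+FUS" = 600, "PHT_ONLY" = 600, "FUS_ONLY" = 600),
    seed = seed)
  truth <- simulate_cohort_truth(cfg)
  n_t <- 0; n_d <- 0; n_m <- 0; berr <- c(); durs <- c()
  for (a in truth$animals$animal_id) for (p in c("pre", "post")) {
    rec <- render_session(truth, cfg, a, p, 1)
    ev <- detect_events(rec, det)
    tr <- truth$events[truth$events$animal_id == a &
                       truth$events$period == p &
                       !truth$events$is_subthreshold, ]
    mm <- match_events(tr, ev)
    n_t <- n_t + mm$summary$n_truth
    n_d <- n_d + mm$summary$n_detected
    n_m <- n_m + nrow(mm$matches)
    berr <- c(berr, abs(mm$matches$boundary_error_start_s),
              abs(mm$matches$boundary_error_end_s))
    durs <- c(durs, ev$duration_s)
  }
  list(sensitivity = n_m / n_t, fdr = (n_d - n_m) / n_d, n_truth = n_t,
       n_detected = n_d, boundary_errors = berr, detected_durations = durs)
}

# Sine-wave record helper.
sine_record <- function(freq, amplitude, duration = 10, fs = 500) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  eeg_record(amplitude * sin(2 * pi * freq * t), fs)
}
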