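# Synthetic EEG generator: background spectrum, ictal waveforms, cohort truth.

test_that("background trace honours length, scale and determinism contracts", {
  x <- generate_background(10, 500, 50, seed = 1)
  expect_length(x, 5000)
  expect_true(abs(sqrt(mean(x^2)) - 50) <= 2.5)        # within 5% of target
  expect_identical(x, generate_background(10, 500, 50, seed = 1))
  expect_false(identical(x, generate_background(10, 500, 50, seed = 2)))
  expect_identical(generate_background(10, 500, 0, seed = 3), numeric(5000))
  expect_error(generate_background(-1, 500, 50), "duration")
  expect_error(generate_background(10, -5, 50), "sampling_rate")
})

test_that("background PSD falls as 1/f over 1-50 Hz", {
  x <- generate_background(60, 500, 50, seed = 7)
  ps <- spec.pgram(ts(x, frequency = 500), spans = c(31, 31), taper = 0.1,
                   plot = FALSE)
  sel <- ps$freq >= 1 & ps$freq <= 50
  slope <- unname(coef(lm(log10(ps$spec[sel]) ~ log10(ps$freq[sel])))[2])
  expect_true(abs(slope - (-1)) <= 0.3)
})

test_that("ictal waveform has the right length, transient count, peak and spectrum", {
  w <- synth_ictal_waveform(5, 10, 400, 500)
  expect_length(w, 2500)
  expect_equal(attr(w, "n_transients"), 50)
  expect_equal(max(abs(w)), 400)
  spec <- Mod(fft(as.numeric(w)))
  freqs <- (seq_along(spec) - 1) / 5            # Hz, 5 s record
  half <- seq_len(length(spec) %/% 2)
  peak_freq <- freqs[half][which.max(spec[half])]
  expect_true(abs(peak_freq - 10) <= 1)

  w3 <- synth_ictal_waveform(3, 2, 100, 500)    # minimum ictal duration
  expect_length(w3, 1500)
  expect_equal(attr(w3, "n_transients"), 6)

  expect_identical(as.numeric(synth_ictal_waveform(5, 10, 0, 500)),
                   numeric(2500))
  expect_error(synth_ictal_waveform(5, 25, 100, 500), "rep_freq")
  expect_silent(synth_ictal_waveform(1, 25, 100, 500, ictal = FALSE))
})

test_that("spectral peak sits at the repetition frequency across the ictal band", {
  for (f0 in c(2, 5, 12, 20)) {
    w <- as.numeric(synth_ictal_waveform(6, f0, 100, 500))
    spec <- Mod(fft(w))
    freqs <- (seq_along(spec) - 1) / 6
    half <- seq_len(length(spec) %/% 2)
    expect_true(abs(freqs[half][which.max(spec[half])] - f0) <= 1)
  }
})

test_that("cohort truth is deterministic and structurally sound", {
  cfg <- cohort_config(session_hours = 0.25, sessions_per_period = 2,
                       n_per_group = 3, seed = 11)
  tr1 <- simulate_cohort_truth(cfg)
  tr2 <- simulate_cohort_truth(cfg)
  expect_identical(tr1, tr2)
  expect_equal(nrow(tr1$animals), 9)
  ev <- tr1$events
  # ictal events all >= 3 s, artifacts all < 3 s: the perfect-detector
  # conservation rule is exact by construction
  expect_true(all(ev$duration_s[!ev$is_subthreshold] >= 3))
  expect_true(all(ev$duration_s[ev$is_subthreshold] < 3))
  expect_true(all(ev$rep_freq_hz[!ev$is_subthreshold] >= 2 &
                  ev$rep_freq_hz[!ev$is_subthreshold] <= 20))
  # no overlap within any session
  by_sess <- split(ev, list(ev$animal_id, ev$period, ev$session), drop = TRUE)
  for (s in by_sess) {
    s <- s[order(s$start_s), ]
    if (nrow(s) > 1)
      expect_true(all(s$start_s[-1] >= (s$start_s + s$duration_s)[-nrow(s)]))
    expect_true(all(s$start_s >= 0))
    expect_true(all(s$start_s + s$duration_s <= cfg$session_hours * 3600))
  }
})

test_that("null intervention effects leave pooled post/pre counts near 1", {
  cfg <- cohort_config(
    session_hours = 1, sessions_per_period = 8, n_per_group = 12,
    effects = list("PHT+FUS" = intervention_effect(),
                   "PHT_ONLY" = intervention_effect(),
                   "FUS_ONLY" = intervention_effect()),
    seed = 21)
  tr <- simulate_cohort_truth(cfg)
  ev <- tr$events[!tr$events$is_subthreshold, ]
  pooled <- table(ev$period)
  expect_true(pooled[["post"]] / pooled[["pre"]] > 0.9)
  expect_true(pooled[["post"]] / pooled[["pre"]] < 1.1)
})

test_that("per-animal count ratios recover the configured rate multiplier", {
  cfg <- cohort_config(session_hours = 1, sessions_per_period = 8,
                       n_per_group = 40, seed = 31)
  tr <- simulate_cohort_truth(cfg)
  ev <- tr$events[!tr$events$is_subthreshold, ]
  ev$amplitude_uv <- ev$peak_amplitude_uv
  idx <- compute_indices(ev, 8, animals = tr$animals[c("animal_id", "group")])
  nrm <- suppressMessages(normalize_indices(idx))
  for (g in cfg$groups) {
    r <- nrm$count_ratio[nrm$group == g]
    r <- r[is.finite(r)]
    target <- cfg$effects[[g]]$rate_multiplier
    expect_true(abs(mean(r) - target) <= 2 * sd(r) / sqrt(length(r)) + 0.02,
                label = sprintf("count ratio for %s near %.2f", g, target))
  }
})

test_that("pre-period counts are strongly overdispersed (SD of order the mean)", {
  # population CV of the count mixture is ~0.9; the sample CV estimator is
  # heavy-tailed, so assert a floor per group and the target on the average
  cfg <- cohort_config(session_hours = 1, sessions_per_period = 8,
                       n_per_group = 100, seed = 41)
  tr <- simulate_cohort_truth(cfg)
  ev <- tr$events[!tr$events$is_subthreshold & tr$events$period == "pre", ]
  counts <- table(factor(ev$animal_id, levels = tr$animals$animal_id))
  cvs <- vapply(cfg$groups, function(g) {
    v <- as.numeric(counts[tr$animals$animal_id[tr$animals$group == g]])
    sd(v) / mean(v)
  }, numeric(1))
  expect_true(all(cvs >= 0.7))
  expect_gte(mean(cvs), 0.8)
})

test_that("planted duration moments match the truncated-lognormal target", {
  cfg <- cohort_config(session_hours = 1, sessions_per_period = 8,
                       n_per_group = 60, seed = 51)
  tr <- simulate_cohort_truth(cfg)
  pre <- tr$events[!tr$events$is_subthreshold & tr$events$period == "pre", ]
  # analytic mean of the >=3 s truncated lognormal
  mu <- cfg$duration_lognorm[["meanlog"]]; s <- cfg$duration_lognorm[["sdlog"]]
  z <- (log(3) - mu) / s
  m_target <- exp(mu + s^2 / 2) * pnorm(s - z) / pnorm(-z)
  expect_true(abs(mean(pre$duration_s) - m_target) <=
                3 * sd(pre$duration_s) / sqrt(nrow(pre)))
})

test_that("rendered sessions are deterministic and carry the planted events", {
  cfg <- cohort_config(session_hours = 0.1, sessions_per_period = 1,
                       n_per_group = 1, seed = 61,
                       event_rate_mean = c(600, 600, 600))
  tr <- simulate_cohort_truth(cfg)
  id <- tr$animals$animal_id[1]
  r1 <- render_session(tr, cfg, id, "pre", 1)
  r2 <- render_session(tr, cfg, id, "pre", 1)
  expect_identical(r1$samples, r2$samples)
  expect_equal(length(r1$samples), 0.1 * 3600 * 500)
})
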