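#' Intervention effect multipliers
#'
#' Post/pre multipliers applied by the cohort generator to the per-animal
#' ictal event rate, the mean event duration and the event amplitude.
#' `(1, 1, 1)` is the identity (null) effect.
#'
#' @param rate_multiplier Post/pre ictal-rate ratio (> 0).
#' @param duration_multiplier Multiplier on the mean event duration (> 0).
#' @param amplitude_multiplier Multiplier on event amplitudes (> 0).
#' @return An object of class `intervention_effect`.
#' @export
intervention_effect <- function(rate_multiplier = 1, duration_multiplier = 1,
                                amplitude_multiplier = 1) {
  assert_scalar_num(rate_multiplier, "rate_multiplier", 0, strict_lower = TRUE)
  assert_scalar_num(duration_multiplier, "duration_multiplier", 0,
                    strict_lower = TRUE)
  assert_scalar_num(amplitude_multiplier, "amplitude_multiplier", 0,
                    strict_lower = TRUE)
  structure(list(rate_multiplier = rate_multiplier,
                 duration_multiplier = duration_multiplier,
                 amplitude_multiplier = amplitude_multiplier),
            class = "intervention_effect")
}

default_effects <- function() {
  list(
    "PHT+FUS"  = intervention_effect(0.43, 0.85, 1.00),
    "PHT_ONLY" = intervention_effect(0.73, 1.22, 1.00),
    "FUS_ONLY" = intervention_effect(1.13, 1.20, 1.00)
  )
}

#' Synthetic chronic-mTLE cohort configuration
#'
#' Defines the study conditions emulated by the generator: a three-arm cohort
#' (combined drug + sonication, drug only, sonication only; n = 10 per arm),
#' one pre- and one post-intervention recording period split into sessions,
#' overdispersed per-animal ictal counts (between-animal SD of the order of
#' the mean), lognormal event durations with a 3 s ictal minimum, and
#' sub-3 s artifact bursts.
#'
#' Baseline 24 h event rates default to the group means reported for chronic
#' kainate-model animals (145, 89, 133 events/24 h) and the default
#' intervention effects are calibrated to the reported per-animal mean
#' changes (count -57%, -27%, +13%; duration -15%, +22%, +20%).
#'
#' @param groups Character vector of group labels.
#' @param n_per_group Animals per group (>= 1).
#' @param sessions_per_period Recording sessions per period.
#' @param session_hours Session length in hours (default 3; scale down for
#'   desk-size runs).
#' @param sampling_rate Sampling rate in Hz (>= 100; default 500, the
#'   acquisition hardware rate of 10 kHz remains configurable).
#' @param background_rms Inter-ictal background RMS amplitude, uV.
#' @param event_rate_mean Baseline ictal events per 24 h, either one value or
#'   one per group (named or in group order).
#' @param event_rate_dispersion Gamma shape of the between-animal rate
#'   mixture (negative-binomial size; 1 gives SD ~ mean).
#' @param rate_floor Minimum per-animal baseline rate as a fraction of the
#'   group mean (stabilizes per-animal post/pre ratios).
#' @param retention Fraction of the baseline event process that persists
#'   into the post period (the paired-design coupling); the remainder of the
#'   post-period rate is fresh events. 0 gives independent periods.
#' @param duration_lognorm `c(meanlog, sdlog)` of event durations in s,
#'   left-truncated at `min_ictal_s`.
#' @param min_ictal_s Minimum ictal duration in s (events below this are the
#'   artifact class).
#' @param event_snr Ratio of ictal waveform RMS to `background_rms`.
#' @param amplitude_jitter_sdlog Lognormal spread of per-event amplitude.
#' @param artifact_rate Sub-threshold artifact bursts per hour.
#' @param artifact_snr_fraction Artifact amplitude relative to ictal scale.
#' @param racine_weights Probabilities of Racine classes 1-5 per event.
#' @param effects Named list of [intervention_effect()] per group.
#' @param seed Integer seed; all generator output is a pure function of the
#'   configuration including this seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(groups = c("PHT+FUS", "PHT_ONLY", "FUS_ONLY"),
                          n_per_group = 10,
                          sessions_per_period = 8,
                          session_hours = 3,
                          sampling_rate = 500,
                          background_rms = 50,
                          event_rate_mean = c("PHT+FUS" = 145,
                                              "PHT_ONLY" = 89,
                                              "FUS_ONLY" = 133),
                          event_rate_dispersion = 1,
                          rate_floor = 0.1,
                          retention = 0.95,
                          duration_lognorm = c(meanlog = log(5.5), sdlog = 0.5),
                          min_ictal_s = 3,
                          event_snr = 8,
                          amplitude_jitter_sdlog = 0.25,
                          artifact_rate = 2,
                          artifact_snr_fraction = 0.5,
                          racine_weights = c(0.60, 0.37, 0.02, 0.007, 0.003),
                          effects = default_effects(),
                          seed = 1L) {
  stopifnot(length(groups) >= 1, !anyDuplicated(groups))
  assert_scalar_num(n_per_group, "n_per_group", lower = 1)
  assert_scalar_num(sessions_per_period, "sessions_per_period", lower = 1)
  assert_scalar_num(session_hours, "session_hours", 0, strict_lower = TRUE)
  assert_scalar_num(sampling_rate, "sampling_rate", lower = 100)
  assert_scalar_num(background_rms, "background_rms", lower = 0)
  assert_scalar_num(event_rate_dispersion, "event_rate_dispersion", 0,
                    strict_lower = TRUE)
  assert_scalar_num(rate_floor, "rate_floor", 0, 1)
  assert_scalar_num(retention, "retention", 0, 1)
  assert_scalar_num(event_snr, "event_snr", 0, strict_lower = TRUE)
  assert_scalar_num(artifact_rate, "artifact_rate", lower = 0)
  stopifnot(length(duration_lognorm) == 2, duration_lognorm[2] > 0,
            length(racine_weights) == 5, all(racine_weights >= 0))
  rates <- rep_len(as.numeric(event_rate_mean), length(groups))
  if (!is.null(names(event_rate_mean)) &&
      all(groups %in% names(event_rate_mean)))
    rates <- as.numeric(event_rate_mean[groups])
  if (any(rates < 0)) stop_invalid("event rates must be >= 0")
  if (!all(groups %in% names(effects)))
    stop_invalid("`effects` must name every group")
  structure(list(
    groups = groups, n_per_group = as.integer(n_per_group),
    sessions_per_period = as.integer(sessions_per_period),
    session_hours = session_hours, sampling_rate = sampling_rate,
    background_rms = background_rms,
    event_rate_mean = setNames(rates, groups),
    event_rate_dispersion = event_rate_dispersion, rate_floor = rate_floor,
    retention = retention,
    duration_lognorm = setNames(as.numeric(duration_lognorm),
                                c("meanlog", "sdlog")),
    min_ictal_s = min_ictal_s, event_snr = event_snr,
    amplitude_jitter_sdlog = amplitude_jitter_sdlog,
    artifact_rate = artifact_rate,
    artifact_snr_fraction = artifact_snr_fraction,
    racine_weights = racine_weights / sum(racine_weights),
    effects = effects[groups], seed = as.integer(seed)
  ), class = "cohort_config")
}

#' 1/f (pink) background EEG trace
#'
#' Gaussian noise shaped in the frequency domain to a power spectral density
#' proportional to 1/f (a standard approximation of inter-ictal background),
#' rescaled so the realized RMS equals `rms_uv` exactly.
#'
#' @param duration_s Trace length in seconds (> 0).
#' @param sampling_rate Sampling rate, Hz (> 0).
#' @param rms_uv Target RMS amplitude, uV (0 gives an all-zero trace).
#' @param seed Optional seed; identical arguments and seed give identical
#'   traces.
#' @return Numeric vector of `round(duration_s * sampling_rate)` samples (uV).
#' @examples
#' x <- generate_background(10, 500, 50, seed = 1)
#' sqrt(mean(x^2)) # 50
#' @export
generate_background <- function(duration_s, sampling_rate, rms_uv,
                                seed = NULL) {
  assert_scalar_num(duration_s, "duration_s", 0, strict_lower = TRUE)
  assert_scalar_num(sampling_rate, "sampling_rate", 0, strict_lower = TRUE)
  assert_scalar_num(rms_uv, "rms_uv", lower = 0)
  n <- round(duration_s * sampling_rate)
  if (n < 2) stop_invalid("trace too short (%d samples)", n)
  if (rms_uv == 0) return(numeric(n))
  with_seed(seed, {
    m <- n %/% 2
    amp <- 1 / sqrt(seq_len(m))          # |X(f)| ~ f^(-1/2)  =>  PSD ~ 1/f
    z <- complex(real = rnorm(m), imaginary = rnorm(m)) * amp
    spec <- complex(length.out = n)      # DC = 0
    spec[2:(m + 1)] <- z
    if (n %% 2 == 0) spec[m + 1] <- complex(real = Re(z[m]) * sqrt(2))
    spec[seq(n, m + 2)] <- Conj(z[seq_len(n - m - 1)])
    x <- Re(fft(spec, inverse = TRUE))
    x * (rms_uv / rms(x))
  })
}

#' Ictal sharp-wave train waveform
#'
#' A train of biphasic sharp transients (difference of two time-shifted
#' Gaussians) repeating at `rep_freq`, with raised-cosine onset/offset ramps
#' of at most 0.5 s, scaled to a given peak amplitude. The dominant spectral
#' peak sits at `rep_freq`.
#'
#' @param duration_s Event duration, s.
#' @param rep_freq Repetition frequency of the sharp waves, Hz, in `[2, 20]`
#'   for the ictal class.
#' @param peak_amplitude_uv Peak absolute amplitude, uV.
#' @param sampling_rate Sampling rate, Hz.
#' @param ictal If `FALSE` (artifact bursts) the `[2, 20]` Hz restriction on
#'   `rep_freq` is not enforced.
#' @return Numeric vector of `round(duration_s * sampling_rate)` samples with
#'   attribute `n_transients`.
#' @examples
#' w <- synth_ictal_waveform(5, 10, 400, 500)
#' attr(w, "n_transients") # 50
#' @export
synth_ictal_waveform <- function(duration_s, rep_freq, peak_amplitude_uv,
                                 sampling_rate, ictal = TRUE) {
  assert_scalar_num(duration_s, "duration_s", 0, strict_lower = TRUE)
  assert_scalar_num(peak_amplitude_uv, "peak_amplitude_uv", lower = 0)
  if (ictal && (rep_freq < 2 || rep_freq > 20))
    stop_invalid("ictal rep_freq must lie in [2, 20] Hz (got %g)", rep_freq)
  assert_scalar_num(rep_freq, "rep_freq", 0, strict_lower = TRUE)
  n <- round(duration_s * sampling_rate)
  t <- (seq_len(n) - 1) / sampling_rate
  period <- 1 / rep_freq
  sig <- period / 8                      # transient sharpness
  off <- period / 6                      # biphasic lobe separation / 2
  n_tr <- max(1L, round(duration_s * rep_freq))
  x <- numeric(n)
  for (k in seq_len(n_tr)) {
    c0 <- (k - 0.5) * period
    x <- x + exp(-(t - c0 + off)^2 / (2 * sig^2)) -
             exp(-(t - c0 - off)^2 / (2 * sig^2))
  }
  ramp_n <- round(min(0.5, duration_s / 4) * sampling_rate)
  if (ramp_n > 0 && 2 * ramp_n <= n) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(ramp_n) / ramp_n))
    x[seq_len(ramp_n)] <- x[seq_len(ramp_n)] * ramp
    x[seq(n - ramp_n + 1, n)] <- x[seq(n - ramp_n + 1, n)] * rev(ramp)
  }
  pk <- max(abs(x))
  if (pk > 0) x <- x * (peak_amplitude_uv / pk)
  attr(x, "n_transients") <- n_tr
  x
}

# ---- truth layer -----------------------------------------------------------

# Post-period meanlog such that the >=min truncated lognormal mean scales by
# `mult` relative to (meanlog, sdlog).
shift_meanlog_for_multiplier <- function(meanlog, sdlog, min_s, mult) {
  target <- mult * truncated_lognorm_mean(meanlog, sdlog, min_s)
  f <- function(mu) truncated_lognorm_mean(mu, sdlog, min_s) - target
  uniroot(f, lower = meanlog + log(mult) - 3, upper = meanlog + log(mult) + 3,
          tol = 1e-10)$root
}

truncated_lognorm_mean <- function(meanlog, sdlog, min_s) {
  z <- (log(min_s) - meanlog) / sdlog
  exp(meanlog + sdlog^2 / 2) * pnorm(sdlog - z) / pnorm(-z)
}

rlnorm_truncated <- function(n, meanlog, sdlog, min_s) {
  lo <- pnorm((log(min_s) - meanlog) / sdlog)
  u <- runif(n, lo, 1)
  exp(meanlog + sdlog * qnorm(u))
}

#' Simulate cohort ground truth (no signal rendering)
#'
#' Draws per-animal baseline rates from a floored gamma mixture (giving
#' overdispersed, negative-binomial-like counts with between-animal SD of the
#' order of the mean), then paired pre/post counts coupled through the
#' baseline rate: a retained fraction of the baseline events persists into
#' the post period (binomial thinning with probability
#' `retention * min(m, 1)` for rate multiplier m) and the remainder of the
#' post-period rate, `(m - retention * min(m, 1))` times the baseline,
#' arrives as fresh events. The per-animal post/pre count ratio is thereby
#' centred on m with a spread far smaller than the between-animal count
#' spread, as the paired chronic-epilepsy design shows. Event
#' durations are lognormal truncated at the 3 s ictal minimum; the
#' post-period location parameter is solved so the truncated mean scales
#' exactly by the configured duration multiplier. Sub-3 s artifact bursts are
#' planted per session at `artifact_rate` with durations uniform on
#' `[0.5, 2.5]` s.
#'
#' All events are placed without overlap and with at least 3 s separation
#' inside their session.
#'
#' @param config A [cohort_config()].
#' @return List with `animals` (tibble: animal_id, group, baseline rate) and
#'   `events` (tibble of ground-truth events: animal_id, group, period,
#'   session, start_s, duration_s, rep_freq_hz, peak_amplitude_uv, racine,
#'   is_subthreshold).
#' @export
simulate_cohort_truth <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    animals <- list(); events <- list()
    hours <- config$sessions_per_period * config$session_hours
    for (g in config$groups) {
      eff <- config$effects[[g]]
      mu <- config$event_rate_mean[[g]]
      for (i in seq_len(config$n_per_group)) {
        id <- sprintf("%s_%02d", gsub("[^A-Za-z0-9]+", "", g), i)
        lam24 <- config$rate_floor * mu +
          rgamma(1, shape = config$event_rate_dispersion,
                 scale = (1 - config$rate_floor) * mu /
                   config$event_rate_dispersion)
        lam_obs <- lam24 * hours / 24
        n_pre <- rpois(1, lam_obs)
        m <- eff$rate_multiplier
        # coupled periods with partial turnover: a fraction of the baseline
        # event process persists (thinned to retention x m), the rest of the
        # post-period rate is fresh events
        surv <- config$retention * min(m, 1)
        n_post <- rbinom(1, n_pre, surv) + rpois(1, (m - surv) * lam_obs)
        animals[[id]] <- tibble::tibble(animal_id = id, group = g,
                                        baseline_rate_per24h = lam24)
        for (period in c("pre", "post")) {
          n_ev <- if (period == "pre") n_pre else n_post
          mult_d <- if (period == "pre") 1 else eff$duration_multiplier
          mult_a <- if (period == "pre") 1 else eff$amplitude_multiplier
          ml <- if (mult_d == 1) config$duration_lognorm[["meanlog"]]
                else shift_meanlog_for_multiplier(
                  config$duration_lognorm[["meanlog"]],
                  config$duration_lognorm[["sdlog"]],
                  config$min_ictal_s, mult_d)
          ev <- draw_period_events(config, id, g, period, n_ev, ml, mult_a)
          events[[paste(id, period)]] <- ev
        }
      }
    }
    ev <- dplyr::bind_rows(events)
    if (nrow(ev) > 0)
      ev <- ev[order(ev$animal_id, ev$period, ev$session, ev$start_s), ]
    list(animals = dplyr::bind_rows(animals), events = ev)
  })
}

# draw events + artifacts for one animal-period and pack them into sessions
draw_period_events <- function(config, id, group, period, n_ev, meanlog,
                               amp_mult) {
  sdlog <- config$duration_lognorm[["sdlog"]]
  sess_s <- config$session_hours * 3600
  n_sess <- config$sessions_per_period
  amp_scale <- config$event_snr * config$background_rms * amp_mult
  rows <- list()
  if (n_ev > 0) {
    dur <- rlnorm_truncated(n_ev, meanlog, sdlog, config$min_ictal_s)
    sess <- sample.int(n_sess, n_ev, replace = TRUE)
    rows$ictal <- tibble::tibble(
      animal_id = id, group = group, period = period, session = sess,
      duration_s = dur,
      rep_freq_hz = runif(n_ev, 2, 20),
      peak_amplitude_uv = amp_scale * exp(rnorm(n_ev, 0,
                                                config$amplitude_jitter_sdlog)),
      racine = sample.int(5, n_ev, replace = TRUE,
                          prob = config$racine_weights),
      is_subthreshold = FALSE)
  }
  n_art <- rpois(1, config$artifact_rate * config$session_hours * n_sess)
  if (n_art > 0) {
    rows$artifact <- tibble::tibble(
      animal_id = id, group = group, period = period,
      session = sample.int(n_sess, n_art, replace = TRUE),
      duration_s = runif(n_art, 0.5, 2.5),
      rep_freq_hz = runif(n_art, 2, 20),
      peak_amplitude_uv = amp_scale * config$artifact_snr_fraction *
        exp(rnorm(n_art, 0, config$amplitude_jitter_sdlog)),
      racine = NA_integer_,
      is_subthreshold = TRUE)
  }
  ev <- dplyr::bind_rows(rows)
  if (nrow(ev) == 0) return(ev)
  ev$start_s <- NA_real_
  for (s in unique(ev$session)) {
    idx <- which(ev$session == s)
    ev$start_s[idx] <- pack_intervals(ev$duration_s[idx], sess_s, margin = 3)
  }
  ev
}

# place intervals of given durations uniformly in [0, total) without overlap,
# keeping `margin` seconds between intervals and to the session edges;
# resamples colliding starts, errors out when packing is impossible
pack_intervals <- function(durations, total, margin = 3, max_tries = 200) {
  k <- length(durations)
  if (sum(durations + margin) + margin > total)
    stop_invalid("cannot pack %d events (%.0f s) into a %.0f s session",
                 k, sum(durations), total)
  ord <- order(durations, decreasing = TRUE)   # place long events first
  starts <- numeric(k)
  placed_lo <- numeric(0); placed_hi <- numeric(0)
  for (j in ord) {
    d <- durations[j]
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      s0 <- runif(1, margin, total - d - margin)
      if (!any(s0 < placed_hi + margin & s0 + d + margin > placed_lo)) {
        ok <- TRUE; break
      }
    }
    if (!ok) stop_invalid("event packing failed after %d retries", max_tries)
    starts[j] <- s0
    placed_lo <- c(placed_lo, s0); placed_hi <- c(placed_hi, s0 + d)
  }
  starts
}

#' Render one session's EEG record from ground truth
#'
#' Background (1/f) noise plus the planted ictal and artifact waveforms of
#' that session. Waveform peak amplitudes are set so the waveform RMS over
#' the event equals the event's `peak_amplitude_uv` scale (see
#' [cohort_config()] `event_snr`). Rendering is deterministic: the session
#' seed is derived from the configuration seed and the session coordinates.
#'
#' @param truth Output of [simulate_cohort_truth()].
#' @param config The same [cohort_config()].
#' @param animal_id,period,session Session coordinates.
#' @return An [eeg_record()].
#' @export
render_session <- function(truth, config, animal_id, period, session) {
  stopifnot(inherits(config, "cohort_config"))
  fs <- config$sampling_rate
  n <- round(config$session_hours * 3600 * fs)
  seed <- derive_seed(config$seed, match(animal_id, truth$animals$animal_id),
                      match(period, c("pre", "post")), session)
  ev <- truth$events[truth$events$animal_id == animal_id &
                     truth$events$period == period &
                     truth$events$session == session, , drop = FALSE]
  with_seed(seed, {
    x <- generate_background(config$session_hours * 3600, fs,
                             config$background_rms)
    for (r in seq_len(nrow(ev))) {
      w <- synth_ictal_waveform(ev$duration_s[r], ev$rep_freq_hz[r],
                                peak_amplitude_uv = 1, sampling_rate = fs,
                                ictal = !ev$is_subthreshold[r])
      w <- as.numeric(w)
      wr <- rms(w)
      if (wr > 0) w <- w * (ev$peak_amplitude_uv[r] / wr)
      i0 <- round(ev$start_s[r] * fs) + 1
      idx <- i0:min(i0 + length(w) - 1, n)
      x[idx] <- x[idx] + w[seq_along(idx)]
    }
    eeg_record(x, fs, animal_id = animal_id, period = period,
               session = session)
  })
}

#' Generate a full synthetic cohort
#'
#' Convenience wrapper: simulates ground truth and renders every session
#' record. Memory scales with
#' `groups x animals x 2 x sessions x session_hours x sampling_rate`;
#' for cohort-scale analyses prefer [run_cohort_pipeline()], which renders
#' and detects one session at a time and only keeps events.
#'
#' @param config A [cohort_config()].
#' @return List with `records` (list of [eeg_record()]), `truth` (see
#'   [simulate_cohort_truth()]).
#' @export
generate_cohort <- function(config) {
  truth <- simulate_cohort_truth(config)
  records <- list()
  for (id in truth$animals$animal_id)
    for (period in c("pre", "post"))
      for (s in seq_len(config$sessions_per_period))
        records[[sprintf("%s_%s_%d", id, period, s)]] <-
          render_session(truth, config, id, period, s)
  list(records = records, truth = truth)
}
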