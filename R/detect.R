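#' Single-channel EEG record
#'
#' @param samples Numeric vector of samples in uV (finite).
#' @param sampling_rate Sampling rate in Hz (> 40, so the 2-20 Hz ictal band
#'   is resolved with margin).
#' @param animal_id,period,session,start_time Provenance labels; `period` is
#'   `"pre"` or `"post"`, `start_time` is seconds from session start.
#' @return An object of class `eeg_record`.
#' @export
eeg_record <- function(samples, sampling_rate, animal_id = NA_character_,
                       period = NA_character_, session = NA_integer_,
                       start_time = 0) {
  if (!is.numeric(samples) || any(!is.finite(samples)))
    stop_invalid("samples must be finite numeric")
  assert_scalar_num(sampling_rate, "sampling_rate", lower = 40,
                    strict_lower = TRUE)
  if (!is.na(period) && !period %in% c("pre", "post"))
    stop_invalid("period must be 'pre' or 'post'")
  structure(list(samples = as.numeric(samples),
                 sampling_rate = sampling_rate,
                 animal_id = animal_id, period = period,
                 session = as.integer(session), start_time = start_time),
            class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> %s/%s session %s: %.1f s at %g Hz (RMS %.1f uV)\n",
              x$animal_id, x$period, x$session,
              length(x$samples) / x$sampling_rate, x$sampling_rate,
              rms(x$samples)))
  invisible(x)
}

#' Ictal-event detector configuration
#'
#' Operationalizes the screening rule "repetitive 2-20 Hz sharp waves whose
#' amplitude deviates from the inter-ictal background, lasting at least 3 s"
#' as: band-pass to `band`, sliding-window RMS envelope, robust threshold at
#' `median + threshold_k * MAD`, merging of close candidates, and a hard
#' minimum duration.
#'
#' @param band `c(low, high)` pass band in Hz (default 2-20).
#' @param envelope_window RMS window, s.
#' @param envelope_step Envelope step, s.
#' @param threshold_k Threshold in MAD multiples above the median envelope.
#' @param merge_gap Candidates closer than this gap (s) are merged.
#' @param min_duration Minimum event duration, s; shorter candidates are
#'   discarded (never reported).
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(band = c(2, 20), envelope_window = 0.5,
                            envelope_step = 0.1, threshold_k = 5,
                            merge_gap = 1.0, min_duration = 3.0) {
  stopifnot(length(band) == 2, band[1] > 0, band[2] > band[1])
  assert_scalar_num(envelope_window, "envelope_window", 0, strict_lower = TRUE)
  assert_scalar_num(envelope_step, "envelope_step", 0, strict_lower = TRUE)
  assert_scalar_num(threshold_k, "threshold_k", 0, strict_lower = TRUE)
  assert_scalar_num(merge_gap, "merge_gap", lower = 0)
  assert_scalar_num(min_duration, "min_duration", 0, strict_lower = TRUE)
  structure(list(band = as.numeric(band), envelope_window = envelope_window,
                 envelope_step = envelope_step, threshold_k = threshold_k,
                 merge_gap = merge_gap, min_duration = min_duration),
            class = "detector_config")
}

#' Zero-phase band-pass filter
#'
#' Applies an order-4 Butterworth magnitude response in the frequency domain
#' (exactly zero phase; the DC component is removed by construction).
#'
#' @param record An [eeg_record()].
#' @param band `c(low, high)` in Hz, strictly inside Nyquist.
#' @return A filtered copy of the record.
#' @export
eeg_bandpass <- function(record, band = c(2, 20)) {
  stopifnot(inherits(record, "eeg_record"))
  fs <- record$sampling_rate
  if (band[2] >= fs / 2 || band[1] <= 0 || band[1] >= band[2])
    stop_invalid("band must satisfy 0 < low < high < sampling_rate/2")
  x <- record$samples
  n <- length(x)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n           # folded frequency axis
  ord <- 4
  lp <- 1 / sqrt(1 + (f / band[2])^(2 * ord))
  hp <- ifelse(f > 0, 1 / sqrt(1 + (band[1] / pmax(f, 1e-300))^(2 * ord)), 0)
  record$samples <- Re(fft(fft(x) * (lp * hp), inverse = TRUE)) / n
  record
}

#' Sliding-window RMS envelope
#'
#' @param record An [eeg_record()] (normally band-passed first).
#' @param window Window length, s.
#' @param step Step between windows, s.
#' @return Tibble with `time` (window centre, s from record start) and `rms`
#'   (uV); `floor((n - window) / step) + 1` rows (in samples).
#' @export
eeg_envelope <- function(record, window = 0.5, step = 0.1) {
  stopifnot(inherits(record, "eeg_record"))
  fs <- record$sampling_rate
  wn <- round(window * fs)
  sn <- max(1L, round(step * fs))
  n <- length(record$samples)
  if (wn > n) stop_invalid("envelope window (%g s) exceeds record length", window)
  if (wn < 2) stop_invalid("envelope window too short for the sampling rate")
  m <- (n - wn) %/% sn + 1
  cs <- cumsum(c(0, record$samples^2))
  idx <- (seq_len(m) - 1) * sn
  tibble::tibble(
    time = record$start_time + (idx + wn / 2) / fs,
    rms = sqrt((cs[idx + wn + 1] - cs[idx + 1]) / wn))
}

#' Detect ictal events in an EEG record
#'
#' Band-passes the record, computes the RMS envelope, thresholds it at
#' `median + threshold_k * MAD`, merges candidate runs separated by less than
#' `merge_gap`, discards candidates shorter than `min_duration`, and locates
#' boundaries at the interpolated outer threshold crossings. The amplitude
#' statistic of each event (time-averaged rectified amplitude, see
#' [ictal_amplitude()]) is computed on the band-passed trace.
#'
#' The threshold is derived from the record itself, so detections are
#' invariant to rescaling the record by any positive gain.
#'
#' @param record An [eeg_record()].
#' @param config A [detector_config()].
#' @return Tibble of events: `animal_id`, `period`, `session`, `start_s`,
#'   `duration_s`, `amplitude_uv`, `peak_envelope_uv`; sorted,
#'   non-overlapping, all durations `>= min_duration`.
#' @export
detect_events <- function(record, config = detector_config()) {
  stopifnot(inherits(record, "eeg_record"), inherits(config, "detector_config"))
  n <- length(record$samples)
  fs <- record$sampling_rate
  if (n / fs <= config$min_duration)
    stop_invalid("record (%.1f s) not longer than min_duration", n / fs)
  filt <- eeg_bandpass(record, config$band)
  env <- eeg_envelope(filt, config$envelope_window, config$envelope_step)
  if (nrow(env) < 3) stop_invalid("envelope too short for detection")
  thr <- median(env$rms) + config$threshold_k * mad(env$rms)
  runs <- supra_runs(env$time, env$rms, thr)
  runs <- merge_runs(runs, config$merge_gap)
  empty <- tibble::tibble(animal_id = character(), period = character(),
                          session = integer(), start_s = numeric(),
                          duration_s = numeric(), amplitude_uv = numeric(),
                          peak_envelope_uv = numeric())
  if (nrow(runs) == 0) return(empty)
  runs <- runs[runs$end - runs$start >= config$min_duration, , drop = FALSE]
  if (nrow(runs) == 0) return(empty)
  amp <- numeric(nrow(runs))
  for (r in seq_len(nrow(runs))) {
    i0 <- max(1, round((runs$start[r] - record$start_time) * fs) + 1)
    i1 <- min(n, round((runs$end[r] - record$start_time) * fs))
    amp[r] <- ictal_amplitude(filt$samples[i0:i1], fs)
  }
  tibble::tibble(animal_id = record$animal_id, period = record$period,
                 session = record$session, start_s = runs$start,
                 duration_s = runs$end - runs$start, amplitude_uv = amp,
                 peak_envelope_uv = runs$peak)
}

# contiguous supra-threshold runs of the envelope with interpolated
# outer crossings
supra_runs <- function(time, env, thr) {
  above <- env > thr
  if (!any(above)) return(data.frame(start = numeric(), end = numeric(),
                                     peak = numeric()))
  d <- diff(c(FALSE, above, FALSE))
  first <- which(d == 1)
  last <- which(d == -1) - 1
  start <- end <- peak <- numeric(length(first))
  for (j in seq_along(first)) {
    i0 <- first[j]; i1 <- last[j]
    start[j] <- if (i0 > 1)
      time[i0 - 1] + (time[i0] - time[i0 - 1]) *
        (thr - env[i0 - 1]) / (env[i0] - env[i0 - 1])
    else time[1]
    end[j] <- if (i1 < length(env))
      time[i1] + (time[i1 + 1] - time[i1]) *
        (env[i1] - thr) / (env[i1] - env[i1 + 1])
    else time[length(env)]
    peak[j] <- max(env[i0:i1])
  }
  data.frame(start = start, end = end, peak = peak)
}

merge_runs <- function(runs, gap) {
  if (nrow(runs) < 2) return(runs)
  out <- runs[1, ]
  for (j in 2:nrow(runs)) {
    k <- nrow(out)
    if (runs$start[j] - out$end[k] < gap) {
      out$end[k] <- runs$end[j]
      out$peak[k] <- max(out$peak[k], runs$peak[j])
    } else out <- rbind(out, runs[j, ])
  }
  out
}

#' Match detected events against ground truth
#'
#' Greedy one-to-one matching by descending overlap fraction
#' (intersection / shorter-interval duration), with ties broken by the
#' smaller start-boundary error. Pairs below `min_overlap` are not matched:
#' unmatched truths are misses, unmatched detections false positives.
#'
#' @param truth Data frame of ground-truth intervals with `start_s`,
#'   `duration_s` (sub-threshold artifact rows should be excluded upstream).
#' @param detected Data frame of detections with `start_s`, `duration_s`.
#' @param min_overlap Minimum overlap fraction for a match.
#' @return List with `matches` (tibble: truth_idx, detected_idx,
#'   overlap_fraction, boundary_error_start_s, boundary_error_end_s) and
#'   `summary` (sensitivity, fdr, n_truth, n_detected, boundary-error
#'   quantiles).
#' @export
match_events <- function(truth, detected, min_overlap = 0.5) {
  t_start <- truth$start_s; t_end <- truth$start_s + truth$duration_s
  if (length(t_start) > 1) {
    o <- order(t_start)
    if (any(t_start[o][-1] < t_end[o][-length(o)] - 1e-9))
      stop_invalid("ground-truth events overlap")
  }
  d_start <- detected$start_s; d_end <- detected$start_s + detected$duration_s
  nt <- length(t_start); nd <- length(d_start)
  pairs <- NULL
  if (nt > 0 && nd > 0) {
    grid <- expand.grid(ti = seq_len(nt), di = seq_len(nd))
    inter <- pmax(0, pmin(t_end[grid$ti], d_end[grid$di]) -
                     pmax(t_start[grid$ti], d_start[grid$di]))
    ov <- inter / pmin(t_end[grid$ti] - t_start[grid$ti],
                       d_end[grid$di] - d_start[grid$di])
    keep <- ov >= min_overlap
    pairs <- data.frame(ti = grid$ti[keep], di = grid$di[keep],
                        ov = ov[keep],
                        serr = abs(d_start[grid$di[keep]] -
                                   t_start[grid$ti[keep]]))
    pairs <- pairs[order(-pairs$ov, pairs$serr), ]
  }
  used_t <- logical(nt); used_d <- logical(nd)
  m <- list()
  for (r in seq_len(NROW(pairs))) {
    ti <- pairs$ti[r]; di <- pairs$di[r]
    if (used_t[ti] || used_d[di]) next
    used_t[ti] <- TRUE; used_d[di] <- TRUE
    m[[length(m) + 1]] <- tibble::tibble(
      truth_idx = ti, detected_idx = di, overlap_fraction = pairs$ov[r],
      boundary_error_start_s = d_start[di] - t_start[ti],
      boundary_error_end_s = d_end[di] - t_end[ti])
  }
  matches <- if (length(m)) dplyr::bind_rows(m) else
    tibble::tibble(truth_idx = integer(), detected_idx = integer(),
                   overlap_fraction = numeric(),
                   boundary_error_start_s = numeric(),
                   boundary_error_end_s = numeric())
  berr <- c(abs(matches$boundary_error_start_s),
            abs(matches$boundary_error_end_s))
  list(matches = matches,
       summary = list(
         sensitivity = if (nt > 0) nrow(matches) / nt else NA_real_,
         fdr = if (nd > 0) (nd - nrow(matches)) / nd else NA_real_,
         n_truth = nt, n_detected = nd,
         boundary_error_q = if (length(berr))
           quantile(berr, c(0.5, 0.9, 0.95)) else
           setNames(rep(NA_real_, 3), c("50%", "90%", "95%"))))
}
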