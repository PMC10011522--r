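#' Time-averaged rectified amplitude of an ictal segment
#'
#' Area under the rectified trace divided by the segment duration,
#' \eqn{(1/T)\int |x(t)|\,dt}, computed with the trapezoid rule at native
#' sampling. For a constant \eqn{|x| = A} this returns A; for a sinusoid of
#' amplitude A over whole periods it approaches \eqn{2A/\pi}.
#'
#' @param segment Numeric vector of samples (uV) spanning the event.
#' @param sampling_rate Sampling rate in Hz.
#' @return Amplitude in uV (sign-invariant, linear in signal gain).
#' @examples
#' ictal_amplitude(rep(100, 500), 500) # 100
#' @export
ictal_amplitude <- function(segment, sampling_rate) {
  if (length(segment) == 0) stop_invalid("empty segment")
  assert_scalar_num(sampling_rate, "sampling_rate", 0, strict_lower = TRUE)
  if (length(segment) == 1) return(abs(segment))
  a <- abs(segment)
  n <- length(a)
  (sum(a) - (a[1] + a[n]) / 2) / (n - 1)   # trapezoid AUC / T
}

#' Per-animal, per-period seizure indices
#'
#' The three indices summarizing one animal's recording period: the count of
#' ictal events, the mean ictal duration per event, and the mean ictal
#' amplitude per event. Periods without events keep count 0 and flagged
#' (`NA`) means.
#'
#' @param events Data frame of events with columns `animal_id`, `period`,
#'   `duration_s`, `amplitude_uv` (detected events or ground truth), and
#'   optionally `group`.
#' @param hours_observed Observation time per period in hours (> 0).
#' @param animals Optional data frame with `animal_id` (and optionally
#'   `group`) defining the full set of animals; the output covers every
#'   animal x period cell, so periods in which an animal had no events get
#'   an explicit zero-count row. Defaults to the animals present in `events`.
#' @param periods Periods to cover (default both `"pre"` and `"post"`).
#' @return Tibble with one row per animal x period: `ictal_count`,
#'   `ictal_duration_per_event_s`, `ictal_amplitude_per_event_uv`,
#'   `hours_observed`.
#' @export
compute_indices <- function(events, hours_observed, animals = NULL,
                            periods = c("pre", "post")) {
  assert_scalar_num(hours_observed, "hours_observed", 0, strict_lower = TRUE)
  stopifnot(all(c("animal_id", "period", "duration_s") %in% names(events)))
  if (!"amplitude_uv" %in% names(events)) events$amplitude_uv <- NA_real_
  if (is.null(animals))
    animals <- unique(events[c("animal_id", intersect("group", names(events)))])
  out <- list()
  for (r in seq_len(nrow(animals))) for (p in periods) {
    sel <- events$animal_id == animals$animal_id[r] & events$period == p
    ev <- events[sel, ]
    out[[length(out) + 1]] <- tibble::tibble(
      animals[r, , drop = FALSE], period = p,
      ictal_count = nrow(ev),
      ictal_duration_per_event_s = if (nrow(ev)) mean(ev$duration_s) else NA_real_,
      ictal_amplitude_per_event_uv = if (nrow(ev)) mean(ev$amplitude_uv) else NA_real_,
      hours_observed = hours_observed)
  }
  dplyr::bind_rows(out)
}

#' Post/pre normalized seizure indices
#'
#' Each animal's post-intervention indices divided by its own
#' pre-intervention indices (never group means of raw indices), with percent
#' changes `100 * (ratio - 1)`. Ratios are undefined (`NA`) when the
#' pre-period index is zero or missing; such animals are excluded per index
#' from downstream group statistics, with a message.
#'
#' @param indices Tibble from [compute_indices()] covering both periods
#'   (optionally with a `group` column, carried through).
#' @return Tibble with one row per animal: `count_ratio`, `duration_ratio`,
#'   `amplitude_ratio` and `count_change_pct`, `duration_change_pct`,
#'   `amplitude_change_pct`.
#' @export
normalize_indices <- function(indices) {
  stopifnot(all(c("animal_id", "period", "ictal_count") %in% names(indices)))
  ids <- unique(indices$animal_id)
  out <- lapply(ids, function(id) {
    pre <- indices[indices$animal_id == id & indices$period == "pre", ]
    post <- indices[indices$animal_id == id & indices$period == "post", ]
    ratio <- function(field) {
      if (nrow(pre) == 0 || nrow(post) == 0) return(NA_real_)
      a <- post[[field]]; b <- pre[[field]]
      if (is.na(a) || is.na(b) || b == 0) NA_real_ else a / b
    }
    tibble::tibble(
      animal_id = id,
      group = if ("group" %in% names(indices))
        indices$group[indices$animal_id == id][1] else NA_character_,
      count_ratio = ratio("ictal_count"),
      duration_ratio = ratio("ictal_duration_per_event_s"),
      amplitude_ratio = ratio("ictal_amplitude_per_event_uv"))
  })
  norm <- dplyr::bind_rows(out)
  for (f in c("count", "duration", "amplitude"))
    norm[[paste0(f, "_change_pct")]] <- 100 * (norm[[paste0(f, "_ratio")]] - 1)
  n_excl <- colSums(is.na(norm[c("count_ratio", "duration_ratio",
                                 "amplitude_ratio")]))
  if (any(n_excl > 0))
    message(sprintf(
      "normalize_indices: undefined ratios excluded per index (count %d, duration %d, amplitude %d)",
      n_excl[1], n_excl[2], n_excl[3]))
  norm
}

#' Racine-scale tallies
#'
#' Counts partial (modified Racine scale 1-2) and tonic-clonic (scale 3-5)
#' events per animal and period. Unlabelled events are tallied separately
#' with a warning; Racine labels are annotations (ground truth or video
#' review), never inferred from the EEG.
#'
#' @param events Data frame with `animal_id`, `period`, `racine`.
#' @return Tibble per animal x period: `partial_count`,
#'   `tonic_clonic_count`, `unknown_count`.
#' @export
racine_tally <- function(events) {
  stopifnot(all(c("animal_id", "period", "racine") %in% names(events)))
  if (any(is.na(events$racine)))
    warning("events without Racine labels tallied as unknown")
  if (any(!is.na(events$racine) & !(events$racine %in% 1:5)))
    stop_invalid("Racine labels must be integers 1-5 or NA")
  keys <- unique(events[c("animal_id", "period")])
  out <- lapply(seq_len(nrow(keys)), function(r) {
    ev <- events[events$animal_id == keys$animal_id[r] &
                 events$period == keys$period[r], ]
    tibble::tibble(keys[r, ],
                   partial_count = sum(ev$racine %in% 1:2),
                   tonic_clonic_count = sum(ev$racine %in% 3:5),
                   unknown_count = sum(is.na(ev$racine)))
  })
  dplyr::bind_rows(out)
}
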