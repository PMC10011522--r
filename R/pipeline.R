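#' Run the full cohort analysis pipeline
#'
#' Generate -> detect -> indices -> normalize, one session at a time so only
#' events are kept in memory: simulates cohort ground truth, renders each
#' session's EEG, runs the ictal-event detector on it, accumulates detected
#' events, computes per-animal seizure indices for both periods, and
#' normalizes them post/pre. Also matches detections against the planted
#' ground truth to report detector performance.
#'
#' @param config A [cohort_config()].
#' @param det A [detector_config()].
#' @param progress Print one line per animal.
#' @return List: `truth` (ground truth), `events` (detected events tibble),
#'   `indices` (per animal x period), `normalized` (per animal),
#'   `detection` (sensitivity, fdr, n_truth, n_detected pooled over the
#'   cohort).
#' @export
run_cohort_pipeline <- function(config = cohort_config(),
                                det = detector_config(),
                                progress = FALSE) {
  stopifnot(inherits(config, "cohort_config"),
            inherits(det, "detector_config"))
  truth <- simulate_cohort_truth(config)
  detected <- list()
  n_match <- 0L; n_truth <- 0L; n_det <- 0L
  for (a in seq_len(nrow(truth$animals))) {
    id <- truth$animals$animal_id[a]
    grp <- truth$animals$group[a]
    for (period in c("pre", "post")) {
      for (s in seq_len(config$sessions_per_period)) {
        rec <- render_session(truth, config, id, period, s)
        ev <- detect_events(rec, det)
        tr <- truth$events[truth$events$animal_id == id &
                           truth$events$period == period &
                           truth$events$session == s &
                           !truth$events$is_subthreshold, , drop = FALSE]
        mm <- match_events(tr, ev)
        n_match <- n_match + nrow(mm$matches)
        n_truth <- n_truth + mm$summary$n_truth
        n_det <- n_det + mm$summary$n_detected
        if (nrow(ev) > 0) {
          ev$group <- grp
          detected[[length(detected) + 1]] <- ev
        }
      }
    }
    if (progress)
      message(sprintf("animal %s (%s): done", id, grp))
  }
  events <- dplyr::bind_rows(detected)
  hours <- config$sessions_per_period * config$session_hours
  indices <- compute_indices(events, hours_observed = hours,
                             animals = truth$animals[c("animal_id", "group")])
  normalized <- normalize_indices(indices)
  list(truth = truth, events = events, indices = indices,
       normalized = normalized,
       detection = list(sensitivity = if (n_truth) n_match / n_truth else NA,
                        fdr = if (n_det) (n_det - n_match) / n_det else NA,
                        n_truth = n_truth, n_detected = n_det))
}

#' Per-group mean normalized index changes
#'
#' Convenience summary of a pipeline run: the group means (and SDs) of the
#' per-animal percent changes in the three seizure indices.
#'
#' @param normalized Tibble from [normalize_indices()] with `group`.
#' @return Tibble: `group`, `index`, `n`, `mean_change_pct`, `sd_change_pct`.
#' @export
summarize_group_changes <- function(normalized) {
  fields <- c(count = "count_change_pct", duration = "duration_change_pct",
              amplitude = "amplitude_change_pct")
  out <- list()
  for (g in unique(normalized$group)) for (f in names(fields)) {
    v <- normalized[[fields[[f]]]][normalized$group == g]
    v <- v[is.finite(v)]
    out[[length(out) + 1]] <- tibble::tibble(
      group = g, index = f, n = length(v),
      mean_change_pct = mean(v), sd_change_pct = sd(v))
  }
  dplyr::bind_rows(out)
}
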