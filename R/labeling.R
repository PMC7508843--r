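#' Prediction horizons analysed by the package
#'
#' Seven windows, 3 to 21 months in 3-month steps; one model is trained per
#' horizon.
#' @return integer vector.
#' @export
default_horizons <- function() seq(3L, 21L, by = 3L)

#' Build per-eye histories from a visit table
#'
#' Splits the canonical visit table by eye, orders visits by month, finds the
#' event month (the minimum of first exudative diagnosis and first
#' treatment), and keeps only the dry, untreated observations strictly before
#' the event. Dry rows recorded after an event (a data error in real exports)
#' are dropped and counted in attribute `n_dropped_post_event`.
#'
#' @param visits data.frame with at least `patient_id`, `eye_id`, `month`,
#'   `dx_status`, `treated` and the feature columns.
#' @param study_end optional study length in months (metadata only).
#' @return named list of `eye_history` objects: each has `eye_id`,
#'   `patient_id`, `visits` (ordered dry rows), `event_month` (NA when
#'   censored at study end) and `last_dry_followup_month`.
#' @export
eye_histories <- function(visits, study_end = NULL) {
  assert_that(
    all(c("eye_id", "month", "dx_status", "treated") %in% names(visits)),
    "visit table must have eye_id, month, dx_status, treated"
  )
  out <- list()
  dropped <- 0L
  for (eid in unique(visits$eye_id)) {
    v <- visits[visits$eye_id == eid, , drop = FALSE]
    v <- v[order(v$month), , drop = FALSE]
    assert_that(!anyDuplicated(v$month),
                sprintf("eye %s has duplicate visit months (average same-session scans first)", eid))
    is_event <- v$dx_status == "exudative" | as.logical(v$treated)
    event_month <- if (any(is_event)) min(v$month[is_event]) else NA_real_
    dry <- v[!is_event, , drop = FALSE]
    if (!is.na(event_month)) {
      post <- dry$month >= event_month
      dropped <- dropped + sum(post)
      dry <- dry[!post, , drop = FALSE]
    }
    out[[eid]] <- structure(
      list(
        eye_id = eid,
        patient_id = if ("patient_id" %in% names(v)) v$patient_id[1] else eid,
        visits = dry,
        event_month = event_month,
        last_dry_followup_month = if (nrow(dry)) max(dry$month) else NA_real_,
        study_end = study_end
      ),
      class = "eye_history"
    )
  }
  attr(out, "n_dropped_post_event") <- dropped
  out
}

#' Label one observation for one prediction horizon
#'
#' An observation at month `t` for horizon `k` is a *progressor* (1) if the
#' eye's event falls within `(t, t + k]` (a tie at exactly `t + k` counts as
#' within); a *non-progressor* (0) if no event occurred within `k` months
#' *and* a later dry observation of the same eye exists strictly beyond
#' `t + k` (certainty of no event over the whole window); otherwise
#' *censored* — the window runs past the last information available, so the
#' ground truth is uncertain and the observation is excluded for that
#' horizon.
#'
#' @param history an `eye_history`.
#' @param obs_month month of a dry observation of that eye.
#' @param horizon_k horizon in months.
#' @return one of `"progressor"`, `"non_progressor"`, `"censored"`.
#' @export
label_observation <- function(history, obs_month, horizon_k) {
  stopifnot(inherits(history, "eye_history"))
  assert_that(is_scalar_num(obs_month) && is_scalar_num(horizon_k) &&
                horizon_k > 0, "obs_month and horizon_k must be scalars")
  ev <- history$event_month
  if (!is.na(ev) && obs_month >= ev) {
    stop_drusenseq("obs_month is at/after the exudation event",
                   "drusenseq_invalid")
  }
  if (!any(abs(history$visits$month - obs_month) < 1e-9)) {
    stop_drusenseq("obs_month is not a dry observation of this eye",
                   "drusenseq_invalid")
  }
  if (!is.na(ev) && ev - obs_month <= horizon_k) return("progressor")
  if (any(history$visits$month > obs_month + horizon_k)) {
    return("non_progressor")
  }
  "censored"
}

label_code <- c(non_progressor = 0L, progressor = 1L, censored = 2L)

#' Label every dry observation of a cohort for every horizon
#'
#' @param histories list of `eye_history` (or a `cohort`).
#' @param horizons integer vector of horizons in months.
#' @return list of `labeled_sequence` objects (eyes with no dry observation
#'   are skipped with a message): each has `eye_id`, `patient_id`, `visits`
#'   (ordered dry rows with features), `obs_months`, and `labels`, an
#'   `n_obs x n_horizons` integer matrix coded 0 = non-progressor,
#'   1 = progressor, 2 = censored.
#' @export
build_labeled_sequences <- function(histories, horizons = default_horizons()) {
  if (inherits(histories, "cohort")) histories <- histories$histories
  out <- list()
  for (h in histories) {
    if (nrow(h$visits) == 0L) {
      message("eye ", h$eye_id,
              ": no dry observation before the event; dropped")
      next
    }
    labs <- matrix(
      NA_integer_, nrow(h$visits), length(horizons),
      dimnames = list(NULL, paste0("h", horizons))
    )
    for (j in seq_along(horizons)) {
      labs[, j] <- label_code[vapply(
        h$visits$month, label_observation,
        "", history = h, horizon_k = horizons[j]
      )]
    }
    out[[h$eye_id]] <- structure(
      list(
        eye_id = h$eye_id, patient_id = h$patient_id,
        visits = h$visits, obs_months = h$visits$month,
        labels = labs, horizons = horizons
      ),
      class = "labeled_sequence"
    )
  }
  out
}

#' Per-horizon outcome counts
#'
#' The per-horizon distribution of progressor / non-progressor / censored
#' observation counts (the study-flowchart bar-chart summary).
#'
#' @param sequences output of [build_labeled_sequences()].
#' @return data.frame with columns `horizon`, `progressor`, `non_progressor`,
#'   `censored`, `total_labeled`.
#' @export
label_counts <- function(sequences) {
  stopifnot(length(sequences) > 0)
  horizons <- sequences[[1]]$horizons
  counts <- t(vapply(seq_along(horizons), function(j) {
    v <- unlist(lapply(sequences, function(s) s$labels[, j]))
    c(sum(v == 1L), sum(v == 0L), sum(v == 2L))
  }, numeric(3)))
  data.frame(
    horizon = horizons,
    progressor = counts[, 1], non_progressor = counts[, 2],
    censored = counts[, 3],
    total_labeled = counts[, 1] + counts[, 2]
  )
}

#' Drop low-signal-strength scans
#'
#' Simple upstream quality filter: removes visit rows whose
#' `signal_strength` column falls below the cutoff (device scale 0-10).
#' Rows are kept when the column is absent.
#'
#' @param visits visit data.frame.
#' @param min_signal cutoff, default 7.
#' @return filtered data.frame.
#' @export
filter_signal_strength <- function(visits, min_signal = 7) {
  if (!"signal_strength" %in% names(visits)) return(visits)
  visits[is.na(visits$signal_strength) |
           visits$signal_strength >= min_signal, , drop = FALSE]
}
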